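#' Derivative log ratio standard deviation (DLRSD)
#'
#' Probe-to-probe noise of a hybridization: the spread of consecutive-probe
#' log2 differences divided by sqrt(2).  Differencing doubles the variance of
#' independent probe noise, so the normalisation makes DLRSD an estimate of
#' the per-probe noise sd, while true copy-number structure (which is locally
#' constant) contributes almost nothing.  Probes are taken in genome order;
#' pairs spanning a chromosome boundary are excluded and missing values are
#' dropped before pairing.
#'
#' @param hyb a \code{hybridization} (or a bare numeric vector of log2
#'   values aligned to \code{probe_map}).
#' @param probe_map the \code{probe_map} the profile is aligned to.
#' @param robust if TRUE, use the IQR-based spread (IQR/1.349) of the
#'   differences instead of the plain standard deviation.
#' @return the DLRSD value (dimensionless, >= 0).
#' @examples
#' pm <- design_probe_map(build_genome(preset = "toy"), seed = 1)
#' hyb <- simulate_hybridization(pm, noise_sd = 0.14, seed = 1)
#' compute_dlrsd(hyb, pm)
#' @export
compute_dlrsd <- function(hyb, probe_map, robust = FALSE) {
  log2v <- if (inherits(hyb, "hybridization")) hyb$log2 else as.numeric(hyb)
  if (length(log2v) != nrow(probe_map))
    stop("profile length does not match the probe map")
  diffs <- unlist(lapply(split(log2v, factor(probe_map$chrom,
                                             unique(probe_map$chrom))),
                         function(v) {
                           v <- v[!is.na(v)]
                           if (length(v) > 1) diff(v) else numeric()
                         }), use.names = FALSE)
  if (length(diffs) < 1L)
    stop("need at least 2 usable probes on some chromosome")
  spread <- if (robust) stats::IQR(diffs) / (2 * stats::qnorm(0.75))
  else stats::sd(diffs)
  spread / sqrt(2)
}

#' Classify hybridization quality from DLRSD
#'
#' Bands follow the platform convention: below 0.2 is excellent, 0.2 to 0.3
#' inclusive is good, above 0.3 is poor.
#'
#' @param dlrsd DLRSD value(s), >= 0.
#' @return character vector: "excellent", "good" or "poor".
#' @export
classify_quality <- function(dlrsd) {
  if (any(dlrsd < 0)) stop("DLRSD cannot be negative")
  ifelse(dlrsd < 0.2, "excellent", ifelse(dlrsd <= 0.3, "good", "poor"))
}

#' Platform false discovery rate from a self-to-self hybridization
#'
#' In a self-to-self hybridization (same DNA in both channels) every CNV
#' call is a false positive.  The platform FDR is the number of self-to-self
#' calls as a percentage of the total calls across all experiments.
#'
#' @param n_self_calls CNV calls made in the self-to-self hybridization.
#' @param n_total_calls total CNV calls across all experiments (> 0).
#' @return FDR in percent.
#' @export
self_to_self_fdr <- function(n_self_calls, n_total_calls) {
  if (n_total_calls <= 0) stop("'n_total_calls' must be positive")
  if (n_self_calls < 0 || n_self_calls > n_total_calls)
    stop("need 0 <= n_self_calls <= n_total_calls")
  100 * n_self_calls / n_total_calls
}

#' Quality report for a hybridization
#'
#' @param hyb a \code{hybridization}.
#' @param probe_map the matching \code{probe_map}.
#' @param robust passed to \code{\link{compute_dlrsd}}.
#' @param fdr_percent optional platform FDR to carry on the report.
#' @return object of class \code{quality_report}: a one-row data.frame with
#'   sample_id, dlrsd, band, n_probes_used, fdr_percent.
#' @export
quality_report <- function(hyb, probe_map, robust = FALSE,
                           fdr_percent = NA_real_) {
  d <- compute_dlrsd(hyb, probe_map, robust = robust)
  out <- data.frame(sample_id = hyb$sample_id, dlrsd = d,
                    band = classify_quality(d),
                    n_probes_used = sum(!is.na(hyb$log2)),
                    fdr_percent = fdr_percent, stringsAsFactors = FALSE)
  class(out) <- c("quality_report", "data.frame")
  out
}

#' @export
print.quality_report <- function(x, ...) {
  if (all(c("sample_id", "dlrsd", "band", "n_probes_used") %in% names(x)))
    cat(sprintf("Hybridization QC: %s  DLRSD = %.4f (%s), %d probes\n",
                x$sample_id, x$dlrsd, x$band, x$n_probes_used), sep = "")
  else print.data.frame(x)
  invisible(x)
}
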