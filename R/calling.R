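#' CNV calling parameters
#'
#' The calling contract: a CNV is a maximal run of at least \code{min_probes}
#' consecutive probes whose log2 ratios all exceed \code{+log2_threshold}
#' (gain) or all fall below \code{-log2_threshold} (loss), with strict
#' inequality at the threshold.  Calls whose mean |log2| exceeds
#' \code{hom_threshold} are flagged as putative homozygous.
#'
#' @param log2_threshold per-probe |log2| exceedance threshold (default 0.5).
#' @param min_probes minimum run length in probes (default 5, >= 2).
#' @param hom_threshold |mean log2| above which a call is tentatively
#'   homozygous (default 2.0).
#' @return a named list of validated parameters.
#' @export
calling_params <- function(log2_threshold = 0.5, min_probes = 5L,
                           hom_threshold = 2.0) {
  stopifnot_scalar_number(log2_threshold, "log2_threshold", positive = TRUE)
  stopifnot_scalar_number(hom_threshold, "hom_threshold", positive = TRUE)
  if (min_probes < 2) stop("'min_probes' must be >= 2")
  list(log2_threshold = log2_threshold, min_probes = as.integer(min_probes),
       hom_threshold = hom_threshold)
}

#' Call CNVs from a log2 profile by the thresholded-run rule
#'
#' Scans each chromosome for maximal runs of consecutive probes beyond the
#' log2 threshold, all in the same direction.  Runs never cross chromosome
#' boundaries; probes with missing values are removed before adjacency is
#' computed (so a run may span a missing probe's position).  Every probe in
#' a reported call exceeds the threshold: this per-probe exceedance rule is
#' deterministic and conservative, in contrast to window-mean segmentation
#' heuristics.  Call coordinates run from the first probe's start to the
#' last probe's end; \code{mean_log2} is the arithmetic mean over the run.
#'
#' @param hyb a \code{hybridization} (or numeric log2 vector aligned to
#'   \code{probe_map}).
#' @param probe_map the matching \code{probe_map}.
#' @param params \code{\link{calling_params}}.
#' @return object of class \code{cnv_calls}: a data.frame with columns
#'   sample_id, chrom, start, end, n_probes, mean_log2, direction, zygosity.
#' @examples
#' pm <- design_probe_map(build_genome(preset = "toy"), seed = 1)
#' truth <- data.frame(sample_id = "S1", chrom = "chrA",
#'                     start = 3e6, end = 3.2e6,
#'                     copy_state = "het_loss", expected_log2 = -1)
#' hyb <- simulate_hybridization(pm, truth, noise_sd = 0.14, seed = 2)
#' call_cnvs(hyb, pm)
#' @export
call_cnvs <- function(hyb, probe_map, params = calling_params()) {
  log2v <- if (inherits(hyb, "hybridization")) hyb$log2 else as.numeric(hyb)
  sample_id <- if (inherits(hyb, "hybridization")) hyb$sample_id else "S1"
  if (length(log2v) != nrow(probe_map))
    stop("profile length does not match the probe map")
  keep <- !is.na(log2v)
  pm <- probe_map[keep, , drop = FALSE]
  v <- log2v[keep]
  if (!length(v)) return(empty_calls())
  out <- list()
  for (chrom in unique(pm$chrom)) {
    ci <- pm$chrom == chrom
    vv <- v[ci]
    starts <- pm$start[ci]
    ends <- pm$end[ci]
    state <- ifelse(vv > params$log2_threshold, 1L,
                    ifelse(vv < -params$log2_threshold, -1L, 0L))
    r <- rle(state)
    hi <- which(r$values != 0L & r$lengths >= params$min_probes)
    if (!length(hi)) next
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (k in hi) {
      i1 <- run_start[k]; i2 <- run_end[k]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = chrom,
        start = starts[i1], end = ends[i2], n_probes = i2 - i1 + 1L,
        mean_log2 = mean(vv[i1:i2]),
        direction = if (r$values[k] > 0) "gain" else "loss",
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else empty_calls()
  calls$zygosity <- classify_zygosity(calls$mean_log2, params)
  rownames(calls) <- NULL
  class(calls) <- c("cnv_calls", "data.frame")
  calls
}

empty_calls <- function() {
  df <- data.frame(sample_id = character(), chrom = character(),
                   start = numeric(), end = numeric(), n_probes = integer(),
                   mean_log2 = numeric(), direction = character(),
                   zygosity = character(), stringsAsFactors = FALSE)
  class(df) <- c("cnv_calls", "data.frame")
  df
}

#' Zygosity flag for CNV calls
#'
#' aCGH on diploid samples cannot genotype alleles, but calls whose run-mean
#' |log2| exceeds the homozygosity threshold (default 2.0, i.e. beyond the
#' two-fold depletion a heterozygous loss can produce) are tentatively
#' flagged as homozygous.  The run mean, not a single probe, decides, so an
#' isolated probe spike cannot flip the flag.
#'
#' @param mean_log2 numeric vector of call means (or a \code{cnv_calls}
#'   data.frame, in which case its \code{mean_log2} column is used).
#' @param params \code{\link{calling_params}}.
#' @return character vector: "putative_homozygous" or
#'   "heterozygous-or-unknown".
#' @export
classify_zygosity <- function(mean_log2, params = calling_params()) {
  if (is.data.frame(mean_log2)) mean_log2 <- mean_log2$mean_log2
  ifelse(abs(mean_log2) > params$hom_threshold,
         "putative_homozygous", "heterozygous-or-unknown")
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat("CNV calls:", nrow(x), "call(s)")
  if (nrow(x)) cat(" (", sum(x$direction == "gain"), "gains,",
                   sum(x$direction == "loss"), "losses )")
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10),
                                row.names = FALSE)
  invisible(x)
}
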