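#' Design a tiling probe map
#'
#' Places 60-mer probes on a jittered regular grid, emulating a whole-genome
#' CGH tiling design with three spacing tiers: a genome-wide default
#' (median spacing ~7.5 kb), denser sub-telomeric tiling (~4 kb in the
#' terminal window of each chromosome end) and sparser tiling on the Y
#' chromosome (~20 kb).  Interior probes are labelled genic or intergenic at
#' a fixed genic fraction mirroring the share of gene-derived probes on a
#' tiling array; sequence-aware probe selection is out of scope.
#'
#' @param genome a \code{genome_build}.
#' @param spacing named list/vector of target spacings in bp:
#'   \code{default} (7500), \code{subtelomere} (4000), \code{chrY} (20000).
#' @param subtelomere_window terminal window at each chromosome end treated
#'   as sub-telomeric, bp (default 1e6).
#' @param jitter_fraction uniform jitter as a fraction of the tier spacing,
#'   in [0, 0.5).
#' @param genic_fraction fraction of interior probes labelled genic.
#' @param probe_length probe length in bp (default 60).
#' @param seed integer seed for reproducible jitter and category draws.
#' @return An object of class \code{probe_map}: a data.frame with columns
#'   \code{probe_id}, \code{chrom}, \code{start}, \code{end},
#'   \code{category}, sorted by genome order then start.
#' @export
design_probe_map <- function(genome,
                             spacing = list(default = 7500,
                                            subtelomere = 4000,
                                            chrY = 20000),
                             subtelomere_window = 1e6,
                             jitter_fraction = 0.3,
                             genic_fraction = 0.21,
                             probe_length = 60,
                             seed = NULL) {
  spacing <- as.list(spacing)
  for (nm in c("default", "subtelomere", "chrY"))
    stopifnot_scalar_number(spacing[[nm]], nm, positive = TRUE)
  if (jitter_fraction < 0 || jitter_fraction >= 0.5)
    stop("'jitter_fraction' must be in [0, 0.5)")
  with_seed(seed, {
    parts <- lapply(seq_len(nrow(genome)), function(i) {
      chrom <- genome$chrom[i]
      L <- genome$length[i]
      is_y <- chrom %in% c("Y", "chrY")
      segs <- if (is_y) {
        list(list(a = 1, b = L, s = spacing$chrY, cat = "chrY"))
      } else if (L > 2 * subtelomere_window) {
        W <- subtelomere_window
        list(list(a = 1, b = W, s = spacing$subtelomere, cat = "subtelomeric"),
             list(a = W + 1, b = L - W, s = spacing$default, cat = "interior"),
             list(a = L - W + 1, b = L, s = spacing$subtelomere,
                  cat = "subtelomeric"))
      } else {
        list(list(a = 1, b = L, s = spacing$subtelomere, cat = "subtelomeric"))
      }
      seg_dfs <- lapply(segs, function(sg) {
        n <- floor((sg$b - sg$a + 1) / sg$s)
        if (n < 1) return(NULL)
        base <- sg$a + (seq_len(n) - 1) * sg$s
        jit <- if (jitter_fraction > 0)
          round(stats::runif(n, -jitter_fraction * sg$s,
                             jitter_fraction * sg$s)) else 0
        start <- pmax(1, pmin(base + jit, L - probe_length + 1))
        cat <- if (sg$cat == "interior") {
          ifelse(stats::runif(n) < genic_fraction, "genic", "intergenic")
        } else rep(sg$cat, n)
        data.frame(chrom = chrom, start = start,
                   end = start + probe_length - 1,
                   category = cat, stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, seg_dfs)
      if (is.null(out) || nrow(out) == 0L) {
        warning("chromosome ", chrom, " is shorter than one spacing unit; ",
                "no probes placed")
        return(NULL)
      }
      out[order(out$start), , drop = FALSE]
    })
    pm <- do.call(rbind, parts)
    if (is.null(pm)) pm <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), category = character())
    pm$probe_id <- paste0(pm$chrom, "_", pm$start)
    pm <- pm[, c("probe_id", "chrom", "start", "end", "category")]
    rownames(pm) <- NULL
    class(pm) <- c("probe_map", "data.frame")
    pm
  })
}

#' @export
print.probe_map <- function(x, ...) {
  cat("Probe map:", nrow(x), "probes on", length(unique(x$chrom)),
      "chromosome(s)\n")
  print(table(x$category))
  invisible(x)
}

# median gap between consecutive probe starts, per category tier,
# within chromosomes
probe_gap_median <- function(probe_map, category = NULL) {
  pm <- probe_map
  if (!is.null(category)) pm <- pm[pm$category %in% category, , drop = FALSE]
  gaps <- unlist(lapply(split(pm$start, pm$chrom), function(s) {
    s <- sort(s)
    if (length(s) > 1) diff(s) else numeric()
  }), use.names = FALSE)
  stats::median(gaps)
}
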