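#' Construct a genome build
#'
#' A genome build is the coordinate authority for every interval in the
#' package: an ordered table of chromosome names and lengths.  Two presets
#' are provided: \code{"equcab2_table2"}, the 33 EquCab2 sequence classes
#' (chr1--chr31, chrX and the unplaced-contig pseudo-chromosome chrUn) with
#' their Ensembl lengths totalling 2,484,515,402 bp, and \code{"toy"}, three
#' small chromosomes (10, 5 and 2 Mb) for tests and examples.
#'
#' @param spec a data.frame (or list of pairs) with columns \code{chrom} and
#'   \code{length}; ignored when \code{preset} is given.
#' @param preset \code{"equcab2_table2"} or \code{"toy"}.
#' @return An object of class \code{genome_build}: a data.frame with columns
#'   \code{chrom} and \code{length}, in authoritative order.
#' @examples
#' g <- build_genome(preset = "toy")
#' total_genome_length(g)
#' @export
build_genome <- function(spec = NULL, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("equcab2_table2", "toy"))
    if (preset == "toy") {
      spec <- data.frame(chrom = c("chrA", "chrB", "chrC"),
                         length = c(10e6, 5e6, 2e6))
    } else {
      tab <- horse_cnvr_by_chrom()
      spec <- data.frame(chrom = tab$chrom, length = tab$chrom_length)
    }
  }
  if (is.null(spec)) stop("either 'spec' or 'preset' must be supplied")
  if (!is.data.frame(spec)) {
    spec <- do.call(rbind, lapply(spec, function(p)
      data.frame(chrom = as.character(p[[1]]), length = as.numeric(p[[2]]))))
  }
  chrom <- as.character(spec$chrom %||% spec[[1]])
  len <- as.numeric(spec$length %||% spec[[2]])
  if (anyDuplicated(chrom)) stop("duplicate chromosome names")
  if (any(!is.finite(len)) || any(len <= 0))
    stop("chromosome lengths must be positive")
  g <- data.frame(chrom = chrom, length = len, stringsAsFactors = FALSE)
  class(g) <- c("genome_build", "data.frame")
  g
}

#' Total genome length of a build
#' @param genome a \code{genome_build}.
#' @return Total length in bp.
#' @export
total_genome_length <- function(genome) sum(genome$length)

#' @export
print.genome_build <- function(x, ...) {
  cat("Genome build:", nrow(x), "chromosomes,",
      format(total_genome_length(x), big.mark = ","), "bp\n")
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("...", nrow(x) - 8, "more\n")
  invisible(x)
}

#' Per-individual CNV call counts of the horse discovery cohort
#'
#' The printed per-individual tally of CNV calls (with gain/loss breakdown,
#' breed and DNA source) for the 36 non-reference horses of the discovery
#' cohort.  Used by the cohort summary statistics and as a realism anchor for
#' the simulator.
#'
#' @return data.frame with columns individual, breed, tissue, calls, gains,
#'   losses.
#' @export
horse_call_counts <- function() {
  path <- system.file("extdata", "horse_call_counts.tsv", package = "equicnv",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Chromosome-wise CNVR statistics of the horse discovery cohort
#'
#' Per-chromosome CNVR counts (shared/private, state, annotation), total CNVR
#' length, chromosome length and enrichment percentage for the published
#' 258-region horse CNV map.  The chromosome-length column doubles as the
#' EquCab2 genome preset.
#'
#' @return data.frame, one row per chromosome (chr1--31, X, Un).
#' @export
horse_cnvr_by_chrom <- function() {
  path <- system.file("extdata", "horse_cnvr_by_chrom.tsv",
                      package = "equicnv", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
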