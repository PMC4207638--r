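#' Annotate CNVRs as genic or intergenic
#'
#' A CNVR is genic iff it overlaps at least one gene interval by one base or
#' more (no minimum overlap fraction); overlapping gene ids are recorded.
#' Genes on chromosomes absent from the CNVR set's universe are skipped with
#' a warning.
#'
#' @param cnvrs a \code{cnvr_set} (or composite set) with chrom/start/end.
#' @param genes data.frame of gene intervals with columns gene_id, chrom,
#'   start, end (1-based inclusive).
#' @param known_chroms chromosomes considered valid; defaults to those seen
#'   in \code{cnvrs}.
#' @return \code{cnvrs} with added columns \code{genic} (logical) and
#'   \code{genes} (comma-joined gene ids).
#' @export
annotate_genic <- function(cnvrs, genes,
                           known_chroms = unique(cnvrs$chrom)) {
  if (is.null(genes) || !nrow(genes)) {
    cnvrs$genic <- rep(FALSE, nrow(cnvrs))
    cnvrs$genes <- rep("", nrow(cnvrs))
    return(cnvrs)
  }
  unknown <- !(genes$chrom %in% known_chroms)
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " gene(s) on unknown chromosome(s): ",
            paste(unique(genes$chrom[unknown]), collapse = ", "))
    genes <- genes[!unknown, , drop = FALSE]
  }
  hits <- lapply(seq_len(nrow(cnvrs)), function(i) {
    g <- genes[genes$chrom == cnvrs$chrom[i] &
                 intervals_overlap(genes$start, genes$end,
                                   cnvrs$start[i], cnvrs$end[i]), ,
               drop = FALSE]
    g$gene_id
  })
  cnvrs$genic <- lengths(hits) > 0
  cnvrs$genes <- vapply(hits, collapse_ids, character(1))
  cnvrs
}

#' Flag sub-telomeric CNVRs
#'
#' A CNVR is sub-telomeric when it overlaps the terminal window (default
#' 1 Mb) at either end of its chromosome by at least one base.  For
#' acrocentric karyotypes only the distal end can be considered
#' (\code{single_end = TRUE}).
#'
#' @param cnvrs a \code{cnvr_set}.
#' @param genome a \code{genome_build}.
#' @param window terminal window size in bp (default 1e6).
#' @param single_end flag only the distal (high-coordinate) window.
#' @return \code{cnvrs} with added logical column \code{subtelomeric}.
#' @export
flag_subtelomeric <- function(cnvrs, genome, window = 1e6,
                              single_end = FALSE) {
  len <- genome$length[chrom_order(cnvrs$chrom, genome)]
  hi <- cnvrs$end >= len - window + 1
  lo <- cnvrs$start <= window
  cnvrs$subtelomeric <- if (single_end) hi else (lo | hi)
  cnvrs
}

#' Per-chromosome CNVR enrichment
#'
#' For every chromosome of the genome build: the number of CNVRs, their total
#' length (CNVRs are non-overlapping after consolidation, so lengths add),
#' and the enrichment percentage, i.e. total CNVR length divided by
#' chromosome length, times 100.  The unrounded percentage is retained
#' alongside a 2-decimal reporting value.
#'
#' @param cnvrs a \code{cnvr_set} (chromosomes must exist in the genome).
#' @param genome a \code{genome_build}.
#' @return data.frame with columns chrom, n_cnvr, cnvr_length_total,
#'   chrom_length, enrichment_pct, enrichment_pct_2dp.
#' @export
chromosome_enrichment <- function(cnvrs, genome) {
  if (nrow(cnvrs)) chrom_order(cnvrs$chrom, genome)  # validates chromosomes
  n <- vapply(genome$chrom, function(ch) sum(cnvrs$chrom == ch), integer(1))
  len <- vapply(genome$chrom, function(ch)
    sum(cnvrs$length[cnvrs$chrom == ch]), numeric(1))
  pct <- enrichment_percent(len, genome$length)
  data.frame(chrom = genome$chrom, n_cnvr = n, cnvr_length_total = len,
             chrom_length = genome$length, enrichment_pct = pct,
             enrichment_pct_2dp = round(pct, 2), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Enrichment percentage from lengths
#'
#' @param cnvr_length total CNVR length in bp (vectorised).
#' @param chrom_length chromosome (or genome) length in bp.
#' @return 100 * cnvr_length / chrom_length.
#' @export
enrichment_percent <- function(cnvr_length, chrom_length) {
  100 * cnvr_length / chrom_length
}

#' Cohort-level summary statistics
#'
#' Per-sample call counts (total, gains, losses) with their means and
#' medians; CNVR size statistics; and genome-wide enrichment, i.e. the total
#' CNVR length as a percentage of total genome length (unplaced contigs
#' included).  Either raw calls or a pre-tabulated per-sample count table
#' (columns calls, gains, losses) may be supplied.
#'
#' @param calls a \code{cnv_calls} data.frame, or NULL when \code{counts}
#'   is given.
#' @param cnvrs optional \code{cnvr_set} for size/enrichment statistics.
#' @param genome optional \code{genome_build} for the enrichment denominator.
#' @param counts optional per-sample count table with columns calls, gains,
#'   losses (one row per sample).
#' @return object of class \code{cohort_summary} (a list).
#' @export
cohort_summary <- function(calls = NULL, cnvrs = NULL, genome = NULL,
                           counts = NULL) {
  if (is.null(counts)) {
    if (is.null(calls) || !nrow(calls))
      stop("supply 'calls' or a per-sample 'counts' table")
    ids <- unique(calls$sample_id)
    counts <- data.frame(
      sample_id = ids,
      calls = vapply(ids, function(s) sum(calls$sample_id == s), integer(1)),
      gains = vapply(ids, function(s)
        sum(calls$sample_id == s & calls$direction == "gain"), integer(1)),
      losses = vapply(ids, function(s)
        sum(calls$sample_id == s & calls$direction == "loss"), integer(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- list(
    per_sample = counts,
    n_samples = nrow(counts),
    mean_calls = mean(counts$calls), median_calls = stats::median(counts$calls),
    mean_gains = mean(counts$gains), median_gains = stats::median(counts$gains),
    mean_losses = mean(counts$losses),
    median_losses = stats::median(counts$losses))
  if (!is.null(cnvrs) && nrow(cnvrs)) {
    out$n_cnvr <- nrow(cnvrs)
    out$mean_cnvr_size <- mean(cnvrs$length)
    out$median_cnvr_size <- stats::median(cnvrs$length)
    out$min_cnvr_size <- min(cnvrs$length)
    out$max_cnvr_size <- max(cnvrs$length)
    out$state_percent <- 100 * table(cnvrs$state) / nrow(cnvrs)
    if (!is.null(genome))
      out$genome_enrichment_pct <-
        enrichment_percent(sum(cnvrs$length), total_genome_length(genome))
  }
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d samples: mean %.1f calls (median %.1f),",
              x$n_samples, x$mean_calls, x$median_calls),
      sprintf("mean %.1f gains / %.1f losses\n", x$mean_gains, x$mean_losses))
  if (!is.null(x$n_cnvr))
    cat(sprintf("%d CNVRs, mean size %s bp (median %s)\n", x$n_cnvr,
                format(round(x$mean_cnvr_size), big.mark = ","),
                format(round(x$median_cnvr_size), big.mark = ",")))
  if (!is.null(x$genome_enrichment_pct))
    cat(sprintf("Genome enrichment: %.2f%%\n", x$genome_enrichment_pct))
  invisible(x)
}

#' Compare per-sample call counts between two DNA sources
#'
#' Equal-variance two-sample Student's t test (two-sided) of per-sample call
#' counts between two tissue groups, e.g. blood-derived vs hair-derived DNA.
#' Samples outside the two groups (e.g. fibroblast lines) are excluded.
#'
#' @param per_sample_counts numeric vector of per-sample call counts.
#' @param tissue character vector of tissue labels, same length.
#' @param groups the two tissue labels to compare.
#' @return list with elements \code{t}, \code{p}, \code{df},
#'   \code{group_means}.
#' @export
tissue_comparison <- function(per_sample_counts, tissue,
                              groups = c("blood", "hair")) {
  if (length(groups) != 2) stop("'groups' must name exactly two tissues")
  a <- per_sample_counts[tissue == groups[1]]
  b <- per_sample_counts[tissue == groups[2]]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 samples")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       group_means = stats::setNames(c(mean(a), mean(b)), groups))
}
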