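#' Normalize study CNVR records to 1-based inclusive coordinates
#'
#' Published CNV tables mix coordinate conventions; each input must declare
#' its own.  BED-style records (0-based, half-open) have 1 added to their
#' start.  Records extending beyond their chromosome are clipped with a
#' warning; records on chromosomes missing from the genome build are an
#' error.
#'
#' @param records data.frame with columns chrom, start, end and optionally
#'   study_id, state, n_carriers.
#' @param convention \code{"one_based_inclusive"} or \code{"bed_half_open"}.
#' @param genome a \code{genome_build}.
#' @param study_id study label applied when the records carry none.
#' @return data.frame of class \code{study_cnvrs} with columns study_id,
#'   chrom, start, end (+ optional state, n_carriers), 1-based inclusive.
#' @export
normalize_records <- function(records,
                              convention = c("one_based_inclusive",
                                             "bed_half_open"),
                              genome, study_id = NULL) {
  convention <- match.arg(convention)
  out <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!is.null(study_id)) out$study_id <- study_id
  if (is.null(out$study_id)) stop("records need a 'study_id'")
  idx <- chrom_order(out$chrom, genome)  # errors on unknown chromosomes
  if (convention == "bed_half_open") out$start <- out$start + 1
  len <- genome$length[idx]
  over <- out$end > len | out$start < 1
  if (any(over)) {
    warning(sum(over), " record(s) extended beyond chromosome bounds; ",
            "clipped")
    out$end <- pmin(out$end, len)
    out$start <- pmax(out$start, 1)
  }
  if (any(out$end < out$start)) stop("record(s) with end < start")
  keep <- intersect(c("study_id", "chrom", "start", "end", "state",
                      "n_carriers"), names(out))
  out <- out[, keep, drop = FALSE]
  class(out) <- c("study_cnvrs", "data.frame")
  out
}

#' Integrate CNVR sets from multiple studies into a composite dataset
#'
#' Applies the same positional merge relation as
#' \code{\link{consolidate_calls}} (overlap of >= 1 base, with end == start
#' adjacency, transitively chained) to the pooled records of all studies.
#' Merging is purely positional: gain/loss state is carried along as
#' metadata but never prevents a merge.  Each composite region records the
#' set of contributing studies and is \code{shared} when two or more studies
#' contribute, \code{novel} otherwise.
#'
#' @param studies a single normalized \code{study_cnvrs} data.frame, or a
#'   list of them.
#' @return object of class \code{composite_cnvrs}: a data.frame with columns
#'   chrom, start, end, length, n_records, n_studies, studies, status, with
#'   member-record indices in \code{attr(, "members")} and the pooled input
#'   in \code{attr(, "records")}.
#' @export
integrate_studies <- function(studies) {
  pooled <- if (is.data.frame(studies)) studies else
    do.call(rbind, lapply(studies, function(s)
      s[, intersect(c("study_id", "chrom", "start", "end"), names(s)),
        drop = FALSE]))
  if (is.null(pooled) || !nrow(pooled)) stop("no study records supplied")
  if (any(pooled$end < pooled$start)) stop("record(s) with end < start")
  groups <- merge_intervals(pooled$chrom, pooled$start, pooled$end)
  rows <- lapply(groups, function(idx) {
    m <- pooled[idx, , drop = FALSE]
    st <- unique(m$study_id)
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
               n_records = nrow(m), n_studies = length(st),
               studies = collapse_ids(st),
               status = if (length(st) >= 2) "shared" else "novel",
               stringsAsFactors = FALSE)
  })
  comp <- do.call(rbind, rows)
  comp$length <- comp$end - comp$start + 1
  ord <- order(match(comp$chrom, unique(pooled$chrom)), comp$start)
  comp <- comp[ord, c("chrom", "start", "end", "length", "n_records",
                      "n_studies", "studies", "status")]
  rownames(comp) <- NULL
  attr(comp, "members") <- groups[ord]
  attr(comp, "records") <- pooled
  class(comp) <- c("composite_cnvrs", "data.frame")
  comp
}

#' Per-study novelty accounting of a composite dataset
#'
#' For every study: the number of composite CNVRs it appears in, the number
#' where it is the sole contributor (novel) and the number of shared
#' composite regions it contributes to.  A study contributing several
#' records to one composite region counts once for that region.
#'
#' @param composite a \code{composite_cnvrs} object.
#' @return list with \code{per_study} (data.frame study_id, total, novel,
#'   shared_contrib) and \code{global} (total, shared, novel counts).
#' @export
novelty_accounting <- function(composite) {
  study_sets <- strsplit(composite$studies, ",", fixed = TRUE)
  all_studies <- sort(unique(unlist(study_sets)))
  per <- do.call(rbind, lapply(all_studies, function(s) {
    inreg <- vapply(study_sets, function(x) s %in% x, logical(1))
    data.frame(study_id = s, total = sum(inreg),
               novel = sum(inreg & composite$status == "novel"),
               shared_contrib = sum(inreg & composite$status == "shared"),
               stringsAsFactors = FALSE)
  }))
  list(per_study = per,
       global = c(total = nrow(composite),
                  shared = sum(composite$status == "shared"),
                  novel = sum(composite$status == "novel")))
}

#' @export
print.composite_cnvrs <- function(x, ...) {
  cat("Composite CNVR set:", nrow(x), "region(s);",
      sum(x$status == "shared"), "shared /", sum(x$status == "novel"),
      "novel\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 8),
                                row.names = FALSE)
  invisible(x)
}
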