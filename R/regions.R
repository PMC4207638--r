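#' Consolidate per-sample CNV calls into CNVRs
#'
#' Merges calls across all samples by single-linkage chaining: two calls
#' belong to the same copy number variable region (CNVR) iff they overlap by
#' at least one base or are adjacent, i.e. the end coordinate of one equals
#' the start coordinate of the next (in 1-based inclusive coordinates the
#' adjacency case is itself a 1-bp overlap).  Intervals that merely touch
#' without sharing a base (end + 1 == start) do not merge.  Merging is
#' transitive, so a chain of pairwise-overlapping calls yields one region
#' spanning their union; the resulting CNVRs are pairwise non-mergeable.
#'
#' Each CNVR is classified by state (gain / loss / complex when both
#' directions occur among members), sharing (shared iff carried by >= 2
#' distinct samples, private otherwise) and, when a breed map is supplied,
#' breed specificity.
#'
#' @param calls a \code{cnv_calls} data.frame (all samples pooled).
#' @param breed_map optional named character vector mapping sample_id to
#'   breed; required for the breed_specific flag.
#' @param exclude_samples sample ids (e.g. reference animals) dropped before
#'   consolidation.
#' @return object of class \code{cnvr_set}: a data.frame with columns chrom,
#'   start, end, length, n_calls, n_samples, samples, breeds, state,
#'   sharing, breed_specific.  The member-call row indices of each CNVR are
#'   kept in \code{attr(, "members")}.
#' @export
consolidate_calls <- function(calls, breed_map = NULL,
                              exclude_samples = character()) {
  if (nrow(calls) && any(calls$end < calls$start))
    stop("calls with end < start")
  calls <- calls[!(calls$sample_id %in% exclude_samples), , drop = FALSE]
  if (!nrow(calls)) return(empty_cnvrs())
  groups <- merge_intervals(calls$chrom, calls$start, calls$end)
  rows <- lapply(groups, function(idx) {
    m <- calls[idx, , drop = FALSE]
    samples <- unique(m$sample_id)
    breeds <- if (!is.null(breed_map)) {
      b <- breed_map[samples]
      if (anyNA(b)) stop("sample(s) without a breed mapping: ",
                         paste(samples[is.na(b)], collapse = ", "))
      unique(unname(b))
    } else character()
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
               n_calls = nrow(m), n_samples = length(samples),
               samples = collapse_ids(samples),
               breeds = collapse_ids(breeds),
               state = classify_state(m$direction),
               sharing = sharing_status(m$sample_id),
               stringsAsFactors = FALSE)
  })
  cnvrs <- do.call(rbind, rows)
  cnvrs$length <- cnvrs$end - cnvrs$start + 1
  ord <- order(match(cnvrs$chrom, unique(calls$chrom)), cnvrs$start)
  cnvrs <- cnvrs[ord, c("chrom", "start", "end", "length", "n_calls",
                        "n_samples", "samples", "breeds", "state", "sharing")]
  rownames(cnvrs) <- NULL
  attr(cnvrs, "members") <- groups[ord]
  cnvrs$breed_specific <- if (!is.null(breed_map))
    breed_specific_flag(cnvrs, calls, breed_map) else NA
  class(cnvrs) <- c("cnvr_set", "data.frame")
  cnvrs
}

empty_cnvrs <- function() {
  df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                   length = numeric(), n_calls = integer(),
                   n_samples = integer(), samples = character(),
                   breeds = character(), state = character(),
                   sharing = character(), breed_specific = logical(),
                   stringsAsFactors = FALSE)
  attr(df, "members") <- list()
  class(df) <- c("cnvr_set", "data.frame")
  df
}

# single-linkage merge of 1-based inclusive intervals; merge relation is
# overlap >= 1 base (which subsumes end == start adjacency).  Returns a list
# of input row-index groups.  A sweep over start-sorted intervals realises
# the transitive closure because the merge relation is an interval overlap.
merge_intervals <- function(chrom, start, end) {
  n <- length(start)
  if (!n) return(list())
  ord <- order(match(chrom, unique(chrom)), start, end)
  groups <- list()
  cur_idx <- ord[1]
  cur_chrom <- chrom[ord[1]]
  cur_end <- end[ord[1]]
  for (i in ord[-1]) {
    if (chrom[i] == cur_chrom && start[i] <= cur_end) {
      cur_idx <- c(cur_idx, i)
      cur_end <- max(cur_end, end[i])
    } else {
      groups[[length(groups) + 1L]] <- cur_idx
      cur_idx <- i
      cur_chrom <- chrom[i]
      cur_end <- end[i]
    }
  }
  groups[[length(groups) + 1L]] <- cur_idx
  groups
}

#' CNVR state from member call directions
#'
#' @param directions character vector of member directions ("gain"/"loss").
#' @return "gain" if all members are gains, "loss" if all are losses,
#'   "complex" if both occur.
#' @export
classify_state <- function(directions) {
  if (!length(directions)) stop("a CNVR needs at least one member call")
  u <- unique(directions)
  if (length(u) > 1) "complex" else u
}

#' CNVR sharing status from member sample ids
#'
#' Counts distinct samples, not calls: a region carried twice by the same
#' individual is still private.
#'
#' @param sample_ids member sample ids.
#' @return "shared" (>= 2 distinct samples) or "private".
#' @export
sharing_status <- function(sample_ids) {
  if (!length(sample_ids)) stop("a CNVR needs at least one member call")
  if (length(unique(sample_ids)) >= 2) "shared" else "private"
}

breed_specific_flag <- function(cnvrs, calls, breed_map) {
  unmapped <- setdiff(unique(calls$sample_id), names(breed_map))
  if (length(unmapped)) stop("sample(s) without a breed mapping: ",
                             paste(unmapped, collapse = ", "))
  vapply(seq_len(nrow(cnvrs)), function(i) {
    samples <- strsplit(cnvrs$samples[i], ",", fixed = TRUE)[[1]]
    b <- unique(unname(breed_map[samples]))
    length(samples) >= 2 && length(b) == 1
  }, logical(1))
}

#' Flag breed-specific CNVRs
#'
#' A CNVR is tentatively breed-specific when it is carried by two or more
#' individuals that all belong to one breed, and by no individual of any
#' other breed.
#'
#' @param cnvrs a \code{cnvr_set} built with a breed map (or any cnvr_set
#'   plus \code{breed_map} here).
#' @param breed_map named character vector sample_id -> breed.
#' @return the flagged subset of \code{cnvrs}.
#' @export
breed_specific_cnvrs <- function(cnvrs, breed_map = NULL) {
  flag <- if (!is.null(breed_map)) {
    vapply(seq_len(nrow(cnvrs)), function(i) {
      samples <- strsplit(cnvrs$samples[i], ",", fixed = TRUE)[[1]]
      b <- breed_map[samples]
      if (anyNA(b)) stop("sample(s) without a breed mapping: ",
                         paste(samples[is.na(b)], collapse = ", "))
      length(samples) >= 2 && length(unique(unname(b))) == 1
    }, logical(1))
  } else {
    if (all(is.na(cnvrs$breed_specific)))
      stop("cnvr_set carries no breed information; supply 'breed_map'")
    cnvrs$breed_specific
  }
  cnvrs[flag, , drop = FALSE]
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat("CNVR set:", nrow(x), "region(s)\n")
  if (nrow(x)) {
    cat("  state:  ", paste(names(table(x$state)), table(x$state),
                            collapse = "  "), "\n")
    cat("  sharing:", paste(names(table(x$sharing)), table(x$sharing),
                            collapse = "  "), "\n")
    print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.cnvr_set <- function(object, ...) {
  list(n = nrow(object),
       by_state = table(object$state),
       by_sharing = table(object$sharing),
       size = if (nrow(object)) summary(object$length) else NULL)
}
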