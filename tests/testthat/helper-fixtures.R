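# shared fixtures and independent oracles, built in code at test time

toy_genome <- function() build_genome(preset = "toy")

# a bare regular probe map (no jitter, single category) for hand traces
probe_frame <- function(n, chrom = "c1", spacing = 1000,
                        probe_length = 60, category = "intergenic") {
  start <- (seq_len(n) - 1) * spacing + 1
  pm <- data.frame(probe_id = paste0(chrom, "_", start), chrom = chrom,
                   start = start, end = start + probe_length - 1,
                   category = category, stringsAsFactors = FALSE)
  class(pm) <- c("probe_map", "data.frame")
  pm
}

hyb_from_values <- function(values, sample_id = "S1") {
  h <- list(sample_id = sample_id, reference_id = "REF", tissue = "blood",
            sex = "F", breed = NA_character_, log2 = values)
  class(h) <- "hybridization"
  h
}

make_calls <- function(sample_id, chrom, start, end,
                       direction = "loss", mean_log2 = NULL) {
  n <- max(length(sample_id), length(chrom), length(start), length(end))
  df <- data.frame(sample_id = rep_len(sample_id, n),
                   chrom = rep_len(chrom, n), start = rep_len(start, n),
                   end = rep_len(end, n), n_probes = 5L,
                   mean_log2 = rep_len(mean_log2 %||%
                                         ifelse(rep_len(direction, n) ==
                                                  "loss", -1, 0.8), n),
                   direction = rep_len(direction, n),
                   zygosity = "heterozygous-or-unknown",
                   stringsAsFactors = FALSE)
  class(df) <- c("cnv_calls", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force oracle for the run rule: enumerate every maximal window of
# >= min_probes values all strictly beyond the threshold in one direction
brute_force_runs <- function(values, threshold = 0.5, min_probes = 5L) {
  n <- length(values)
  dir <- ifelse(values > threshold, 1L,
                ifelse(values < -threshold, -1L, 0L))
  runs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      d <- dir[i:j]
      if (all(d == d[1]) && d[1] != 0L && (j - i + 1) >= min_probes) {
        maximal <- (i == 1 || dir[i - 1] != d[1]) &&
          (j == n || dir[j + 1] != d[1])
        if (maximal)
          runs[[length(runs) + 1L]] <- c(i, j, d[1])
      }
    }
  }
  if (!length(runs)) return(data.frame(i = integer(), j = integer(),
                                       dir = integer()))
  out <- unique(do.call(rbind, runs))
  data.frame(i = out[, 1], j = out[, 2], dir = out[, 3])
}

# brute-force transitive-closure merge of 1-based inclusive intervals:
# explicit relation matrix + connected components by BFS
brute_force_merge <- function(chrom, start, end) {
  n <- length(start)
  if (!n) return(list())
  rel <- outer(seq_len(n), seq_len(n), function(i, j)
    chrom[i] == chrom[j] & start[i] <= end[j] & start[j] <= end[i])
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(rel[v, ] & is.na(comp)))
    }
  }
  lapply(seq_len(cid), function(k) which(comp == k))
}

# canonical span table from index groups, for comparing merge outputs
spans_of <- function(groups, chrom, start, end) {
  df <- do.call(rbind, lapply(groups, function(idx)
    data.frame(chrom = chrom[idx[1]], start = min(start[idx]),
               end = max(end[idx]), stringsAsFactors = FALSE)))
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

random_interval_set <- function(n, n_chrom = 2, max_pos = 1000,
                                max_len = 120) {
  chrom <- sample(paste0("c", seq_len(n_chrom)), n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + len - 1,
             stringsAsFactors = FALSE)
}

# internal helpers exercised directly in tests
probe_gap_median <- equicnv:::probe_gap_median
merge_intervals <- equicnv:::merge_intervals

# cached large fixtures (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

equcab2_probe_map <- function() {
  cached("equcab2_pm", function()
    design_probe_map(build_genome(preset = "equcab2_table2"), seed = 11L))
}
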