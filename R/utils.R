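# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical chromosome ordering: the order of the genome build is authoritative
chrom_order <- function(chrom, genome) {
  idx <- match(chrom, genome$chrom)
  if (anyNA(idx)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(idx)]), collapse = ", "))
  }
  idx
}

# 1-based inclusive overlap test (vectorised over the first interval set)
intervals_overlap <- function(start1, end1, start2, end2) {
  start1 <= end2 & start2 <= end1
}

# deterministic per-unit seed derivation from a master seed; kept < 2^31
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 1000003 + index) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number")
  if (positive && x <= 0) stop("'", name, "' must be positive")
  invisible(x)
}

collapse_ids <- function(x) paste(sort(unique(x)), collapse = ",")
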