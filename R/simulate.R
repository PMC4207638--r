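#' Expected log2 ratio for a copy state
#'
#' Sample-vs-reference log2 ratio expected for a diploid reference:
#' \code{log2(copy/2)} for 1, 3 and 4 copies (-1.0, +0.585, +1.0).  A true
#' homozygous loss has log2 of minus infinity; it is represented by a finite
#' floor (default -4.0) since hybridization background bounds the observable
#' depletion.
#'
#' @param copy_state one of \code{hom_loss}, \code{het_loss},
#'   \code{het_gain}, \code{multi_gain} (vectorised).
#' @param hom_floor finite log2 assigned to homozygous losses.
#' @return numeric vector of expected log2 ratios.
#' @export
expected_log2_for_state <- function(copy_state, hom_floor = -4.0) {
  map <- c(hom_loss = hom_floor, het_loss = log2(1 / 2),
           het_gain = log2(3 / 2), multi_gain = log2(4 / 2))
  bad <- setdiff(unique(copy_state), names(map))
  if (length(bad)) stop("unknown copy_state: ", paste(bad, collapse = ", "))
  unname(map[copy_state])
}

#' Default truth-planting parameters
#'
#' Defaults mirror the discovery-cohort conditions: a mean of 26.4 CNVs per
#' sample, sizes log-uniform between 1 kb and 2.5 Mb, 72\% losses, 1.7\%
#' homozygous/high-amplitude states, 30\% of variants shared by two or more
#' samples and 2\% restricted to a single breed.
#'
#' @param mean_cnvs_per_sample Poisson mean of CNVs planted per sample.
#' @param size_range two-element bp range; sizes drawn log-uniformly.
#' @param loss_fraction fraction of variants that are losses.
#' @param hom_fraction fraction of losses that are homozygous (and of gains
#'   that are multi-copy).
#' @param shared_fraction fraction of variants copied into additional samples.
#' @param breed_restricted_fraction fraction of variants planted only within
#'   one breed (in at least two of its samples).
#' @param hom_floor expected log2 for homozygous losses.
#' @param max_retries placement retries before giving up on a chromosome.
#' @return a named list of parameters.
#' @export
truth_params <- function(mean_cnvs_per_sample = 26.4,
                         size_range = c(1e3, 2.5e6),
                         loss_fraction = 0.72,
                         hom_fraction = 0.017,
                         shared_fraction = 0.30,
                         breed_restricted_fraction = 0.02,
                         hom_floor = -4.0,
                         max_retries = 100L) {
  fr <- c(loss_fraction, hom_fraction, shared_fraction,
          breed_restricted_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (mean_cnvs_per_sample < 0) stop("'mean_cnvs_per_sample' must be >= 0")
  if (length(size_range) != 2L || size_range[1] <= 0 ||
      size_range[2] < size_range[1])
    stop("'size_range' must be an increasing positive pair")
  list(mean_cnvs_per_sample = mean_cnvs_per_sample, size_range = size_range,
       loss_fraction = loss_fraction, hom_fraction = hom_fraction,
       shared_fraction = shared_fraction,
       breed_restricted_fraction = breed_restricted_fraction,
       hom_floor = hom_floor, max_retries = as.integer(max_retries))
}

# chromosomes eligible for planted CNVs: everything except the Y, on which
# the discovery platform found no variants
eligible_chroms <- function(genome) {
  genome[!(genome$chrom %in% c("Y", "chrY")), , drop = FALSE]
}

#' Plant ground-truth CNVs into a cohort
#'
#' Draws per-sample CNV counts from a Poisson distribution, places variants
#' with log-uniform sizes uniformly on the genome (chrY excluded), and keeps
#' each sample's variants non-overlapping.  A configurable fraction of
#' variants is copied into additional samples (shared variants) or planted
#' only within one breed (breed-restricted variants).
#'
#' @param genome a \code{genome_build}.
#' @param samples data.frame with columns \code{sample_id}, \code{breed},
#'   \code{tissue}, \code{sex} (only \code{sample_id} and \code{breed} are
#'   used here).
#' @param params list from \code{\link{truth_params}}.
#' @param seed integer seed.
#' @return An object of class \code{truth_cnv_set}: a data.frame with
#'   columns sample_id, chrom, start, end, copy_state, expected_log2.
#' @export
plant_truth_cnvs <- function(genome, samples, params = truth_params(),
                             seed = NULL) {
  elig <- eligible_chroms(genome)
  if (params$size_range[1] > min(elig$length))
    stop("'size_range' exceeds the smallest eligible chromosome")
  sample_ids <- as.character(samples$sample_id)
  breeds <- as.character(samples$breed %||% rep(NA_character_,
                                                length(sample_ids)))
  names(breeds) <- sample_ids
  with_seed(seed, {
    quota <- stats::rpois(length(sample_ids), params$mean_cnvs_per_sample)
    names(quota) <- sample_ids
    placed <- lapply(sample_ids, function(s)
      data.frame(chrom = character(), start = numeric(), end = numeric()))
    names(placed) <- sample_ids
    rows <- list()

    place_one <- function(target) {
      # returns c(chrom, start, end) avoiding overlap in `target`, or NULL
      for (try in seq_len(params$max_retries)) {
        size <- round(exp(stats::runif(1, log(params$size_range[1]),
                                       log(params$size_range[2]))))
        ok <- elig$length >= size
        ci <- sample(which(ok), 1, prob = elig$length[ok])
        chrom <- elig$chrom[ci]
        start <- floor(stats::runif(1, 1, elig$length[ci] - size + 1))
        end <- start + size - 1
        ex <- placed[[target]]
        hit <- ex$chrom == chrom &
          intervals_overlap(ex$start, ex$end, start, end)
        if (!any(hit)) return(list(chrom = chrom, start = start, end = end))
      }
      stop("could not place a non-overlapping CNV for sample ", target,
           " (last attempted chromosome: ", chrom, ")")
    }

    fits <- function(target, iv) {
      ex <- placed[[target]]
      !any(ex$chrom == iv$chrom &
             intervals_overlap(ex$start, ex$end, iv$start, iv$end))
    }

    while (any(quota > 0)) {
      primary <- sample(rep(sample_ids[quota > 0], 2L), 1)
      iv <- place_one(primary)
      is_loss <- stats::runif(1) < params$loss_fraction
      is_hom <- stats::runif(1) < params$hom_fraction
      state <- if (is_loss) {
        if (is_hom) "hom_loss" else "het_loss"
      } else if (is_hom) "multi_gain" else "het_gain"
      carriers <- primary
      u <- stats::runif(1)
      if (u < params$breed_restricted_fraction && !is.na(breeds[primary])) {
        mates <- sample_ids[breeds == breeds[primary] &
                              sample_ids != primary]
        mates <- mates[vapply(mates, fits, logical(1), iv = iv)]
        if (length(mates)) {
          pick <- if (length(mates) == 1) mates else sample(mates, 1)
          carriers <- c(carriers, pick)
        }
      } else if (u < params$breed_restricted_fraction +
                 params$shared_fraction) {
        others <- sample_ids[sample_ids != primary]
        others <- others[vapply(others, fits, logical(1), iv = iv)]
        if (length(others)) {
          with_quota <- others[quota[others] > 0]
          pool <- if (length(with_quota)) with_quota else others
          k <- min(length(pool), sample(1:3, 1))
          pick <- if (length(pool) == 1) pool else sample(pool, k)
          carriers <- c(carriers, pick)
        }
      }
      for (s in carriers) {
        placed[[s]] <- rbind(placed[[s]],
                             data.frame(chrom = iv$chrom, start = iv$start,
                                        end = iv$end))
        quota[s] <- max(0L, quota[s] - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, chrom = iv$chrom, start = iv$start, end = iv$end,
          copy_state = state, stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(sample_id = character(), chrom = character(),
                 start = numeric(), end = numeric(),
                 copy_state = character(), stringsAsFactors = FALSE)
    truth$expected_log2 <- if (nrow(truth))
      expected_log2_for_state(truth$copy_state, params$hom_floor) else numeric()
    truth <- truth[order(match(truth$sample_id, sample_ids),
                         chrom_order(truth$chrom, genome), truth$start), ]
    rownames(truth) <- NULL
    class(truth) <- c("truth_cnv_set", "data.frame")
    truth
  })
}

#' Simulate one sample-vs-reference hybridization
#'
#' Builds a per-probe log2 profile: each probe overlapping a planted truth
#' CNV of the sample takes that CNV's expected log2 ratio (0 elsewhere), an
#' optional X-chromosome baseline shift of -1.0 emulates a male sample
#' hybridized against a female reference, and i.i.d. Gaussian probe noise of
#' the requested standard deviation is added.  The reference channel is
#' treated as copy-neutral.
#'
#' @param probe_map a \code{probe_map}.
#' @param truth \code{truth_cnv_set} rows for this sample (may be empty).
#' @param noise_sd per-probe Gaussian noise sd (> 0); ~0.14 for blood-grade
#'   DNA, ~0.41 for hair-grade DNA.
#' @param sex_effect \code{"off"} or \code{"male_vs_female_ref"}.
#' @param seed integer seed.
#' @param sample_id,reference_id,tissue,sex,breed sample metadata carried on
#'   the result.
#' @return An object of class \code{hybridization}: a list with the metadata
#'   fields and \code{log2}, one value per probe of \code{probe_map}.
#' @export
simulate_hybridization <- function(probe_map, truth = NULL, noise_sd = 0.14,
                                   sex_effect = c("off", "male_vs_female_ref"),
                                   seed = NULL, sample_id = "S1",
                                   reference_id = "REF", tissue = "blood",
                                   sex = "F", breed = NA_character_) {
  sex_effect <- match.arg(sex_effect)
  stopifnot_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  baseline <- numeric(nrow(probe_map))
  if (!is.null(truth) && nrow(truth)) {
    tr <- truth[is.null(truth$sample_id) | truth$sample_id == sample_id, ,
                drop = FALSE]
    for (k in seq_len(nrow(tr))) {
      idx <- which(probe_map$chrom == tr$chrom[k] &
                     intervals_overlap(probe_map$start, probe_map$end,
                                       tr$start[k], tr$end[k]))
      if (!length(idx)) {
        warning("truth CNV ", tr$chrom[k], ":", tr$start[k], "-", tr$end[k],
                " covers no probes (undetectable)")
        next
      }
      baseline[idx] <- tr$expected_log2[k]
    }
  }
  if (sex_effect == "male_vs_female_ref") {
    xi <- probe_map$chrom %in% c("X", "chrX")
    baseline[xi] <- baseline[xi] - 1.0
  }
  log2v <- with_seed(seed,
                     baseline + stats::rnorm(nrow(probe_map), 0, noise_sd))
  hyb <- list(sample_id = sample_id, reference_id = reference_id,
              tissue = tissue, sex = sex, breed = breed, log2 = log2v)
  class(hyb) <- "hybridization"
  hyb
}

#' @export
print.hybridization <- function(x, ...) {
  cat("Hybridization", x$sample_id, "vs", x$reference_id,
      sprintf("(%s, %s, %s): %d probes, %d missing\n",
              x$breed, x$tissue, x$sex, length(x$log2), sum(is.na(x$log2))))
  invisible(x)
}

#' Simulate a cohort of hybridizations
#'
#' Plants a cohort-wide truth set and simulates one hybridization per sample,
#' with tissue-dependent noise (blood and fibroblast DNA at sd 0.14,
#' hair DNA at sd 0.41 by default).  Each sample's noise seed is derived
#' deterministically from the master seed (\code{(seed * 1000003 + i) mod
#' 2147483629}), so cohorts are reproducible piecewise.
#'
#' @param genome a \code{genome_build}.
#' @param probe_map a \code{probe_map} on that genome.
#' @param samples data.frame with columns sample_id, breed, tissue, sex and
#'   optionally reference_id.
#' @param params truth-planting parameters (\code{\link{truth_params}}).
#' @param seed master integer seed.
#' @param noise_sd_by_tissue named vector of per-probe noise sds.
#' @return list with elements \code{hybridizations} (list of
#'   \code{hybridization}) and \code{truth} (\code{truth_cnv_set}).
#' @export
simulate_cohort <- function(genome, probe_map, samples,
                            params = truth_params(), seed = 1L,
                            noise_sd_by_tissue = c(blood = 0.14, hair = 0.41,
                                                   fibroblast = 0.14)) {
  truth <- plant_truth_cnvs(genome, samples, params,
                            seed = derive_seed(seed, 0L))
  hybs <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    sd_i <- unname(noise_sd_by_tissue[as.character(s$tissue)])
    if (is.na(sd_i)) sd_i <- noise_sd_by_tissue[["blood"]]
    simulate_hybridization(
      probe_map, truth[truth$sample_id == s$sample_id, , drop = FALSE],
      noise_sd = sd_i, seed = derive_seed(seed, i),
      sample_id = as.character(s$sample_id),
      reference_id = as.character(s$reference_id %||% "REF"),
      tissue = as.character(s$tissue), sex = as.character(s$sex %||% "F"),
      breed = as.character(s$breed %||% NA))
  })
  names(hybs) <- as.character(samples$sample_id)
  list(hybridizations = hybs, truth = truth)
}
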