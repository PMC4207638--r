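two_samples <- data.frame(sample_id = c("A", "B"),
                          breed = c("x", "x"),
                          tissue = c("blood", "blood"), sex = "F")

test_that("expected log2 shifts follow log2(copy/2) with a hom-loss floor", {
  expect_equal(expected_log2_for_state(c("het_loss", "het_gain",
                                         "multi_gain")),
               c(-1, log2(1.5), 1))
  expect_equal(expected_log2_for_state("hom_loss"), -4)
  expect_equal(expected_log2_for_state("hom_loss", hom_floor = -3.5), -3.5)
  expect_error(expected_log2_for_state("dup"), "unknown")
})

test_that("truth planting honours count, sharing and overlap contracts", {
  g <- toy_genome()
  empty <- plant_truth_cnvs(g, two_samples,
                            truth_params(mean_cnvs_per_sample = 0), seed = 1)
  expect_equal(nrow(empty), 0)

  both <- plant_truth_cnvs(
    g, two_samples,
    truth_params(mean_cnvs_per_sample = 5, size_range = c(1e3, 2e3),
                 shared_fraction = 1, breed_restricted_fraction = 0),
    seed = 3)
  key <- paste(both$chrom, both$start, both$end)
  for (k in unique(key))
    expect_setequal(both$sample_id[key == k], c("A", "B"))

  # no two truth CNVs of one sample overlap
  tr <- plant_truth_cnvs(g, two_samples,
                         truth_params(mean_cnvs_per_sample = 30,
                                      size_range = c(1e4, 3e5)), seed = 9)
  for (s in unique(tr$sample_id)) {
    ts <- tr[tr$sample_id == s, ]
    for (ch in unique(ts$chrom)) {
      iv <- ts[ts$chrom == ch, ]
      iv <- iv[order(iv$start), ]
      if (nrow(iv) > 1) expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
    }
  }
  expect_true(all(tr$end <= g$length[match(tr$chrom, g$chrom)]))
  expect_true(all(tr$start >= 1))
})

test_that("cohort-scale truth count is Poisson-consistent with 950 calls", {
  g <- build_genome(preset = "equcab2_table2")
  samples <- data.frame(sample_id = sprintf("H%02d", 1:36),
                        breed = rep(sprintf("breed%d", 1:12), each = 3),
                        tissue = "blood", sex = "F")
  tr <- plant_truth_cnvs(g, samples, truth_params(), seed = 7)
  expect_lt(abs(nrow(tr) - 36 * 26.4), 3 * sqrt(36 * 26.4))
  expect_false(any(tr$chrom %in% c("Y", "chrY")))
})

test_that("noiseless hybridization reproduces planted shifts exactly", {
  pm <- probe_frame(20, chrom = "c1", spacing = 1000)
  truth <- data.frame(sample_id = "S1", chrom = "c1", start = 5001,
                      end = 10060, copy_state = "het_loss",
                      expected_log2 = -1)
  expect_silent(hyb <- simulate_hybridization(pm, truth, noise_sd = 1e-9,
                                              seed = 1))
  covered <- pm$start <= 10060 & pm$end >= 5001
  expect_equal(hyb$log2[covered], rep(-1, sum(covered)), tolerance = 1e-6)
  expect_equal(hyb$log2[!covered], rep(0, sum(!covered)), tolerance = 1e-6)
})

test_that("noise calibration: empirical probe sd matches the requested sd", {
  pm <- probe_frame(100000, spacing = 100)
  hyb <- simulate_hybridization(pm, NULL, noise_sd = 0.14, seed = 4)
  expect_gte(sd(hyb$log2), 0.135)
  expect_lte(sd(hyb$log2), 0.145)
})

test_that("male-vs-female-reference shifts X probes by -1", {
  pm <- rbind(probe_frame(50, chrom = "chr1"), probe_frame(50, chrom = "chrX"))
  class(pm) <- c("probe_map", "data.frame")
  hyb <- simulate_hybridization(pm, NULL, noise_sd = 1e-9,
                                sex_effect = "male_vs_female_ref", seed = 1)
  expect_equal(mean(hyb$log2[pm$chrom == "chrX"]), -1, tolerance = 1e-6)
  expect_equal(mean(hyb$log2[pm$chrom == "chr1"]), 0, tolerance = 1e-6)
})

test_that("a truth CNV covering no probes is kept but warned about", {
  pm <- probe_frame(10, spacing = 10000)  # probes at 1, 10001, ...
  truth <- data.frame(sample_id = "S1", chrom = "c1", start = 2000,
                      end = 3000, copy_state = "het_loss",
                      expected_log2 = -1)
  expect_warning(simulate_hybridization(pm, truth, noise_sd = 0.1, seed = 1),
                 "no probes")
})

test_that("cohort simulation is deterministic and tissue noise is honoured", {
  g <- toy_genome()
  pm <- design_probe_map(g, seed = 2)
  samples <- data.frame(sample_id = c("A", "B", "C"),
                        breed = c("x", "x", "y"),
                        tissue = c("blood", "hair", "fibroblast"), sex = "F")
  p <- truth_params(mean_cnvs_per_sample = 4, size_range = c(5e4, 2e5))
  s1 <- simulate_cohort(g, pm, samples, p, seed = 10)
  s2 <- simulate_cohort(g, pm, samples, p, seed = 10)
  expect_identical(s1$truth, s2$truth)
  expect_identical(lapply(s1$hybridizations, `[[`, "log2"),
                   lapply(s2$hybridizations, `[[`, "log2"))
  s3 <- simulate_cohort(g, pm, samples, p, seed = 11)
  expect_false(identical(s1$hybridizations$A$log2, s3$hybridizations$A$log2))
})

test_that("per-sample DLRSD recovers each tissue's injected noise sd", {
  g <- build_genome(spec = data.frame(chrom = "c1", length = 400e6))
  pm <- design_probe_map(g, seed = 3)  # ~53k probes
  samples <- data.frame(sample_id = sprintf("S%02d", 1:6),
                        breed = "b", sex = "F",
                        tissue = rep(c("blood", "hair"), 3))
  sim <- simulate_cohort(g, pm, samples,
                         truth_params(mean_cnvs_per_sample = 5,
                                      size_range = c(1e4, 1e6)), seed = 21)
  for (i in seq_len(nrow(samples))) {
    target <- if (samples$tissue[i] == "hair") 0.41 else 0.14
    d <- compute_dlrsd(sim$hybridizations[[i]], pm)
    expect_lt(abs(d - target) / target, 0.05)
  }
})
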