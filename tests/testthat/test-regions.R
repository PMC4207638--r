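test_that("consolidation merges overlap and shared-boundary adjacency only", {
  one <- consolidate_calls(make_calls("s1", "chr1", 100, 200))
  expect_equal(nrow(one), 1)
  expect_equal(one$sharing, "private")
  expect_equal(c(one$start, one$end), c(100, 200))

  both <- consolidate_calls(rbind(
    make_calls("s1", "chr1", 100, 200, "loss"),
    make_calls("s2", "chr1", 150, 250, "gain")))
  expect_equal(nrow(both), 1)
  expect_equal(c(both$start, both$end), c(100, 250))
  expect_equal(both$state, "complex")
  expect_equal(both$sharing, "shared")

  adj <- consolidate_calls(rbind(make_calls("s1", "chr1", 100, 200),
                                 make_calls("s2", "chr1", 200, 300)))
  expect_equal(nrow(adj), 1)
  expect_equal(c(adj$start, adj$end), c(100, 300))

  # touching without a shared base does not merge
  touch <- consolidate_calls(rbind(make_calls("s1", "chr1", 100, 200),
                                   make_calls("s2", "chr1", 201, 300)))
  expect_equal(nrow(touch), 2)

  # chromosomes never merge across
  chroms <- consolidate_calls(rbind(make_calls("s1", "chr1", 100, 200),
                                    make_calls("s2", "chr2", 150, 250)))
  expect_equal(nrow(chroms), 2)

  expect_error(consolidate_calls(make_calls("s1", "chr1", 200, 100)),
               "end < start")
})

test_that("state, sharing and breed-specific rules match their truth tables", {
  expect_equal(classify_state(c("loss", "loss")), "loss")
  expect_equal(classify_state(c("gain", "loss")), "complex")
  expect_equal(classify_state("gain"), "gain")
  expect_error(classify_state(character()), "at least one")

  expect_equal(sharing_status("A"), "private")
  expect_equal(sharing_status(c("A", "B")), "shared")
  expect_equal(sharing_status(c("A", "A")), "private")

  breed_map <- c(E1 = "Exmoor", E2 = "Exmoor", F1 = "Friesian")
  flagged <- consolidate_calls(rbind(make_calls("E1", "chr9", 100, 300),
                                     make_calls("E2", "chr9", 200, 400)),
                               breed_map)
  expect_true(flagged$breed_specific)
  solo <- consolidate_calls(make_calls("E1", "chr9", 100, 300), breed_map)
  expect_false(solo$breed_specific)
  mixed <- consolidate_calls(rbind(make_calls("E1", "chr9", 100, 300),
                                   make_calls("E2", "chr9", 200, 400),
                                   make_calls("F1", "chr9", 350, 500)),
                             breed_map)
  expect_false(mixed$breed_specific)
  expect_equal(nrow(breed_specific_cnvrs(flagged)), 1)
  expect_equal(nrow(breed_specific_cnvrs(mixed)), 0)
  expect_error(consolidate_calls(make_calls("ZZ", "chr9", 1, 10), breed_map),
               "breed mapping")
})

test_that("same-sample repeated calls stay private; excluded samples drop out", {
  same <- consolidate_calls(rbind(make_calls("A", "chr1", 100, 200),
                                  make_calls("A", "chr1", 150, 260)))
  expect_equal(same$sharing, "private")
  expect_equal(same$n_calls, 2L)
  expect_equal(same$n_samples, 1L)

  excl <- consolidate_calls(rbind(make_calls("A", "chr1", 100, 200),
                                  make_calls("REF", "chr1", 150, 260)),
                            exclude_samples = "REF")
  expect_equal(excl$samples, "A")
  expect_equal(c(excl$start, excl$end), c(100, 200))
})

test_that("consolidation matches brute-force transitive closure and is idempotent", {
  set.seed(91)
  for (case in 1:60) {
    iv <- random_interval_set(sample(1:20, 1))
    calls <- make_calls(sample(c("a", "b", "c"), nrow(iv), replace = TRUE),
                        iv$chrom, iv$start, iv$end)
    got <- consolidate_calls(calls)
    want <- spans_of(brute_force_merge(iv$chrom, iv$start, iv$end),
                     iv$chrom, iv$start, iv$end)
    got_spans <- got[order(got$chrom, got$start, got$end),
                     c("chrom", "start", "end")]
    expect_equal(unname(as.matrix(got_spans)), unname(as.matrix(want)))

    # coverage conservation: CNVR bases == union of member call bases
    cov_calls <- sum(sapply(split(iv, iv$chrom), function(d) {
      pos <- unique(unlist(Map(seq, d$start, d$end)))
      length(pos)
    }))
    expect_equal(sum(got$length), cov_calls)

    # idempotence: consolidating the consolidated set returns it unchanged
    again <- consolidate_calls(make_calls("z", got$chrom, got$start,
                                          got$end))
    expect_equal(again[, c("chrom", "start", "end")],
                 got[order(match(got$chrom, unique(got$chrom)), got$start),
                     c("chrom", "start", "end")],
             ignore_attr = TRUE)
  }
})

test_that("consolidation agrees with IRanges reduce at zero gap width", {
  set.seed(17)
  iv <- random_interval_set(40, n_chrom = 1)
  got <- consolidate_calls(make_calls("s", iv$chrom, iv$start, iv$end))
  red <- IRanges::reduce(IRanges::IRanges(iv$start, iv$end),
                         min.gapwidth = 0L)
  expect_equal(got$start, sort(IRanges::start(red)))
  expect_equal(got$end, IRanges::end(red)[order(IRanges::start(red))])
})
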