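cnvr_frame <- function(chrom, start, end) {
  df <- data.frame(chrom = chrom, start = start, end = end,
                   length = end - start + 1, stringsAsFactors = FALSE)
  df
}

test_that("genic annotation uses the any-overlap rule and records gene ids", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = c("chr1", "chr1"),
                      start = c(150, 500), end = c(400, 600))
  cn <- cnvr_frame("chr1", c(100, 100, 420), c(200, 149, 480))
  ann <- annotate_genic(cn, genes)
  expect_equal(ann$genic, c(TRUE, FALSE, FALSE))
  expect_equal(ann$genes[1], "g1")
  # adjacent-but-not-overlapping gene (starts one base after the CNVR ends)
  gene_after <- data.frame(gene_id = "g", chrom = "chr1",
                           start = 201, end = 400)
  expect_false(annotate_genic(cnvr_frame("chr1", 100, 200), gene_after)$genic)
  # no gene set: everything intergenic
  none <- annotate_genic(cn, NULL)
  expect_false(any(none$genic))
  # unknown chromosomes are skipped with a warning, not an error
  expect_warning(
    ann2 <- annotate_genic(cn, rbind(genes,
                                     data.frame(gene_id = "gX",
                                                chrom = "chrZZ",
                                                start = 1, end = 10))),
    "chrZZ")
  expect_equal(ann2$genic, ann$genic)
})

test_that("sub-telomeric flagging covers both terminal windows", {
  g <- build_genome(spec = data.frame(chrom = "chr1", length = 50e6))
  cn <- cnvr_frame("chr1", c(2e5, 25e6, 49.5e6, 9.9e5), c(4e5, 26e6, 49.8e6, 1.2e6))
  fl <- flag_subtelomeric(cn, g)
  expect_equal(fl$subtelomeric, c(TRUE, FALSE, TRUE, TRUE))
  one_end <- flag_subtelomeric(cn, g, single_end = TRUE)
  expect_equal(one_end$subtelomeric, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("chromosome enrichment is CNVR length over chromosome length", {
  g <- build_genome(spec = data.frame(chrom = c("c1", "c2"),
                                      length = c(1e6, 2e6)))
  cn <- cnvr_frame(c("c1", "c1"), c(1, 50001), c(20000, 60000))
  enr <- chromosome_enrichment(cn, g)
  expect_equal(enr$cnvr_length_total, c(30000, 0))
  expect_equal(enr$enrichment_pct, c(3, 0))
  expect_equal(enr$n_cnvr, c(2L, 0L))
  expect_error(chromosome_enrichment(cnvr_frame("cZ", 1, 10), g), "unknown")
  # genome enrichment equals the length-weighted mean of per-chromosome values
  expect_equal(sum(enr$enrichment_pct * g$length) / sum(g$length),
               enrichment_percent(sum(cn$length), total_genome_length(g)))
})

test_that("published per-chromosome lengths reproduce every printed enrichment", {
  tab <- horse_cnvr_by_chrom()
  recomputed <- round(enrichment_percent(tab$cnvr_length, tab$chrom_length), 2)
  expect_equal(recomputed, tab$enrichment_pct)
  expect_equal(sum(tab$n_cnvr), 258)
  expect_equal(sum(tab$gains) + sum(tab$losses) + sum(tab$complex), 258)
})

test_that("cohort summary handles raw calls and degenerate inputs", {
  calls <- rbind(make_calls("A", "chr1", c(100, 500), c(200, 900), "loss"),
                 make_calls("B", "chr1", 150, 260, "gain"))
  cs <- cohort_summary(calls)
  expect_equal(cs$per_sample$calls, c(2L, 1L))
  expect_equal(cs$mean_calls, 1.5)
  expect_equal(cs$mean_gains, 0.5)
  expect_equal(cs$mean_losses, 1)
  # one CNVR of size s: mean == median == s
  one <- cohort_summary(make_calls("A", "chr1", 100, 199),
                        cnvrs = cnvr_frame("chr1", 100, 199),
                        genome = build_genome(spec = data.frame(
                          chrom = "chr1", length = 1e4)))
  expect_equal(one$mean_cnvr_size, 100)
  expect_equal(one$median_cnvr_size, 100)
  expect_equal(one$genome_enrichment_pct, 1)
  expect_error(cohort_summary(NULL), "counts")
})

test_that("tissue comparison is an equal-variance two-sided Student's t", {
  same <- tissue_comparison(c(1, 2, 3, 1, 2, 3),
                            rep(c("blood", "hair"), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- c(10, 12, 14); b <- c(20, 22, 24)
  got <- tissue_comparison(c(a, b), rep(c("blood", "hair"), each = 3))
  # textbook pooled-variance computation as the oracle
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$t, t_hand)
  expect_equal(got$df, 4)
  expect_equal(got$p, 2 * pt(-abs(t_hand), 4))

  # third-tissue samples are ignored, small groups are an error
  with_fibro <- tissue_comparison(c(a, b, 99, 98),
                                  c(rep(c("blood", "hair"), each = 3),
                                    "fibroblast", "fibroblast"))
  expect_equal(with_fibro$t, t_hand)
  expect_error(tissue_comparison(c(1, 2, 3), c("blood", "blood", "hair")),
               "at least 2")
})
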