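test_that("positional deduplication keeps the highest-mapq read, first on ties", {
  aln <- make_reads("chr1", c(100, 100, 101), mapq = c(30L, 42L, 10L))
  out <- dedup_alignments(aln)
  expect_equal(nrow(out), 2L)
  expect_equal(out$mapq[out$start == 100], 42L)

  tie <- make_reads("chr1", c(100, 100, 100), mapq = c(10L, 10L, 10L),
                    id = c("first", "second", "third"))
  out <- dedup_alignments(tie)
  expect_equal(nrow(out), 1L)
  expect_equal(out$read_id, "first")
})

test_that("deduplication is idempotent and rejects unsorted input", {
  set.seed(3)
  aln <- make_reads("chr1", sort(sample(1:200, 80, replace = TRUE)),
                    mapq = sample(0:60, 80, replace = TRUE))
  once <- dedup_alignments(aln)
  expect_equal(dedup_alignments(once), once)

  bad <- make_reads("chr1", c(100, 50), id = c("ok", "late"))
  expect_error(dedup_alignments(bad), "late")
  interleaved <- make_reads(c("chr1", "chr2", "chr1"), c(1, 1, 5))
  expect_error(dedup_alignments(interleaved), "not sorted")
})

test_that("deduplication warns when read ids repeat across positions", {
  aln <- make_reads("chr1", c(100, 200), id = c("dup", "dup"))
  expect_warning(dedup_alignments(aln), "multi-hit")
})

test_that("overlap counting uses >= 1 bp half-open intersection", {
  genes <- gene_intervals(c("g1", "g2"), "chr1", c(0, 200), c(200, 400))
  # read ending exactly at a gene start touches nothing of it
  aln <- make_reads("chr1", c(100, 200, 164, 170))
  n <- count_overlaps(aln, genes)
  # [100,136) in g1; [200,236) NOT in g1, in g2; [164,200) only g1;
  # [170,206) spans the boundary: both genes
  expect_equal(unname(n), c(3L, 2L))
})

test_that("overlap counting agrees with the brute-force oracle", {
  set.seed(7)
  genes <- gene_intervals(sprintf("g%d", 1:12),
                          rep(c("chr1", "chr2"), each = 6),
                          rep(seq(0, 5000, by = 1000), 2),
                          rep(seq(0, 5000, by = 1000), 2) +
                            sample(100:900, 12))
  aln <- make_reads(sample(c("chr1", "chr2"), 300, replace = TRUE),
                    sample(0:6000, 300, replace = TRUE),
                    len = sample(c(36L, 51L), 300, replace = TRUE))
  expect_equal(count_overlaps(aln, genes), oracle_overlap_counts(aln, genes))
})

test_that("count_reads assembles counts and post-dedup totals per sample", {
  genes <- gene_intervals("g1", "chr1", 0, 200)
  s1 <- make_reads("chr1", c(10, 10, 50, 300), mapq = c(10L, 42L, 42L, 42L))
  s2 <- make_reads("chr1", c(100, 400))
  cm <- count_reads(genes, list(a = s1, b = s2), group = c("A", "B"))
  expect_equal(unname(cm$counts[1, ]), c(2, 1))     # dedup collapses 10/10
  expect_equal(cm$samples$total_mapped_reads, c(3, 2))
})

test_that("gene filtering applies the per-100bp median and zero rules", {
  # 4 samples; gene lengths chosen to hit both rules and the boundary
  counts <- rbind(
    c(8, 8, 8, 8),     # len 1000: median per-100bp = 0.8 < 1 -> removed
    c(5, 9, 0, 7),     # zero in one individual -> removed
    c(10, 10, 10, 10), # len 1000: per-100bp exactly 1 -> retained
    c(50, 60, 70, 80)) # comfortably retained
  cm <- toy_count_matrix(counts, lengths = c(1000, 100, 1000, 1000))
  out <- filter_genes(cm)
  expect_equal(out$genes$gene_id, c("g003", "g004"))
  log <- attr(out, "removal_log")
  expect_equal(log$rule[log$gene_id == "g001"], "median_per_100bp")
  expect_equal(log$rule[log$gene_id == "g002"], "zero_individual")
})

test_that("filtering never retains a gene with a zero count anywhere", {
  set.seed(5)
  for (rep in 1:10) {
    counts <- matrix(rpois(20 * 8, 3), 20, 8)
    cm <- toy_count_matrix(counts, lengths = sample(100:2000, 20))
    out <- filter_genes(cm)
    if (nrow(out$counts)) expect_true(all(out$counts > 0))
  }
})

test_that("normalization divides by totals and is scale invariant", {
  cm <- toy_count_matrix(matrix(c(10, 20), 1, 2), totals = c(1e6, 1e6))
  cm <- normalize_counts(cm)
  expect_equal(cm$normalized[1, 1], 1e-5)

  cm2 <- toy_count_matrix(matrix(c(20, 20), 1, 2), totals = c(2e6, 1e6))
  cm2 <- normalize_counts(cm2)
  expect_equal(cm2$normalized[1, 1], cm$normalized[1, 1])

  cm$samples$total_mapped_reads[1] <- 0
  expect_error(normalize_counts(cm), "zero total")
})

test_that("group ratios, pair standard deviations, and undefined flags", {
  counts <- rbind(c(20, 20, 10, 10),
                  c(5, 5, 5, 5),
                  c(7, 7, 0, 0))
  cm <- toy_count_matrix(counts)
  gr <- group_ratio(cm)
  expect_equal(gr$ratio_A_over_B[1], 2)
  expect_equal(gr$ratio_A_over_B[2], 1)
  expect_true(is.na(gr$ratio_A_over_B[3]) && gr$undefined[3])

  # three pairs engineered to per-pair ratios 1, 2, 3 for gene 1
  counts <- rbind(c(10, 20, 30, 10, 10, 10), c(5, 5, 5, 5, 5, 5))
  cm <- toy_count_matrix(counts, group = rep(c("A", "B"), each = 3))
  pairing <- list(list(A = "s01", B = "s04"),
                  list(A = "s02", B = "s05"),
                  list(A = "s03", B = "s06"))
  gr <- group_ratio(cm, pairing)
  expect_equal(gr$sd_pairs[1], 1)  # sd of {1,2,3}
  expect_equal(gr$sd_pairs[2], 0)
})
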