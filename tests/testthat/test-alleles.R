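test_that("the pileup caller requires two supported high-quality alleles", {
  # column of A x10: monomorphic
  mono <- reads_for_haplotypes(c(AA = 10), 100, 110)
  expect_equal(nrow(call_snvs(mono)), 0L)

  # A x6 / G x4 at the first position, all Q40
  bi <- reads_for_haplotypes(c(AC = 6, GC = 4), 100, 110)
  snv <- call_snvs(bi)
  expect_equal(snv$pos, 100)
  expect_equal(snv$n_alleles, 2L)
  expect_match(snv$alleles, "A:6")
  expect_match(snv$alleles, "G:4")

  # minor allele with a single read does not qualify at min_allele_reads=2
  weak <- reads_for_haplotypes(c(AC = 6, GC = 1), 100, 110)
  expect_equal(nrow(call_snvs(weak)), 0L)

  # low-quality bases are excluded before counting (Q < 30)
  lowq <- reads_for_haplotypes(c(AC = 6, GC = 4), 100, 110, qual_int = 20L)
  expect_equal(nrow(call_snvs(lowq)), 0L)
})

test_that("SNV pairs are those coverable by one read", {
  snvs <- data.frame(chrom = "chr1", pos = c(100, 130))
  expect_equal(nrow(snv_pairs(snvs, 36)), 1L)         # 30 <= 35
  snvs2 <- data.frame(chrom = "chr1", pos = c(100, 140))
  expect_equal(nrow(snv_pairs(snvs2, 36)), 0L)        # 40 > 35
  expect_equal(nrow(snv_pairs(snvs2, 36, inclusive = TRUE)), 0L)
  snvs3 <- data.frame(chrom = "chr1", pos = c(100, 135))
  expect_equal(nrow(snv_pairs(snvs3, 36)), 1L)        # 35 boundary in
  snvs4 <- data.frame(chrom = "chr1", pos = c(100, 136))
  expect_equal(nrow(snv_pairs(snvs4, 36)), 0L)
  expect_equal(nrow(snv_pairs(snvs4, 36, inclusive = TRUE)), 1L)

  trio <- data.frame(chrom = "chr1", pos = c(100, 110, 120))
  expect_equal(nrow(snv_pairs(trio, 36)), 3L)

  # pairs never cross reference sequences
  mixed <- data.frame(chrom = c("chr1", "chr2"), pos = c(100, 110))
  expect_equal(nrow(snv_pairs(mixed, 36)), 0L)
})

test_that("pair enumeration agrees with the quadratic oracle", {
  set.seed(83)
  for (i in 1:10) {
    pos <- sort(sample(0:500, sample(3:15, 1)))
    got <- snv_pairs(data.frame(chrom = "c", pos = pos), 36)
    ref <- oracle_snv_pairs(pos, 36)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) {
      expect_equal(got$pos1, ref[, 1])
      expect_equal(got$pos2, ref[, 2])
    }
  }
})

test_that("haplotype counting enforces support and quality thresholds", {
  reads <- reads_for_haplotypes(c(AC = 5, AG = 4, TC = 3), 100, 110)
  hp <- pair_haplotypes(reads, "chr1", 100, 110)
  expect_equal(hp$n_haplotypes, 3L)
  expect_equal(hp$haplotypes[["AC"]], 5L)

  weak <- reads_for_haplotypes(c(AC = 5, AG = 1), 100, 110)
  expect_equal(pair_haplotypes(weak, "chr1", 100, 110)$n_haplotypes, 1L)

  # a read with N at either position is excluded from the tally
  withN <- reads_for_haplotypes(c(AC = 2, NC = 2), 100, 110)
  hp <- pair_haplotypes(withN, "chr1", 100, 110)
  expect_equal(names(hp$haplotypes), "AC")

  # reads must cover BOTH positions
  short <- reads_for_haplotypes(c(AC = 5), 100, 110)
  expect_equal(pair_haplotypes(short, "chr1", 100, 150)$n_haplotypes, 0L)
})

test_that("error-free diploid reads never exceed two haplotypes", {
  for (seed in 1:5) {
    aln <- simulate_paralog_reads(2, depth_per_haplotype = 12, seed = seed)
    res <- paracnv:::individual_multiplicity(aln)
    expect_lte(res$max_haplotypes, 2L)
  }
})

test_that("collapsed paralogs reveal their true haplotype number", {
  for (h in 2:4) {
    aln <- simulate_paralog_reads(h, depth_per_haplotype = 15, seed = h)
    res <- paracnv:::individual_multiplicity(aln)
    expect_equal(res$max_haplotypes, h)
  }
})

test_that("group classification needs three qualifying individuals in one group", {
  grp <- rep(c("A", "B"), each = 5)
  # 3 group-A individuals with 2 qualifying pairs each: call + strong
  n3 <- setNames(c(2, 2, 2, 0, 0, 0, 0, 0, 0, 0), sprintf("i%02d", 1:10))
  call <- classify_multiplicity(n3, grp)
  expect_true(call$group_call[["A"]])
  expect_true(call$strong[["A"]])
  expect_false(call$group_call[["B"]])

  # only 2 qualifying individuals: no call
  n2 <- setNames(c(3, 3, 0, 0, 0, 0, 0, 0, 0, 0), sprintf("i%02d", 1:10))
  expect_false(any(classify_multiplicity(n2, grp)$group_call))

  # 2 + 2 split across groups: no call for either
  n22 <- setNames(c(1, 1, 0, 0, 0, 1, 1, 0, 0, 0), sprintf("i%02d", 1:10))
  expect_false(any(classify_multiplicity(n22, grp)$group_call))

  # 3 individuals with exactly 1 qualifying pair: call but not strong
  n1 <- setNames(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), sprintf("i%02d", 1:10))
  call <- classify_multiplicity(n1, grp)
  expect_true(call$group_call[["A"]])
  expect_false(call$strong[["A"]])
})

test_that("gene_multiplicity runs the per-individual pipeline end to end", {
  grp <- rep(c("A", "B"), each = 5)
  aln <- lapply(1:10, function(i)
    simulate_paralog_reads(if (i <= 4) 3 else 2, depth_per_haplotype = 15,
                           seed = 200 + i))
  names(aln) <- sprintf("i%02d", 1:10)
  call <- gene_multiplicity(aln, grp)
  expect_true(call$group_call[["A"]])
  expect_false(call$group_call[["B"]])
  expect_equal(sum(call$per_individual$n_pairs_ge3[1:4] >= 1), 4L)
})

test_that("externally supplied SNV sites replace the internal caller", {
  reads <- reads_for_haplotypes(c(AC = 5, AG = 4, TC = 3), 100, 110)
  snvs <- data.frame(chrom = "chr1", pos = c(100, 110))
  res <- paracnv:::individual_multiplicity(reads, snvs = snvs)
  expect_equal(res$max_haplotypes, 3L)
})
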