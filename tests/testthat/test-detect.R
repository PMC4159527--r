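test_that("exact test agrees with full enumeration across dispersions", {
  set.seed(101)
  for (i in 1:60) {
    yA <- sample(0:50, 1); yB <- sample(0:50, 1)
    phi <- sample(c(0, 0.05, 0.2, 1), 1)
    nA <- sample(2:10, 1); nB <- sample(2:10, 1)
    expect_equal(nb_exact_test(yA, yB, nA, nB, phi),
                 oracle_exact_p(yA, yB, nA, nB, phi), tolerance = 1e-12)
  }
})

test_that("exact test hits the closed-form binomial limit and symmetry", {
  # observed split (10, 0) under phi = 0, equal groups: only the two
  # extreme splits are as improbable as the observed one
  expect_equal(nb_exact_test(10, 0, 10, 10, 0), 2 * 0.5^10)
  # the balanced split is the most probable one
  expect_equal(nb_exact_test(25, 25, 10, 10, 0.1), 1)
  expect_equal(nb_exact_test(0, 0, 10, 10, 0.1), 1)
  # group swap leaves p unchanged for equal group sizes
  set.seed(17)
  for (i in 1:20) {
    yA <- sample(0:200, 1); yB <- sample(0:200, 1)
    expect_equal(nb_exact_test(yA, yB, 10, 10, 0.13),
                 nb_exact_test(yB, yA, 10, 10, 0.13))
  }
  expect_error(nb_exact_test(5, 5, 10, 10, -0.1), "non-negative")
})

test_that("exact test matches edgeR's minimum-likelihood exact test", {
  skip_if_not_installed("edgeR")
  set.seed(23)
  y1 <- matrix(rnbinom(50 * 10, mu = 60, size = 10), 50, 10)
  y2 <- matrix(rnbinom(50 * 10, mu = 60, size = 10), 50, 10)
  p_ref <- edgeR::exactTestBySmallP(y1, y2, dispersion = 0.1)
  p_own <- nb_exact_test(rowSums(y1), rowSums(y2), 10, 10, 0.1)
  expect_equal(p_own, as.numeric(p_ref), tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up oracle and spec examples", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("common dispersion is recovered from simulated truth", {
  # identical counts in every sample: no excess variance at all
  cm <- toy_count_matrix(matrix(50, 1, 8))
  expect_equal(estimate_common_dispersion(cm)$phi, 0)

  set.seed(41)
  mu <- rlnorm(2000, log(80), 0.7)
  pois <- toy_count_matrix(matrix(rpois(2000 * 20, mu), 2000, 20),
                           group = rep(c("A", "B"), each = 10))
  expect_lt(estimate_common_dispersion(pois)$phi, 0.05)

  nb <- toy_count_matrix(matrix(rnbinom(2000 * 20, mu = mu, size = 10),
                                2000, 20),
                         group = rep(c("A", "B"), each = 10))
  phi_hat <- estimate_common_dispersion(nb)$phi
  expect_gt(phi_hat, 0.05)
  expect_lt(phi_hat, 0.2)

  expect_error(estimate_common_dispersion(
    toy_count_matrix(matrix(0, 3, 4))), "all-zero")
  expect_error(estimate_common_dispersion(
    toy_count_matrix(matrix(5, 3, 2), group = c("A", "B"))), ">= 2 samples")
})

test_that("library equalization scales to the geometric mean", {
  cm <- toy_count_matrix(matrix(c(100, 400), 1, 2), totals = c(1e6, 4e6))
  eq <- equalize_libsizes(cm)
  expect_equal(eq$target, 2e6)
  expect_equal(unname(eq$pseudo[1, ]), c(200, 200))
})

test_that("consensus requires significance under every stringency with a
           coherent direction", {
  # 30 genes, 5+5 samples; g1 shifted in all three stringencies, g2 only
  # in two of them
  set.seed(53)
  base <- matrix(rpois(30 * 10, 100), 30, 10)
  up <- c(rep(3, 5), rep(1, 5))  # signal in group A
  m <- list()
  for (k in 1:3) {
    counts <- base
    counts[1, ] <- rpois(10, 120 * up)
    if (k < 3) counts[2, ] <- rpois(10, 120 * up)
    m[[sprintf("opt%d", k)]] <- toy_count_matrix(counts)
  }
  fit <- gcnv_detect(m, alpha = 0.05)
  tab <- fit$table
  expect_true(tab$consensus_gcnv[tab$gene_id == "g001"])
  expect_false(tab$consensus_gcnv[tab$gene_id == "g002"])
  expect_true(tab$sig_opt1[tab$gene_id == "g002"])  # 2/3 is not consensus
  expect_equal(tab$direction[tab$gene_id == "g001"], "increased_in_A")
  # alpha >= 1 disables thresholding: every tested gene significant
  # (consensus can still drop direction conflicts among null genes)
  fit1 <- suppressWarnings(gcnv_detect(m, alpha = 1))
  for (l in fit1$labels)
    expect_true(all(fit1$table[[paste0("sig_", l)]]))
})

test_that("the gene universe is the intersection of post-filter sets", {
  counts <- matrix(rpois(10 * 6, 50), 10, 6)
  m1 <- toy_count_matrix(counts, group = rep(c("A", "B"), each = 3))
  counts2 <- counts
  counts2[4, 2] <- 0  # fails the zero rule only under stringency 2
  m2 <- toy_count_matrix(counts2, group = rep(c("A", "B"), each = 3))
  fit <- gcnv_detect(list(a = m1, b = m2))
  expect_false("g004" %in% fit$table$gene_id)
  expect_equal(fit$n_genes_tested, 9L)
})

test_that("null p-values are roughly uniform (screen calibration)", {
  set.seed(61)
  mu <- rlnorm(800, log(60), 0.6)
  counts <- matrix(rnbinom(800 * 20, mu = mu, size = 10), 800, 20)
  cm <- toy_count_matrix(counts, lengths = pmax(round(mu * 15), 150),
                         group = rep(c("A", "B"), each = 10))
  fit <- gcnv_detect(cm, alpha = 0.05)
  p <- fit$table$p_option1
  expect_lt(suppressWarnings(
    ks.test(p, "punif")$statistic), 0.08)
  expect_lt(mean(fit$table$sig_option1), 0.02)
})
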