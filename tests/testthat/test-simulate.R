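test_that("scenario configuration validates its inputs", {
  expect_error(scenario_config(stringency_retention = c(0.8, 0.9, 1.0)),
               "non-increasing")
  expect_error(scenario_config(stringency_retention = c(1, 0.9, 0)),
               "\\(0, 1\\]")
  expect_error(scenario_config(gcnv_spec = gcnv_events(1, "A", 2.5)),
               "integer")
  expect_error(scenario_config(gcnv_spec = gcnv_events(1, "fresh", 4)),
               "'A' or 'B'")
})

test_that("copy number scales expected counts linearly", {
  cfg <- scenario_config(n_genes = 300, phi = 0.05, lib_size_cv = 0,
                         gcnv_spec = gcnv_events(1:30, "A", 4), seed = 5)
  sim <- simulate_count_matrices(cfg)
  cm <- normalize_counts(sim$matrices[[1]])
  A <- cm$samples$group == "A"
  ratio <- rowMeans(cm$normalized[1:30, A]) / rowMeans(cm$normalized[1:30, !A])
  # CN 4 vs 2 -> ratio 2 in expectation, averaged over 30 genes x 10+10
  expect_equal(mean(ratio), 2, tolerance = 0.1)
  base_ratio <- rowMeans(cm$normalized[31:300, A]) /
    rowMeans(cm$normalized[31:300, !A])
  expect_equal(mean(base_ratio), 1, tolerance = 0.1)
})

test_that("zero dispersion and full retention make the replicates identical", {
  cfg <- scenario_config(n_genes = 100, phi = 0,
                         stringency_retention = c(1, 1, 1), seed = 2)
  sim <- simulate_count_matrices(cfg)
  expect_identical(sim$matrices[[1]]$counts, sim$matrices[[2]]$counts)
  expect_identical(sim$matrices[[2]]$counts, sim$matrices[[3]]$counts)
})

test_that("the study-shaped scenario flags exactly 24 true GCNVs, 19 + 5", {
  sim <- simulate_count_matrices(parallel_scenario(n_genes = 800, seed = 3))
  tr <- sim$truth
  expect_equal(sum(tr$is_true_gcnv), 24L)
  expect_equal(sum(tr$direction == "increased_in_A", na.rm = TRUE), 19L)
  expect_equal(sum(tr$direction == "increased_in_B", na.rm = TRUE), 5L)
  expect_true(all(tr$cn_A[tr$is_true_gcnv & tr$direction ==
                            "increased_in_A"] == 4))
  # placement respects the eligibility floor: baseline expectation >= 20
  cfg <- sim$config
  len <- sim$matrices[[1]]$genes$length
  mu0 <- cfg$mean_depth / cfg$read_length * (len + cfg$read_length - 1)
  expect_true(all(mu0[tr$is_true_gcnv] >= cfg$min_mean_count))
  # one 7-gene cluster among the group-A events
  idxA <- which(tr$direction == "increased_in_A")
  runs <- rle(diff(sort(idxA)) == 1)
  expect_true(any(runs$lengths[runs$values] >= 6))
})

test_that("simulated counts are mean-accurate (moment check)", {
  # tiny scenario replicated 200 times; per-gene empirical means must sit
  # within 3 standard errors of the model expectation
  cfg0 <- scenario_config(n_genes = 12, n_per_group = 2, phi = 0.1,
                          lib_size_cv = 0, n_stringencies = 1,
                          stringency_retention = 0.8, seed = 1)
  # gene lengths are redrawn per replicate seed, so compare each count to
  # its own replicate's expectation and test the centred residuals
  resid <- lapply(1:200, function(s) {
    cfg <- cfg0; cfg$seed <- s
    m <- simulate_count_matrices(cfg)$matrices[[1]]
    mu <- 0.8 * cfg0$mean_depth / cfg0$read_length * (m$genes$length + 35)
    m$counts - mu   # CN 2 baseline everywhere
  })
  arr <- simplify2array(resid)          # genes x samples x reps
  ndraws <- prod(dim(arr)[2:3])
  emp <- apply(arr, 1, mean)
  se <- apply(arr, 1, sd) / sqrt(ndraws)
  expect_true(all(abs(emp) <= 3 * se + 1e-9))
})

test_that("binomial thinning preserves the NB dispersion (moments)", {
  set.seed(9)
  cfg <- scenario_config(n_genes = 3000, n_per_group = 10, phi = 0.2,
                         lib_size_cv = 0, n_stringencies = 2,
                         stringency_retention = c(1, 0.7), seed = 9)
  sim <- simulate_count_matrices(cfg)
  thinned <- sim$matrices[[2]]$counts
  m <- rowMeans(thinned)
  v <- apply(thinned, 1, var)
  phi_mom <- median((v - m) / m^2, na.rm = TRUE)
  expect_lt(abs(phi_mom - 0.2), 0.06)
})

test_that("fixture bundles are byte-reproducible under a fixed seed", {
  cfg <- scenario_config(n_genes = 40, gcnv_spec = gcnv_events(c(5, 20), "A", 4),
                         min_mean_count = 0, seed = 12)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  make_fixture_bundle(cfg, d1)
  make_fixture_bundle(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
  expect_true(any(grepl("^reads/", f1)))  # multiplicity fixtures present
  expect_true(all(c("genes.bed", "groups.tsv", "truth.tsv",
                    "config.txt") %in% f1))
})

test_that("truth directions match the simulated expectation in sign", {
  cfg <- scenario_config(n_genes = 200, phi = 0.05, lib_size_cv = 0,
                         gcnv_spec = rbind(gcnv_events(1:5, "A", 4),
                                           gcnv_events(6:10, "B", 4),
                                           gcnv_events(11:15, "A", 1)),
                         min_mean_count = 0, seed = 21)
  sim <- simulate_count_matrices(cfg)
  cm <- normalize_counts(sim$matrices[[1]])
  A <- cm$samples$group == "A"
  dirs <- ifelse(rowMeans(cm$normalized[, A]) >=
                   rowMeans(cm$normalized[, !A]),
                 "increased_in_A", "increased_in_B")
  tr <- sim$truth
  idx <- which(tr$is_true_gcnv)
  expect_true(mean(dirs[idx] == tr$direction[idx]) > 0.9)
  expect_equal(tr$direction[11], "increased_in_B")  # CN 1 in A = loss
})
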