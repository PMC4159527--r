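# Null distribution of the GCNV count under random balanced reallocation
# of individuals into two groups.

# Precompute everything label-free for one stringency so each permutation
# only redoes the label-dependent work (group sums, dispersion, exact
# test, FDR). Library sizes, pseudo-counts and both filter rules do not
# involve the group labels, so the filtered gene set and the equalized
# matrix are permutation-invariant.
make_stringency_engine <- function(cm, alpha, filter = TRUE) {
  if (filter) cm <- filter_genes(cm)
  eq <- equalize_libsizes(cm)
  pseudo <- eq$pseudo
  v <- as.vector(pseudo)
  vals <- sort(unique(v))
  y_tab <- list(vals = vals, freq = tabulate(match(v, vals)))
  n <- ncol(pseudo)
  list(
    gene_id = cm$genes$gene_id,
    n_samples = n,
    count_significant = function(idx_A) {
      idx_B <- setdiff(seq_len(n), idx_A)
      f <- function(phi) cond_loglik(phi, pseudo, list(idx_A, idx_B), y_tab)
      opt <- optimize(f, interval = c(0, 10), maximum = TRUE, tol = 1e-6)
      phi <- if (f(0) >= opt$objective) 0 else opt$maximum
      sumA <- rowSums(pseudo[, idx_A, drop = FALSE])
      sumB <- rowSums(pseudo[, idx_B, drop = FALSE])
      p <- nb_exact_test(sumA, sumB, length(idx_A), length(idx_B), phi)
      fdr <- bh_fdr(p)
      list(n_sig = sum(fdr < alpha), sig = fdr < alpha)
    })
}

#' Permutation null for the number of detected GCNVs
#'
#' Randomly reallocates the individuals into two balanced groups
#' \code{n_perm} times, reruns the full per-stringency analysis
#' (filtering, library equalization, dispersion estimation, exact test,
#' BH FDR) on each reallocation, and records the number of significant
#' genes. The empirical p-value for the observed count is
#' \eqn{(\#\{null \ge observed\} + 1) / (n_{perm} + 1)} (the +1 correction
#' avoids p = 0; set \code{plus_one = FALSE} for the raw fraction). The
#' identity permutation, if drawn, counts as an ordinary null draw.
#'
#' In \code{"per_stringency"} mode each stringency gets its own null and
#' empirical p (the per-mapping-option test); in \code{"consensus"} mode
#' the permuted statistic is the number of genes significant under every
#' stringency at once.
#'
#' @param matrices a \code{\link{count_matrix}} or list of them (one per
#'   stringency). Group sizes must be balanced (n vs n).
#' @param n_perm number of reallocations (10000 for a full analysis;
#'   presets of 200 or 1000 are practical for desk-scale work).
#' @param seed RNG seed; the null count vector is reproducible bit for bit
#'   under a fixed seed.
#' @param mode \code{"per_stringency"} or \code{"consensus"}.
#' @param alpha per-stringency FDR threshold.
#' @param filter apply \code{\link{filter_genes}} (label-free, hence
#'   computed once up front).
#' @param plus_one use the +1/(n_perm+1) correction.
#' @return An object of class \code{"gcnv_perm"}: \code{null_counts}
#'   (n_perm x k matrix in per-stringency mode, vector in consensus mode),
#'   \code{observed}, \code{empirical_p}, plus the run settings.
#' @export
gcnv_permute <- function(matrices, n_perm = 10000, seed = NULL,
                         mode = c("per_stringency", "consensus"),
                         alpha = 0.05, filter = TRUE, plus_one = TRUE) {
  mode <- match.arg(mode)
  if (inherits(matrices, "count_matrix")) matrices <- list(matrices)
  if (!is_count(n_perm) || n_perm < 1) stopf("n_perm must be >= 1")
  k <- length(matrices)
  labels <- names(matrices) %||% sprintf("option%d", seq_len(k))
  labels[labels == ""] <- sprintf("option%d", which(labels == ""))

  group <- matrices[[1]]$samples$group
  lev <- group_levels(group)
  nA <- sum(group == lev[1]); nB <- sum(group == lev[2])
  if (nA != nB)
    stopf("balanced reallocation requires equal group sizes (got %d vs %d)",
          nA, nB)
  n <- nA + nB

  engines <- lapply(matrices, make_stringency_engine, alpha = alpha,
                    filter = filter)
  if (mode == "consensus") {
    universe <- Reduce(intersect, lapply(engines, `[[`, "gene_id"))
    if (!length(universe)) stopf("no genes survive the filter under every stringency")
    keep <- lapply(engines, function(e) match(universe, e$gene_id))
  }

  stat <- function(idx_A) {
    res <- lapply(engines, function(e) e$count_significant(idx_A))
    if (mode == "per_stringency") {
      vapply(res, `[[`, 0L, "n_sig")
    } else {
      sig <- mapply(function(r, kp) r$sig[kp], res, keep)
      sum(rowSums(matrix(sig, ncol = k)) == k)
    }
  }

  observed <- stat(which(group == lev[1]))
  if (!is.null(seed)) set.seed(seed)
  null_counts <- if (mode == "per_stringency")
    matrix(0L, n_perm, k, dimnames = list(NULL, labels)) else integer(n_perm)
  for (b in seq_len(n_perm)) {
    idx_A <- sample.int(n, nA)
    s <- stat(idx_A)
    if (mode == "per_stringency") null_counts[b, ] <- s else null_counts[b] <- s
  }

  emp <- function(nullv, obs) {
    if (plus_one) (sum(nullv >= obs) + 1) / (n_perm + 1)
    else mean(nullv >= obs)
  }
  empirical_p <- if (mode == "per_stringency") {
    setNames(vapply(seq_len(k),
                    function(i) emp(null_counts[, i], observed[i]), 0),
             labels)
  } else emp(null_counts, observed)
  if (mode == "per_stringency") names(observed) <- labels

  structure(list(n_perm = n_perm, mode = mode, alpha = alpha,
                 labels = labels, observed = observed,
                 null_counts = null_counts, empirical_p = empirical_p,
                 plus_one = plus_one, seed = seed),
            class = "gcnv_perm")
}

#' @export
print.gcnv_perm <- function(x, ...) {
  cat(sprintf("permutation null, %d balanced reallocations (%s mode, alpha = %g)\n",
              x$n_perm, x$mode, x$alpha))
  if (x$mode == "per_stringency") {
    for (i in seq_along(x$labels))
      cat(sprintf("  %s: observed %d significant genes, null mean %.2f, empirical p = %.4g\n",
                  x$labels[i], x$observed[i], mean(x$null_counts[, i]),
                  x$empirical_p[i]))
  } else {
    cat(sprintf("  observed %d consensus GCNVs, null mean %.2f, empirical p = %.4g\n",
                x$observed, mean(x$null_counts), x$empirical_p))
  }
  invisible(x)
}
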