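# Two-group screen for copy-number differences: library-size
# equalization, common NB dispersion by conditional maximum likelihood,
# per-gene exact test, BH FDR, consensus over mapping stringencies.

#' Equalize library sizes by proportional scaling
#'
#' Scales each sample's counts to the geometric mean of the genome-wide
#' totals and rounds to the nearest integer, producing pseudo-counts on a
#' common library size — the counts the exact test and the dispersion
#' estimator operate on.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @return list: \code{pseudo} (matrix), \code{target} (common library
#'   size).
#' @export
equalize_libsizes <- function(cm) {
  totals <- cm$samples$total_mapped_reads
  target <- exp(mean(log(totals)))
  pseudo <- round(sweep(cm$counts, 2L, target / totals, "*"))
  list(pseudo = pseudo, target = target)
}

# conditional log-likelihood of a common dispersion phi, given per-group
# gene totals, on equalized pseudo-counts. For iid NB(mu, size r) samples
# the distribution of (y_1..y_n) given z = sum y_i is negative
# hypergeometric: P(y|z) = prod C(y_i+r-1, y_i) / C(z+nr-1, z); the phi=0
# limit is multinomial with equal cell probabilities.
# Terms in y alone are label-free; terms in the group totals z are not.
cond_loglik <- function(phi, pseudo, group_idx, y_tab = NULL) {
  n_tot <- ncol(pseudo)
  if (is.null(y_tab)) {
    v <- as.vector(pseudo)
    vals <- sort(unique(v))
    y_tab <- list(vals = vals, freq = tabulate(match(v, vals)))
  }
  ll <- 0
  if (phi <= 0) {
    y_term <- -sum(y_tab$freq * lgamma(y_tab$vals + 1))
    for (idx in group_idx) {
      z <- rowSums(pseudo[, idx, drop = FALSE])
      n <- length(idx)
      ll <- ll + sum(lgamma(z + 1) - z * log(n))
    }
    return(ll + y_term)
  }
  r <- 1 / phi
  y_term <- sum(y_tab$freq * (lgamma(y_tab$vals + r) - lgamma(y_tab$vals + 1)))
  m <- nrow(pseudo)
  for (idx in group_idx) {
    n <- length(idx)
    z <- rowSums(pseudo[, idx, drop = FALSE])
    ll <- ll + sum(-lgamma(z + n * r) + lgamma(z + 1)) +
      m * (lgamma(n * r) - n * lgamma(r))
  }
  ll + y_term
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes, over \eqn{\phi \in [0, 10]}, the sum across genes and groups
#' of the negative-binomial log-likelihood conditional on the per-group
#' gene totals, computed on library-size-equalized pseudo-counts
#' (variance model \eqn{\mu + \phi \mu^2}; \eqn{\phi = 0} is Poisson).
#' Conditioning removes the per-gene means, leaving a one-dimensional
#' likelihood in the dispersion alone.
#'
#' @param cm a \code{\link{count_matrix}}, or a pseudo-count matrix.
#' @param group per-sample group labels (required if \code{cm} is a bare
#'   matrix; otherwise taken from \code{cm}).
#' @param interval search bracket for \eqn{\phi}.
#' @param tol convergence tolerance on \eqn{\phi}.
#' @return list of class \code{"dispersion_estimate"}: \code{phi},
#'   \code{loglik}.
#' @export
estimate_common_dispersion <- function(cm, group = NULL,
                                       interval = c(0, 10), tol = 1e-6) {
  if (inherits(cm, "count_matrix")) {
    group <- group %||% cm$samples$group
    pseudo <- equalize_libsizes(cm)$pseudo
  } else {
    pseudo <- as.matrix(cm)
  }
  if (is.null(group)) stopf("group labels required")
  if (sum(pseudo) == 0) stopf("all-zero count matrix")
  lev <- group_levels(group)
  group_idx <- lapply(lev, function(l) which(group == l))
  if (any(lengths(group_idx) < 2L))
    stopf("need >= 2 samples per group to estimate dispersion")
  v <- as.vector(pseudo)
  vals <- sort(unique(v))
  y_tab <- list(vals = vals, freq = tabulate(match(v, vals)))
  f <- function(phi) cond_loglik(phi, pseudo, group_idx, y_tab)
  opt <- optimize(f, interval = interval, maximum = TRUE, tol = tol)
  ll0 <- f(0)
  if (ll0 >= opt$objective) {
    phi <- 0; ll <- ll0
  } else {
    phi <- opt$maximum; ll <- opt$objective
  }
  structure(list(phi = phi, loglik = ll), class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("common NB dispersion phi = %.6g (variance = mu + phi*mu^2)\n",
              x$phi))
  invisible(x)
}

#' Negative-binomial exact test for a two-group difference in counts
#'
#' Tests whether the group-A and group-B sums of library-size-equalized
#' counts are compatible with a common per-sample mean. Group sums are NB
#' with sizes \eqn{n_A/\phi} and \eqn{n_B/\phi} (sum of iid NB); the test
#' conditions on the total and sums the probabilities of all splits no
#' more probable than the observed one (minimum-likelihood two-sided
#' rule). With \eqn{\phi = 0} this reduces to the conditional binomial
#' (Poisson) test. Vectorized over genes.
#'
#' @param count_sum_A,count_sum_B per-gene group sums of equalized
#'   (pseudo-)counts; non-negative integers.
#' @param n_A,n_B group sizes.
#' @param phi common NB dispersion (scalar, >= 0); a
#'   \code{"dispersion_estimate"} is accepted.
#' @param tol relative tolerance when comparing split probabilities to the
#'   observed one (guards ties against rounding).
#' @return p-values in (0, 1].
#' @export
nb_exact_test <- function(count_sum_A, count_sum_B, n_A, n_B, phi,
                          tol = 1e-7) {
  if (inherits(phi, "dispersion_estimate")) phi <- phi$phi
  if (length(phi) != 1L || is.na(phi) || phi < 0)
    stopf("phi must be a single non-negative number")
  if (any(count_sum_A < 0) || any(count_sum_B < 0))
    stopf("count sums must be non-negative")
  yA <- round(as.numeric(count_sum_A))
  yB <- round(as.numeric(count_sum_B))
  .nb_exact_pvals_cpp(yA, yB, as.numeric(n_A), as.numeric(n_B),
                      as.numeric(phi), tol)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' capped at 1 and mapped back to input order. Input p-values are
#' validated to lie in [0, 1].
#'
#' @param p p-values in [0, 1].
#' @return Adjusted values (same order as input).
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# one stringency: pseudo-counts -> dispersion -> exact test -> FDR
detect_one <- function(cm, alpha = 0.05) {
  lev <- group_levels(cm$samples$group)
  A <- cm$samples$group == lev[1]
  B <- cm$samples$group == lev[2]
  eq <- equalize_libsizes(cm)
  disp <- estimate_common_dispersion(eq$pseudo, cm$samples$group)
  sumA <- rowSums(eq$pseudo[, A, drop = FALSE])
  sumB <- rowSums(eq$pseudo[, B, drop = FALSE])
  p <- nb_exact_test(sumA, sumB, sum(A), sum(B), disp$phi)
  fdr <- bh_fdr(p)
  cmn <- if (is.null(cm$normalized)) normalize_counts(cm) else cm
  mA <- rowMeans(cmn$normalized[, A, drop = FALSE])
  mB <- rowMeans(cmn$normalized[, B, drop = FALSE])
  list(gene_id = cm$genes$gene_id, p = p, fdr = fdr,
       mean_norm_A = mA, mean_norm_B = mB,
       direction = ifelse(mA >= mB, "increased_in_A", "increased_in_B"),
       phi = disp$phi, groups = lev)
}

#' Detect GCNVs likely under parallel selection
#'
#' The main fitting function. For each mapping-stringency count matrix:
#' filter weakly covered genes, restrict to the genes surviving the filter
#' under every stringency (the shared universe), equalize library sizes,
#' estimate a common dispersion, run the per-gene NB exact test, and
#' adjust by Benjamini-Hochberg. A gene is a consensus GCNV iff its FDR is
#' below \code{alpha} under every stringency; its direction (which group
#' has more copies) is read off the reference stringency's normalized
#' means and must agree across stringencies, else the gene is dropped from
#' the consensus with a warning.
#'
#' @param matrices a \code{\link{count_matrix}} or (named) list of them,
#'   one per mapping stringency.
#' @param alpha per-stringency FDR threshold (\code{alpha >= 1} disables
#'   thresholding: every tested gene is significant).
#' @param reference index of the stringency used for reported normalized
#'   means and directions.
#' @param filter apply \code{\link{filter_genes}} first (set to FALSE if
#'   the matrices are already filtered).
#' @return An object of class \code{"gcnv_fit"}; its \code{table} has one
#'   row per tested gene with per-stringency \code{p_*}, \code{fdr_*},
#'   \code{sig_*} columns, the direction, and \code{consensus_gcnv}.
#' @seealso \code{\link{gcnv_permute}} for the chance-expectation null,
#'   \code{\link{gene_multiplicity}} for duplication confirmation.
#' @export
gcnv_detect <- function(matrices, alpha = 0.05, reference = 1L,
                        filter = TRUE) {
  if (inherits(matrices, "count_matrix")) matrices <- list(matrices)
  k <- length(matrices)
  labels <- names(matrices) %||% sprintf("option%d", seq_len(k))
  labels[labels == ""] <- sprintf("option%d", which(labels == ""))
  if (!(alpha > 0)) stopf("alpha must be positive")

  removal_logs <- list()
  if (filter) {
    for (i in seq_len(k)) {
      matrices[[i]] <- filter_genes(matrices[[i]])
      removal_logs[[labels[i]]] <- attr(matrices[[i]], "removal_log")
    }
  }
  n_in <- vapply(matrices, function(m) nrow(m$counts), 0L)
  universe <- Reduce(intersect, lapply(matrices, function(m) m$genes$gene_id))
  if (!length(universe))
    stopf("no genes survive the filter under every stringency")
  matrices <- lapply(matrices, function(m)
    subset_genes(m, match(universe, m$genes$gene_id)))

  per <- lapply(matrices, detect_one, alpha = alpha)
  ref <- per[[reference]]
  tab <- data.frame(gene_id = universe,
                    mean_norm_A = ref$mean_norm_A,
                    mean_norm_B = ref$mean_norm_B,
                    direction = ref$direction,
                    stringsAsFactors = FALSE)
  sig <- matrix(FALSE, length(universe), k)
  for (i in seq_len(k)) {
    tab[[paste0("p_", labels[i])]] <- per[[i]]$p
    tab[[paste0("fdr_", labels[i])]] <- per[[i]]$fdr
    sig[, i] <- if (alpha >= 1) TRUE else per[[i]]$fdr < alpha
    tab[[paste0("sig_", labels[i])]] <- sig[, i]
  }
  consensus <- rowSums(sig) == k
  dirs <- vapply(per, `[[`, character(length(universe)), "direction")
  dirs <- matrix(dirs, nrow = length(universe))
  agree <- apply(dirs, 1L, function(d) length(unique(d)) == 1L)
  conflicted <- consensus & !agree
  if (any(conflicted)) {
    warnf("dropping %d consensus gene(s) with conflicting direction across stringencies: %s",
          sum(conflicted), paste(universe[conflicted], collapse = ", "))
    consensus[conflicted] <- FALSE
  }
  tab$consensus_gcnv <- consensus

  structure(list(table = tab, alpha = alpha, labels = labels,
                 reference = labels[reference],
                 groups = ref$groups,
                 dispersion = setNames(vapply(per, `[[`, 0, "phi"), labels),
                 n_genes_in = setNames(n_in, labels),
                 n_genes_tested = length(universe),
                 removal_log = removal_logs),
            class = "gcnv_fit")
}

#' @export
print.gcnv_fit <- function(x, ...) {
  cat(sprintf("GCNV detection: %d genes tested under %d mapping stringencies (%s)\n",
              x$n_genes_tested, length(x$labels),
              paste(x$labels, collapse = ", ")))
  cat(sprintf("  groups: A = %s, B = %s; FDR threshold alpha = %g\n",
              x$groups[1], x$groups[2], x$alpha))
  cat(sprintf("  common dispersion phi: %s\n",
              paste(sprintf("%s=%.4g", x$labels, x$dispersion), collapse = ", ")))
  nsig <- vapply(x$labels, function(l) sum(x$table[[paste0("sig_", l)]]), 0L)
  cat(sprintf("  significant per stringency: %s\n",
              paste(sprintf("%s=%d", x$labels, nsig), collapse = ", ")))
  nc <- sum(x$table$consensus_gcnv)
  up <- sum(x$table$consensus_gcnv & x$table$direction == "increased_in_A")
  cat(sprintf("  consensus GCNVs: %d (%d increased in %s, %d in %s)\n",
              nc, up, x$groups[1], nc - up, x$groups[2]))
  invisible(x)
}

#' @export
summary.gcnv_fit <- function(object, ...) {
  tab <- object$table[object$table$consensus_gcnv, , drop = FALSE]
  tab <- tab[order(tab[[paste0("fdr_", object$reference)]]), , drop = FALSE]
  structure(list(fit = object, consensus = tab), class = "summary.gcnv_fit")
}

#' @export
print.summary.gcnv_fit <- function(x, ...) {
  print(x$fit)
  if (nrow(x$consensus)) {
    cat("\nConsensus GCNVs (ordered by reference-stringency FDR):\n")
    cols <- c("gene_id", "direction", "mean_norm_A", "mean_norm_B",
              paste0("fdr_", x$fit$reference))
    print(format(x$consensus[, cols], digits = 3), row.names = FALSE)
  } else {
    cat("\nNo consensus GCNVs.\n")
  }
  invisible(x)
}

#' Plot a GCNV detection fit
#'
#' Reference-stringency FDR per gene (\eqn{-\log_{10}}) along the gene
#' index, consensus GCNVs highlighted, threshold line at \code{alpha}.
#'
#' @param x a \code{"gcnv_fit"}.
#' @param ... passed to \code{plot}.
#' @export
plot.gcnv_fit <- function(x, ...) {
  fdr <- x$table[[paste0("fdr_", x$reference)]]
  cons <- x$table$consensus_gcnv
  plot(seq_along(fdr), -log10(pmax(fdr, 1e-300)), pch = 16, cex = 0.5,
       col = ifelse(cons, "firebrick", "grey40"),
       xlab = "gene index", ylab = expression(-log[10] ~ FDR),
       main = sprintf("GCNV screen (%s)", x$reference), ...)
  abline(h = -log10(x$alpha), lty = 2)
  if (any(cons))
    legend("topright", pch = 16, col = "firebrick", bty = "n",
           legend = sprintf("consensus GCNV (n=%d)", sum(cons)))
  invisible(x)
}

#' Consensus GCNV calls from a fit
#'
#' @param fit a \code{"gcnv_fit"}.
#' @return data.frame of consensus genes with directions.
#' @export
consensus_gcnvs <- function(fit) {
  stopifnot(inherits(fit, "gcnv_fit"))
  fit$table[fit$table$consensus_gcnv,
            c("gene_id", "direction", "mean_norm_A", "mean_norm_B"),
            drop = FALSE]
}
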