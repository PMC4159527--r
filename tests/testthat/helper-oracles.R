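# Independent reference implementations used to cross-check the package:
# each recomputes a quantity by direct enumeration, never by calling the
# code path it validates.

# two-sided minimum-likelihood exact p by full enumeration of the
# conditional split distribution (dbinom / dnbinom, log space)
oracle_exact_p <- function(yA, yB, nA, nB, phi) {
  N <- yA + yB
  a <- 0:N
  if (phi <= 0) {
    lp <- dbinom(a, N, nA / (nA + nB), log = TRUE)
  } else {
    mu <- N / (nA + nB)
    lp <- dnbinom(a, size = nA / phi, mu = nA * mu, log = TRUE) +
      dnbinom(N - a, size = nB / phi, mu = nB * mu, log = TRUE)
  }
  p <- exp(lp - max(lp))
  sum(p[p <= p[yA + 1] * (1 + 1e-7)]) / sum(p)
}

# Benjamini-Hochberg step-up by the textbook formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, cummin(rev(p[o] * m / seq_len(m))))[m:1]
  out <- numeric(m)
  out[o] <- q
  out
}

# O(reads x genes) overlap counting
oracle_overlap_counts <- function(aln, genes) {
  n <- integer(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    for (r in seq_len(nrow(aln))) {
      if (aln$chrom[r] == genes$chrom[g] &&
          aln$start[r] < genes$end[g] &&
          aln$start[r] + aln$read_length[r] > genes$start[g])
        n[g] <- n[g] + 1L
    }
  }
  setNames(n, genes$gene_id)
}

# O(n^2) SNV pair enumeration
oracle_snv_pairs <- function(pos, L) {
  out <- list()
  pos <- sort(pos)
  for (i in seq_along(pos)) for (j in seq_along(pos)) {
    if (i < j && pos[j] - pos[i] <= L - 1)
      out[[length(out) + 1L]] <- c(pos[i], pos[j])
  }
  if (!length(out)) return(matrix(numeric(), 0, 2))
  do.call(rbind, out)
}

# hand-assembled count_matrix for unit tests
toy_count_matrix <- function(counts, lengths = NULL, group = NULL,
                             totals = NULL) {
  counts <- as.matrix(counts)
  ng <- nrow(counts); ns <- ncol(counts)
  if (is.null(lengths)) lengths <- rep(1000, ng)
  if (is.null(group)) group <- rep(c("A", "B"), each = ns / 2)
  if (is.null(totals)) totals <- rep(1e6, ns)
  start <- cumsum(c(0, lengths[-ng] + 100))
  genes <- gene_intervals(sprintf("g%03d", seq_len(ng)), "chr1", start,
                          start + lengths)
  count_matrix(counts, genes, group, totals,
               sprintf("s%02d", seq_len(ns)))
}

# alignment record builder (tabular convention)
make_reads <- function(chrom, start, len = 36L, mapq = 42L, seq = NULL,
                       qual = NULL, id = NULL) {
  n <- length(start)
  len <- rep_len(len, n)
  if (is.null(seq)) seq <- vapply(len, function(l)
    paste(rep("A", l), collapse = ""), "")
  if (is.null(qual)) qual <- vapply(len, function(l)
    strrep(rawToChar(as.raw(40L + 33L)), l), "")
  if (is.null(id)) id <- sprintf("r%04d", seq_len(n))
  data.frame(read_id = id, chrom = rep_len(chrom, n), start = start,
             read_length = len, mapq = rep_len(mapq, n), sequence = seq,
             base_qualities = qual, stringsAsFactors = FALSE)
}

# reads giving prescribed two-base haplotypes at positions p1 < p2:
# haps is a named count vector, e.g. c(AC = 5, AG = 4)
reads_for_haplotypes <- function(haps, p1, p2, chrom = "chr1", len = 36L,
                                 qual_int = 40L) {
  start <- p1 - 2L
  stopifnot(p2 - start < len)
  reads <- list()
  for (h in names(haps)) for (k in seq_len(haps[[h]])) {
    s <- rep("T", len)
    s[p1 - start + 1L] <- substr(h, 1, 1)
    s[p2 - start + 1L] <- substr(h, 2, 2)
    reads[[length(reads) + 1L]] <- make_reads(
      chrom, start, len, seq = paste(s, collapse = ""),
      qual = strrep(rawToChar(as.raw(qual_int + 33L)), len),
      id = sprintf("%s_%d", h, k))
  }
  do.call(rbind, reads)
}

minimal_sam <- function(path, records,
                        sq = "@SQ\tSN:chr1\tLN:100000") {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", sq, records), path)
  path
}
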