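# From alignment records to a filtered, normalized gene x individual
# count matrix.

#' Remove positional duplicates, keeping the best-mapped read
#'
#' Emulates single-end \code{samtools rmdup -s} semantics as used on
#' low-coverage resequencing data: among all reads aligned to the same
#' (chrom, start) position, only the one with the highest mapping quality
#' survives; ties are broken by first occurrence in input order. Strand is
#' ignored (the tabular alignment format carries none). Input must be
#' sorted by (chrom, start).
#'
#' Uniquely-mapping input is an upstream contract (multi-hit reads are
#' assumed removed by the aligner); a warning is raised if the same
#' read_id occurs at several positions.
#'
#' @param aln alignment data.frame (see \code{\link{read_alignments}}).
#' @return The surviving records, one per occupied position, in
#'   positional order.
#' @export
dedup_alignments <- function(aln) {
  n <- nrow(aln)
  if (n <= 1L) return(aln)
  # sortedness check: chroms in contiguous blocks, starts non-decreasing
  same <- aln$chrom[-1] == aln$chrom[-n]
  bad <- which(same & aln$start[-1] < aln$start[-n])
  blocks <- rle(aln$chrom)$values
  if (anyDuplicated(blocks)) {
    first_bad <- which(aln$chrom == blocks[anyDuplicated(blocks)])[1]
    stopf("alignments not sorted by (chrom, start): record '%s' out of order",
          aln$read_id[first_bad])
  }
  if (length(bad))
    stopf("alignments not sorted by (chrom, start): record '%s' out of order",
          aln$read_id[bad[1] + 1L])
  if (anyDuplicated(aln$read_id))
    warnf("read_id(s) repeat across positions (multi-hit reads?); upstream filtering expects uniquely mapped reads")
  key <- paste(aln$chrom, aln$start, sep = "\r")
  o <- order(match(key, unique(key)), -aln$mapq, method = "radix")  # stable
  sel <- sort(o[!duplicated(key[o])])
  aln[sel, , drop = FALSE]
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(start = genes$start + 1,
                                          end = genes$end))
}

#' Count reads overlapping each gene
#'
#' A read increments a gene's count iff the read interval
#' \eqn{[start, start + len)} and the gene body share at least 1 bp
#' (\code{intersectBed} default semantics). A read overlapping two genes
#' increments both.
#'
#' @param aln deduplicated alignment data.frame.
#' @param genes a \code{\link{gene_intervals}} table.
#' @return Named integer vector of per-gene counts.
#' @export
count_overlaps <- function(aln, genes) {
  if (nrow(aln) == 0L)
    return(setNames(integer(nrow(genes)), genes$gene_id))
  reads <- GenomicRanges::GRanges(
    aln$chrom, IRanges::IRanges(start = aln$start + 1,
                                end = aln$start + aln$read_length))
  n <- GenomicRanges::countOverlaps(genes_to_granges(genes), reads,
                                    minoverlap = 1L)
  setNames(as.integer(n), genes$gene_id)
}

#' Construct a count matrix object
#'
#' The container for all downstream stages: per-gene, per-individual
#' mapped-read counts, per-individual genome-wide totals (the
#' normalization denominators), and the two group labels. The first group
#' label encountered is "group A" for directions.
#'
#' @param counts integer matrix, genes x samples.
#' @param genes a \code{\link{gene_intervals}} table, row-aligned with
#'   \code{counts}.
#' @param group character/factor of per-sample group labels (2 levels).
#' @param total_mapped_reads per-sample genome-wide mapped read totals
#'   (after deduplication), all > 0.
#' @param sample_id optional sample names (default: counts colnames).
#' @return An object of class \code{"count_matrix"}.
#' @export
count_matrix <- function(counts, genes, group, total_mapped_reads,
                         sample_id = colnames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) != nrow(genes))
    stopf("counts rows (%d) and genes (%d) differ", nrow(counts), nrow(genes))
  if (ncol(counts) != length(group) || ncol(counts) != length(total_mapped_reads))
    stopf("samples are inconsistent across counts/group/totals")
  if (any(counts < 0)) stopf("negative counts")
  if (any(total_mapped_reads <= 0)) stopf("total_mapped_reads must be > 0")
  if (is.null(sample_id)) sample_id <- sprintf("s%02d", seq_along(group))
  group_levels(group)
  rownames(counts) <- genes$gene_id
  colnames(counts) <- sample_id
  samples <- data.frame(sample_id = sample_id, group = as.character(group),
                        total_mapped_reads = as.numeric(total_mapped_reads),
                        stringsAsFactors = FALSE)
  structure(list(genes = genes, samples = samples, counts = counts,
                 normalized = NULL),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  lev <- group_levels(x$samples$group)
  cat(sprintf("count_matrix: %d genes x %d samples (%s: %d, %s: %d)\n",
              nrow(x$counts), ncol(x$counts),
              lev[1], sum(x$samples$group == lev[1]),
              lev[2], sum(x$samples$group == lev[2])))
  cat(sprintf("  totals: %s .. %s reads/sample; normalized: %s\n",
              format(min(x$samples$total_mapped_reads), big.mark = ","),
              format(max(x$samples$total_mapped_reads), big.mark = ","),
              if (is.null(x$normalized)) "no" else "yes"))
  invisible(x)
}

#' Count reads over genes for a set of samples
#'
#' Runs deduplication and overlap counting per sample and assembles the
#' \code{\link{count_matrix}}. The genome-wide total per sample is the
#' number of deduplicated records (the matrix being normalized is itself
#' post-deduplication).
#'
#' @param genes a \code{\link{gene_intervals}} table.
#' @param alignments named list of alignment data.frames (or file paths to
#'   tabular alignment files), one per sample.
#' @param group per-sample group labels, aligned with \code{alignments}.
#' @return A \code{\link{count_matrix}}.
#' @export
count_reads <- function(genes, alignments, group) {
  if (is.null(names(alignments)))
    names(alignments) <- sprintf("s%02d", seq_along(alignments))
  counts <- matrix(0, nrow(genes), length(alignments),
                   dimnames = list(genes$gene_id, names(alignments)))
  totals <- numeric(length(alignments))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    if (is.character(a)) a <- read_alignments(a, "tabular")
    d <- dedup_alignments(a)
    counts[, i] <- count_overlaps(d, genes)
    totals[i] <- nrow(d)
  }
  count_matrix(counts, genes, group, totals, names(alignments))
}

#' Filter weakly covered genes
#'
#' Two removal rules guard against false GCNVs from sparse coverage: a
#' gene is removed if the median over individuals of its mapped reads per
#' 100 bp of gene length is less than one, or if at least one individual
#' has zero mapped reads. The median over an even number of individuals is
#' the mean of the two central order statistics. Both rules depend only on
#' the counts, not on group labels.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @return The subset \code{count_matrix} of retained genes, with a
#'   \code{"removal_log"} attribute (data.frame: gene_id, rule).
#' @export
filter_genes <- function(cm) {
  per100 <- cm$counts * (100 / cm$genes$length)
  med <- apply(per100, 1L, median)
  low_median <- med < 1
  has_zero <- apply(cm$counts, 1L, min) < 1
  drop <- low_median | has_zero
  rule <- ifelse(low_median & has_zero, "median_per_100bp+zero_individual",
                 ifelse(low_median, "median_per_100bp", "zero_individual"))
  log <- data.frame(gene_id = cm$genes$gene_id[drop], rule = rule[drop],
                    stringsAsFactors = FALSE)
  out <- subset_genes(cm, !drop)
  attr(out, "removal_log") <- log
  out
}

subset_genes <- function(cm, idx) {
  cm$genes <- cm$genes[idx, , drop = FALSE]
  class(cm$genes) <- c("gene_intervals", "data.frame")
  cm$counts <- cm$counts[idx, , drop = FALSE]
  if (!is.null(cm$normalized))
    cm$normalized <- cm$normalized[idx, , drop = FALSE]
  cm
}

#' Normalize counts by genome-wide mapped totals
#'
#' Fills the \code{normalized} slot with
#' \code{counts[g, s] / total_mapped_reads[s]}; counts are left untouched.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @return \code{cm} with \code{normalized} filled.
#' @export
normalize_counts <- function(cm) {
  if (any(cm$samples$total_mapped_reads <= 0))
    stopf("zero total mapped reads; cannot normalize")
  cm$normalized <- sweep(cm$counts, 2L, cm$samples$total_mapped_reads, "/")
  cm
}

#' Per-gene group ratio of mean normalized counts
#'
#' The reporting statistic for gene-cluster views: for each gene, the
#' ratio of the group-A mean to the group-B mean of normalized counts. If
#' a pairing of samples (e.g. same-geography freshwater/marine pairs) is
#' supplied, the standard deviation of per-pair ratios is reported; each
#' side of a pair may be several samples, in which case their mean
#' normalized count is used.
#'
#' @param cm a \code{\link{count_matrix}} (normalized if needed).
#' @param pairing optional list of pairs; each element is
#'   \code{list(A = <sample ids/indices>, B = <sample ids/indices>)}.
#' @return data.frame: gene_id, mean_norm_A, mean_norm_B, ratio_A_over_B,
#'   undefined (TRUE where the group-B mean is zero), and sd_pairs if a
#'   pairing was given.
#' @export
group_ratio <- function(cm, pairing = NULL) {
  if (is.null(cm$normalized)) cm <- normalize_counts(cm)
  lev <- group_levels(cm$samples$group)
  A <- cm$samples$group == lev[1]
  B <- cm$samples$group == lev[2]
  if (!any(A) || !any(B)) stopf("both groups must be nonempty")
  mA <- rowMeans(cm$normalized[, A, drop = FALSE])
  mB <- rowMeans(cm$normalized[, B, drop = FALSE])
  undef <- mB == 0
  ratio <- ifelse(undef, NA_real_, mA / mB)
  out <- data.frame(gene_id = cm$genes$gene_id, mean_norm_A = mA,
                    mean_norm_B = mB, ratio_A_over_B = ratio,
                    undefined = undef, stringsAsFactors = FALSE)
  if (!is.null(pairing)) {
    pr <- vapply(pairing, function(p) {
      a <- rowMeans(cm$normalized[, p$A, drop = FALSE])
      b <- rowMeans(cm$normalized[, p$B, drop = FALSE])
      ifelse(b == 0, NA_real_, a / b)
    }, numeric(nrow(cm$counts)))
    pr <- matrix(pr, nrow = nrow(cm$counts))
    out$sd_pairs <- apply(pr, 1L, sd)
  }
  out
}
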