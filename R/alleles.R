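# Duplication/multiplication confirmation from allelic multiplicity:
# a diploid locus can carry at most two allelic sequences, so three or
# more read-supported haplotypes at an SNV position pair indicate
# collapsed duplicated copies.

# long-form pileup of base calls: one row per aligned base
pileup_long <- function(aln, q_min = 0) {
  if (nrow(aln) == 0L)
    return(data.frame(chrom = character(), pos = numeric(),
                      base = character(), qual = integer(),
                      stringsAsFactors = FALSE))
  L <- aln$read_length
  bases <- strsplit(aln$sequence, "", fixed = TRUE)
  quals <- lapply(aln$base_qualities, decode_quals)
  out <- data.frame(
    chrom = rep(aln$chrom, L),
    pos = unlist(lapply(seq_len(nrow(aln)),
                        function(i) aln$start[i] + seq_len(L[i]) - 1)),
    base = unlist(bases),
    qual = unlist(quals),
    stringsAsFactors = FALSE)
  out[out$qual >= q_min & out$base != "N", , drop = FALSE]
}

#' Minimal pileup SNV caller
#'
#' A position is called an SNV iff at least two distinct bases are each
#' supported by \code{min_allele_reads} or more reads whose base quality
#' at that position is at least \code{q_min} (high-quality bases only, the
#' \code{-Q 30} rule). \code{N} bases are ignored. This convenience caller
#' can be bypassed by supplying externally called SNVs (e.g.
#' \code{\link{read_snv_vcf}}) to \code{\link{gene_multiplicity}}.
#'
#' @param aln alignment data.frame over the region of interest.
#' @param q_min minimum base quality (Phred).
#' @param min_allele_reads minimum supporting reads per allele.
#' @return data.frame of class \code{"snv_sites"}: \code{chrom},
#'   \code{pos} (0-based), \code{alleles} (comma-separated
#'   \code{base:count}), \code{n_alleles}.
#' @export
call_snvs <- function(aln, q_min = 30, min_allele_reads = 2) {
  pl <- pileup_long(aln, q_min)
  empty <- data.frame(chrom = character(), pos = numeric(),
                      alleles = character(), n_alleles = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("snv_sites", "data.frame")
  if (nrow(pl) == 0L) return(empty)
  key <- paste(pl$chrom, pl$pos, sep = "\r")
  tab <- table(key, pl$base)
  counts <- as.matrix(tab)
  supported <- counts >= min_allele_reads
  is_snv <- rowSums(supported) >= 2L
  if (!any(is_snv)) return(empty)
  counts <- counts[is_snv, , drop = FALSE]
  supported <- supported[is_snv, , drop = FALSE]
  keys <- strsplit(rownames(counts), "\r", fixed = TRUE)
  alleles <- vapply(seq_len(nrow(counts)), function(i) {
    j <- which(supported[i, ])
    paste(sprintf("%s:%d", colnames(counts)[j], counts[i, j]), collapse = ",")
  }, "")
  out <- data.frame(chrom = vapply(keys, `[[`, "", 1L),
                    pos = as.numeric(vapply(keys, `[[`, "", 2L)),
                    alleles = alleles,
                    n_alleles = rowSums(supported),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snv_sites", "data.frame")
  out
}

#' Enumerate SNV position pairs within the read length
#'
#' All pairs (i, j), i < j, on the same reference sequence with
#' \code{pos_j - pos_i <= read_length - 1}, i.e. both positions coverable
#' (and thus phased) by one read. Set \code{inclusive = TRUE} for the
#' looser \code{<= read_length} interpretation.
#'
#' @param snvs data.frame with \code{chrom} and 0-based \code{pos}
#'   (e.g. from \code{\link{call_snvs}} or \code{\link{read_snv_vcf}}).
#' @param read_length read length L in bp.
#' @param inclusive if TRUE the maximum span is L instead of L - 1.
#' @return data.frame: \code{chrom}, \code{pos1}, \code{pos2}.
#' @export
snv_pairs <- function(snvs, read_length = 36, inclusive = FALSE) {
  max_d <- if (inclusive) read_length else read_length - 1
  out <- list()
  for (ch in unique(snvs$chrom)) {
    pos <- sort(unique(snvs$pos[snvs$chrom == ch]))
    if (length(pos) < 2L) next
    for (i in seq_len(length(pos) - 1L)) {
      j <- which(pos > pos[i] & pos - pos[i] <= max_d)
      if (length(j))
        out[[length(out) + 1L]] <- data.frame(chrom = ch, pos1 = pos[i],
                                              pos2 = pos[j],
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos1 = numeric(),
                      pos2 = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Count read-supported two-base haplotypes at an SNV position pair
#'
#' Tallies the nucleotide pairs carried by reads covering both positions,
#' requiring base quality \code{>= q_min} at both and no \code{N}; a
#' haplotype is retained iff supported by at least \code{min_support}
#' reads ("supported by multiple reads").
#'
#' @param aln alignment data.frame.
#' @param chrom reference sequence of the pair.
#' @param pos1,pos2 0-based SNV positions, \code{pos1 < pos2}.
#' @param q_min minimum base quality at each of the two positions.
#' @param min_support minimum reads per retained haplotype.
#' @return list of class \code{"haplotype_pair_table"}: \code{chrom},
#'   \code{pos1}, \code{pos2}, \code{haplotypes} (named integer vector,
#'   names are two-base strings), \code{n_haplotypes}.
#' @export
pair_haplotypes <- function(aln, chrom, pos1, pos2, q_min = 30,
                            min_support = 2) {
  stopifnot(pos1 < pos2)
  cov <- aln$chrom == chrom & aln$start <= pos1 &
    aln$start + aln$read_length > pos2
  sub <- aln[cov, , drop = FALSE]
  haps <- integer(0)
  if (nrow(sub)) {
    o1 <- pos1 - sub$start + 1
    o2 <- pos2 - sub$start + 1
    b1 <- substr(sub$sequence, o1, o1)
    b2 <- substr(sub$sequence, o2, o2)
    q1 <- as.integer(charToRaw(paste(substr(sub$base_qualities, o1, o1),
                                     collapse = ""))) - 33L
    q2 <- as.integer(charToRaw(paste(substr(sub$base_qualities, o2, o2),
                                     collapse = ""))) - 33L
    ok <- q1 >= q_min & q2 >= q_min & b1 != "N" & b2 != "N"
    if (any(ok)) {
      tal <- table(paste0(b1[ok], b2[ok]))
      tal <- tal[tal >= min_support]
      haps <- setNames(as.integer(tal), names(tal))
    }
  }
  structure(list(chrom = chrom, pos1 = pos1, pos2 = pos2,
                 haplotypes = haps, n_haplotypes = length(haps)),
            class = "haplotype_pair_table")
}

#' @export
print.haplotype_pair_table <- function(x, ...) {
  cat(sprintf("SNV pair %s:%d/%d - %d supported haplotype(s)%s\n",
              x$chrom, x$pos1, x$pos2, x$n_haplotypes,
              if (x$n_haplotypes)
                paste0(": ", paste(sprintf("%s x%d", names(x$haplotypes),
                                           x$haplotypes), collapse = ", "))
              else ""))
  invisible(x)
}

# per-individual summary over all pairs of a gene region
individual_multiplicity <- function(aln, snvs = NULL, read_length = 36,
                                    q_min = 30, min_allele_reads = 2,
                                    min_support = 2, inclusive = FALSE) {
  if (is.null(snvs)) snvs <- call_snvs(aln, q_min, min_allele_reads)
  pairs <- snv_pairs(snvs, read_length, inclusive)
  if (!nrow(pairs))
    return(list(max_haplotypes = 0L, n_pairs = 0L, n_pairs_ge3 = 0L,
                pairs = pairs))
  nh <- vapply(seq_len(nrow(pairs)), function(i)
    pair_haplotypes(aln, pairs$chrom[i], pairs$pos1[i], pairs$pos2[i],
                    q_min, min_support)$n_haplotypes, 0L)
  pairs$n_haplotypes <- nh
  list(max_haplotypes = max(nh), n_pairs = nrow(pairs),
       n_pairs_ge3 = sum(nh >= 3L), pairs = pairs)
}

#' Classify a gene as duplicated/multiplied from per-individual
#' multiplicity
#'
#' A group is called duplicated iff at least \code{min_individuals} of its
#' individuals each show at least one SNV position pair with three or more
#' read-supported haplotypes (impossible from a single diploid locus). A
#' stronger flag additionally requires \code{min_pairs_strong} such pairs
#' per qualifying individual.
#'
#' @param n_pairs_ge3 named integer vector: per individual, the number of
#'   pairs with >= 3 retained haplotypes.
#' @param group per-individual group labels, aligned with
#'   \code{n_pairs_ge3}.
#' @param min_individuals individuals required per group.
#' @param min_pairs_strong qualifying pairs per individual for the strong
#'   flag.
#' @return list of class \code{"multiplicity_call"}: \code{group_call} and
#'   \code{strong} (named logicals per group), \code{per_individual}.
#' @export
classify_multiplicity <- function(n_pairs_ge3, group, min_individuals = 3,
                                  min_pairs_strong = 2) {
  lev <- group_levels(group)
  per <- data.frame(individual = names(n_pairs_ge3) %||%
                      sprintf("i%02d", seq_along(n_pairs_ge3)),
                    group = as.character(group),
                    n_pairs_ge3 = as.integer(n_pairs_ge3),
                    stringsAsFactors = FALSE)
  call1 <- function(min_pairs) vapply(lev, function(l)
    sum(per$group == l & per$n_pairs_ge3 >= min_pairs) >= min_individuals,
    TRUE)
  structure(list(group_call = call1(1L), strong = call1(min_pairs_strong),
                 per_individual = per, min_individuals = min_individuals,
                 min_pairs_strong = min_pairs_strong),
            class = "multiplicity_call")
}

#' @export
print.multiplicity_call <- function(x, ...) {
  for (l in names(x$group_call))
    cat(sprintf("group %s: duplicated = %s (strong = %s); qualifying individuals: %d\n",
                l, x$group_call[[l]], x$strong[[l]],
                sum(x$per_individual$group == l &
                      x$per_individual$n_pairs_ge3 >= 1L)))
  invisible(x)
}

#' Allelic-multiplicity test for one gene across individuals
#'
#' Full per-gene pipeline: per individual, call SNVs from the reads (or
#' use supplied sites), enumerate within-read-length SNV position pairs,
#' count read-supported two-base haplotypes per pair, then classify the
#' gene per group.
#'
#' @param alignments named list of per-individual alignment data.frames
#'   over the gene region.
#' @param group per-individual group labels.
#' @param snvs optional externally called SNV sites (data.frame with
#'   \code{chrom}, \code{pos}); if supplied, the internal caller is
#'   skipped and the same sites are used for every individual.
#' @param read_length read length L (bp).
#' @param q_min minimum base quality.
#' @param min_allele_reads SNV-calling support threshold per allele.
#' @param min_support reads required per retained haplotype.
#' @param min_individuals individuals per group required for a call.
#' @param min_pairs_strong qualifying pairs per individual for the strong
#'   flag.
#' @param inclusive pair-span interpretation, see \code{\link{snv_pairs}}.
#' @return A \code{\link{classify_multiplicity}} call object with a
#'   \code{details} element (per-individual pair tables).
#' @export
gene_multiplicity <- function(alignments, group, snvs = NULL,
                              read_length = 36, q_min = 30,
                              min_allele_reads = 2, min_support = 2,
                              min_individuals = 3, min_pairs_strong = 2,
                              inclusive = FALSE) {
  res <- lapply(alignments, individual_multiplicity, snvs = snvs,
                read_length = read_length, q_min = q_min,
                min_allele_reads = min_allele_reads,
                min_support = min_support, inclusive = inclusive)
  n_ge3 <- setNames(vapply(res, `[[`, 0L, "n_pairs_ge3"),
                    names(alignments) %||% sprintf("i%02d", seq_along(res)))
  out <- classify_multiplicity(n_ge3, group, min_individuals,
                               min_pairs_strong)
  out$details <- res
  out
}
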