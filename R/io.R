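# Reading and writing the formats the pipeline touches. Internal
# coordinate convention everywhere: 0-based, half-open [start, end).

#' Construct a validated gene interval table
#'
#' Gene spans are gene bodies (most 5' to most 3' position: exons plus
#' introns), held 0-based half-open. Strand is ignored throughout the
#' package; scaffolds are treated like any other reference sequence.
#'
#' @param gene_id character vector, unique within the set.
#' @param chrom reference sequence names.
#' @param start,end 0-based half-open span; \code{0 <= start < end}.
#' @return A \code{data.frame} of class \code{"gene_intervals"} with
#'   columns \code{gene_id}, \code{chrom}, \code{start}, \code{end},
#'   \code{length} (bp).
#' @export
gene_intervals <- function(gene_id, chrom, start, end) {
  gene_id <- as.character(gene_id)
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (anyNA(gene_id) || anyNA(chrom) || anyNA(start) || anyNA(end))
    stopf("gene intervals contain missing values")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stopf("invalid interval for gene '%s': start=%s end=%s (need 0 <= start < end)",
          gene_id[bad[1]], format(start[bad[1]]), format(end[bad[1]]))
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup))
    stopf("duplicate gene_id: %s", paste(unique(dup), collapse = ", "))
  out <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                    end = end, length = end - start,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_intervals", "data.frame")
  out
}

split_fields <- function(lines, what) {
  strsplit(lines, "\t", fixed = TRUE)
}

# numbers possibly printed with thousands separators ("21,543,442")
parse_num <- function(x) suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))

#' Read gene models from BED, GFF, or a 1-based Ensembl-style TSV
#'
#' All dialects are converted to the internal 0-based half-open
#' convention at the boundary: BED4 is taken as-is; GFF and the
#' Ensembl-style TSV (columns gene_id, chrom, start, end, 1-based
#' inclusive, thousands separators tolerated) have 1 subtracted from the
#' start. Duplicate gene identifiers are rejected.
#'
#' @param path file path.
#' @param dialect one of \code{"bed"}, \code{"gff"}, \code{"ensembl_tsv"}.
#' @return A \code{\link{gene_intervals}} table.
#' @export
read_gene_models <- function(path, dialect = c("bed", "gff", "ensembl_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(gene_intervals(character(), character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)

  parse_fail <- function(i, why) {
    stopf("%s: parse error at line %d: %s", path, lineno[i], why)
  }

  if (dialect == "bed") {
    for (i in seq_along(fields)) {
      if (length(fields[[i]]) < 4L) {
        # BED also allows whitespace-delimited
        fields[[i]] <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
        if (length(fields[[i]]) < 4L) parse_fail(i, "expected >= 4 BED columns")
      }
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- parse_num(vapply(fields, `[[`, "", 2L))
    end <- parse_num(vapply(fields, `[[`, "", 3L))
    id <- vapply(fields, `[[`, "", 4L)
    bad <- which(is.na(start) | is.na(end))
    if (length(bad)) parse_fail(bad[1], "non-numeric coordinate")
  } else if (dialect == "ensembl_tsv") {
    # header row (non-numeric coordinate columns) skipped if present
    if (length(fields[[1]]) < 4L) parse_fail(1L, "expected 4 columns")
    if (is.na(parse_num(fields[[1]][3]))) {
      fields <- fields[-1]; lineno <- lineno[-1]
    }
    for (i in seq_along(fields))
      if (length(fields[[i]]) < 4L) parse_fail(i, "expected 4 columns")
    id <- vapply(fields, `[[`, "", 1L)
    chrom <- vapply(fields, `[[`, "", 2L)
    s1 <- parse_num(vapply(fields, `[[`, "", 3L))
    e1 <- parse_num(vapply(fields, `[[`, "", 4L))
    bad <- which(is.na(s1) | is.na(e1))
    if (length(bad)) parse_fail(bad[1], "non-numeric coordinate")
    start <- s1 - 1  # 1-based inclusive -> 0-based half-open
    end <- e1
  } else {  # gff
    for (i in seq_along(fields))
      if (length(fields[[i]]) < 9L) parse_fail(i, "expected 9 GFF columns")
    type <- vapply(fields, `[[`, "", 3L)
    sel <- if (any(type == "gene")) type == "gene" else rep(TRUE, length(fields))
    fields <- fields[sel]; lineno <- lineno[sel]
    chrom <- vapply(fields, `[[`, "", 1L)
    s1 <- parse_num(vapply(fields, `[[`, "", 4L))
    e1 <- parse_num(vapply(fields, `[[`, "", 5L))
    bad <- which(is.na(s1) | is.na(e1))
    if (length(bad)) parse_fail(bad[1], "non-numeric coordinate")
    attrs <- vapply(fields, `[[`, "", 9L)
    id <- sub('^.*(?:^|;)\\s*(?:ID|gene_id)[=\\s]+"?([^";]+)"?.*$', "\\1",
              attrs, perl = TRUE)
    noid <- which(id == attrs)
    if (length(noid)) parse_fail(noid[1], "no ID= or gene_id attribute")
    start <- s1 - 1
    end <- e1
  }

  tryCatch(gene_intervals(id, chrom, start, end),
           error = function(e) stopf("%s: %s", path, conditionMessage(e)))
}

#' Write gene models in a named dialect
#'
#' Inverse of \code{\link{read_gene_models}}: the internal 0-based
#' half-open spans round-trip exactly through any dialect.
#'
#' @param genes a \code{\link{gene_intervals}} table.
#' @param path output path.
#' @param dialect one of \code{"bed"}, \code{"gff"}, \code{"ensembl_tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_gene_models <- function(genes, path,
                              dialect = c("bed", "gff", "ensembl_tsv")) {
  dialect <- match.arg(dialect)
  lines <- switch(dialect,
    bed = sprintf("%s\t%.0f\t%.0f\t%s", genes$chrom, genes$start, genes$end,
                  genes$gene_id),
    ensembl_tsv = sprintf("%s\t%s\t%.0f\t%.0f", genes$gene_id, genes$chrom,
                          genes$start + 1, genes$end),
    gff = sprintf("%s\tparacnv\tgene\t%.0f\t%.0f\t.\t.\t.\tID=%s",
                  genes$chrom, genes$start + 1, genes$end, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

validate_alignments <- function(aln, path = "<alignments>") {
  qlen <- nchar(aln$base_qualities)
  slen <- nchar(aln$sequence)
  bad <- which(slen != aln$read_length | qlen != aln$read_length)
  if (length(bad))
    stopf("%s: read '%s': sequence/quality length (%d/%d) does not match read_length %d",
          path, aln$read_id[bad[1]], slen[bad[1]], qlen[bad[1]],
          aln$read_length[bad[1]])
  if (any(aln$mapq < 0)) stopf("%s: negative mapping quality", path)
  aln
}

new_alignments <- function(read_id, chrom, start, read_length, mapq,
                           sequence, base_qualities) {
  data.frame(read_id = as.character(read_id), chrom = as.character(chrom),
             start = as.numeric(start), read_length = as.integer(read_length),
             mapq = as.integer(mapq), sequence = as.character(sequence),
             base_qualities = as.character(base_qualities),
             stringsAsFactors = FALSE)
}

#' Read single-end alignment records
#'
#' Accepts SAM, BAM, or the package's minimal tabular alignment format
#' (tab-separated: read_id, chrom, 0-based start, read length, mapq,
#' sequence, Phred+33 quality string; lines starting with \code{#}
#' ignored). Unmapped records are skipped; records are returned sorted by
#' (chrom, start). SAM/BAM positions (1-based) are converted to the
#' internal 0-based convention.
#'
#' @param path file path.
#' @param format \code{"tabular"}, \code{"sam"}, or \code{"bam"}.
#' @return A data.frame with columns \code{read_id}, \code{chrom},
#'   \code{start}, \code{read_length}, \code{mapq}, \code{sequence},
#'   \code{base_qualities}.
#' @export
read_alignments <- function(path, format = c("tabular", "sam", "bam")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam))
    return(read_alignments(bam, "bam"))
  }
  if (format == "bam") {
    param <- Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "mapq", "seq", "qual"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    rec <- Rsamtools::scanBam(path, param = param)[[1]]
    seqs <- as.character(rec$seq)
    quals <- as.character(rec$qual)
    aln <- new_alignments(rec$qname, as.character(rec$rname), rec$pos - 1,
                          nchar(seqs), ifelse(is.na(rec$mapq), 0L, rec$mapq),
                          seqs, quals)
  } else {
    tab <- read.table(path, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE,
                      col.names = c("read_id", "chrom", "start",
                                    "read_length", "mapq", "sequence",
                                    "base_qualities"),
                      colClasses = c("character", "character", "numeric",
                                     "integer", "integer", "character",
                                     "character"))
    aln <- new_alignments(tab$read_id, tab$chrom, tab$start, tab$read_length,
                          tab$mapq, tab$sequence, tab$base_qualities)
  }
  aln <- validate_alignments(aln, path)
  aln[order(aln$chrom, aln$start, method = "radix"), , drop = FALSE]
}

#' Write alignments in the minimal tabular format
#'
#' @param aln alignment data.frame (see \code{\link{read_alignments}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_alignments <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#read_id\tchrom\tstart\tread_length\tmapq\tsequence\tbase_qualities",
             con)
  if (nrow(aln))
    writeLines(sprintf("%s\t%s\t%.0f\t%d\t%d\t%s\t%s", aln$read_id, aln$chrom,
                       aln$start, aln$read_length, aln$mapq, aln$sequence,
                       aln$base_qualities), con)
  invisible(path)
}

#' Read SNV sites from a VCF
#'
#' Only CHROM/POS/REF/ALT are used; positions are converted to 0-based.
#' Supplying caller output here replaces the package's minimal pileup
#' caller (\code{\link{call_snvs}}) in the allelic-multiplicity stage.
#'
#' @param path VCF (v4.x) file path.
#' @return A data.frame with columns \code{chrom}, \code{pos} (0-based),
#'   \code{ref}, \code{alt}.
#' @export
read_snv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  data.frame(chrom = as.character(fix[, "CHROM"]),
             pos = as.numeric(fix[, "POS"]) - 1,
             ref = as.character(fix[, "REF"]),
             alt = as.character(fix[, "ALT"]),
             stringsAsFactors = FALSE)
}

#' Write a detection results table to TSV
#'
#' One row per gene: identifier, per-group mean normalized counts,
#' direction (\code{increased_in_A} / \code{increased_in_B}), then p-value,
#' FDR and significance per mapping stringency, and the consensus GCNV
#' flag. Numeric columns are written with 17 significant digits so the
#' table re-reads to the exact values.
#'
#' @param results the \code{table} of a \code{\link{gcnv_detect}} fit (or
#'   any data.frame with those columns).
#' @param path output path.
#' @param header_lines optional character vector of \code{#}-prefixed
#'   lines written before the header (provenance, config echo).
#' @return \code{path}, invisibly.
#' @export
write_results_table <- function(results, path, header_lines = character()) {
  df <- as.data.frame(results)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    if (is.logical(df[[j]])) df[[j]] <- ifelse(df[[j]], "TRUE", "FALSE")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  invisible(path)
}

#' Read back a detection results table written by
#' \code{\link{write_results_table}}
#'
#' @param path TSV path.
#' @return A data.frame; numeric/logical column types restored.
#' @export
read_results_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (nrow(df) && is.character(df[[j]]) &&
        all(df[[j]] %in% c("TRUE", "FALSE")))
      df[[j]] <- as.logical(df[[j]])
  }
  df
}
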