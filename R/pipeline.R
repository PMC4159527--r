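# End-to-end orchestration over a fixture/input directory: count-matrix
# input -> detection -> permutation -> allelic multiplicity -> TSV
# reports plus a JSON-lines run log.

#' Run configuration
#'
#' Collects the fixed analysis thresholds: FDR threshold (0.05), number
#' of permutations (10000), read length (36 bp), base-quality floor
#' (Q30), haplotype support (multiple reads = 2), individuals per group
#' for a multiplicity call (3), and the root seed from which every
#' stochastic stage derives its own seed by a fixed offset.
#'
#' @param alpha FDR threshold in (0, 1] (1 disables thresholding).
#' @param n_perm permutations for the null of the GCNV count.
#' @param read_length read length L (bp).
#' @param q_min minimum base quality (Phred).
#' @param min_support reads per retained haplotype.
#' @param min_individuals individuals per group for a multiplicity call.
#' @param min_pairs_strong qualifying pairs for the strong flag.
#' @param seed root seed.
#' @param perm_mode permutation mode, see \code{\link{gcnv_permute}}.
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(alpha = 0.05, n_perm = 10000, read_length = 36,
                       q_min = 30, min_support = 2, min_individuals = 3,
                       min_pairs_strong = 2, seed = 1,
                       perm_mode = "per_stringency") {
  if (!(alpha > 0 && alpha <= 1)) stopf("alpha must lie in (0, 1]")
  if (!is_count(n_perm) || n_perm < 1) stopf("n_perm must be >= 1")
  structure(list(alpha = alpha, n_perm = n_perm, read_length = read_length,
                 q_min = q_min, min_support = min_support,
                 min_individuals = min_individuals,
                 min_pairs_strong = min_pairs_strong, seed = seed,
                 perm_mode = perm_mode),
            class = "run_config")
}

config_lines <- function(config) {
  sprintf("%s=%s", names(config),
          vapply(config, function(v) paste(format(v), collapse = ","), ""))
}

config_md5 <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(config_lines(config), tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline on an input directory
#'
#' Expects the layout written by \code{\link{make_fixture_bundle}}:
#' \code{counts_<label>.tsv} per mapping stringency, \code{groups.tsv},
#' optionally \code{genes.bed} and per-gene read directories under
#' \code{reads/}. Runs detection, the permutation null, and (if reads are
#' present) the allelic-multiplicity test, writing \code{detection.tsv},
#' \code{permutation.tsv}, \code{multiplicity.tsv}, \code{run_log.jsonl}
#' and \code{config.txt} to \code{outdir}. Every output carries the
#' config hash and seed in its header; a rerun with identical inputs and
#' config is byte-identical (no timestamps are written).
#'
#' @param input_dir directory with the inputs.
#' @param outdir output directory (created if needed).
#' @param config a \code{\link{run_config}}.
#' @return list with the \code{\link{gcnv_detect}} fit, the
#'   \code{\link{gcnv_permute}} null, and multiplicity calls (or NULL).
#' @export
run_pipeline <- function(input_dir, outdir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  md5 <- config_md5(config)
  hdr <- c(sprintf("# config_md5=%s", md5), sprintf("# seed=%d", config$seed))
  log_con <- file(file.path(outdir, "run_log.jsonl"), "w")
  on.exit(close(log_con))
  log_seq <- 0L
  log_event <- function(stage, ...) {
    log_seq <<- log_seq + 1L
    rec <- c(list(seq = log_seq, stage = stage), list(...))
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE)), log_con)
  }
  log_event("start", config_md5 = md5, seed = config$seed)

  count_files <- sort(list.files(input_dir, pattern = "^counts_.*\\.tsv$",
                                 full.names = TRUE))
  if (!length(count_files))
    stopf("stage 'detect': no counts_<label>.tsv found in %s", input_dir)
  groups_path <- file.path(input_dir, "groups.tsv")
  if (!file.exists(groups_path))
    stopf("stage 'detect': missing groups.tsv in %s", input_dir)
  groups <- read.table(groups_path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  genes <- NULL
  if (file.exists(file.path(input_dir, "genes.bed")))
    genes <- read_gene_models(file.path(input_dir, "genes.bed"), "bed")
  labels <- sub("^counts_(.*)\\.tsv$", "\\1", basename(count_files))
  matrices <- setNames(lapply(count_files, read_count_matrix, group = groups,
                              genes = genes), labels)
  log_event("load", stringencies = labels,
            n_genes = nrow(matrices[[1]]$counts),
            n_samples = ncol(matrices[[1]]$counts))

  fit <- gcnv_detect(matrices, alpha = config$alpha)
  for (lab in names(fit$removal_log)) {
    rl <- fit$removal_log[[lab]]
    log_event("filter", stringency = lab,
              genes_in = unname(fit$n_genes_in[lab]) + nrow(rl),
              removed_median_rule = sum(grepl("median", rl$rule)),
              removed_zero_rule = sum(grepl("zero", rl$rule)),
              genes_kept = unname(fit$n_genes_in[lab]))
  }
  log_event("detect", genes_tested = fit$n_genes_tested,
            dispersion = as.list(fit$dispersion),
            significant = as.list(vapply(fit$labels, function(l)
              sum(fit$table[[paste0("sig_", l)]]), 0L)),
            consensus_gcnvs = sum(fit$table$consensus_gcnv))
  write_results_table(fit$table, file.path(outdir, "detection.tsv"), hdr)

  perm <- gcnv_permute(matrices, n_perm = config$n_perm,
                       seed = stage_seed(config$seed, 1L),
                       mode = config$perm_mode, alpha = config$alpha)
  ptab <- if (perm$mode == "per_stringency") {
    data.frame(stringency = perm$labels, observed = as.integer(perm$observed),
               null_mean = colMeans(perm$null_counts),
               empirical_p = perm$empirical_p, stringsAsFactors = FALSE)
  } else {
    data.frame(stringency = "consensus", observed = perm$observed,
               null_mean = mean(perm$null_counts),
               empirical_p = perm$empirical_p, stringsAsFactors = FALSE)
  }
  log_event("permute", n_perm = perm$n_perm, mode = perm$mode,
            empirical_p = as.list(setNames(as.numeric(perm$empirical_p),
                                           ptab$stringency)))
  write_results_table(ptab, file.path(outdir, "permutation.tsv"), hdr)

  mult <- NULL
  reads_dir <- file.path(input_dir, "reads")
  if (dir.exists(reads_dir)) {
    gene_dirs <- list.dirs(reads_dir, recursive = FALSE)
    rows <- list()
    mult <- list()
    for (gd in gene_dirs) {
      gid <- basename(gd)
      files <- sort(list.files(gd, pattern = "\\.tsv$", full.names = TRUE))
      ids <- sub("\\.tsv$", "", basename(files))
      aln <- setNames(lapply(files, read_alignments, format = "tabular"), ids)
      grp <- groups$group[match(ids, groups$sample_id)]
      call <- gene_multiplicity(aln, grp, read_length = config$read_length,
                                q_min = config$q_min,
                                min_support = config$min_support,
                                min_individuals = config$min_individuals,
                                min_pairs_strong = config$min_pairs_strong)
      mult[[gid]] <- call
      for (l in names(call$group_call))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, group = l,
          n_individuals_ge3 = sum(call$per_individual$group == l &
                                    call$per_individual$n_pairs_ge3 >= 1L),
          group_call = call$group_call[[l]], strong = call$strong[[l]],
          stringsAsFactors = FALSE)
    }
    mtab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene_id = character(), group = character(),
                 n_individuals_ge3 = integer(), group_call = logical(),
                 strong = logical())
    log_event("alleles", genes = length(gene_dirs),
              duplicated_calls = sum(mtab$group_call))
    write_results_table(mtab, file.path(outdir, "multiplicity.tsv"), hdr)
  }

  writeLines(c(hdr, config_lines(config)), file.path(outdir, "config.txt"))
  log_event("done")
  invisible(list(fit = fit, permutation = perm, multiplicity = mult))
}
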