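# Synthetic inputs with the statistical structure the analysis assumes,
# plus ground truth for every downstream stage.

#' Scenario configuration for the count simulator
#'
#' Defaults emulate the study regime: 10 + 10 individuals sequenced to
#' about 2.3x with 36-bp single-end reads, gene lengths log-normal
#' (median 3 kb, sd(log) 0.9, spanning roughly 0.2-70 kb), a common NB
#' overdispersion across individuals, and three mapping-stringency
#' replicates derived from one latent count by binomial thinning (the
#' three real mappings share reads, so their counts are correlated —
#' which is what the consensus rule exploits). Retention fractions must be
#' non-increasing from the most permissive to the strictest option.
#'
#' @param n_genes number of genes.
#' @param n_per_group individuals per group (balanced).
#' @param mean_depth mean genome coverage per individual.
#' @param read_length read length L (bp).
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene-length
#'   parameters (bp).
#' @param gcnv_spec optional data.frame with columns \code{gene} (index,
#'   or NA to be placed at simulation time among genes with expected
#'   baseline count >= \code{min_mean_count}), \code{group} ("A"/"B") and
#'   \code{copy_number} (integer, baseline is 2); see
#'   \code{\link{gcnv_events}}.
#' @param min_mean_count eligibility threshold for automatic GCNV
#'   placement.
#' @param cluster_sizes_A,cluster_sizes_B sizes of runs of consecutive
#'   genes among the group-A / group-B events (segmental duplications hit
#'   gene clusters); remaining events are isolated genes.
#' @param phi NB dispersion (variance \eqn{\mu + \phi\mu^2}); 0 gives
#'   Poisson counts.
#' @param lib_size_cv coefficient of variation of per-individual library
#'   sizes.
#' @param intergenic_factor genome size as a multiple of the summed gene
#'   lengths (sets the genome-wide totals that normalization divides by).
#' @param n_stringencies number of mapping-stringency replicates.
#' @param stringency_retention per-option read retention fractions in
#'   (0, 1], non-increasing.
#' @param stringency_labels option labels.
#' @param seed RNG seed; a fixed seed makes the scenario bit-reproducible.
#' @return list of class \code{"scenario_config"}.
#' @export
scenario_config <- function(n_genes = 2000, n_per_group = 10,
                            mean_depth = 2.3, read_length = 36,
                            gene_length_meanlog = log(3000),
                            gene_length_sdlog = 0.9,
                            gcnv_spec = NULL, min_mean_count = 20,
                            cluster_sizes_A = integer(),
                            cluster_sizes_B = integer(),
                            phi = 0.1, lib_size_cv = 0.2,
                            intergenic_factor = 2,
                            n_stringencies = 3,
                            stringency_retention = c(1, 0.9, 0.8),
                            stringency_labels = c("e130", "e100", "e70"),
                            seed = 1) {
  stopifnot(is_count(n_genes), is_count(n_per_group), mean_depth > 0,
            is_count(read_length), phi >= 0, lib_size_cv >= 0,
            is_count(n_stringencies))
  stringency_retention <- stringency_retention[seq_len(n_stringencies)]
  stringency_labels <- stringency_labels[seq_len(n_stringencies)]
  if (any(is.na(stringency_retention)) ||
      any(stringency_retention <= 0 | stringency_retention > 1))
    stopf("stringency_retention must lie in (0, 1]")
  if (any(diff(stringency_retention) > 0))
    stopf("stringency_retention must be non-increasing (stricter mapping keeps fewer reads)")
  if (!is.null(gcnv_spec)) {
    stopifnot(all(c("gene", "group", "copy_number") %in% names(gcnv_spec)))
    if (any(gcnv_spec$copy_number < 0) ||
        any(gcnv_spec$copy_number != floor(gcnv_spec$copy_number)))
      stopf("copy_number must be a non-negative integer")
    if (!all(gcnv_spec$group %in% c("A", "B")))
      stopf("gcnv_spec$group must be 'A' or 'B'")
  }
  structure(list(n_genes = n_genes, n_per_group = n_per_group,
                 mean_depth = mean_depth, read_length = read_length,
                 gene_length_meanlog = gene_length_meanlog,
                 gene_length_sdlog = gene_length_sdlog,
                 gcnv_spec = gcnv_spec, min_mean_count = min_mean_count,
                 cluster_sizes_A = cluster_sizes_A,
                 cluster_sizes_B = cluster_sizes_B,
                 phi = phi, lib_size_cv = lib_size_cv,
                 intergenic_factor = intergenic_factor,
                 n_stringencies = n_stringencies,
                 stringency_retention = stringency_retention,
                 stringency_labels = stringency_labels, seed = seed),
            class = "scenario_config")
}

#' Describe a set of copy-number events
#'
#' @param gene gene indices (NA = place at simulation time).
#' @param group affected group, "A" or "B" (recycled).
#' @param copy_number copy number in the affected group (baseline 2;
#'   recycled).
#' @return data.frame suitable for \code{scenario_config(gcnv_spec = )}.
#' @export
gcnv_events <- function(gene, group, copy_number = 4) {
  data.frame(gene = gene, group = group, copy_number = copy_number,
             stringsAsFactors = FALSE)
}

#' Study-shaped scenario: 24 GCNVs, 19 increased in group A
#'
#' Convenience wrapper reproducing the shape of the motivating analysis:
#' among \code{n_genes} genes, 24 true GCNVs at copy-number ratio 2
#' (copy number 4 vs the diploid 2), 19 with more copies in group A (the
#' freshwater-like group, including one 7-gene cluster) and 5 with more
#' copies in group B (including one 2-gene cluster), all placed on genes
#' whose expected baseline count is at least \code{min_mean_count}.
#'
#' @param n_genes,seed,... passed to \code{\link{scenario_config}}.
#' @return A \code{"scenario_config"}.
#' @export
parallel_scenario <- function(n_genes = 2000, seed = 1, ...) {
  spec <- rbind(gcnv_events(rep(NA_integer_, 19), "A", 4),
                gcnv_events(rep(NA_integer_, 5), "B", 4))
  scenario_config(n_genes = n_genes, gcnv_spec = spec,
                  cluster_sizes_A = 7, cluster_sizes_B = 2,
                  seed = seed, ...)
}

# place GCNV events on eligible genes: clusters on runs of consecutive
# eligible genes, the rest on isolated eligible genes
place_events <- function(spec, eligible, cluster_A, cluster_B, n_genes) {
  need <- is.na(spec$gene)
  if (!any(need)) return(spec)
  taken <- spec$gene[!need]
  pick_run <- function(size, pool) {
    runs <- which(vapply(pool, function(s)
      all((s:(s + size - 1)) %in% pool), TRUE))
    if (!length(runs)) stopf("no eligible run of %d consecutive genes", size)
    s <- pool[runs[sample.int(length(runs), 1)]]
    s:(s + size - 1)
  }
  for (g in c("A", "B")) {
    idx <- which(need & spec$group == g)
    if (!length(idx)) next
    clusters <- if (g == "A") cluster_A else cluster_B
    chosen <- integer(0)
    for (sz in clusters) {
      pool <- setdiff(eligible, c(taken, chosen))
      run <- pick_run(sz, pool)
      chosen <- c(chosen, run)
    }
    n_single <- length(idx) - length(chosen)
    if (n_single < 0) stopf("cluster sizes exceed the number of events")
    pool <- setdiff(eligible, c(taken, chosen))
    if (length(pool) < n_single) stopf("not enough eligible genes for GCNV placement")
    chosen <- c(chosen, sample(pool, n_single))
    spec$gene[idx] <- chosen
    taken <- c(taken, chosen)
  }
  spec
}

#' Simulate correlated count matrices with ground truth
#'
#' Per gene g and individual s the latent expected count is
#' \deqn{\mu = lib_s \cdot \frac{depth}{L}(len_g + L - 1) \cdot CN_{g,
#' group(s)}/2,} i.e. counts scale with library size, with gene length
#' (every start position putting >= 1 bp inside the gene), and linearly
#' with copy number. Latent counts are NB(\eqn{\mu}, \eqn{\phi}); each
#' mapping-stringency replicate is an independent binomial thinning of the
#' same latent count (thinning preserves the NB dispersion and induces the
#' cross-option correlation of the real mappings). Genome-wide totals are
#' thinned the same way. A fixed seed makes everything bit-reproducible.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return list: \code{matrices} (named list of
#'   \code{\link{count_matrix}}, one per stringency), \code{truth}
#'   (data.frame: gene_id, cn_A, cn_B, is_true_gcnv, direction),
#'   \code{config}.
#' @export
simulate_count_matrices <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n_genes
  L <- config$read_length
  npg <- config$n_per_group
  ns <- 2L * npg

  len <- pmax(round(rlnorm(n, config$gene_length_meanlog,
                           config$gene_length_sdlog)), 200)
  gap <- 500
  start <- cumsum(c(0, len[-n] + gap))
  genes <- gene_intervals(sprintf("g%04d", seq_len(n)), "chr1", start,
                          start + len)

  # per-read chance of overlapping the gene body
  mu0 <- config$mean_depth / L * (len + L - 1)

  cn <- matrix(2, n, 2, dimnames = list(genes$gene_id, c("A", "B")))
  spec <- config$gcnv_spec
  if (!is.null(spec) && nrow(spec)) {
    eligible <- which(mu0 >= config$min_mean_count)
    spec <- place_events(spec, eligible, config$cluster_sizes_A,
                         config$cluster_sizes_B, n)
    for (i in seq_len(nrow(spec)))
      cn[spec$gene[i], spec$group[i]] <- spec$copy_number[i]
  }
  truth <- data.frame(gene_id = genes$gene_id, cn_A = cn[, "A"],
                      cn_B = cn[, "B"],
                      is_true_gcnv = cn[, "A"] != cn[, "B"],
                      direction = ifelse(cn[, "A"] >= cn[, "B"],
                                         "increased_in_A", "increased_in_B"),
                      stringsAsFactors = FALSE)
  truth$direction[!truth$is_true_gcnv] <- NA_character_
  rownames(truth) <- NULL

  group <- rep(c("A", "B"), each = npg)
  sample_id <- sprintf("%s%02d", group, c(seq_len(npg), seq_len(npg)))
  sdlog <- sqrt(log(1 + config$lib_size_cv^2))
  lib_rel <- exp(rnorm(ns, -sdlog^2 / 2, sdlog))
  genome_bp <- sum(len) * config$intergenic_factor
  totals_latent <- pmax(round(config$mean_depth / L * genome_bp * lib_rel), 1)

  mu <- outer(mu0, lib_rel) * (cn[, match(group, colnames(cn))] / 2)
  latent <- if (config$phi > 0) {
    matrix(rnbinom(n * ns, mu = mu, size = 1 / config$phi), n, ns)
  } else {
    matrix(rpois(n * ns, mu), n, ns)
  }

  matrices <- vector("list", config$n_stringencies)
  names(matrices) <- config$stringency_labels
  for (i in seq_len(config$n_stringencies)) {
    ret <- config$stringency_retention[i]
    counts <- matrix(rbinom(n * ns, size = latent, prob = ret), n, ns)
    totals <- rbinom(ns, size = totals_latent, prob = ret)
    matrices[[i]] <- count_matrix(counts, genes, group, pmax(totals, 1),
                                  sample_id)
  }
  list(matrices = matrices, truth = truth, config = config)
}

#' Simulate short reads from collapsed paralogous haplotypes
#'
#' Emulates the duplication signature the allelic-multiplicity test looks
#' for: reads are drawn uniformly along one reference template from
#' \code{n_haplotypes} divergent paralog copies that all map to the same
#' locus. Divergence sites give every haplotype a distinct base pair at
#' two positions within \code{read_length - 1} bp of each other (so the
#' pair is phaseable by one read); further sites may be supplied.
#'
#' @param n_haplotypes number of distinct haplotypes (2 = ordinary
#'   diploid).
#' @param template_length template (gene region) length, bp.
#' @param divergence_sites optional list(pos = 0-based positions, bases =
#'   site x haplotype character matrix); if NULL, two sites 20 bp apart in
#'   the middle of the template with automatically distinct base pairs.
#' @param depth_per_haplotype mean coverage contributed by each haplotype.
#' @param read_length read length L (bp).
#' @param error_rate per-base substitution error probability.
#' @param base_quality constant Phred base quality written to all bases.
#' @param chrom reference name for the records.
#' @param offset 0-based template start on \code{chrom}.
#' @param seed RNG seed.
#' @return alignment data.frame (tabular convention); attribute
#'   \code{"haplotypes"} holds the true haplotype sequences.
#' @export
simulate_paralog_reads <- function(n_haplotypes, template_length = 200,
                                   divergence_sites = NULL,
                                   depth_per_haplotype = 10,
                                   read_length = 36, error_rate = 0,
                                   base_quality = 40, chrom = "chr1",
                                   offset = 0, seed = NULL) {
  if (!is_count(n_haplotypes) || n_haplotypes < 1)
    stopf("n_haplotypes must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  template <- sample(bases, template_length, replace = TRUE)
  if (is.null(divergence_sites)) {
    # both sites polymorphic and every haplotype's two-base combination
    # distinct: site 1 cycles ACGT, site 2 the reverse cycle (h <= 4)
    if (n_haplotypes > 4)
      stopf("default divergence sites support at most 4 haplotypes; supply divergence_sites")
    mid <- floor(template_length / 2)
    b1 <- bases[seq_len(max(2L, n_haplotypes))][seq_len(n_haplotypes)]
    b2 <- rev(bases[seq_len(max(2L, n_haplotypes))])[seq_len(n_haplotypes)]
    divergence_sites <- list(pos = c(mid - 5, mid + 5),
                             bases = rbind(b1, b2))
  }
  pos <- divergence_sites$pos
  bmat <- divergence_sites$bases
  stopifnot(length(pos) == nrow(bmat), ncol(bmat) >= n_haplotypes)
  haps <- vapply(seq_len(n_haplotypes), function(h) {
    s <- template
    s[pos + 1] <- bmat[, h]
    paste(s, collapse = "")
  }, "")

  n_reads <- max(1, round(n_haplotypes * depth_per_haplotype *
                            template_length / read_length))
  starts <- sample.int(template_length - read_length + 1, n_reads,
                       replace = TRUE) - 1L
  hap_of <- sample.int(n_haplotypes, n_reads, replace = TRUE)
  seqs <- substring(haps[hap_of], starts + 1, starts + read_length)
  if (error_rate > 0) {
    chars <- strsplit(seqs, "", fixed = TRUE)
    for (i in seq_len(n_reads)) {
      err <- which(runif(read_length) < error_rate)
      if (length(err))
        chars[[i]][err] <- vapply(chars[[i]][err], function(b)
          sample(setdiff(bases, b), 1), "")
    }
    seqs <- vapply(chars, paste, "", collapse = "")
  }
  qual <- strrep(rawToChar(as.raw(base_quality + 33L)), read_length)
  aln <- new_alignments(sprintf("r%05d", seq_len(n_reads)), chrom,
                        offset + starts, read_length, 42L, seqs, qual)
  aln <- aln[order(aln$start), , drop = FALSE]
  rownames(aln) <- NULL
  attr(aln, "haplotypes") <- haps
  aln
}

#' Write a self-contained fixture bundle to disk
#'
#' Materializes a simulated scenario as plain-text files the pipeline can
#' run end to end: \code{genes.bed}, one \code{counts_<label>.tsv} per
#' stringency (with a \code{#totals} header line), \code{groups.tsv},
#' \code{truth.tsv}, a \code{config.txt} echo, and — when the scenario
#' contains true GCNVs — per-individual tabular alignment files under
#' \code{reads/<gene_id>/} for the first two increased genes, in which
#' individuals of the affected group carry 3 collapsed haplotypes and the
#' others 2. Regenerating with the same seed reproduces every file byte
#' for byte.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param outdir output directory (created if needed).
#' @param with_reads also write the allelic-multiplicity read fixtures.
#' @return Invisibly, the simulation result of
#'   \code{\link{simulate_count_matrices}}.
#' @export
make_fixture_bundle <- function(config, outdir, with_reads = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_count_matrices(config)
  write_gene_models(sim$matrices[[1]]$genes, file.path(outdir, "genes.bed"),
                    "bed")
  for (lab in names(sim$matrices))
    write_count_matrix(sim$matrices[[lab]],
                       file.path(outdir, sprintf("counts_%s.tsv", lab)))
  smp <- sim$matrices[[1]]$samples
  writeLines(c("sample_id\tgroup",
               sprintf("%s\t%s", smp$sample_id, smp$group)),
             file.path(outdir, "groups.tsv"))
  tr <- sim$truth
  writeLines(c("gene_id\tcn_A\tcn_B\tis_true_gcnv\tdirection",
               sprintf("%s\t%d\t%d\t%s\t%s", tr$gene_id, tr$cn_A, tr$cn_B,
                       tr$is_true_gcnv, ifelse(is.na(tr$direction), ".",
                                               tr$direction))),
             file.path(outdir, "truth.tsv"))
  cfg <- config[setdiff(names(config), "gcnv_spec")]
  writeLines(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(v) paste(format(v), collapse = ","),
                            "")),
             file.path(outdir, "config.txt"))
  if (with_reads && any(tr$is_true_gcnv)) {
    idx <- which(tr$is_true_gcnv)[1:min(2, sum(tr$is_true_gcnv))]
    rd <- file.path(outdir, "reads")
    for (g in idx) {
      gd <- file.path(rd, tr$gene_id[g])
      dir.create(gd, showWarnings = FALSE, recursive = TRUE)
      affected <- if (tr$cn_A[g] != 2) "A" else "B"
      for (s in seq_len(nrow(smp))) {
        h <- if (smp$group[s] == affected) 3L else 2L
        aln <- simulate_paralog_reads(
          h, template_length = 200, read_length = config$read_length,
          chrom = sim$matrices[[1]]$genes$chrom[g],
          offset = sim$matrices[[1]]$genes$start[g],
          seed = stage_seed(config$seed, 100 * g + s))
        write_alignments(aln, file.path(gd, paste0(smp$sample_id[s], ".tsv")))
      }
    }
  }
  invisible(sim)
}

#' Write a count matrix as TSV
#'
#' Layout: a \code{#totals} line carrying the per-sample genome-wide
#' totals, then a header (gene_id, length, one column per sample) and one
#' row per gene.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_count_matrix <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#totals\t",
                    paste(sprintf("%.0f", cm$samples$total_mapped_reads),
                          collapse = "\t")), con)
  writeLines(paste(c("gene_id", "length", cm$samples$sample_id),
                   collapse = "\t"), con)
  body <- apply(cm$counts, 1L, function(r)
    paste(sprintf("%.0f", r), collapse = "\t"))
  writeLines(sprintf("%s\t%.0f\t%s", cm$genes$gene_id, cm$genes$length, body),
             con)
  invisible(path)
}

#' Read a count matrix written by \code{\link{write_count_matrix}}
#'
#' @param path counts TSV path.
#' @param group per-sample group labels, or a 2-column
#'   \code{sample_id}/\code{group} data.frame (e.g. read from
#'   \code{groups.tsv}).
#' @param genes optional \code{\link{gene_intervals}} with real
#'   coordinates; if NULL, placeholder intervals of the recorded lengths
#'   are used.
#' @return A \code{\link{count_matrix}}.
#' @export
read_count_matrix <- function(path, group, genes = NULL) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#totals"))
    stopf("%s: missing #totals header line", path)
  totals <- as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]][-1])
  tab <- read.table(path, sep = "\t", header = TRUE, skip = 1L,
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
  counts <- as.matrix(tab[, -(1:2), drop = FALSE])
  sample_id <- colnames(counts)
  if (is.data.frame(group))
    group <- group$group[match(sample_id, group$sample_id)]
  if (is.null(genes)) {
    start <- cumsum(c(0, tab$length[-nrow(tab)] + 500))
    genes <- gene_intervals(tab$gene_id, "chr1", start, start + tab$length)
  } else {
    genes <- genes[match(tab$gene_id, genes$gene_id), , drop = FALSE]
    class(genes) <- c("gene_intervals", "data.frame")
  }
  count_matrix(counts, genes, group, totals, sample_id)
}
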