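---
title: "Detecting gene copy number variants under parallel selection from read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene copy number variants under parallel selection from read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paracnv)
```

## The problem

When related lineages adapt independently to the same environment —
marine sticklebacks repeatedly colonizing fresh water are the canonical
case — genetic variants shared specifically within the adapted lineages
are strong candidates for positive (parallel) selection, because drift is
unlikely to produce the same change many times over. Copy number variants
of whole genes (GCNVs) change gene dosage and are therefore plausible
substrates of such adaptation, but at low sequencing coverage (a few
reads per position) per-individual copy-number calling is hopeless.

`paracnv` implements the group-contrast alternative: copy-number gains
and losses scale the *expected number of reads mapping to a gene*, so a
gene whose normalized mapped-read counts differ consistently between two
groups of individuals — across every mapping stringency tried — is a GCNV
candidate shared by one group, exactly the footprint parallel selection
leaves. The package covers the full path from alignment records to
calls, the chance-expectation test for the number of calls, and a
read-level confirmation that a candidate gain really is a duplication.

## The model and procedure

### Counting and filtering

Reads (single-end, typically 36 bp) are deduplicated positionally — one
survivor per (chromosome, start), the one with the highest mapping
quality, ties to the first seen — to suppress PCR duplicates, and counted
against gene bodies (most 5' to most 3' position) with ≥ 1 bp overlap
semantics; a read spanning a boundary counts for both genes. Two
label-free filters then remove genes where low coverage would fabricate
signal: a gene is dropped when the median across individuals of mapped
reads per 100 bp of gene length falls below one ("less than one", so a
median of exactly one survives), or when any individual has zero mapped
reads. Counts are normalized by each individual's genome-wide total of
mapped reads; no GC or mappability correction is applied, and none is
assumed by the test, because the contrast is between groups at the same
locus.

### The negative-binomial exact test

Counts for gene $g$ in individual $s$ are modelled as
$y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi)$ with
$\mathrm{Var} = \mu + \phi\mu^2$ and a single dispersion $\phi$ shared by
all genes. Library sizes are first equalized by scaling every sample's
counts to the geometric-mean total and rounding ("pseudo-counts").
$\phi$ is estimated by maximizing the likelihood *conditional on the
per-group gene totals* — conditioning removes every per-gene mean from
the problem, leaving a one-dimensional likelihood — with a bracketed
search on $\phi \in [0, 10]$ to tolerance $10^{-6}$; $\phi = 0$
degenerates to Poisson and is returned when the boundary fits best.

For the test, each group's sum of equalized counts is NB with size
$n_g/\phi$ (a sum of i.i.d. NB variables with common dispersion is NB
with summed size — this is the modelling assumption, exact for shared
$\mu$ within a group). Conditioning on the total $N = A + B$ removes the
mean; the two-sided p-value is the minimum-likelihood rule: the summed
probability of all splits $(a, N-a)$ no more probable than the observed
one. With $\phi = 0$ this is exactly the conditional binomial test, which
is the package's primary correctness oracle; the split enumeration runs
in compiled code because the permutation stage re-runs it thousands of
times. The implementation agrees with an independent minimum-likelihood
exact-test implementation (edgeR's `exactTestBySmallP`) to ~1e-15, but
exact agreement with a full edgeR pipeline is *not* claimed: edgeR's
quantile-adjusted pseudo-counts and default doubletail rule differ by
design, and the statistical core here is owned, testable code.

Per-gene p-values are adjusted by Benjamini–Hochberg (via
`stats::p.adjust`), and a gene is *significant* at FDR < 0.05.

### Consensus across mapping stringencies

Mapping parameters (e.g. the permitted mismatch-quality budget) change
which reads survive, and a call that flips with them is not trustworthy.
The screen therefore runs on one count matrix per mapping option and
intersects: a **consensus GCNV** must be significant under every option,
with a direction (which group has the higher normalized mean) that agrees
across options; direction conflicts are dropped with a warning. Genes
surviving the coverage filter under only some options are excluded from
the shared universe — the conservative choice where the source procedure
is silent.

### Permutation null for the number of calls

Whether the *number* of consensus calls exceeds drift expectations is
assessed by reallocating the $2n$ individuals into two balanced groups
uniformly at random (10,000 times at full scale; 200/1,000 presets for
desk work), rerunning the same analysis each time, and reporting the
empirical p-value $(\#\{\mathrm{null} \ge \mathrm{obs}\} + 1)/(B + 1)$.
The +1 correction avoids a literal zero and is standard for permutation
tests; `plus_one = FALSE` restores the raw fraction. The identity
permutation, if drawn, is an ordinary null draw. Dispersion is
re-estimated inside every permutation; the coverage filters involve no
group labels, so re-applying them per permutation provably returns the
same gene set and the implementation computes them once up front.

### Allelic multiplicity: separating duplication from deletion

A higher count in group A is consistent with a gain in A *or* a loss in
B. Read-level haplotypes discriminate: a diploid locus carries at most
two allelic sequences, so if reads covering a pair of nearby SNVs support
**three or more** distinct two-base haplotypes, the reads must come from
collapsed duplicated copies. The package calls SNVs from a minimal pileup
(≥ 2 distinct bases, each with ≥ 2 supporting reads of base quality
≥ 30; an external VCF may be supplied instead), enumerates SNV pairs
within the read length (distance ≤ L − 1 = 35 bp, so one read can phase
the pair; the ≤ L reading is available as a switch), counts haplotypes
supported by at least 2 reads with quality ≥ 30 at both positions (reads
with N are excluded), and calls a group *duplicated* when at least 3 of
its individuals each show a ≥ 3-haplotype pair, with a *strong* flag when
each such individual shows at least 2 such pairs.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | per-stringency FDR threshold (fixed by the procedure; exposed as a knob) |
| `n_perm` | 10000 | balanced reallocations for the null of the GCNV count |
| `read_length` | 36 bp | maximum span of a phaseable SNV pair (L − 1) |
| `q_min` | 30 | Phred floor for bases entering SNV calls and haplotype tallies |
| `min_allele_reads` | 2 | reads per allele for a pileup SNV call |
| `min_support` | 2 | reads per retained haplotype ("multiple reads") |
| `min_individuals` | 3 | individuals per group for a duplication call |
| `min_pairs_strong` | 2 | qualifying pairs per individual for the strong flag |

The dispersion search bracket `[0, 10]` and its `1e-6` tolerance, the
geometric-mean equalization target, and the `1e-7` relative tie tolerance
in the exact test (which guards the minimum-likelihood comparison against
floating-point noise on symmetric splits) are numerical choices, not
scientific ones; degenerate inputs (all-zero matrices, empty gene
universes, zero totals, unbalanced groups) raise informative errors
rather than propagating NaNs.

## What the simulator emulates — and what it does not

`simulate_count_matrices()` generates the study regime: 10 + 10
individuals, ~2.3× coverage, 36-bp reads, per-gene expected counts
$\mathrm{lib}_s \cdot \frac{\mathrm{depth}}{L}(\mathrm{len}_g + L - 1)
\cdot \mathrm{CN}/2$, NB noise with common $\phi$ (default 0.1, a
moderate cross-individual overdispersion), log-normal library-size
variation (CV 0.2), and gene lengths log-normal with median 3 kb and
sd(log) 0.9 — spanning roughly 0.2–70 kb so the per-100-bp filter is
exercised across realistic spans, including the ~1.6–62 kb range of the
loci that motivated the method. The three mapping-stringency replicates
are *binomial thinnings of one latent count* (retentions 1/0.9/0.8 from
the most permissive to the strictest option): thinning preserves the NB
dispersion and reproduces the essential feature that the real mappings
share reads, which is what makes a consensus rule meaningful. Segmental
events are available as gene clusters; `parallel_scenario()` reproduces
the motivating shape (24 GCNVs at copy-number ratio 2, 19 up in group A
with a 7-gene cluster, 5 up in group B with a 2-gene cluster, placed on
genes with expected baseline count ≥ 20). `simulate_paralog_reads()`
draws error-configurable 36-bp reads from 2–4 divergent haplotypes
collapsed onto one reference locus.

The simulator does **not** model mappability or GC structure along the
genome, positional sequencing biases (real read depth fluctuates along a
gene), linked SNV ascertainment, or reference bias against the diverged
group — so green tests certify the statistical machinery under the
stated model, not robustness to those artifacts. On real data the
mapping-efficiency question (a diverged group mapping worse to the
reference) must be addressed as in the source procedure, by checking SNV
densities in called genes.

## Design choices made where the design was open

* **Coordinates** are 0-based half-open internally; 1-based inclusive
  gene tables are converted at the boundary. Strand is ignored
  throughout (reads are counted against the gene body regardless of
  strand), and gene spans are assumed start < end after conversion.
* **Deduplication keys on (chrom, start) only**, single-end `rmdup`
  semantics; the tabular alignment format carries no strand, and where
  SAM input has one this is a documented divergence.
* **Totals are counted after deduplication**, matching the matrix being
  normalized; the source procedure does not say which side of dedup its
  totals came from.
* **A read overlapping two genes counts for both**; summed counts may
  then exceed the total, which only matters for overlapping annotations.
* **Multi-hit exclusion is an input contract** (the aligner's unique-hit
  option), not an operation; repeated read ids trigger a warning only.
* **The classic exact test** (not a GLM) is assumed, with one common
  dispersion — no tagwise/trended dispersion, no TMM, matching a
  normalization that divides by genome-wide totals only.
* **Uniform balanced reallocation** in the permutation null; geographic
  pairing of individuals is not preserved (the source is silent).
* **Any qualifying SNV pair** counts toward an individual's multiplicity
  call; the pairs need not be the same pair across individuals.
* The per-gene screen is exposed as a classed fit (`gcnv_fit`) with
  `print`/`summary`/`plot` methods; `coef`/`predict` make no sense for an
  exact-test screen and are deliberately absent.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the full study scale where
it matters: 2,000 genes × 20 individuals × 3 stringencies for
calibration (type-I error ≤ nominal, Kolmogorov–Smirnov distance of null
p-values from uniform < 0.05) and for power (detection rate of the 24
planted GCNVs pooled over 5 replicate data sets — a single 24-event draw
has ~±8% binomial noise on the rate — with 100% direction agreement
required), and n_perm = 1,000 for the permutation p on the signal
scenario. The null-uniformity of the permutation p is checked at 300
genes × 200 permutations × 50 data replicates: the uniformity of an
empirical p does not depend on the gene count, and this keeps the check
inside a desk-scale run. The allelic-multiplicity recovery checks
(haplotype number 2, 3, 4 at 10× per haplotype) run in seconds.

## Known limitations

* At ~2.3× coverage the screen is conservative: weakly covered genes are
  filtered, and modest copy-ratio changes at short genes are
  undetectable — more coverage means more calls, not fewer.
* The common-dispersion assumption borrows strength across genes but
  under-serves genes with atypical variability; a tagwise model is out
  of scope by design.
* The exact test conditions on totals of *rounded* pseudo-counts;
  with very small libraries the rounding granularity is visible.
* The allelic-multiplicity test requires divergence between copies
  within 35 bp windows; recent identical duplicates are invisible to it.
* The permutation null at 10 + 10 has $\binom{20}{10}/2$ distinct
  reallocations; empirical p-values below ~1/92,378 are unreachable in
  principle and below 1/(n_perm+1) in practice.
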