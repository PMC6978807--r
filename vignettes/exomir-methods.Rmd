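---
title: "Models and methods behind exomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind exomir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomir)
```

exomir is an end-to-end pipeline for miRNA profiling and A-to-I editing
detection in small RNA libraries from exosome-enriched fractions. This
vignette explains the models the package implements, the parameters that
matter, the design choices that were genuinely open, and what the bundled
simulator does and does not capture.

## Study design and data model

The canonical design is factorial: biological replicates (default 3) of
{control, KA} animals at {24 h, 2 wk} after insult, with exosomes isolated
either by ultracentrifugation (UC) or by a precipitation kit. Isolation
method is treated as a batch-like factor: detection and edited-site
replication are assessed within a method, while the default group contrast
pools methods at a timepoint.

The reference is a table of mature miRNAs annotated on hairpin sequences.
All reported coordinates are 1-based on the mature strand (position 1 =
5′ nucleotide); the seed window defaults to mature positions 2–8 inclusive
and is configurable per reference. The internal alphabet is RNA; T on input
is converted to U on read.

## Read assignment and modification counting

The quantifier is deliberately simple and fully auditable: each read is
matched ungapped against every hairpin at every offset placing the read 5′
end within ± 2 nt of an annotated mature start. Placements with more than 2
mismatches are rejected; among acceptable placements the fewest-mismatch
one wins. Ties at the minimal mismatch count across different genes leave
the read unassigned (tallied, never fatal); ties within one gene resolve to
the placement nearest the annotated start. Mismatch budget and slack are
parameters; the defaults tolerate one true edit plus one sequencing miscall
while keeping assignment unambiguous on desk-scale references.

Maximal runs of contiguous mismatches touching the read 3′ end are
classified as 3′ non-templated additions and excluded from internal
modifications; 5′ terminal runs are treated symmetrically. Mismatches
falling outside the annotated mature window are likewise excluded. What
remains is the modification tensor: read counts per (sample, miRNA, mature
position, ref>obs substitution).

Matching is implemented in C++ on unique read sequences (libraries collapse
heavily, since most reads are error-free copies of a mature sequence), so a
24-library study at ~5 × 10⁴ reads per library quantifies in seconds.

## Expression stages

* **Detection.** A miRNA is "expressed" if its CPM (on raw library sizes,
  pre-normalization) is ≥ 1 — log-CPM ≥ 0 — in at least 6 samples. Both
  thresholds are parameters.
* **Normalization.** Trimmed mean of M-values with the published defaults:
  reference sample chosen by the upper-quartile rule, two-sided trims of
  30% on M and 5% on A over genes nonzero in both samples,
  precision-weighted mean of the surviving M-values with inverse asymptotic
  binomial variances, factors rescaled to geometric mean 1. The
  implementation is validated in the test suite against
  `edgeR::calcNormFactors` to 10⁻⁶ on toy matrices and satisfies the exact
  invariants (duplicated or rescaled samples give factors of exactly 1).
* **log-CPM.** `log2((count + c) / (lib × factor + 2c) × 1e6)` with prior
  count c = 0.5 (a common default; the transform is otherwise
  parameter-free).
* **Differential abundance.** Per miRNA, a two-sided Welch t-test on
  log-CPM between the groups at one timepoint; log₂ fold-change is the
  difference of group means. The primary flag uses the *unadjusted*
  p < 0.05 rule; BH-adjusted q-values and a BH flag are reported alongside.
  This is a deliberate, documented simplification: the moderated
  empirical-Bayes machinery of edgeR/limma is out of scope here, and the
  Welch test keeps the stage fully specified, dependency-light and
  testable. Degenerate rows are handled explicitly — both groups constant
  and equal gives p = 1; constant but unequal gives the smallest positive
  double and a `zero_variance` flag so users can triage such rows.
* **PCA, ranking, overlaps.** PCA is a singular value decomposition of
  row-centered log-CPM (sample coordinates plus variance fractions; a
  constant matrix returns zeros rather than an error). Abundance ranking
  orders miRNAs by mean log-CPM and flags which of the top-*n* are detected
  in every sample; set overlap and cell-type attribution are exact set
  partitions, with multi-list members reported as "ambiguous" rather than
  double-counted.

### A note on Welch calibration at n = 3

With 3 samples per side the Welch test is intrinsically conservative
(empirical type-I error ≈ 0.02–0.03 at nominal 0.05, even on normal data),
which is one reason the unadjusted p < 0.05 rule is less anti-conservative
in this design than it looks. On the pipeline's default contrast — methods
pooled at a timepoint, 6 vs 6 — the empirical type-I error is ≈ 0.047,
and that is where the test suite audits calibration.

## Editing model

The null hypothesis for every observed modification is that it is
sequencing error: with per-base miscall probability p = 0.01 (Phred 20),
the modification count k of a miRNA with n reads is Binomial(n, p). The
p-value is the exact upper tail P(X ≥ k), computed via the binomial
survival function — never naive summation, which loses mass for large n —
and verified in the tests against direct summation to 10⁻¹² for all
n ≤ 500.

Decisions and their rationale:

* **Count floor.** miRNAs with fewer than 10 reads in a sample are not
  tested there (and their editing levels are reported as missing, not 0):
  below that depth k/n is too unstable to interpret.
* **Null rate scope.** p = 0.01 is applied to *any* miscall at the
  position, not divided by 3 for the specific target base. Since real
  miscalls to a specific base occur at roughly p/3, the test is mildly
  conservative — a deliberate property inherited from the aggregate error
  rate the null is defined with. A per-substitution p/3 variant exists
  behind an argument, off by default.
* **BH scope.** Adjustment is within each sample, across all (miRNA,
  position, substitution) tests of that sample; a pooled mode is available.
  Within-sample adjustment matches the per-sample language of the
  replication rule below.
* **Replication.** A significant modification becomes an edited site only
  if it is significant in ≥ 2 samples of at least one (group, timepoint)
  cell within at least one isolation method. This is the lenient reading of
  "at least two UC or two kit samples per group"; the strict reading
  (replication in every cell of some method) is available via
  `rule = "all_cells"`.
* **ADAR restriction.** Sites are filtered to A>G by default — inosine
  reads as G — and can additionally be restricted to a whitelist of bona
  fide miRNA genes.
* **Differential editing.** Welch t-tests on per-sample levels per
  timepoint, BH across sites within the contrast. Missing levels (n < 10)
  are excluded, never imputed as zero. Note that with very few sites a
  single overwhelming signal lowers the BH bar for the remaining sites, so
  a marginal q ≈ 0.05 call on a null site occasionally accompanies a real
  one; that is the expected behaviour of FDR control, not a defect.
* **Seed enrichment.** Whether edited sites concentrate in seed regions is
  tested as an exact upper-tail binomial with success probability 1/3 (the
  seed's approximate share of a mature miRNA; a per-reference mean share is
  available via `seed_fraction_of()`). For the bundled catalog — 4 seed
  sites out of 6 — this gives p = 73/729 ≈ 0.100. The enrichment is
  suggestive, not significant, at conventional thresholds; the package
  reports its own exact computation.
* **Motif context.** Per site the (preceding, edited, following)
  trinucleotide is read off the mature sequence; aggregate counts are
  emitted as a position-frequency table suitable for logo rendering.
  Boundary sites yield one-sided contexts with the absent flank missing.

## The simulator

The generator emulates exactly the structure the analysis assumes, so every
downstream stage can be tested against ground truth:

* **Abundances.** Relative abundances are drawn log-normal (default log-sd
  1.5) *once per miRNA* and shared across samples, with a mild per-sample
  log-normal noise multiplier (log-sd 0.2) representing replicate
  variability of pooled libraries. Drawing abundances independently per
  sample would make replicates of the same condition nearly uncorrelated —
  no realistic study behaves that way, and no fold-change of plausible size
  would be detectable at n = 3.
* **Counts.** Library sizes are negative-binomial around the configured
  mean (default 2 × 10⁵ reads, dispersion 20 — desk-scale but deep enough
  that a median miRNA has hundreds of reads); counts are multinomial given
  the library size, so column sums conserve exactly.
* **Reads.** Every read is the full mature sequence. A planted edit at
  level e flips a Binomial(n, e) subset of that miRNA's reads at the
  planted position *before* error; each base is then independently
  miscalled with probability 0.01, uniformly to the other three
  nucleotides. FASTQ qualities are constant Phred 20. Realized (not just
  nominal) edited-read counts are recorded as ground truth.
* **Determinism.** All randomness derives from the config seed; identical
  configs produce byte-identical FASTQ files.

What the simulator does *not* model: adapters and trimming artifacts, read
length variation and true isomiRs, 3′ non-templated additions (an optional
rate exists solely to exercise the quantifier's exclusion rule), PCR
duplicates, machine-specific quality profiles, or substitution-biased
error. Passing tests therefore demonstrate correctness of the statistical
machinery under the stated error model, not robustness to every artifact of
real libraries.

## Numerical and engineering choices

* Exact survival-function binomial tails (stable to n ≈ 10⁷).
* BH via `p.adjust`; PCA via `prcomp`; all distributions via base R.
* Zero-variance t-test cases handled explicitly (see above) rather than
  erroring mid-pipeline.
* The TMM trim uses rank-based boundaries (floor(n · trim) + 1), matching
  the reference implementation's tie behaviour.
* Multi-mapping reads are discarded rather than fractionally assigned —
  the simplest auditable policy — and tallied in the per-sample log.
* Empty inputs degrade gracefully: an empty FASTQ yields an empty count
  column with a warning; an all-null modification table yields zero tests.

## Problem sizes used in the test suite

The suite validates operating characteristics by Monte Carlo at sizes
chosen to finish in minutes on one core while leaving comfortable
statistical margins: pure-error false-positive audits on 20 simulated
12-library studies at 10⁵ reads each (expected edited sites after
replication: ~0 — observed 0); editing-level recovery at ~2 500× depth
across levels 0.05–0.5 (|bias| ≤ 0.02, dominated by the +p/3 error inflow
and −p·e outflow, which nearly cancel); differential-editing power at
~5 000× depth, 0.05 vs 0.50, 3 vs 3 (100 runs, ≥ 95% detected); DE power
for a planted 4-fold change at 10⁶ reads (100 runs, ≥ 95%); and 20
full-pipeline fixture runs (all three planted edits, no spurious sites, in
≥ 90% of seeds).

## Known limitations

* The Welch substitution means moderated-variance gains of edgeR/limma are
  absent; at n = 3 per group the test is conservative.
* The quantifier is a stand-in for production aligners: ungapped, no indel
  handling, no isomiR cataloguing beyond the terminal-run exclusion.
* Editing levels are raw k/n; no deconvolution of the small error-rate
  inflation is attempted (it is quantified in the tests instead).
* The bundled six-site catalog carries mature sequences only; analyses
  needing hairpin context for those miRNAs must supply a full reference.
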