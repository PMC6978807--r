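# exomir

Analysis of microRNA content and adenosine-to-inosine (A-to-I) editing in
small RNA sequencing libraries from exosome-enriched fractions (EEFs).

Brain cells release exosomes (~100 nm extracellular vesicles) whose miRNA
cargo changes after insults such as status epilepticus. Profiling that cargo
raises two questions this package addresses for desk-scale, fully
reproducible data:

1. **Which miRNAs are present, and do their abundances differ** between
   treated (KA, kainic acid) and control animals, at different timepoints,
   for libraries prepared by ultracentrifugation (UC) or by precipitation
   kit?
2. **Which miRNA positions are ADAR-edited?** ADAR enzymes deaminate A to
   inosine on double-stranded RNA; inosine base-pairs like G, so editing
   appears in sequencing as an A>G substitution. Edits inside the seed
   region (mature positions 2–8) can retarget a miRNA.

## The statistical core

For a miRNA with total read count *n* in a sample, the read count *k* of a
particular substitution at a particular mature position is compared against
the sequencing-error null

> *k* ~ Binomial(*n*, *p*), with *p* = 0.01,

the Phred-20 miscall probability. The reported p-value is the exact upper
tail P(X ≥ k), computed with a survival-function formulation that is stable
up to *n* ≈ 10⁷. Within each sample, p-values across all (miRNA, position,
substitution) tests are Benjamini–Hochberg adjusted; modifications with
q < 0.05 on miRNAs with at least 10 reads are *significant*. A site becomes
an **edited site** only if it is significant in at least two samples of one
(group, timepoint) cell within one isolation method. Editing level is
*k*/*n*; group differences per timepoint are tested with unpaired two-sided
Welch t-tests, BH-adjusted across sites.

Around that core the package provides the standard expression stages —
detection filtering (CPM ≥ 1 in ≥ 6 samples), TMM normalization, log₂-CPM,
PCA, Welch differential abundance with the unadjusted p < 0.05 rule,
abundance ranking, UC/kit set overlaps, cell-type marker attribution — a
transparent read-to-hairpin quantifier (ungapped, ≤ 2 mismatches, read
start within ± 2 nt of the annotated mature start, ties discarded, terminal
mismatch runs excluded as 3′ additions), and a simulator that emits FASTQ
libraries with known abundances, planted fold-changes, planted edits and
Phred-calibrated miscalls, together with full ground truth.

## Worked example

The bundled catalog holds six A>G edited sites on mouse miRNAs with their
miRBase v21 mature sequences:

```r
library(exomir)
cat6 <- edited_site_catalog()
annotate_seed(cat6$sites, cat6$reference)
#> # A tibble: 6 × 5
#>   mature_id       position substitution extent in_seed
#> 1 mmu-miR-411-5p         5 A>G          heavy  TRUE
#> 2 mmu-miR-376b-3p        6 A>G          heavy  TRUE
#> 3 mmu-miR-3099-3p        7 A>G          heavy  TRUE
#> 4 mmu-miR-381-3p         7 A>G          slight TRUE
#> 5 mmu-miR-421-3p        14 A>G          slight FALSE
#> 6 mmu-miR-378a-3p       16 A>G          heavy  FALSE
seed_enrichment(6, 4)         # 4 of 6 sites in seed vs 1/3 expected
#> [1] 0.1001372
motif_context(cat6$sites, cat6$reference)$pfm
#>           A C G U
#> preceding 1 1 0 4   # U-enriched, G-depleted upstream of the edited A
#> edited    6 0 0 0
#> following 1 0 5 0   # G-enriched downstream
```

Four of the six sites lie in the seed window 2–8; the exact binomial
enrichment p-value is 0.100. The flank counts show the canonical ADAR
preference (U before, G after the edited adenosine).

A full simulated study — 24 libraries (3 replicates × {control, KA} ×
{24 h, 2 wk} × {UC, kit}), 50 miRNAs, three planted A>G edits, four planted
4-fold expression changes — runs in seconds:

```r
fx <- make_fixture(seed = 1)
res <- run_pipeline(fx$reference, fx$config)
res$sites
#> # A tibble: 3 × 4
#>   mature_id      position substitution in_seed
#> 1 syn-miR-010-3p        4 A>G          TRUE
#> 2 syn-miR-037-3p        2 A>G          TRUE
#> 3 syn-miR-043-3p       11 A>G          FALSE
```

All three planted edits are recovered with no spurious site; the site
planted at different levels in the two groups (0.05 in control, 0.50 in KA)
dominates the differential-editing table:

```r
dplyr::filter(res$diff_editing, significant)[, c("mature_id", "position",
    "timepoint", "mean_level_1", "mean_level_2", "diff_q")]
#>   mature_id      position timepoint mean_level_1 mean_level_2   diff_q
#> 1 syn-miR-010-3p        4 24h              0.491       0.0526 6.93e-12
#> 2 syn-miR-010-3p        4 2wk              0.496       0.0556 7.12e- 8
#> 3 syn-miR-037-3p        2 2wk              0.296       0.289  4.75e- 2
```

(`mean_level_1` is the KA group. The third row is a borderline q = 0.048
call on an equal-level site — the kind of marginal positive an FDR
threshold admits by construction; the vignette discusses it.)

A thin command-line wrapper mirrors the same stages:

```sh
Rscript inst/scripts/exomir.R simulate --seed 1 --out sim/
Rscript inst/scripts/exomir.R run --reference-fasta sim/reference.fa \
    --reference-annotation sim/reference.tsv --design sim/design.tsv \
    --reads sim/ --out results/
```

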