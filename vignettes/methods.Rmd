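---
title: "Inferring outcome-associated transcription factors from DNA methylation: models and design choices"
author: "methSurvTF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring outcome-associated transcription factors from DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methSurvTF)
```

# The scientific problem

Transcription-factor (TF) binding and DNA methylation are intertwined: many
factors bind poorly to methylated recognition sites, and methylation changes
near binding sites track with TF activity.  methSurvTF exploits this to infer
which TFs are associated with clinical outcome from methylation array data
alone.  The chain of reasoning is:

1. **Screen CpGs.**  Each CpG's beta-value (fraction methylated, in [0, 1])
   is tested either for differential methylation between two sample groups
   (e.g. ER+ vs ER-) or for association with survival in a univariate Cox
   proportional-hazards model.
2. **Regions.**  Around every significant CpG a 102-bp genomic window is
   built; overlapping windows are removed by a greedy lowest-p rule so no
   binding site is counted twice.
3. **Motif presence.**  Each retained window is scanned with a library of
   position weight matrices (PWMs); a motif is "present" when some window
   position, on either strand, scores above an exact-p-value threshold.
4. **Enrichment.**  For every motif, a two-sided Fisher's exact test
   compares presence in the significant ("foreground") regions against a
   background region set, summarised by the relative enrichment
   RE = (foreground presence fraction) / (background presence fraction).
5. **TF networks.**  Motif-level results are aggregated to TFs and embedded
   in a protein-protein interaction graph to show the regulatory
   neighbourhood of outcome-associated factors.

Each step is exported as its own documented function, and `runPipeline()`
chains them from a single declarative config.

# Statistical models and conventions

## Differential methylation

`diffMethylation()` uses a pooled-variance two-tailed Student t-test by
default ("student t-test" is read as the classical equal-variance form;
Welch is available via `var_equal = FALSE`), or a Wilcoxon rank-sum test.
P-values are Benjamini-Hochberg adjusted across all *tested* CpGs: CpGs
with fewer than two complete observations in either group yield no p-value
and are excluded from the BH denominator.  At adjusted p below `alpha`
(default 0.05), a positive statistic labels the CpG *hyper*methylated in
group 1 and a negative one *hypo*methylated.

## Survival screen

`screenSurvivalCpGs()` fits one univariate Cox model per CpG with the
beta-value, untransformed, as the covariate, so the hazard ratio is per
unit beta.  Fitting uses the Efron tie approximation (the default of
mainstream survival software; Breslow is available for cross-checks) with
Newton-Raphson tolerance 1e-9 and at most 50 iterations.  Significance is
the Wald test, and — deliberately — the 0.02 cutoff that defines
*protective* (HR < 1) and *hazardous* (HR > 1) CpGs is **unadjusted**: the
screen trades specificity for power, and the enrichment stage's relative
scores absorb the resulting false positives on both sides of the 2x2 table.
Monotone likelihoods (perfect separation) are flagged `converged = FALSE`
with a missing p-value rather than reported at an arbitrary boundary.
Samples missing time, event or the CpG's beta are dropped per CpG.

## The 102-bp window and "centered"

A CpG occupies two bases.  An even, 102-bp window cannot be centred on a
single base; the package reads it as the unique symmetric decomposition
**50 bp flank + CG + 50 bp flank**: for a 1-based C position p the region
is [p - 51, p + 51) in 0-based half-open coordinates.  Windows are never
clipped at chromosome ends — CpGs too close to an end are dropped — so all
scanned regions have identical length and identical null motif-presence
probability, keeping the 2x2 tables unbiased.

## Overlap filtering

Within each (chromosome, strand) pair — different chromosomes or strands
never conflict — regions are grouped into connected components of the
interval-overlap graph.  Inside a component the region with the smallest
screen p-value is kept, everything overlapping it is discarded, and the
rule recurses on the remainder.  Ties in p are broken by smaller start
coordinate, then lexicographic CpG id, making the output deterministic and
the operation idempotent.  For the pooled "pro+haz" analysis, protective
and hazardous CpGs are pooled *first* and filtered jointly.  The
implementation is validated against an independent quadratic brute-force
greedy oracle on a thousand random instances.

## Exact motif-presence thresholds

The scanner is written from first principles because the presence rule —
per-window p strictly below 1e-4 — needs an *exact* null distribution of
the log-odds score.  For motif probabilities p_i(b) and background q(b),
each position contributes log2(p_i(b)/q(b)) bits.  Scores are discretised
at `granularity` (default 1e-4 bits, so the tail error is bounded by
width x 1e-4) and the null distribution of the window score under
independent background positions is built by dynamic programming.  The
threshold is the smallest attainable score s with P(score >= s) < 1e-4.

Two consequences worth knowing:

* **Short motifs can be uncallable.**  Under the uniform background even a
  perfect width-6 match has p = 0.25^6 ≈ 2.4e-4 >= 1e-4, so a width-6
  consensus motif is *unattainable* and never called present; at width 7
  (0.25^7 ≈ 6.1e-5) exactly the consensus word passes.  The scanner
  reports such sentinels explicitly instead of silently emitting an
  all-FALSE column.
* **Both strands are always scanned** (motif models are single-stranded,
  DNA is not), windows containing N are skipped, and overlapping matches
  collapse into a single Boolean per (region, motif) — the presence matrix
  is Boolean by design.

The default background is uniform (0.25 per base): parameter-free and
reproducible.  A zero-order background estimated from the scanned regions
is available via `scanParams(background = "zero_order_from_regions")` for
sensitivity analysis.  PWMs are regularised on input — count matrices get
a 0.1 pseudocount per cell, probability matrices are floored at 1e-4 and
renormalised — so no log-odds score is ever -Inf.

## Enrichment and background choice

`fisherTwoSided()` sums hypergeometric point probabilities (computed in log
space, safe at N ~ 1e5) of every fixed-margin table at most as probable as
the observed one, with the conventional (1 + 1e-7) tolerance; any zero
margin returns p = 1.  The foreground's complement — all overlap-filtered
tested regions not in the foreground — is the default background.  This is
a genuine design choice (an alternative restricts the background to
non-significant CpGs only; both are exposed via
`pipelineConfig(background =)`); the complement was chosen because it is
well-defined for every foreground type, including cluster memberships,
and keeps foreground + background a partition of the tested regions.
`matchSetSizes()` implements the power control used when two foregrounds of
unequal size are compared: both are truncated to their top-n most
significant CpGs, n being the smaller set size.

RE is defined as the ratio of presence proportions — the only definition
under which mild depletion (e.g. 0.93-fold) can coexist with a highly
significant Fisher p on large region sets.  RE is +Inf when a motif occurs
in the foreground but in no background region, and undefined (reported
"flat" with p = 1) when absent everywhere.

## Clustering

`kmeansBeta()` clusters CpGs by their beta-value profiles with Lloyd
iterations from k-means++ seedings, best of `restarts` starts by WCSS, and
relabels clusters by descending centroid mean so "cluster 1" is always the
most methylated.  The elbow rule for k is deliberately not automated:
`wcssCurve()` reports best-of-restarts WCSS for k = 1..10 (each k also
warm-starts from the previous solution plus the farthest point, which
guarantees a non-increasing curve), and the default k = 5 is a config
value, not an inference.  Missing beta-values are imputed by the CpG's row
mean before clustering.

## TF aggregation and networks

Only motifs *enriched* at adjusted p < alpha (default 0.01) contribute to a
TF — depleted motifs are excluded — and when several motifs of one TF
qualify, their p-values are averaged.  Adjusted p is used for the
threshold, raw p for the averaged `mean_p`, and both columns are emitted so
either convention can be inspected.  The subnetwork is the *induced*
subgraph on significant TFs plus their first-degree interaction partners
(neighbour-neighbour edges retained), with per-node mean_p, degree and
category (protective / hazardous / both / neighbor) carried into GraphML.

# The synthetic-data generator

No public, license-free dataset reproduces the controlled inputs this kind
of analysis consumes (methylation array + survival + licensed motif
libraries), so the package ships a generator whose defaults define its
reference study: two 1-Mb chromosomes, 10,000 CpGs at true CG dinucleotides,
300 samples in two groups (0.77/0.23), 40 decoy + 2 planted motifs, 300
causal survival CpGs, plant rates 0.6 (foreground) vs 0.05 (background),
a target censoring fraction of 0.3, and a baseline hazard of 1/2000 per
day.  Design choices:

* **Survival model.**  Event times are exponential with hazard
  `baseline_hazard * exp(gamma * mean beta over causal CpGs)` — the
  simplest generative model satisfying proportional hazards, i.e. exactly
  the assumption the screen makes.  Censoring is independent exponential
  with its rate tuned by root-finding so the expected censored fraction
  matches the target.  The generator makes no claim that real tumour data
  arise this way; it is the cleanest model under which the screen *should*
  work, which is what a correctness test needs.
* **A latent methylation risk factor.**  Causal CpGs draw their
  beta-values from Beta distributions centred on a per-sample latent score
  m_j ~ Beta(4, 4) (concentration 60, s.d. ≈ 0.065).  This correlates the
  causal CpGs with each other and with the hazard; without it, a hazard
  driven by the *mean* over 300 independent CpGs would be nearly
  independent of any single CpG and no per-CpG screen could succeed.
* **gamma = 3 per unit beta** by default.  With latent-score s.d. ≈ 0.17
  and ≈ 210 events at n = 300, the expected per-CpG Wald z is ≈ 7, i.e.
  high power at the unadjusted 0.02 cutoff — the regime the reference
  study needs so that foreground membership reflects the planted truth
  rather than screening noise.
* **Plants overwrite the genome** (rather than mutating it
  probabilistically) at a uniform offset within the CpG's 102-bp window,
  reverse-complemented for minus-strand plants, so ground truth is
  unambiguous; scanning is strand-symmetric, so strand choice cannot
  affect detection.  Planted PWMs are high-information (0.94 dominant
  base, ≈ 1.58 bits/column, width >= 7) so a sampled occurrence is almost
  always callable at p < 1e-4.  When plant windows of nearby CpGs overlap,
  a later plant may clobber an earlier one — both remain recorded, and the
  tests account for it.
* **Causal = foreground.**  The survival-causal CpGs are also the
  motif-planting foreground, mirroring the premise under test: that
  survival-associated CpGs carry TF binding sites.
* **Optional planted cluster structure** (`n_clusters > 0`) draws CpG
  baselines around k evenly spaced methylation levels (0.1..0.9) with a
  configurable within-cluster s.d., used to verify cluster recovery
  (adjusted Rand index > 0.9 at 5x separation).

What the generator does **not** emulate: Illumina probe chemistry and
type-I/II bias, batch effects, copy-number confounding, spatial
correlation of methylation beyond the causal latent factor, and realistic
motif co-occurrence structure.  Passing tests therefore demonstrate the
*algorithms* are correct and calibrated under their stated assumptions —
not that biological conclusions transfer to any particular cohort.

# Numerical choices and degenerate inputs

* Fisher point probabilities in log space; the two-sided "as extreme"
  comparison uses the standard (1 + 1e-7) relative tolerance.
* DP score discretisation 1e-4 bits; thresholds compare *integerised*
  scores on both the DP and scanning sides, so presence calls agree
  exactly with brute-force enumeration (verified for all widths <= 8).
* Cox: Newton-Raphson eps 1e-9, max 50 iterations; non-convergence is a
  flag, not an error; constant covariates and zero-event strata are
  errors naming the problem.
* BH excludes untestable features from m; `bhAdjust(p, m)` exposes m for
  callers with their own conventions.
* k-means empty-cluster failures (possible under Lloyd) are retried with a
  fresh k-means++ draw; all seeding is reproducible from the seed.
* Ties: overlap filtering breaks p-ties by start then id;
  `matchSetSizes()` breaks boundary ties by genomic coordinate then id.
* Degenerate censoring targets (0 or 1) warn; beta-values exactly 0 or 1
  are valid (closed interval).

# Problem sizes used in the shipped experiments

The package's own test suite and `scripts/acceptance.R` run: the reference
study (10,000 CpGs x 300 samples, 2 Mb genome, 42 motifs) end to end —
single-seeded in the script, five-seeded in the test suite; a 5,000-CpG
null calibration of the Cox screen; 200 replicates of coefficient recovery
at gamma = 0.8, n = 500; exhaustive Fisher enumeration for all margins with
N <= 48; 20 brute-forced PWMs (4^w word enumerations, w <= 8); 1,000
random overlap-filter instances; and a 600-CpG planted 5-cluster recovery.
These sizes were chosen as the smallest at which the binomial/oracle
tolerances in the tests are meaningful.

# Known limitations

* The 102-bp window is local by construction; long-range chromatin
  contacts between CpGs and binding sites are out of scope.
* The exact-p scanner uses an order-0 background; FIMO-style higher-order
  Markov backgrounds are not implemented (the uniform default is the
  recorded stand-in, and a region-estimated zero-order background is the
  sensitivity knob).
* Enrichment treats regions as exchangeable; residual spatial correlation
  between nearby (non-overlapping) regions is ignored.
* The genome build behind user-supplied coordinates is caller-supplied
  metadata; the package never guesses it.

# A minimal worked run

```{r example, eval = FALSE}
cfg <- pipelineConfig(
    simulate = simulationConfig(seed = 1,
                                n_chromosomes = 1, chrom_length = 2e5,
                                n_samples = 120, n_cpgs = 1000,
                                n_motifs_decoy = 10,
                                n_causal_survival_cpgs = 100),
    out_dir = "run1")
res <- runPipeline(cfg)
head(res$analyses$pro_haz$enrichment)
res$network
```
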