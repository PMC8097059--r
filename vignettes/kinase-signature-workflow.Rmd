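---
title: "From differential phosphoproteomes to kinase signatures and drug synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From differential phosphoproteomes to kinase signatures and drug synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinasesig)
```

`kinasesig` implements the analysis chain used to find shared kinase
signatures of drug resistance from quantitative (phospho)proteomics:
per-sample normalization and completeness filtering; moderated
differential tests with three flavors of FDR control; volcano-style
prioritization of phosphosites corrected for protein-level changes and
filtered by functional scores; kinase-substrate enrichment analysis
(KSEA) over an expanded substrate network; aggregation of KSEA scores
across comparisons into a clustered kinase signature; gene-set
over-representation and up/down-signature connectivity queries; and
dose-response / Bliss-independence synergy analysis of candidate drug
combinations. A synthetic-data generator with complete ground truth
makes every stage testable without raw mass-spectrometry data.

## The statistical model

All quantitative inputs are log2 intensity matrices (features x
samples), with missing values allowed. Replicate noise is treated as
additive Gaussian on the log2 scale; all variances use the n - 1
denominator; thresholds are strict inequalities throughout.

### Moderated two-class statistic and permutation FDR

For a feature with case/control means and pooled two-sample standard
error `se`, the moderated statistic is

    d = (mean_case - mean_control) / (se + s0)

with the fudge factor `s0` (default 0.1, log2-intensity units) a fixed
additive constant. `s0` damps the otherwise explosive statistics of
low-variance features; with `s0 = 0`, `d` is the Student t statistic
exactly. Features with fewer than two observed values in either group
are left unscored.

The FDR of the two-class test is estimated by group-label permutation.
For a cutoff `c` on `|d|`,

    FDR(c) = mean over permutations of #{|d_perm| >= c} / #{|d_obs| >= c}

capped at 1, with the null-proportion factor fixed at pi0 = 1 (a
conservative choice). A feature's q value is the minimum `FDR(c)` over
all cutoffs that admit it, which makes q monotone non-increasing in
`|d|`; the significant set at target `q*` is the largest set with
estimated FDR below `q*`. When the design admits at most `B` distinct
relabelings (default `B = 250`) all of them are enumerated, which makes
the result deterministic and seed-independent; otherwise `B` relabelings
are sampled from the given seed.

Two numerical points about this estimator were settled by simulation
during development and are worth knowing:

* *Mean, not median.* Taking the median of the permuted exceedance
  counts (a variant sometimes described as conservative) is actually
  anti-conservative at the extreme tail: under a complete null the
  observed maximum exceeds the median of the permuted maxima about half
  the time, handing the top feature q = 0. With the mean rule, measured
  over 50 null simulations at five replicates per group, no more than a
  few runs in fifty make any call at `q* = 0.05`. The mean is also what
  the classical formulation of this test computes.
* *Small designs have an FDR floor.* With three samples per group there
  are only 20 distinct relabelings, two of which (the identity and its
  complement) reproduce the observed statistics; the estimated FDR can
  therefore never fall below 2/20 = 0.1. Such designs should use the
  parametric companion test below — this is also what the original
  analyses did at n = 3.

### Parametric companions

* `two_class_t_bh()`: the same moderated `d`, with a two-sided p value
  from the t distribution with `n1 + n2 - 2` degrees of freedom
  evaluated at `d` (exact for `s0 = 0`, slightly conservative
  otherwise), then Benjamini-Hochberg correction. Intended for
  three-replicate designs.
* `anova_oneway()`: the standard per-feature F test across all
  conditions with BH correction; all-constant features are excluded
  from the BH family. No moderation is applied: a "moderated ANOVA"
  has no standard definition, so the fudge factor is a two-class
  concept here.
* `one_sample_t()`: for designs where each sample is expressed as a
  log2 ratio against the reference arm's row median
  (`make_log2_ratios_vs_reference()`), `d = mean / (sd/sqrt(n) + s0)`
  with a t-tail p at n - 1 degrees of freedom. `s0` regularizes
  zero-variance features (ratios `[1,1,1,1]` give d = 10, not
  infinity).

### Volcano prioritization with proteome correction

Phosphosite regulation is called at a configured BH/permutation FDR
*and* an asymmetric fold-change threshold: three times the standard
deviation of all positive log2 fold-changes for upregulated sites, and
three times the SD of all negative ones for downregulated sites, both
computed over all scored sites before any FDR filtering. Degenerate
sides (SD zero, or fewer than two fold-changes) behave gracefully: a
zero SD lets every site on that side with a passing q through; a
missing side makes no calls and warns.

Because a phosphosite can change merely because its parent protein
changed, each selected site is checked against a volcano selection run
on the proteome with the same rules: sites whose protein is selected in
the same direction are flagged `proteome_regulated` (not
phospho-specific). Sites on proteins that were not quantified keep the
flag `FALSE` with provenance `"protein not testable"`. Finally,
`prioritize_functional()` keeps selected sites whose functional score
strictly exceeds 0.5; unscored sites are excluded with provenance.

### KSEA and the cross-comparison signature

For each comparison, every kinase with at least `min_substrates = 4`
matched substrate sites is scored as

    z = (mean_s - mean_p) * sqrt(m) / delta

where `mean_s` is the mean log2 fold-change of its `m` matched
substrates and `mean_p`, `delta` are the mean and SD of the fold-changes
of *all* quantified sites (not just network-mapped ones — the convention
of the reference KSEA implementation). Two-sided p values come from the
standard normal tail, with BH correction across scored kinases. The
statistic is invariant to shifting or positively rescaling all
fold-changes. Substrate networks combine curated edges (always kept)
with predicted edges kept when their prediction score is at least 3
(inclusive); sites annotated to several kinases contribute to each.

The signature across comparisons retains kinases significant
(`q < 0.05`) in at least 3 of 5 comparisons (both numbers
configurable); unscored kinase/comparison cells are missing and count as
non-significant, and kinases scored in too few comparisons are reported
in a provenance table rather than silently dropped. Retained rows are
clustered by seeded multi-start k-means (k = 3, Euclidean distance on z
profiles, best of 10 starts); missing z values are zero-imputed and
flagged, and cluster labels are canonicalized by descending cluster mean
z so label 1 is always the most activated cluster.

### Enrichment and connectivity

Over-representation uses the one-sided hypergeometric tail (enrichment
only — the direction of interest here) with sets intersected against
the quantified background before testing and BH correction across sets.
Ranked queries (`rank_and_select_top()`) order by fold-change or test
statistic with id-lexicographic tie-breaks, taking e.g. the top 100 per
cluster for transcription-factor target enrichment or 150 per side for
connectivity queries.

The connectivity score of an up/down query against a ranked reference
profile uses unweighted Kolmogorov-Smirnov running sums: each list's
enrichment score is the signed maximum deviation of a walk that steps up
1/n at query hits and down 1/(N - n) elsewhere; the combined score is
`(ES_up - ES_down)/2` when the two have opposite signs and 0 otherwise,
so scores live in [-1, 1], positive means the reference resembles the
query signature, and swapping the lists negates the score. This is a
local stand-in for service-side connectivity scoring: comparable in sign
and rank, not in magnitude, to permutation-normalized scores reported by
online tools.

### Dose-response and Bliss synergy

`fit_4pl()` fits `y = bottom + (top - bottom)/(1 + (dose/IC50)^hill)`
by unweighted least squares on log10 dose (Levenberg-Marquardt,
multi-start from data quantiles, hill slope unconstrained in sign,
log-IC50 bounded within 10^4-fold of the dose range). At least four
distinct doses are required; a response range under `min_range`
(default 0.05, surviving-fraction units) is rejected as carrying no dose
information. Noiseless curves are recovered to machine-level accuracy,
and IC50s are compared between arms on the log scale
(`compare_ic50()`).

The Bliss independence index for surviving fractions is

    index = S_A * S_B - S_AB

so positive values mean synergy (the combination kills more than the
independence expectation), negative antagonism, and zero additivity.
The defining inequality — synergy when `S_AB < S_A * S_B` — fixes this
sign convention unambiguously, and the additive zero is
convention-independent. Surviving fractions are expected normalized to
the vehicle control; values slightly above 1 (assay noise) are tolerated
up to 1.2.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws a per-protein baseline (log2 intensity
N(25, 2) by default), plants differential proteins (default 5% of
proteins, |log2 FC| uniform on [0.5, 2], random sign — conventions, not
estimates from real data), attaches phosphosites to proteins with fixed
per-site offsets, and adds kinase-activity shifts: each planted kinase
shifts its m substrate sites by delta log2 units in the case conditions.
A configurable fraction of sites is "protein-driven" (the site inherits
its differential parent protein's fold-change — exactly the confound the
proteome-correction stage exists to flag). Replicate noise is Gaussian
on log2 (default SD 0.3), missingness is missing-at-random (default 5%),
predicted network edges carry scores uniform on [0, 10] so the
threshold-3 expansion genuinely bites, functional scores are uniform on
[0, 1] over 80% of sites, and one gene set is enriched for the planted
upregulated proteins. Planted-kinase edges are written as curated so the
planted signal survives network expansion. All draws derive from a
single seed consumed in a fixed order, so identical (config, seed) pairs
are bit-identical.

Deliberately not emulated: peptide-level quantification and razor
peptide ambiguity, isobaric-label ratio compression, intensity-dependent
(MNAR) missingness (available as a config option but off by default,
since the original data do not characterize their missingness),
correlated noise across sites of one protein beyond the shared baseline,
and multiply-phosphorylated peptides (each row is one site). Passing
tests on this generator therefore demonstrate the *statistical
machinery* — calibration under the null, recovery of planted effects,
correctness against oracles — not robustness to every artifact of real
MS data.

`generate_dose_response()` produces replicate plates from true 4PL
curves and combination surfaces `S_A * S_B - epsilon + noise`, with
`epsilon` the planted Bliss interaction; responses are deliberately not
clamped so the noiseless interaction is recovered exactly.

## The shipped example design

`example_run_config()` encodes a five-comparison resistance study over
one synthetic dataset: a resistant vs sensitive comparison with nine
samples per group analyzed by permutation SAM; persister vs parental and
persister vs short-term-treated comparisons at three replicates analyzed
by the moderated t + BH test (the permutation floor at n = 3 is the
reason); and two treated-vs-control comparisons with five animals per
arm analyzed by the one-sample test on ratios against the control arm's
median. One kinase ("KIN_A", delta = 1.2 log2 units, 16 substrates) is
planted active in every case condition and should be retained by the
signature stage — the end-to-end test asserts exactly that. Note that at
three replicates and BH FDR 0.01, only multi-fold effects are callable
per feature; kinase inference does not suffer because KSEA consumes
fold-changes, not per-site significance calls.

```{r, eval = FALSE}
res <- run_pipeline(example_run_config(seed = 1), output_dir = "run1")
res$report$signature_kinases
res$clusters
```

## Numerical choices and edge cases

* Processing order is completeness filter, then median centering —
  centering medians are computed on observed values, so the order only
  matters through which rows contribute; fixing it makes reruns
  reproducible.
* "Scaled per replicate" display heatmaps use per-sample median
  centering followed by row z-scaling; tests always run on centered,
  *not* row-scaled, values.
* PCA uses complete rows only (the exclusion is reported); component
  signs are fixed by making each component's largest-magnitude loading
  positive. Hierarchical clustering uses Canberra distance for rows,
  1 - Pearson correlation for columns, and average linkage (the linkage
  is a choice; the metrics are the workflow's convention).
* Ties everywhere are broken id-lexicographically (rankings, top-N
  selection), making outputs invariant to row order.
* The k-means within-cluster optimum is checked against exhaustive
  partition enumeration on small instances in the test suite.
* An enrichment FDR of exactly 0 is a domain error for the heatmap
  z-normalization (`-log10` undefined); callers floor at the smallest
  representable value.

## Problem sizes and runtime

The test suite and acceptance checks run at deliberately small scales:
null-calibration and planted-kinase recovery use 50 simulations of
150-200 proteins / up to 400 sites with exhaustive or 250-permutation
FDR; the end-to-end run uses 400 proteins, 700 sites, 20 kinases and
five comparisons. The full default example (1000 proteins, 1600 sites,
40 kinases) completes in a few seconds on one core; scaling to
proteome-wide matrices (5000+ proteins, 8000+ sites) stays within
minutes because every per-feature computation is vectorized across
features.

## Known limitations

* The permutation FDR is a plug-in estimate; for very small significant
  sets its realized false-discovery proportion is noisy even when the
  mean is controlled.
* KSEA treats substrate sites as exchangeable and independent given the
  global fold-change distribution; shared-protein correlation between
  substrates is ignored, as in the reference implementation.
* The connectivity score is unweighted (classic KS walk), not the
  rank-weighted variant, and is not normalized against a permutation
  null.
* The 4PL fit is unweighted; strongly heteroscedastic viability data
  may warrant weighting that is not provided.
* No batch or plex correction: single-batch data are assumed.
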