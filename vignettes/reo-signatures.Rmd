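---
title: "Qualitative gene-pair signatures from relative expression orderings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative gene-pair signatures from relative expression orderings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reosig)
```

## The method

Quantitative expression signatures travel poorly between laboratories: the
measured level of a gene depends on platform, batch and normalization, so a
cutoff fitted on one cohort rarely transfers to another. The relative
expression ordering (REO) of a gene pair — whether, **within one sample**,
gene *i* is expressed above or below gene *j* — is unchanged by any strictly
monotone transformation of that sample's values, and therefore by scaling,
shifting, log-transformation and most batch or normalization effects. A
classifier built only on REOs can be applied to a single sample from any
laboratory with no reference cohort and no renormalization.

`reosig` implements the full discovery-to-application path for such
signatures in a two-class (case/control) design:

1. **Stable-pair mining.** For every canonical gene pair (IDs in
   lexicographic order) and each class separately, count the samples with
   `E_i > E_j` and with `E_i < E_j`. A pair is *highly stable* in a class
   when one direction holds in at least a threshold fraction (default
   `0.85`, inclusive) of the class's evaluable samples.
2. **Reversal.** Pairs stable in *both* classes but with *opposite*
   directions are reversed pairs — the only pairs that carry class
   information at the single-sample level. Pairs stable with the same
   direction in both classes are reported separately; they are biologically
   common (genes of very different baseline abundance) and diagnostically
   useless.
3. **Gene-set restriction.** Discovery is usually restricted to a
   biologically motivated gene set (for instance T-cell-related genes in an
   autoimmune setting); `discover_signature()` takes any gene-set
   collection in GMT form.
4. **Winner-takes-all classification.** Each signature pair is oriented as
   `(low_in_case, high_in_case)`. A sample votes "case" on a pair exactly
   when `E(low_in_case) < E(high_in_case)` (strict); the majority of votes
   labels the sample. With the single-pair signatures that discovery
   typically yields, this is precisely the published rule "call case iff
   the pair is in its case orientation".

A continuous companion score, `log2(E(high_in_case)/E(low_in_case))`,
supports ROC analysis. Unlike the vote, the score is **not**
monotone-invariant; it is never used for labelling.

### Tie and missing-value policy

The binary encoding of a pair admits two more states: ties and missingness.

* A tie (`E_i == E_j`) counts toward **neither** direction but **stays in
  the evaluable denominator** during mining, so ties erode stability rather
  than inflating it — the conservative reading of a strict binary relation.
* A sample missing either gene leaves the denominator entirely. A pair must
  be evaluable in at least `min_evaluable` samples (default: half the class
  size, rounded up) to be reported at all, which prevents pairs supported
  by a handful of observations from passing a fractional threshold.
* In classification, a tied pair votes for control (the case rule demands
  strict inequality), and an exact vote tie labels control for the same
  reason. A sample in which **no** pair has both genes observed is
  `"unclassifiable"` — a distinct outcome that the evaluation module counts
  as an error against the sample's true class, keeping `n` fixed.

### Thresholds and parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `threshold` | 0.85 | fraction (0.5, 1] | minimum per-class ordering consistency; inclusive comparison; values at or below 0.5 are rejected because the majority direction is then ambiguous |
| `min_evaluable` | ceil(n/2) | samples | support guard for pairs with missing data |
| `alpha` | 0.25 | exponent | ssGSEA rank weighting |
| `fdr_cutoff` | 0.01 | fraction | BH significance for differential expression |
| `rho_cutoff` | 0.6 | \|rho\| | strict absolute-correlation threshold for network edges |
| `network_fdr_cutoff` | 0.01 | fraction | BH cutoff for the co-expression screen, one family over all seed-by-candidate tests |

## Downstream characterization

* **Differential expression** (`wilcoxon_deg`): two-sided Wilcoxon rank-sum
  per gene, BH adjustment over all tested genes, significance at
  `fdr < 0.01`. Exact p-values are used when both classes have at most 25
  samples and the data are tie-free; otherwise the tie-corrected normal
  approximation with continuity correction. Direction comes from class
  medians; equal medians give direction `"none"`, which can never enter the
  cross-cohort consistent-DEG intersection (`consistent_degs`), since
  consistency requires a sign.
* **ssGSEA** (`ssgsea_scores`): per sample, genes are ranked by expression
  and each set is scored by the weighted Kolmogorov–Smirnov-like running
  sum — the cumulative `rank^alpha`-weighted in-set distribution minus the
  uniform out-of-set distribution, summed over the whole ranking. `alpha =
  0.25` and the optional global range normalization follow the method's
  customary defaults, since scores are only interpreted relatively; the
  per-set z-score mode is what relative-infiltration heat maps display.
  Within-sample rank ties are weighted by their average rank and walked in
  gene-ID order, so scores are deterministic. Only within-sample ranks
  enter, so scores are monotone-invariant.
* **One-sided class comparisons** (`compare_feature_by_class`): Wilcoxon
  rank-sum in a stated direction, for immune scores and other per-sample
  features.
* **Co-expression networks** (`coexpression_network`): Spearman correlation
  of every (seed gene, candidate gene) pair, one BH family across the whole
  screen, edges requiring both `|rho| > 0.6` (strict) and `fdr < 0.01`.
* **Over-representation** (`hypergeom_enrich`): upper-tail hypergeometric
  p-value `P(X >= overlap)` for each user-supplied set against an explicit
  universe, BH across sets. No ontology database is bundled; sets come from
  GMT files.

### Which correlations are batch-invariant?

Classical Spearman correlation between two genes is computed **across**
samples, so a per-sample monotone distortion (which preserves every
within-sample ordering) can still destroy or fabricate it: a sample-level
scale factor shared by all genes induces strong spurious positive
correlation everywhere. We verified this directly on synthetic cohorts —
under the generator's default distortion, unrelated genes reach
`|rho| ~ 0.7` classically.

`coexpression_network()` therefore first replaces each sample by its
within-sample ranks over all genes of the matrix and correlates those
across samples (`rank_within_sample = TRUE`, the default). This makes the
network exactly as batch-robust as the signature itself, at the price of
mild attenuation of strong correlations (in the generator's regime, a
module planted at log-scale correlation 0.8 screens at about 0.7). Pass
`rank_within_sample = FALSE` for the classical estimate when samples are
known to be comparably normalized. `gene_cell_correlations()` defaults to
the classical mode (`FALSE`), matching the customary
expression-versus-infiltration heat map; the same switch is available
there.

## The synthetic cohort generator

No public expression data ship with the package; every statistical claim
is exercised on cohorts from `generate_cohort()`, whose configuration
(`cohort_config()`) states the generating conditions explicitly:

* **Baseline**: each gene is log-normal with its own mean drawn uniformly
  on the log scale between `log(50)` and `log(5000)` and common log-sd
  `noise_sd = 0.5` — positive, right-skewed intensities with realistic
  abundance spread, so that (as in real transcriptomes) millions of gene
  pairs are trivially stable in both classes and only planted reversals
  survive the intersection.
* **Planted reversed pairs**: per sample, a Bernoulli flag at the pair's
  per-class stability decides whether the intended ordering (`E_i > E_j`
  in controls, `E_i < E_j` in cases) is enforced, by swapping the two
  genes' values when needed. This controls the ordering frequency exactly,
  independently of the marginals. Both members of a planted pair share one
  baseline log-mean: enforcing an ordering by swapping makes the two
  marginals class-dependent, and if a third gene's abundance sat between
  two very different pair means, that gene would form *genuine* collateral
  reversed pairs with the planted genes. With a shared mean, the ordering
  frequency of either pair gene against any third gene is bounded near 2/3
  in both classes — safely below the 0.85 threshold — and the pair's
  within-sample fold change stays near 1, which is exactly the regime
  where qualitative reversal carries information a quantitative cutoff
  would miss.
* **Same-direction decoy pairs** (`planted_stable_pairs_per_class`) are
  planted by the same mechanism at stability 0.95 in *both* classes: they
  must survive mining but never reversal.
* **Differential expression**: `n_de_genes` genes (drawn from genes not
  used by any planted pair, so a DE shift can never contradict a planted
  direction — the configuration validator rejects structures that would
  require it) receive a `de_log_fold_change` log2 shift in cases, signs
  alternating up/down.
* **Correlated modules**: equicorrelated on the log scale through a shared
  per-sample latent factor at `module_correlation`.
* **Monotone distortion**: each sample is independently transformed by
  `x -> a x^c + b` with `a ~ U(0.5, 2)`, `c ~ U(0.8, 1.25)`,
  `b ~ U(0, 5)` (raised if needed to keep values positive) — a stand-in
  for platform, batch and normalization differences. It is applied *after*
  planting, so it cannot disturb any planted ordering, and the defaults are
  deliberately aggressive so that anything not rank-based visibly breaks.
* **Missingness** is applied last, completely at random at `missing_rate`.

One integer seed drives a single RNG stream; the same configuration is
bit-reproducible and the caller's RNG state is untouched.

**What the generator does not emulate**: probe-level structure,
platform-specific noise shapes, realistic immune-cell mixing proportions,
label noise, and confounding between class and batch. Passing tests
therefore demonstrate the pipeline's contracts (exactness of counting,
invariance, calibration, recovery under controlled signal), not clinical
performance on real cohorts.

## Evaluation choices

* Sensitivity, specificity, accuracy, PPV and NPV come from the exact
  integer confusion matrix; unclassifiable samples are counted as errors.
* AUC is the Mann–Whitney probability with ties at 1/2; the 95% CI uses
  DeLong's tie-corrected asymptotic method (via pROC). For a label-only
  predictor the AUC equals `(sensitivity + specificity)/2` identically,
  and both the binary and the score-based AUC are reported side by side,
  since a published single-pair rule admits either reading.
* The ROC direction is fixed (higher score favours case), never
  auto-selected, so an anti-predictive score is reported below 0.5 rather
  than silently flipped.
* `fold_change_summary()` reports per-class min/median/max of the ratio
  `E(low_in_case)/E(high_in_case)` — the control-oriented ratio that sits
  above 1 in most controls and below 1 in most cases for a reversed pair.

## Numerical and degenerate-input policies

* Threshold comparisons are inclusive (`>= threshold`, `fdr < cutoff`,
  `|rho| > cutoff` strict), matching their conventional statements.
* Constant features and constant genes are retained with `p = 1` (with a
  warning where a user calls them directly).
* Probe collapsing averages the surviving probes' stored values (no
  unlogging), excludes missing values from each mean, drops probes mapping
  to zero or multiple genes, and orders output genes lexicographically so
  results are deterministic.
* Gene IDs are opaque, case-sensitive strings; no alias resolution is ever
  attempted.
* Expression values are used exactly as stored: the package never
  normalizes or log-transforms input matrices, because every labelling
  statistic is rank-based within samples.

## Problem sizes in the test suite

The shipped tests validate the miner against a brute-force triple-loop
oracle on 200 random matrices (up to 12 genes by 10 samples, with ties and
missing values), sweep signature recovery over 20 seeds of the reference
scenario (200 genes, 100+100 samples, one pair planted at 0.95/0.95),
calibrate the null on a 2,000-gene 50+50 cohort with 1,000-replicate
p-value uniformity checks, and verify bit-identity of all rank-based
outputs under random per-sample distortions. The scalability contract —
exhaustive mining of all pairs of 2,000 genes across 200 samples on one
CPU in under a minute — is met by accumulating pairwise comparison counts
with vectorized outer products per sample.

## Known limitations

* Multi-pair signatures generalize the published single-pair rule by
  majority vote; the generalization is flagged in the signature's
  provenance and has no external validation here.
* The DeLong CI is asymptotic; for very small cohorts a resampling CI
  would be preferable but is out of scope.
* The score used for ROC analysis requires strictly positive expression
  for its fold-change form; non-positive values trigger a flagged
  difference fallback.
* `consistent_degs` intersects full significant lists; when two cohorts'
  test families differ in size, interpretation of the overlap is the
  user's responsibility.

## A minimal end-to-end run

```{r example}
co <- generate_cohort(cohort_config(rng_seed = 1))
co

sig <- discover_signature(co$matrix, co$labels)
sig

heldout <- generate_cohort(cohort_config(rng_seed = 2))
pred <- classify_samples(heldout$matrix, sig)
confusion_metrics(pred$label, heldout$labels, positive_label = "case")
```
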