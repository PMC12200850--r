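# reosig — rank-based qualitative gene-pair signatures

`reosig` discovers and applies **qualitative transcriptomic signatures**
built from within-sample relative expression orderings (REO) of gene
pairs, for two-class diagnostic problems (case vs control). Its audience
is computational biologists who need a classifier that works on **one
sample at a time**, across platforms and laboratories, without reference
cohorts, cutoff re-fitting or normalization.

## The idea

For genes *i*, *j* and a single sample, the REO is the binary relation
E<sub>i</sub> &gt; E<sub>j</sub> or E<sub>i</sub> &lt; E<sub>j</sub>. It is
invariant to any strictly monotone transformation of that sample's values,
hence to scaling, log-transformation and most batch effects. The pipeline:

1. **Mine stable pairs** per class: a pair is *highly stable* when one
   direction holds in ≥ 85% (configurable, inclusive) of the class's
   evaluable samples — ties stay in the denominator, missing values leave
   it.
2. **Intersect** the two classes: pairs stable in both but with
   **opposite** directions ("reversed pairs") carry single-sample class
   information.
3. **Restrict** candidates to a biologically motivated gene set (GMT).
4. **Classify** each sample by winner-takes-all vote: orienting each pair
   as (low-in-case, high-in-case), a sample votes "case" on a pair iff
   E(low) &lt; E(high) strictly; the majority labels the sample.

Downstream characterization mirrors what such studies report: ssGSEA
immune-infiltration scores with one-sided Wilcoxon class comparisons,
Wilcoxon/Benjamini–Hochberg differential expression with cross-cohort
consistency, Spearman co-expression networks around seed genes
(|rho| &gt; 0.6, FDR &lt; 0.01), and hypergeometric over-representation
against user-supplied gene sets. A synthetic two-class cohort generator
with planted reversed pairs, differential expression, correlated modules,
per-sample monotone distortion and missingness makes the whole pipeline
testable without any downloads.

## Worked example

Discover a signature on a synthetic training cohort (200 genes, 100+100
samples, one reversed pair planted at 95% per-class stability), then
validate it on an independent cohort from the same conditions:

```r
library(reosig)

co  <- generate_cohort(cohort_config(rng_seed = 1))
sig <- discover_signature(co$matrix, co$labels)
sig
#> REO qualitative signature: 1 pair(s), case = 'case', control = 'control'
#>   case rule: E[g0001] < E[g0002]

heldout <- generate_cohort(cohort_config(rng_seed = 2))
pred    <- classify_samples(heldout$matrix, sig)
confusion_metrics(pred$label, heldout$labels, positive_label = "case")
#> Confusion matrix (n = 200): TP 95  FN 5  TN 95  FP 5
#>   sensitivity 95.00%  specificity 95.00%  accuracy 95.00%
#>   PPV 95.00%  NPV 95.00%  binary AUC 95.00%

roc_auc(pred$score, heldout$labels, "case")$auc
#> [1] 0.9503
```

Discovery found exactly the planted pair, and held-out sensitivity and
specificity track the planted 95% stability: a sample is mislabelled
precisely when its planted ordering is the non-conforming one. The
fold-change summary of the pair shows why a quantitative rule could not do
this: the within-sample ratio spans 0.09–3.35 in cases and 0.64–7.30 in
controls (medians 0.64 and 1.48) — overlapping ranges whose *ordering*,
not magnitude, separates the classes.

The same flow is scriptable from a shell via the thin CLI:

```sh
Rscript inst/cli/reosig.R simulate --seed 1 --out-dir cohort/
Rscript inst/cli/reosig.R discover --matrix cohort/matrix.tsv \
    --labels cohort/labels.tsv --out-dir disc/
Rscript inst/cli/reosig.R validate --signature disc/signature.json \
    --matrix cohort/matrix.tsv --labels cohort/labels.tsv --out-dir val/
```

Real data enter through `read_matrix()` (plain TSV or GEO series-matrix
dialect), `collapse_probes()` (averages multi-probe genes, drops unmapped
and multi-mapping probes) and `read_gmt()`; see the vignette
(`vignettes/reo-signatures.Rmd`) for the full methods account, including
the tie/missing-value policies and which statistics are batch-invariant.

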