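# connfp

Functional connectome graph metrics and phenotype prediction in R.

`connfp` is for researchers who ask whether resting-state brain network
organisation differs between groups and tracks individual cognitive style.
Starting from per-subject ROI time series (rows = timepoints, columns =
labeled regions), it implements the full graph-theoretical pipeline used in
cross-cultural connectome studies:

1. **Network construction** — Pearson correlation matrices, negative
   correlations zeroed, binarization over a sparsity range
   (0.10 ≤ S ≤ 0.30 by default): at sparsity *S* the
   round(S·R(R−1)/2) strongest positive pairs become edges, so every
   subject's graph has the same density.
2. **Nodal metrics** — degree *K<sub>i</sub>* and nodal global efficiency
   *E<sub>i</sub>* = (1/(N−1)) Σ<sub>j≠i</sub> 1/min L<sub>ij</sub>
   (unreachable nodes contribute 0), each integrated over the sparsity
   grid as an area under the curve (AUC), one number per node per metric.
3. **Group screening** — per-node MANCOVA (Pillai's trace) plus ANCOVAs of
   each metric, adjusting for age, sex, head motion and site, with
   Benjamini–Hochberg FDR within each test family; "consistent" nodes are
   significant in all three.
4. **Phenotype association** — covariate-adjusted partial correlations of
   nodal metrics (and seed-node functional connectivity) with an
   analytic–holistic style score, FDR-corrected.
5. **Prediction** — sign-unified metrics averaged into two composites
   (T<sub>deg</sub>, T<sub>eg</sub>), evaluated by 10-fold cross-validated
   regression (score) and stratified logistic classification (group), each
   calibrated against a permutation null whose 95% bound is read at sorted
   positions 25/975 of 1000; plus a connectome-based predictive modeling
   (CPM) variant with within-fold feature selection and 10/10 stability
   selection.

Because suitable multi-site data cannot be redistributed, the package ships
a **synthetic cohort generator** with planted group effects (multiplicative
edge-weight changes at designated nodes) and a style score coupled to true
generating-network metrics — every stage has recovery and type-I-error
tests with known ground truth. See the methods vignette
(`vignettes/connectome-fingerprint-methods.Rmd`) for the model and the
documented operating points.

## Worked example

```r
library(connfp)

network <- make_ground_truth(20, 0.3, effect_nodes = c(1, 3, 7, 15),
                             effect_delta = 1.2, seed = 8)
spec <- cohort_spec(n_per_group = 100,
                    phenotype_weights = default_phenotype_weights())
cohort <- generate_cohort(spec, network, seed = 42)

config <- run_config(n_perm = 200, seed = 7)
res <- run_full_pipeline(cohort, config)
```

Printed summaries from this run:

```
consistent nodes: ROI_01 ROI_07 ROI_15
selected metrics: degree:ROI_07 efficiency:ROI_07
intrasample r = 0.271 (perm 95% upper 0.161, p = 0.005)
cross-sample accuracy = 79.5% (null upper 57.0%)
CPM r = 0.136 (p = 0.114), stable metrics: 2
```

Three of the four planted effect nodes survive the triple-FDR screen at
this modest sample size (n = 100 per group), the style score is predicted
from the two composites well above its permutation null (r = 0.27 against
an upper bound of 0.16), and the composites classify the two groups at ~80%
accuracy where shuffled labels stay near 50%. The CPM variant, which
re-selects features inside each training fold, is more conservative here —
its estimate is smaller and not significant at this n, illustrating the
cost of leakage-free selection.

`run_full_pipeline(..., out_dir = "out")` additionally writes
`metrics.tsv`, `node_stats.tsv`, `consistent_nodes.json`,
`associations.tsv`, per-seed `fc_associations/<roi>.tsv`,
`predictions.tsv`, `null_distribution.tsv`, `prediction_report.json` and a
`manifest.json` that records the configuration hash, seeds and stage notes
so a run can be reproduced exactly.

A thin command-line wrapper is installed with the package
(`inst/scripts/connfp`):

```sh
Rscript inst/scripts/connfp simulate --out cohort_dir --seed 5
Rscript inst/scripts/connfp run-all --in cohort_dir --out results_dir --seed 5
```

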