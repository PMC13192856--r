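# placentaFcR

Maternal IgG crosses the placenta through Fc-receptor-mediated transport,
and transfer efficiency varies across the population with IgG subclass, Fc
glycosylation, placental Fc receptor expression, and maternal clinical
state. `placentaFcR` implements the complete quantitative workflow for
dissecting that variation from multimodal cohort data — multiplex
immunohistochemistry (mIHC) image-quantification tables, Luminex isotyping
standard curves, subclass-specific Fc glycoform relative abundances, and
clinical covariates — for researchers in reproductive and systems
immunology.

## What the package computes

- **Image quantification** (`build_expression_profile`,
  `coexpression_partition`, `receptor_ratio`): cell-type-specific receptor
  expression frequency from HALO-style area tables, e.g. for
  syncytiotrophoblasts (STBs)
  `freq = CGA⁺R⁺ area / CGA⁺ area × 100`, averaged per patient over images;
  Hofbauer cells use cell densities instead of areas. Pairwise receptor
  colocalization is partitioned by inclusion–exclusion into
  R1⁺R2⁺ / R1⁺R2⁻ / R1⁻R2⁺ / R1⁻R2⁻ fractions that close to 100%.
- **Serology** (`fit_5pl`, `invert_5pl`, `cm_ratio`, `summary_glycans`,
  `paired_enrichment`): five-parameter logistic standard curves
  `y = d + (a − d)/(1 + (x/c)^b)^g` with closed-form inversion and dilution
  scaling; log10 cord:maternal transfer ratios; glycan motif summaries
  (fucosylation, bisection, G0/G1/G2 galactosylation, sialylation) over a
  registry of 21 glycoform codes; Wilcoxon signed-rank dyad contrasts.
- **Clinical clustering** (`fit_latent_model`, `project_cohort`,
  `assign_clusters`): log/center/scale preprocessing, PCA, k-means on
  PC1–PC2 with the within-cluster-sum-of-squares (WSS) elbow choosing K,
  and projection of a second cohort into the first cohort's latent space
  using the frozen preprocessing parameters and loadings, with
  nearest-centroid assignment.
- **PLS engine** (`fit_pls`, `fit_plsda`, `orthogonalize`, `vip_scores`,
  `cross_validate`, `permutation_test`, `q2_score`): NIPALS PLSR/PLSDA;
  orthogonalization rotating the fitted score space so LV1 carries the
  outcome variation (predictions exactly invariant); VIP scores with
  `mean(VIP²) = 1`; repeated stratified 5-fold cross-validation; permutation
  significance via a two-sided two-sample t-test against label-shuffled
  models; cross-validated `Q² = 1 − PRESS/TSS`.
- **Stability selection** (`stability_select`, `cocorrelate_network`):
  repeated subsampled LASSO (glmnet, penalty by inner CV), keeping features
  selected in >90% of iterations, plus the Pearson co-correlate network
  (p < 0.05) around the stable set.
- **Partial-correlation networks** (`partial_corr`, `build_pcn`,
  `compare_marginal_partial`): residual-based partial Pearson correlations
  controlling for gestational age and maternal covariates, trimmed at
  |r| > 0.15 and p < 0.1, with per-edge complete-case n and GraphML export.
- **Gestational trends** (`fit_cubic`, `peak_location`, `fit_exponential`):
  3rd-order polynomial receptor trajectories with within-range peak
  estimation, and log-linear exponential regression of cord IgG
  accumulation.
- **Synthetic cohorts** (`sim_config`, `generate_bundle`): every input table
  family with planted ground truth — clinical clusters, cluster-dependent
  transfer offsets, cord-vs-maternal glycan shifts, cubic receptor
  trajectories, and receptor–transfer partial correlations — so the entire
  workflow is verifiable without patient data.

## Worked example

The numbered drivers under `analysis/` run the workflow over two synthetic
cohorts (90 patients each, three planted clinical clusters at 4-sd
separation, 14 glycan dyads):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/04_cluster.R
Rscript analysis/05_pls_models.R
```

prints, among other things:

```
PC1+PC2 capture 55% of clinical variance; WSS elbow selects K = 3
cluster recovery vs planted labels: ARI = 0.934
median IgG1 log10 C:M by fitted cluster:
     1      2      3
-0.260 -0.008  0.312
Kruskal-Wallis across clusters: p = 1.9e-15
trimester PLSDA: mean CV accuracy 88.7% over 200 rounds, permutation p = 6.8e-196
gestational-age OPLSR: Q2 = 0.85; cohort-2 prediction Pearson R = 0.90, slope = 0.92
```

The WSS elbow recovers the three planted clusters (adjusted Rand index
0.93), the fitted clusters reproduce the planted transfer gradient (one
cluster transfers IgG ~2× more efficiently than another,
log10 C:M +0.31 vs −0.26), and receptor expression predicts trimester and
gestational age with high cross-validated accuracy. `analysis/06` recovers
the planted maternal/cord glycoform contrast by LASSO stability selection,
`analysis/07` shows the receptor–transfer correlations that appear only
after controlling for gestational age, and `analysis/08` locates the
planted 20-week receptor expression peaks.

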