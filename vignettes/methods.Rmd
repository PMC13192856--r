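---
title: "Models and methods for multimodal placental antibody-transfer analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multimodal placental antibody-transfer analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentaFcR)
```

Placental IgG transfer is shaped jointly by maternal Fc characteristics
(subclass, glycosylation), placental Fc receptor expression in the barrier
cell types, gestational timing, and the maternal clinical state. This
vignette documents the models implemented in `placentaFcR`, the
assumptions behind them, the tunable parameters with their defaults, what
the synthetic cohort generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## Image quantification

Cell-type-specific receptor expression is quantified from per-image
area-quantification tables. For area-based cell types (STBs via the CGA
marker, endothelial cells via CD34) the per-image frequency is the
colocalized marker∩receptor area divided by marker area, times 100;
Hofbauer cells are enumerated as CD163⁺ cell densities (cells/mm²) and the
frequency is the receptor-positive density as a percentage of total HBC
density. The per-patient value is the **unweighted mean over the patient's
images** — not an area-weighted mean — because each image is treated as an
equally informative biopsy of the tissue. Images with zero marker area (or
zero HBC density) are skipped for that metric; a patient with no usable
image is excluded with a warning rather than silently dropped.

Pairwise colocalization partitions the marker-positive area by
inclusion–exclusion into the four ±/± compartments; the implementation
checks `pair ≤ each single intersection` to 1e-9 and the partition closes
to 100% by construction. Receptor-relative expression (e.g.
FcγRIIIa⁺/FcRn⁺ in third-trimester STBs) is reported both as the ratio of
group means and the mean of per-patient ratios, because the two summaries
differ under between-patient heterogeneity and either may be wanted;
patients with a zero denominator frequency are excluded and counted.

Trimester boundaries are T1 < 14 weeks, 14 ≤ T2 < 28, T3 ≥ 28, with
boundary values assigned to the later trimester.

## Serology and glycoforms

Isotyping standard curves use the five-parameter logistic
$y = d + (a-d)\,(1+(x/c)^b)^{-g}$ fit by Levenberg–Marquardt least squares.
The $(b, g)$ pair is weakly identified from crude starting values, so the
fit multi-starts over a small $(b, g)$ grid and keeps the lowest-SSR
solution; tolerances are tightened (`ftol = ptol = 1e-15`) so noiseless
standards are reproduced to machine precision. Inversion is closed-form
and refuses to extrapolate: responses outside the open interval between
the asymptotes are flagged, not inverted. Reported concentrations are
multiplied by the sample dilution factor (assays of this kind run plasma
at approximately 1:15,000).

Transfer is summarized per dyad and feature as $\log_{10}(\text{cord} /
\text{maternal})$: zero means equal concentrations and positive values
efficient transfer. Non-positive or missing values exclude the
dyad-feature pair with a warning, and the exclusion count is reported.

Glycoform tables use a registry of 21 shorthand codes (NG plus the 20 most
common Fc glycoforms, parsed by the grammar `G[0-2][F][N][S]`). Summary
motifs (fucosylated, bisected, G0/G1/G2, sialylated) are sums of the
relative abundances of codes carrying the motif; a code with several
motifs contributes to each matching summary independently, and NG
contributes to none — motif summaries describe glycans, so the
non-glycosylated peptide is excluded from every motif. Paired
maternal-vs-cord contrasts use the two-sided Wilcoxon signed-rank test
with at least 5 complete dyads per feature; all-tie features report p = 1
with a flag. The covariate–glycan screen uses Spearman correlations with
the t-approximation and tie correction, masking pairs with fewer than 5
complete observations or a constant column.

## Clinical clustering and cross-cohort projection

Rows with incomplete observations are removed first. Positive continuous
covariates are log10-transformed; where zeros occur (EPDS can be 0) an
offset of **half the smallest positive observed value** of that feature is
added. Categorical covariates (ethnicity, fetal sex) are one-hot encoded
with the first level dropped (a full dummy set is collinear after
centering); all retained columns are z-scored and constant columns dropped
with a warning. The fitted transform is frozen and reapplied verbatim to
new data: a shared latent space requires a shared coordinate frame, so a
second cohort is scaled with the *training* cohort's offsets, centers and
scales, then multiplied by the training loadings.

PCA is computed by SVD of the centered matrix; k-means runs on PC1–PC2
with 50 random restarts keeping the best within-cluster sum of squares,
deterministic given the seed. K is chosen from the WSS curve for
k = 1..k_max as the **maximum second difference** — the sharpest bend —
which formalizes the usual visual elbow; when the best second difference
is under 20% of the total WSS drop the choice is flagged as a weak elbow.
New samples are assigned to the nearest centroid in Euclidean distance,
with ties broken toward the lowest cluster index.

## The PLS engine

PLSR and PLSDA use NIPALS with deflation; features are centered and
scaled (optionally log10-transformed first) and the outcome centered.
Class labels are dummy-coded one column per class and predicted by argmax
of the predicted dummy columns. NIPALS was chosen over SIMPLS for
transparency: every quantity (weights, scores, loadings) has an explicit
deflation-step meaning, and the full-component limit provably reproduces
least squares, which the tests assert.

**Orthogonalization.** Models are orthogonalized so that latent variable 1
carries the outcome-predictive variation. The implementation rotates the
fitted score space: the orthonormalized scores are rotated so their
leading direction(s) span the outcome-predictive subspace (the span of the
Y-loadings in score space) and the remaining components are exactly
uncorrelated with the outcome. Because a rotation re-expresses the same
fitted subspace, predictions are *identically* invariant, LV1's
correlation with the outcome equals the model's multiple correlation
(hence at least that of any unrotated component), and the construction
generalizes unchanged to multi-class outcomes — which a sequential
filtering formulation does not. Single-component models are returned
untouched with a notice.

**VIP.** $\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a (w_{aj}/\lVert
w_a\rVert)^2 / \sum_a \mathrm{SSY}_a}$ with $\mathrm{SSY}_a$ the outcome
variance explained by component $a$; the normalization gives
$\mathrm{mean}(\mathrm{VIP}^2) = 1$, so VIP > 1 is above-average influence.
After orthogonalization the orthogonal components have zero SSY and drop
out, as intended.

**Validation.** Cross-validation runs independent rounds of stratified
5-fold splitting (an 80:20 split per fold); the study design this
implements used 1,000 rounds, and the round count is a parameter.
Preprocessing is refit inside every training fold — the original
description does not state this, but refitting is the leakage-free choice
and is documented as a deliberate strengthening. Permutation significance
compares the true-label accuracy distribution against accuracies of
label-shuffled models (one CV evaluation per shuffled model, matching one
permuted model per round) with a two-sided two-sample t-test. This t-test
on accuracy distributions is anti-conservative relative to a proper
permutation p-value — distributions of CV accuracies are not independent
samples — and the tests treat its null behavior accordingly (calibration
is checked only at the ~10% level). $Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$
sums PRESS over held-out folds with TSS about each training fold's mean.

## Stability selection and co-correlate network

Each iteration subsamples 80% of samples without replacement (class
stratified), fits an L1-penalized logistic model with the penalty chosen
by inner 5-fold CV on that subsample (`lambda.min`; the one-standard-error
rule is available), and records the nonzero-coefficient features. Features
selected in more than 90% of iterations form the stable set; the default
is 1,000 iterations, scaled to 200 in the tests. The threshold is
exclusive and raising it can only shrink the set. Colinear structure is
then read off a Pearson co-correlate network: every (selected, other)
pair with two-sided p < 0.05 becomes an edge; nodes are tagged selected
vs co-correlate.

## Partial-correlation networks

Partial correlations are computed by the residual method: regress x and y
on an intercept plus the covariate block Z by least squares and correlate
the residuals; p-values use the t statistic with $n - 2 - |Z|$ degrees of
freedom. The precision-matrix formulation is algebraically identical and
serves as an independent oracle in the tests (agreement to 1e-10). The
default covariate set is gestational age, maternal age, gravidity,
pregravid BMI and EPDS. Networks keep edges with **|r| > 0.15** and
p < 0.1 — the absolute-value reading is required for negative edges to
appear at all — with complete-case analysis per pair (not listwise over
the table) to preserve the small matched subsets these analyses run on;
the per-edge n is recorded. No multiple-testing correction is applied
across edges, deliberately matching the descriptive use of these
networks; the calibration test verifies the null edge rate against a
brute-force simulation instead. The marginal-vs-partial comparison
reports both coefficients, the absolute change, and a sign-change flag,
the diagnostic for gestational age acting as a masking confounder.

## Gestational trends

Receptor trajectories are 3rd-order polynomials fit by OLS on
$[1, g, g^2, g^3]$ with pointwise 95% confidence bands from the
coefficient covariance. The reported peak is the argmax over the
*observed* GA range: the interior derivative root with negative second
derivative when one exists inside the range, else the better endpoint —
extrapolated maxima are never reported. The derivative roots use the
numerically stable quadratic formula because a near-zero cubic coefficient
(e.g. data that are really parabolic) makes the textbook formula
cancel catastrophically. Cord IgG accumulation is fit as log-linear OLS
$\ln c = \alpha + \beta g$ and back-transformed; this matches an
exponential-growth model with multiplicative noise, which concentration
data obey, and a nonlinear fit would weight large concentrations unduly.

## The synthetic cohort generator

The generator produces every input table family with planted ground truth
under one configuration (`sim_config`). Defaults encode the study
conditions the package is verified under: 3 clusters × 30 patients,
cluster separation 4 within-cluster standard deviations applied per
feature, 14 glycan dyads, gestational ages 9–41 weeks drawn from trimester
strata with weights 0.25/0.30/0.45 mirroring an unbalanced delivery-heavy
cohort, per-cluster log10 C:M offsets +0.3/0/−0.3, sialylated glycoforms
shifted toward the maternal side and agalactosylated toward cord (log-odds
0.3), cubic receptor trajectories with the barrier-cell receptors peaking
at 20 weeks, a patient-level trajectory deviation of 5 percentage points,
and a receptor–transfer coupling of 0.1 log10 units per standard deviation
of that deviation for STB-FcRn and EC-FcγRIIb. Where the emulated study
reports no effect size these defaults are calibration choices, chosen once
for realism, not facts about any cohort.

Distributional families are chosen for the constraints real data obey:
log-normal clinical covariates and concentrations (positivity), Dirichlet
compositions perturbed on log-odds and renormalized (the 100% simplex),
Gaussian measurement noise on areas clipped to `[0, parent area]`
(clipping, not rejection, keeps sample sizes fixed). EPDS is rounded to
non-negative integers and gravidity to positive integers; the planted
cluster offsets are placed on the continuous covariates because rounding
would blunt them. Ethnicity is generated fully cluster-linked for cluster
1, emulating the clinical profile the clustering is meant to find.
Zero-noise configurations round-trip exactly through the corresponding
estimators, and identical configurations produce byte-identical output
(all stage seeds derive from the root seed).

What the generator does **not** emulate: pixel-level images (it emits the
downstream quantification tables), LC-MS spectra (it emits relative
abundances), gestational accumulation of cord IgG (C:M offsets are
GA-independent, so the exponential-trend estimator is verified on its own
planted fixture), missingness patterns, batch effects, or real covariate
correlation structure beyond the planted clusters. Passing tests therefore
demonstrate estimator correctness under the planted mechanisms, not
robustness to every artifact of real cohort data.

## Problem sizes and determinism

The verification suite runs the study's designs scaled for a desk machine:
200 rounds of 5-fold CV and 200 permuted models (the full design uses
1,000), 200 LASSO iterations, cohorts of 90, dyad sets of 14, and planted
two-class fixtures of n = 40 with 4 informative of 30 features at a 2-sd
shift. Every stochastic stage takes an explicit seed, and the pipeline
derives per-stage seeds from a single root so a run is reproducible from
one integer.

## Known limitations

The permutation t-test inherits the anti-conservatism noted above. The
5PL fit reports curve-level uncertainty only through residuals, not a full
inverse-prediction interval. The WSS second-difference elbow requires
k_max ≥ K + 1 to see the bend. Stability-selection frequencies depend on
the resampling scheme (80% subsampling here) and transfer only
qualitatively to other schemes. Partial-correlation p-values assume
approximately Gaussian residuals; with the small matched subsets these
networks are exploratory, which is why edges carry their per-edge n.
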