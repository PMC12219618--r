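---
title: "Regional fractal dimension and DBS outcome modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional fractal dimension and DBS outcome modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractaldbs)
```

# What this package models

`fractaldbs` studies whether the geometric complexity of brain structures,
summarized per atlas region as a fractal dimension (FD), carries
information about how patients with Parkinson's disease respond to deep
brain stimulation (DBS). Response is quantified through medication
change: the percent reduction in levodopa equivalent daily dose (LEDD)
from before surgery to roughly six months after,

$$\Delta\mathrm{LEDD} = 100\% \times
  \frac{\mathrm{LEDD}_{pre} - \mathrm{LEDD}_{post}}{\mathrm{LEDD}_{pre}},$$

with $\Delta\mathrm{LEDD} > 0$ (medication decreased) versus
$\Delta\mathrm{LEDD} \le 0$ as the binary outcome. The pipeline spans FD
extraction from labelled volumes, biomarker-validation statistics,
penalized feature selection, nested-model variance decomposition, and a
hypergraph neural network (HGNN) classifier.

Because the clinical cohorts behind such analyses are not redistributable,
the package ships a synthetic-data generator that emulates their
statistical structure with known ground truth. Every stage is exercised
end to end on synthetic data; what that does and does not establish is
discussed at the end.

# Box-counting fractal dimension

A region's binary mask is cropped to its bounding box and covered by
non-overlapping axis-aligned boxes of edge $s$ voxels, anchored at the
bounding-box origin. $N(s)$ counts boxes containing at least one
foreground voxel; partial boxes at the far faces count when occupied. FD
is the ordinary-least-squares slope of $\log N(s)$ on $\log(1/s)$.

```{r fd-example}
sponge <- make_shape("menger_sponge", 27, level = 3)
fit_fd(box_count(sponge, c(27, 9, 3, 1)))
```

The level-3 Menger sponge recovers its similarity dimension
$\log 20 / \log 3 \approx 2.727$ exactly at the divisor scales, and solid
cubes, planes and lines recover 3, 2 and 1 with perfect fits. Those exact
power laws are the estimator's primary oracles.

Numerical and design choices:

* **Size schedule.** The largest box equals the smallest dimension of the
  *region's* bounding box (making FD region-intrinsic and
  translation-invariant), then floor-halving with duplicate removal down
  to 1 voxel. At least three scales are required; regions too small for
  that are reported as missing rather than fitted.
* **Grid anchoring.** Boxes are anchored at the bounding-box origin with
  no offset averaging, so counting is deterministic and exactly
  translation-invariant. Along the halving schedule the counts are
  monotone non-decreasing as boxes shrink; for arbitrary size pairs that
  monotonicity can fail (a box of 3 can merge voxels that two boxes of 4
  separate), which is why the property is asserted on the default
  schedule only.
* **Mask versus boundary.** Literature descriptions of ROI box counting
  oscillate between covering the region's voxels and covering its
  surface. The default mode counts all foreground voxels (`"mask"`);
  `"boundary"` first reduces the mask to its 6-connectivity boundary.
  For a solid 32³ cube the boundary-mode estimate is ≈ 2.5 rather than
  2: the coarsest scales see the shell's 3-D envelope (counts 1, 8, …)
  before the quasi-planar regime sets in. This scale mixing is inherent
  to whole-schedule fits and is why boundary-mode values should only be
  compared under a common size schedule.
* **Anisotropy.** FD is computed in voxel units. When spacing anisotropy
  exceeds 20% a warning is emitted and `resample_isotropic()` offers
  nearest-neighbour resampling; typical T1-weighted acquisitions mix
  1.0 mm isotropic with 0.5 × 0.5 × 1.0 mm voxels and no correction
  convention is established.

## Synthetic phantoms

`make_shape()` provides the oracle family: cubes/planes/lines (exact
integer dimensions), the Menger sponge via the recursive 20-of-27
occupancy rule, and spheres whose radius is displaced by band-limited
value noise. The perturbation displaces the radius *inward* only, so the
outer envelope — and hence the bounding box — does not grow with
amplitude, and the noise mixes equal-weight octaves so that amplitude
adds genuinely fine-scale roughness. Boundary-mode FD measured at a
fixed mid-scale schedule (16, 8, 4, 2, 1) is then non-decreasing in the
amplitude over 0.1–0.5. The exact ball (amplitude 0) is excluded from
that sweep: its perfectly axis-aligned polar caps are a degenerate
discretization case whose plate-like voxel runs inflate the counts
relative to a slightly rough sphere.

# Outcome metric

`compute_ledd()` sums dose × conversion factor over a medication
schedule. The shipped factor table (levodopa 1.0, controlled-release
levodopa 0.75, pramipexole 100, ropinirole 20, rotigotine 30, rasagiline
100, oral selegiline 10, amantadine 1.0) is a documented stand-in for
literature values and fully overridable from a TSV; entacapone follows
the adjunct rule of adding 0.33 × the concomitant immediate-release
levodopa dose. Visit selection is the latest visit strictly before
surgery (pre) and the visit nearest six months after (post), ties toward
the later visit. `classify_outcome()` places the boundary case
$\Delta\mathrm{LEDD} = 0$ in the no-decrease group.

# Validation statistics

* **Normality**: Anderson–Darling test of the composite normal
  hypothesis plus QQ quantile pairs. Monte-Carlo checks in the test
  suite confirm nominal size on normal draws and high power against
  exponential ones.
* **Group comparison**: per-region two-sided t-tests (Welch by default —
  the pooled-variance test is a flag, since equal variances are not
  guaranteed across cohorts), Benjamini–Hochberg adjustment across the
  tested regions, Cohen's d always with pooled SD. The BH implementation
  is `stats::p.adjust`, held to a brute-force step-up oracle in the
  tests.
* **Severity regressions**: per region and medication state, OLS of the
  motor score on FD with age and sex as covariates; 180 models (90
  regions × ON/OFF) are BH-adjusted jointly. The reported coefficient is
  the partial correlation of FD with the score given the covariates,
  $r = \mathrm{sign}(t)\sqrt{t^2/(t^2 + \nu)}$, with a Fisher-z 95%
  interval; published tables do not define their $r$ precisely, so this
  covariate-adjusted reading is documented as the package's choice.

# Feature selection

Continuous features are standardized to training-split mean 0 / SD 1,
and those statistics — never the validation or test rows — are applied
everywhere (`standardize_features()` records the provenance).
Categorical coding: STN = 1/GPi = 0, bilateral = 1/unilateral = 0,
female = 1/male = 0.

`lasso_select()` fits a linear LASSO of ΔLEDD% on the training features
over 40 log-spaced shrinkage values spanning the path from full to empty
selection. Each candidate feature set is scored by the 5-fold
cross-validated AUC of a logistic refit predicting the outcome class,
and the shrinkage maximizing mean CV AUC wins (ties to the sparser
model). This two-stage reading — continuous-outcome LASSO, class-AUC
model choice — matches the way the selection and its tuning are usually
described; a `logistic = TRUE` flag runs the LASSO on the class
directly. `ridge_weights()` then fits a CV-tuned ridge on the selected
set and normalizes absolute coefficients to a maximum of 1; these become
hyperedge weights.

# Variance decomposition

`fit_nested()` compares clinical-only against clinical + FD OLS models
on identical rows:

$$F = \frac{(\mathrm{RSS}_1 - \mathrm{RSS}_2)/q}{\mathrm{RSS}_2/df_2},$$

with $q$ the number of added parameters and $df_2$ the residual degrees
of freedom of the larger model (printed forms of this statistic
sometimes order the df difference the other way; with residual df that
difference is negative, so the standard convention is used). The
implementation is held to a brute-force oracle — explicit normal-equation
solves and numerical integration of the F density — to 1e-8, its type-I
error is calibrated to [0.03, 0.07] at the 5% level over 1,000 null
simulations, and a planted population ΔR² of 0.15 is recovered within
±0.05 on average. The clinical covariate list is target, laterality,
age, sex and % preoperative motor improvement. The interaction analysis
fits, per selected region, ΔLEDD ~ FD × target + covariates and derives
within-target slopes from the main effect (GPi reference) plus the
interaction coefficient.

# Hypergraph classification

Subjects are nodes. Each categorical feature contributes one hyperedge
per category (singleton categories are dropped — they carry no
connectivity). Each continuous feature contributes a k-uniform
hypergraph: one edge per subject containing it and its $k-1$ nearest
neighbours by absolute difference in that standardized feature, ties
broken by subject index. Per-feature incidence matrices are concatenated
horizontally, each edge inheriting its feature's normalized ridge
weight.

Each HGNN layer computes
$X' = \sigma(D_v^{-1/2} H W D_e^{-1} H^{\top} D_v^{-1/2} X \Theta)$ —
node-to-edge mean aggregation, weight scaling, edge-to-node
redistribution with symmetric degree normalization, then a learned
affine map and ReLU. Defaults (2 layers, hidden width 32, dropout 0.5,
Adam at 0.01, ≤ 300 epochs, patience 30) are conventional values for
small-cohort transductive graphs and are exposed in `hgnn_config()`.
Training is full-batch cross-entropy on the training nodes only
(transductive: all subjects participate in message passing, labels are
masked); the epoch with best validation AUC is kept, and the test report
(AUC, sensitivity, specificity at threshold 0.5) comes from the held-out
nodes. Node inputs are the standardized selected-feature vectors; what
the original architecture consumed as node features is not documented,
so this is the package's documented default. Gradients are closed-form
(the propagation matrix is symmetric), which keeps the fit exactly
reproducible for a given config and seed. `scan_k()` retrains over
k = 5…13 and picks the validation-AUC argmax, ties to the smaller k.

# Synthetic cohorts

`make_cohort()` draws regional FD from region-specific normals (cortical
baseline 2.4, subcortical 2.2, SD 0.08, exchangeable correlation 0.2 to
stress collinearity handling), plants a Cohen's-d shift in chosen
regions for the PD group, draws clinical covariates at the target
marginals (age 65 ± 9, 33% female, 58% GPi, 80% bilateral, motor
improvement 53 ± 16), and generates ΔLEDD from a linear model on
standardized features plus Gaussian noise, solving the noise SD
numerically so the marginal SD hits its target (23 ± 36, capped at
100%). The default outcome model gives the DBS target the largest
coefficient, followed by laterality, motor improvement, age, and 16 FD
regions of alternating sign. FD values are generated directly at the
feature level for cohort-scale work; voxel-level synthesis is reserved
for the box-counting oracles, keeping cohort tests fast.

What the generator does *not* emulate: scanner effects, registration
error, realistic inter-regional covariance beyond exchangeability,
non-Gaussian FD tails, informative missingness. Passing tests therefore
establish correctness of the estimators and calibration of the
statistics under the stated model — not clinical performance on real
cohorts. One consequence worth noting: with the target effect as
dominant as the cohort description implies, the clinical-only
hypergraph model can match or beat the combined one on a 35-subject
test split; the added FD edges must overcome their own noise at that
sample size.

# Problem sizes and runtimes

The shipped tests use the sizes at which the statistical claims are
stable and a laptop-class single core stays comfortable: 27³ phantoms
for the sponge oracle, 48³ for perturbed spheres, cohorts of 140 (70/70
case–control), 200 (planted-regression recovery) and 231 (full study,
90 regions), 1,000 replicates for calibration rates, 20 seeds for
recovery rates. The full suite runs in a few minutes; the acceptance
script in under a minute.

# Known limitations

* Whole-schedule log–log fits mix scaling regimes; no automatic scaling-
  window selection is attempted.
* Box grids are anchored, not offset-averaged; offset averaging would
  reduce discretization noise at the cost of translation invariance.
* The severity regressions assume linear FD–score relations and
  homoscedastic errors; no robust or mixed-effects variants.
* The HGNN is a small spectral model without attention or learned edge
  weights; its role here is the architecture's faithful, dependency-free
  reference implementation, not state-of-the-art performance.
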