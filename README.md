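# fractaldbs

Regional fractal dimension (FD) of brain structures as a candidate
biomarker for deep-brain-stimulation (DBS) outcomes in Parkinson's
disease, implemented as a tested, reusable R pipeline.

## The problem and who this is for

Patients with Parkinson's disease who respond well to DBS can typically
reduce their dopaminergic medication afterwards. Whether the structural
complexity of the brain, measured before surgery, predicts that response
is a question for neuroimaging methodologists and DBS outcome
researchers. This package implements the full analysis chain:

1. **FD extraction** — 3D box-counting over atlas-labelled volumes
   (NIfTI in, TSV out). FD is the slope of log *N*(*s*) versus
   log(1/*s*), where *N*(*s*) counts the non-overlapping boxes of edge
   *s* voxels covering the region.
2. **Outcome metric** — levodopa equivalent daily dose (LEDD)
   accounting and the percent change
   ΔLEDD = 100% × (LEDD_pre − LEDD_post)/LEDD_pre, with ΔLEDD > 0
   versus ≤ 0 as the binary response.
3. **Biomarker validation** — Anderson–Darling normality checks,
   per-region case–control t-tests with Benjamini–Hochberg correction
   and Cohen's d, covariate-adjusted FD-vs-motor-severity regressions.
4. **Feature selection** — training-split standardization, linear LASSO
   over a shrinkage path scored by 5-fold cross-validated
   classification AUC, normalized ridge coefficients as importances.
5. **Variance decomposition** — nested OLS (clinical vs clinical + FD)
   with F = ((RSS₁ − RSS₂)/q)/(RSS₂/df₂), plus per-region FD × target
   interaction models.
6. **Hypergraph classification** — categorical and k-uniform
   nearest-neighbour hyperedges concatenated into a weighted
   multi-feature hypergraph, classified by a spectral hypergraph neural
   network (node–edge–node convolution with symmetric degree
   normalization), written from scratch with closed-form gradients.

A synthetic-data module generates phantoms with known dimension (Menger
sponge, perturbed spheres) and cohorts with planted statistical
structure, so everything is testable without clinical data.

## Worked example

```r
library(fractaldbs)

# A level-3 Menger sponge recovers its similarity dimension log20/log3
sponge <- make_shape("menger_sponge", 27, level = 3)
fit_fd(box_count(sponge, c(27, 9, 3, 1)))
#> <fd_result> fd = 2.7268 (R^2 = 1.000000, 4 sizes, mode = mask)

# A 70/70 case-control cohort with a d = 1 shift planted in 3 regions
co <- make_cohort(cohort_spec(n_subjects = 140, pd_fraction = 0.5,
                              effect_regions = c(3, 8, 19),
                              effect_size_d = 1, seed = 42))
res <- group_compare(co$fd_table, co$group)
head(res[order(res$p_adjusted), ], 4)
#>        region t_statistic    p_raw p_adjusted cohens_d    direction significant
#> 19 region_019        6.18 6.91e-09   6.22e-07    1.044 higher-in-PD        TRUE
#> 8  region_008        5.69 7.47e-08   3.36e-06    0.962 higher-in-PD        TRUE
#> 3  region_003        5.10 1.11e-06   3.32e-05    0.862 higher-in-PD        TRUE
#> 13 region_013        2.81 5.68e-03   1.28e-01    0.475 higher-in-PD       FALSE

delta_ledd(1000, 600)
#> [1] 40
```

The three planted regions are exactly the ones surviving FDR correction,
with realized effect sizes near the planted d = 1; ΔLEDD is the percent
medication reduction (40% here).

The whole chain, on a synthetic 231-patient study plus a 70/70
validation cohort:

```r
man <- run_pipeline(pipeline_config(out_dir = "run1", seed = 17))
# stage outputs (fd_table.tsv, selection.json, variance.json,
# classification.json, manifest.json) land in run1/; the manifest holds
# the chosen shrinkage, selected-feature count, R2 of the clinical and
# combined models, the nested F, and the clinical vs combined HGNN AUCs.
```

Re-running with the same config reproduces every number bit for bit;
all stage seeds derive from the one master seed.

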