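# odornets

Group spatial ICA and task-modulated functional connectivity (TMFC) analysis
of odor-identification task fMRI, with moderated group regression on
Alzheimer's-risk covariates.

## The scientific problem

Poor odor identification and odor familiarity, combined with ApoE ε4 carrier
status, predict conversion to mild cognitive impairment and Alzheimer's
disease. This package implements the network-level analysis behind that
question for task fMRI of an odor-identification paradigm (16-s odorant
presentation/choice events, hits and misses, two runs at TR 2 s):

1. **Group spatial ICA** — two-stage PCA reduction, minimum-description-length
   (MDL) order selection, infomax unmixing stabilized by ICASSO (10
   repetitions, average-linkage clustering of pooled estimates, quality index
   I_q), GICA3 back-reconstruction of subject maps/time courses, z-scored
   aggregate maps.
2. **Temporal sorting** — components are ranked by the mean absolute Pearson
   correlation of their subject time courses with the generic HRF-convolved
   stimulus regressor (10-s double-gamma kernel); components with |r| > .2
   are retained as task-relevant, and per-subject hit/miss condition betas
   are estimated by multiple regression.
3. **Hybrid ICA–gPPI TMFC** — per subject and retained component, a voxelwise
   GLM with main effects of hits, misses and the seed time course plus the
   seed × condition interactions, controlling for the 24-parameter motion
   expansion, five aCompCor components, FD > 1 mm / standardized DVARS > 2
   spike regressors and a 0.01-Hz DCT high-pass basis. The interaction betas
   are condition-specific connectivity-change maps.
4. **Group statistics** — one-sample t maps of component maps
   (p < .0001, k ≥ 100); moderated regression of activation betas and TMFC
   maps on ApoE × SDOIT × familiarity (all continuous predictors
   mean-centered, age and sex as covariates), cluster-extent thresholding
   (p < .001, k ≥ 75, connectivity 26), and marginal-means tables for
   interaction plots.

In the moderated regression the model for an outcome $y$ (activation beta or
TMFC value) is

$$y = \beta_0 + \beta_1\,\mathrm{ApoE} + \beta_2\,\mathrm{SDOIT}_c +
\beta_3\,\mathrm{Fam}_c + \beta_4\,\mathrm{sex} + \beta_5\,\mathrm{age}_c +
\beta_6\,\mathrm{ApoE}{\times}\mathrm{SDOIT}_c +
\beta_7\,\mathrm{ApoE}{\times}\mathrm{Fam}_c +
\beta_8\,\mathrm{SDOIT}_c{\times}\mathrm{Fam}_c +
\beta_9\,\mathrm{ApoE}{\times}\mathrm{SDOIT}_c{\times}\mathrm{Fam}_c + \varepsilon.$$

Because no participant imaging data are deposited, the package ships a
first-class **synthetic cohort generator** (`generate_cohort()`) that plants
spatial networks, covariate-moderated activation, and hit-specific
seed–voxel coupling with full ground truth, so every stage is validated by
parameter recovery.

## Worked example

Simulate a 10-subject cohort and recover the planted networks:

```r
library(odornets)

spec <- cohort_spec(n_subjects = 10, reps_per_run = 2, n_frames = 160)
cohort <- generate_cohort(spec, seed = 42)
comps <- group_ica(cohort$bold, order = "mdl", icasso_runs = 10, seed = 7)
comps
#> <component_set> 8 components, 10 subjects, 2520 mask voxels
#>   stability Iq: 1.00 0.99 0.99 0.99 0.99 0.99 0.85 0.85

hrf <- canonical_hrf(10, spec$tr_s)
generic <- unlist(lapply(1:2, function(r)
  build_condition_regressor(cohort$events[[1]][[r]], "all_stim", 160, 2, hrf)))
rel <- sort_by_task_correlation(comps$subject_timecourses, generic,
                                run_frames = c(160, 160))
head(as.data.frame(rel), 3)
#>   component mean_abs_corr rank
#> 1         1         0.764    1
#> 2         7         0.715    2
#> 3         8         0.708    3
retained <- retain_task_components(rel, threshold = 0.2)

# permutation-resolved match of recovered aggregate maps to ground truth
match_components(comps$aggregate_maps,
  t(matrix(cohort$ground_truth$planted_maps, prod(spec$grid), 5)[comps$mask, ]))
#>   ref est abs_r
#> 1   1   4 0.997
#> 2   2   2 0.999
#> 3   3   5 0.998
#> 4   4   6 0.986
#> 5   5   3 0.995
```

All five planted networks are recovered with spatial |r| ≥ 0.99 for most and
ICASSO I_q ≥ 0.85 throughout; the MDL order (8) exceeds the planted 5
because intrinsic network activity and drift carry their own components.

Moderated group regression recovering a planted three-way interaction
(coefficient 0.078) from simulated activation betas at the study's n = 34:

```r
set.seed(11)
pp <- data.frame(apoe4 = rbinom(34, 1, 16/36), sdoit = rbinom(34, 8, 0.55),
                 familiarity = pmin(pmax(rnorm(34, 4.75, 1.9), 1), 10),
                 age = rnorm(34, 76.6, 4.2), sex = rbinom(34, 1, 0.5))
des <- group_design(pp)
truth <- c(0.1, -0.25, 0.05, 0.05, 0.02, 0.001, -0.1, 0.1, 0.02, 0.078)
y <- as.numeric(des$x %*% truth) + rnorm(34, 0, 0.1)
fit_group_regression(y, des)
#> <group_fit> n = 34, df = 24, 1 outcome(s)
#>                       coef     se       t      p
#> intercept           0.1148 0.0303  3.7881 0.0009
#> apoe               -0.2888 0.0489 -5.9055 0.0000
#> ...
#> apoe_x_sdoit_x_fam  0.0815 0.0227  3.5940 0.0015
```

The three-way coefficient is estimated at 0.0815 (planted 0.078); a single
n = 34 replicate carries an SE of ~0.02, which is why the validation suite
averages 200 Monte-Carlo replicates. `marginal_means(fit)` returns the
carrier/non-carrier × low/high-familiarity prediction table used for
interaction plots.

The full pipeline (smoothing → ICA → sorting → betas → confounds → TMFC →
group statistics) runs from a config via `run_pipeline(pipeline_config(...))`
or from a shell via the wrapper in `inst/scripts/odornets.R`
(`simulate` / `run` / `report` subcommands).

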