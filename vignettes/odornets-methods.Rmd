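---
title: "Methods: group ICA and task-modulated connectivity for odor-identification fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group ICA and task-modulated connectivity for odor-identification fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis in one paragraph

`odornets` studies which brain networks support odor identification and how
their activation and task-modulated functional connectivity (TMFC) relate to
Alzheimer's-risk covariates. Multi-subject task fMRI is decomposed by group
spatial independent components analysis (ICA) into spatially independent
network maps with associated time courses. Networks are called task-relevant
when their time courses correlate with the expected hemodynamic response to
odor presentation (absolute correlation strictly greater than 0.2). For each
retained network, hit- and miss-specific activation betas are estimated per
subject, and a hybrid ICA/generalized-psychophysiological-interaction (gPPI)
GLM measures how each network's coupling with every voxel changes during
correct (hit) versus incorrect (miss) identification. Finally, activation
betas and TMFC maps are regressed on ApoE &epsilon;4 carrier status,
odor-identification score (SDOIT, 0–8), mean odor-familiarity rating (1–10)
and their two- and three-way interactions, controlling for age and sex, with
cluster-extent thresholding of the voxelwise results.

## Group spatial ICA

The decomposition treats spatial maps as the independent sources and is
computed in three stages.

**Order selection.** The number of components is chosen by the classic
minimum-description-length criterion on the eigenvalues of the temporal
covariance (Wax–Kailath form),
$\mathrm{MDL}(k) = -N(p-k)\log(g_k/a_k) + \tfrac12 k(2p-k+1)\log N$,
where $g_k/a_k$ is the geometric/arithmetic mean ratio of the trailing
eigenvalues. MDL assumes $N$ i.i.d. samples; after Gaussian smoothing,
neighbouring voxels are strongly correlated and the criterion grossly
overestimates the order. The pipeline therefore uses an effective sample
size equal to the resel count (in-mask voxels divided by the kernel volume
in voxels), exposed as `mdl_n_effective`; on unsmoothed data the voxel count
is used directly. Estimates are computed per subject (where frames ≤ voxels
holds) and aggregated by the median.

**Reduction and unmixing.** Each subject's voxel time series are centered
and reduced to $l_1$ temporal principal components (default
$\lceil 1.5c \rceil$, a common group-ICA practice; configurable), the
reduced data are concatenated over subjects, reduced again to $c$ dimensions
and whitened to unit per-voxel variance. Infomax ICA (natural-gradient
ascent through a logistic nonlinearity, the standard contrast for sparse,
super-Gaussian spatial maps) unmixes the whitened matrix. The learning rate
anneals when successive update directions turn by more than 60°; iteration
stops when the Frobenius norm of the natural-gradient factor falls below
`tol` (1e-6) or at `max_steps` (512). The whitening scale matters: rows are
scaled to unit variance per voxel so the logistic nonlinearity operates in
its curved regime — with unit-sum-of-squares rows the update degenerates to
a linear map and provides no separation contrast.

**Stability and back-reconstruction.** ICASSO reruns infomax 10 times from
random orthonormal initializations (no bootstrap: the reliability check
repeats estimation only), pools all $10c$ estimates, clusters them by
average linkage on $1-|r|$ and keeps each cluster's centrotype. The quality
index $I_q$ is the mean within-cluster minus mean between-cluster
similarity. Subject maps and time courses come from GICA3's partitioned
projection: $S_i = N\,W\Lambda^{-1/2}E_i^{\top}Y_i$ and
$R_i = F_iE_i\Lambda^{1/2}W^{-1}$. This formula is used (rather than a
per-subject least-squares solve) because its defining identity — the mean of
subject maps equals the aggregate map *exactly* — is what makes group and
subject results commensurable, and the package tests it at every run.
Aggregate maps are z-scored over the mask with the sign fixed so the voxel
of maximum absolute loading is positive; the same sign flip is applied to
the time courses.

## Temporal sorting and condition betas

The canonical hemodynamic response function is a double gamma (response
shape 6, undershoot shape 16, undershoot ratio 1/6, unit rate; peak
normalized) truncated at 10 s and sampled at the TR. A short 10-s kernel is
used because, for 16-s presentation/choice blocks, it tracks the rise of
the response without the long tail that blurs adjacent events; kernel
parameters are configurable. Boxcars are sampled at TR resolution without
microtime upsampling — at TR 2 s and 16-s events the difference is
negligible. Note that the kernel is exactly zero at lag 0 (a gamma density
at the origin), so a regressor's first strictly positive sample falls one
frame after the event onset.

Per-subject component time courses are correlated with the generic all-stim
regressor per run (run-wise computation avoids spurious correlation from
concatenation discontinuities), and the aggregate is the mean of absolute
correlations over subjects and runs — retention operates on magnitude, so
the absolute value is taken before averaging (mean of signed r is available
via `aggregate = "mean_r"`). Retention is strictly greater than 0.2,
matching the rule's wording; a component at exactly 0.2 is dropped.
Hit/miss condition betas are ordinary least squares of each retained
component's concatenated time course on per-run intercepts plus the
HRF-convolved hit and miss regressors; empty conditions are dropped and
their betas marked missing rather than zero.

## The hybrid ICA–gPPI TMFC model

For each subject and retained component the design contains per-run
intercepts, the centered hit and miss regressors, the centered component
(seed) time course, the two interactions (centered seed × centered
condition regressor), the 24-parameter motion expansion, five aCompCor
components, one spike regressor per flagged frame and a per-run
discrete-cosine high-pass basis (0.01 Hz). Centering is per run so that
run-specific offsets cannot masquerade as coupling. The interaction betas
are the TMFC maps: the change in seed–voxel coupling specific to hits or to
misses.

Three deliberate choices: the seed is *not* hemodynamically deconvolved
before forming products (the interaction is formed directly at the BOLD
level; deconvolution at TR 2 s with a 10-s kernel is ill-posed, and a
boxcar-psychological variant is available by configuration); both condition
interactions sit in one model, gPPI style, rather than one model per
condition; and the GLM is plain OLS without AR(1) prewhitening, as in
ordinary PPI practice. Nuisance columns are orthogonal to nothing in
particular — but OLS guarantees the interaction betas are invariant to
adding any linear combination of nuisance columns to the data, and the
suite tests that invariance.

### Nuisance model details

* **FD** uses Power's formulation: sum of absolute backward differences of
  the translations plus 50 mm times the rotations' differences.
* **DVARS** is the spatial RMS of the frame difference over the mask. "A
  DVARS threshold of 2 mm" is not dimensionally meaningful for raw DVARS, so
  the threshold is applied to the median-standardized series (median 1 by
  construction; 2 means "twice the typical frame-to-frame change") — the
  conventional spike criterion. Raw-threshold semantics can be selected by
  configuration.
* **aCompCor** detrends (mean + linear) the voxels of a CSF-like noise
  region disjoint from the analysis mask and keeps the top five principal
  time series. No tissue segmentation is performed; the synthetic generator
  designates a noise slab.
* **High-pass filtering** is implemented as DCT regressors inside the GLM
  (K = ⌊2·T·TR·f_c⌋ columns) rather than as a temporal pre-filter, keeping
  the filtering and the model in a single projection with correct residual
  degrees of freedom.

## Group statistics

One-sample t maps of subject component maps use the textbook per-voxel
formula (df = n − 1, two-tailed) with voxel p < .0001 and cluster extent
k ≥ 100. The moderated regression design has ten columns: intercept, ApoE
(0/1), centered SDOIT, centered familiarity, sex (0/1), centered age, and
the ApoE×SDOIT, ApoE×familiarity, SDOIT×familiarity and three-way
interaction terms. Continuous predictors are mean-centered before products
are formed; the binary ApoE and sex columns are not. Centering changes
lower-order coefficients' interpretation but leaves the highest-order
(three-way) coefficient identical — a property the suite asserts to 1e-10.
Voxelwise regressions of TMFC maps use p < .001 and k ≥ 75. Positive and
negative statistic voxels are clustered separately; connectivity defaults
to 26 (vertex-connected, the more permissive common default; 6 and 18 are
available), and the labeling is validated against an independent flood-fill
oracle. Tests are two-tailed throughout; the one-sample threshold's
sidedness is not dictated by the procedure itself, and two-tailed is
assumed. No correction beyond the voxel + extent thresholds is applied; the
three-way interaction is treated as exploratory. Marginal means are
predicted over an identification-score grid at familiarity one SD below and
above the mean, for carriers and non-carriers, with age at its mean and sex
weighted one half.

## What the synthetic cohort emulates — and what it does not

The generator is first-class, tested code, and defines the conditions every
recovery test runs under. Defaults mirror the modeled study: two runs at
TR 2 s; per run, eight odorants presented in random order for 16 s each,
four times, with a 16-s baseline block after each set of eight (288 frames);
ApoE carrier fraction 16/36; SDOIT drawn as Binomial(8, 0.55) and
familiarity as a clamped Normal(4.75, 1.9), approximating the published
cohort means; age Normal(76.6, 4.2²) clamped at 68. In-scanner accuracy is
logistic in the identification score, `plogis(0.35·(SDOIT − 4))`, so
identification ability and hit/miss imbalance correlate as in real data;
the paper reports no per-subject accuracies, so this model is configuration,
not a claim.

Signal structure: five planted spatial networks (1–3 Gaussian blobs each,
standardized to zero mean and unit SD over the grid, pairwise spatial
|r| < 0.2 by rejection sampling). Maps are standardized rather than
peak-normalized so that downstream z-scoring of ICA maps preserves planted
amplitude scale, keeping moderation coefficients identifiable in absolute
units. Each component's time course is the HRF-convolved hit/miss
regressors scaled by per-subject amplitudes (hit 1.0, miss 0.7, subject
jitter SD 0.1) plus intrinsic AR(1) activity (SD 1). The intrinsic term is
essential, not cosmetic: real network time courses fluctuate outside task
events, and without it a zero-noise seed time course lies exactly in the
span of the hit/miss regressors, making the gPPI design singular and the
planted networks temporally rank-deficient for ICA. The designated
component's hit amplitude is a linear function of the centered covariates
with planted coefficients (three-way 0.078, ApoE −0.25, mirroring the
magnitudes the pipeline is meant to detect). The TMFC effect adds, during
hits only, gain × centered-seed × centered-hit-regressor signal into a
40-voxel target set chosen as the in-mask voxels with the weakest planted
loadings. Noise is linear drift (per-voxel slope SD 0.5) plus AR(1)
(φ = 0.3) thermal noise (innovation SD 1); the first x-plane of the grid is
reserved as the CSF-like aCompCor slab and excluded from the analysis mask.

Not emulated: hemodynamic nonlinearity and saturation, susceptibility
artifacts, physiological (cardiac/respiratory) cycles, spatial
heterogeneity of the HRF, registration error, and anatomical structure.
Passing recovery tests therefore demonstrates the estimators' correctness
under the stated statistical structure, not robustness to every artifact of
real acquisitions.

## Numerical choices and degenerate inputs

* OLS is solved by SVD pseudo-inverse with relative tolerance 1e-10; one
  pseudo-inverse serves all voxels of a GLM.
* Convolution of boxcars with the HRF is direct (non-FFT) so that
  conditions without events produce exactly zero columns.
* Smoothing uses nearest-neighbour boundary extension, preserving constants
  exactly and avoiding edge darkening on desk-scale grids; the affine must
  have orthogonal axes (shear is rejected).
* Zero-variance voxels in t maps are flagged and pinned to the p boundary;
  all-zero design columns are dropped with a message; aliased group-design
  columns are reported by name.
* ICA sign ambiguity is resolved by the max-|loading|-positive convention;
  permutation ambiguity in tests by exact assignment on |spatial r| (the
  optimal matching is enumerated for ≤ 8 components).
* Derived RNG seeds are folded modulo 2³¹ so every seed remains a valid R
  integer; all per-subject seeds are recorded in the ground-truth manifest.

## Problem sizes

The validation suites run at desk scale by design: ICA recovery uses 10
subjects on a 15×15×12 grid with 2 × 160 frames (a two-repetition variant
of the schedule that fits 160 frames); TMFC recovery uses 8 subjects at the
same grid; moderation recovery uses 200 Monte-Carlo replicates at n = 34
with residual SD 0.1 (small enough that the Monte-Carlo mean isolates bias
in the estimator rather than sampling noise; confidence-interval coverage is
insensitive to this choice); type-I calibration uses 20 null replicates of
34 × 12³ outcomes. The full published schedule (four repetitions, 288
frames) is the generator default.

## Known limitations

* Infomax optimizes a finite-sample likelihood whose optimum is near, but
  not exactly at, the separating matrix; even at zero noise the recovered
  time courses carry a small mixing error. End-to-end recovery of planted
  moderation coefficients through the ICA stage is therefore accurate to a
  few percent, not to machine precision; the algebra-exact path (true time
  courses → condition betas → group regression) recovers coefficients to
  1e-8 and both properties are tested separately.
* MDL's effective-sample-size correction is a heuristic for smoothed data;
  the resel count is a reasonable default, not an estimate of the true
  spatial degrees of freedom.
* Cluster-extent thresholds control false positives only under the
  stationarity assumptions of the voxel + extent heuristic; no permutation
  or random-field calibration is implemented.
* The pipeline assumes minimally preprocessed, spatially aligned input;
  registration, distortion correction and segmentation are out of scope.
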