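---
title: "Predicting treat-and-extend outcomes from quantitative OCT biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting treat-and-extend outcomes from quantitative OCT biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Neovascular age-related macular degeneration (nAMD) is treated with
repeated intravitreal anti-VEGF injections. Under a *treat-and-extend*
(T&E) regimen every visit is an injection visit, and the interval to the
next visit is stretched by 2 weeks when the retina is dry and shortened by
2 weeks when fluid recurs, between a 4-week floor and a 12-week ceiling.
Two clinically central questions can in principle be answered from the
first two OCT scans of a treatment course — the baseline scan and the
first follow-up 4 weeks after the first injection:

* **Visual outcome** — will the eye's best corrected visual acuity (BCVA)
  respond to treatment over the following year?
* **Treatment requirement** — will the eye be *extendable*, reaching and
  maintaining injection intervals of at least 8 weeks, or will it stay at
  4–6-week intervals?

`tepredict` implements this analysis end-to-end as a tested, reusable
pipeline. Because the underlying trial data are not publicly available,
the package ships a seeded synthetic cohort generator that emulates the
trial arm's data structure, so every stage — feature extraction, regimen
simulation, trajectory clustering, and prediction — runs and is tested
without any download. The synthetic cohort is a study of the *method*,
not a reproduction of the trial's effect sizes.

```{r, eval = FALSE}
library(tepredict)
result <- run_pipeline(pipeline_config(global_seed = 1))
glance(result$experiments$responder)
```

# Stage 1: the synthetic cohort generator

`generate_cohort()` draws one latent state per eye. Every random draw
comes from a per-eye stream keyed by `(seed, eye_id)`, so cohorts are
bit-reproducible and invariant to eye reordering.

**BCVA trajectories.** Each eye belongs to one of six latent classes with
quadratic mean trajectories in time (letters vs. months, one month = 4
weeks), plus a Normal per-eye random intercept (SD 5 letters) and
per-visit measurement noise (SD 3 letters, a typical ETDRS test–retest
spread), truncated to 0–100 letters. The default classes form a 2 x 2
responder/non-responder by high/low-baseline structure plus two small
declining classes, with weights 4:173:58:12:15:8 over 270 eyes — the
composition of the trial arm the generator emulates. A class counts as a
*responder* class when its model-implied 12-month gain
`12 b1 + 144 b2` is at least +5 letters.

**Fluid kinetics.** Four compartments are tracked per eye in nanoliters:
intraretinal fluid (IRF), subretinal fluid (SRF), pigment epithelial
detachment (PED) and hyperreflective foci (HRF). An injection multiplies
each volume by a per-eye *retention factor*; between visits each week adds
`recurrence_frac` (default 0.05) of the baseline volume with a per-eye
weekly hazard. Retention factors are ordered IRF ≤ SRF ≤ PED — IRF
clears fastest, SRF more slowly, PED responds only partially — and PED is
floored at 35% of its baseline so it persists throughout the course.
These functional forms (exponential decay, Bernoulli recurrence) are the
simplest ones satisfying the qualitative kinetics the generator must
emulate; they are calibration devices, not biological claims.

**Response phenotypes and coupling.** Retention factors are drawn from a
three-component mixture: *fast complete resolvers* (both fluids nearly
cleared after 1–2 injections), *persistent-SRF* eyes that never dry, and
an *intermediate* majority. The mixture weights (0.45/0.08 within
responder classes, 0.20/0.22 otherwise) and the hazard's dependence on
SRF retention (`0.003 + 0.04 * ret_srf`) were calibrated once so the
simulated regimen reproduces the emulated trial arm's published
composition — roughly 18% monthly-intensive, 22% continually extended,
60% individualized, and 55% extendable eyes — and then frozen. Two
couplings make the prediction tasks genuinely learnable: IRF retention is
lower in responder classes (linking visual response to IRF clearance),
and the recurrence hazard rises with SRF retention (linking
extendability to SRF persistence).

With `coupling = FALSE` the generator attaches to each eye a second,
seeded-permuted copy of the outcome-driving state (`out_*` columns).
Courses and outcome trajectories then come from the permuted state while
features come from the original one, making labels exactly independent
of features — the null control used by the acceptance suite. One fixed
permutation carries its own sampling variability of order `1/sqrt(n)`,
which is why the null check averages a few generator replicates.

**Maps.** `render_maps()` turns per-visit volumes into en-face thickness
maps (um) on the eye's native scanner grid — 49 x 768 or 128 x 512 pixels
over a fixed 6 x 6 mm macular field, mixed 65/35 by default. Each fluid
map is a smooth sum of Gaussian bumps placed in the three ETDRS zones;
the three bump-group amplitudes are solved from a 3 x 3 linear system so
the map's zonal volumes match the simulated targets (an exact per-zone
rescale absorbs the residual), and pixels beyond the 3 mm radius are
zero, so the full-grid volume equals the zonal total. Zonal shares per
biomarker are fixed: IRF is fovea-dominant while SRF sits mostly outside
the central millimetre, matching the compartments' known predilection
sites. The photoreceptor (PR) map is a thickness field around the eye's
baseline with a shallow foveal depression. No speckle, no B-scan
synthesis, no segmentation errors are modelled: passing tests show the
pipeline's statistics are correct, not that it is robust to real
segmentation noise.

**Attrition.** The default 270-eye configuration marks 10 eyes with a
missing baseline/follow-up scan, 22 lost to follow-up, 5 with bad scan
quality, and 5 protocol deviators. `exclusion_filter()` detects these
from the realized visit table (not from hidden flags) and applies the
rules sequentially, tallying each eye once, leaving 228 evaluable eyes.

# Stage 2: zonal OCT features

Maps are resampled by `resample_map()` — bilinear interpolation on pixel
centers spanning the common 6 x 6 mm extent — onto a canonical isotropic
128 x 128 analysis grid. (The source scanners differ only in sampling
density; volumes are integrals and insensitive to in-plane resolution, so
an isotropic canonical grid simplifies the zone geometry at no cost;
cross-grid agreement is tested at 2%.)

`etdrs_zone_masks()` partitions the grid by each pixel center's distance
from the grid center: a central 1 mm disc, a 1–3 mm parafoveal ring and a
3–6 mm perifoveal ring, with half-open boundaries `[r_lo, r_hi)`. The
fovea is assumed at the grid center, as the scans are macula-centered and
no foveal localization step is modelled. `zonal_volume()` integrates
thickness over a zone; numerically `sum(um) * pixel_area_mm2` *is* the
volume in nl (1 um over 1 mm² = 1 nl), so a uniform 100 um field over
the full grid is exactly 3600 nl. Fluids and HRF are summarized as zonal
volumes, PR as zonal mean thickness. (The source analysis groups HRF
with the volume maps, so HRF is quantified in nl here; and zonal "mean
values" for fluids are expressed directly as volumes, the stated unit.)

The per-eye predictor vector has a pinned 50-element layout
(`feature_names()`): 45 imaging features — five biomarkers x three zones
x three time blocks (baseline `m0`, follow-up `m1`, and `change = m1 -
m0`) — then `bcva_m0`, `bcva_m1`, `bcva_change`, `age`, `sex` (female =
1; the coding is inert for tree models). Because the zonal reduction is
linear, differencing zonal aggregates equals aggregating the pixel-wise
difference maps; this equivalence is tested. Eyes missing either visit
are excluded, never imputed — `assemble_features()` raises an explicit
missing-data error.

# Stage 3: the treat-and-extend state machine

`simulate_course()` runs the regimen closed-loop over 52 weeks: every
visit injects; the first two visits (weeks 0 and 4) are the loading
phase; disease activity is *presence of IRF or SRF* — operationalized as
more than 1 nl of either, since the trial's investigators judged
"presence" — and PED/HRF never trigger activity. From the first
follow-up on, `next_interval()` extends a dry eye by 2 weeks (to 12) and
shortens an active eye by 2 weeks (to 4). Extension is limited to two
*attempts*: an attempt is consumed when an extension episode is revoked,
i.e. a recurrence-driven shortening follows a prior extension; after the
second revocation the interval can shorten but never re-extend. (The
trial text does not define "attempt" operationally; this revocation
reading matches the plain wording and is isolated behind one predicate.)
Visits happen exactly on schedule; missed visits are out of scope, and
the trial's visual-acuity activity criterion is left unspecified in the
protocol text and therefore omitted.

`label_extendable()` encodes the outcome definition: an eye is
extendable when its course ends in a run of at least two injections at
intervals ≥ 8 weeks — "reached and maintained". The alternative reading
(any two ≥ 8-week injections regardless of later fall-back) is available
via `maintained = FALSE`. `classify_pattern()` partitions courses into
`monthly_intensive` (all intervals 4), `continually_extended`
(never-shortening intervals with extension beginning by the 4th
injection) and `individualized`.

# Stage 4: latent-class trajectory clustering

`fit_lcmm()` fits a latent class mixed model: a finite mixture of linear
mixed models in which each class has its own quadratic fixed-effect BCVA
trajectory, all classes share a random-intercept variance `tau2` and
residual variance `sigma2`, and no baseline covariates enter. Six classes
are used by default so subgroups emerge from the visual response alone
and are merged afterwards.

The fitter is a multicycle ECM algorithm with the random intercept
integrated out in closed form (scalar Woodbury identities): an E-step
computes posterior class probabilities from the Gaussian marginal
likelihoods; the class coefficients are then updated by
posterior-weighted generalized least squares (the exact conditional
maximizer given the variance components); after a fresh E-step the
proportions and the two variance components are updated from the
conditional random-intercept moments. Each cycle provably does not
decrease the observed-data log-likelihood, which the tests assert on
every fit. Numerical choices: variances floored at 1e-8; convergence at a
relative log-likelihood change below 1e-6 or 500 iterations; 10 starts
initialized by k-means on per-eye OLS quadratic coefficients (k-means
itself restarted 10 times — weaker initialization was observed to leave
class-splitting local optima), best final log-likelihood wins, ties to
the lowest start seed; a start that collapses a class (proportion below
`1/(10 n)`) is discarded and the next seed tried. Classes are reported
sorted by intercept, descending, so label switching cannot affect
downstream consumers; posterior ties in `posterior_assign()` break
toward the lower class index.

The random-effect structure is an intercept only — the smallest
structure identifiable from three or more visits per eye; a random slope
is a possible extension but is not implemented. The observed BCVA enters
through an identity link (letters are quasi-continuous). Equivalence
with any particular external mixed-model package is not claimed; what is
claimed, and tested, is exactness against a generalized-least-squares
oracle at K = 1, agreement with an independent ML mixed-model fit,
near-perfect recovery of well-separated two-class cohorts, and
parameter recovery of a six-class design across replicates (proportion
RMSE under 0.05; dominant-class coefficients within ~2 Wald SE of
truth).

`merge_to_responder()` formalizes the responder merge as a threshold on
the model-implied 12-month gain (default +5 letters, a conventional
clinically meaningful BCVA change; the source analysis merged classes by
inspection). `crosstab_by_baseline()` stratifies responder status by
baseline BCVA at 50 letters with one-decimal percentages.

# Stage 5: prediction and evaluation

`cv_predict()` evaluates a random forest — 2,000 trees, minimum node
size 1, 7 candidate features per split, delegated to the classical
`randomForest` implementation — under stratified 10-fold
cross-validation: folds differ in size by at most one, per-fold class
counts are within one of proportional, and every eye's probability (the
fraction of trees voting positive) comes from a forest never trained on
it. The out-of-bag error of each fold's forest is recorded as the
validation error; hyperparameters stay pinned (no tuning grid by
default). Three predictor subsets mirror the analysis layout: `all`
(50), `baseline_only` (18), `imaging_only` (45).

`roc_auc()` computes the AUC as the Mann-Whitney concordance probability
with ties at one half — tested exact against brute-force all-pairs
concordance and against an independent ROC package.
`bootstrap_auc_ci()` gives a percentile 95% interval over 1000
case-resampled AUCs (single-class resamples redrawn).
`operating_points()` reports the Youden-optimal point (ties resolved
toward higher specificity, the conservative choice when false
"extendable" calls are costlier than false negatives) and the
sensitivity at the smallest specificity ≥ 80%.
`permutation_importance()` measures, for each feature, the mean decrease
in *out-of-fold* accuracy over seeded whole-cohort permutations of that
column (10 by default) — computed out-of-fold rather than from the
forests' internal out-of-bag samples so the measure is independent of
the forest implementation. Pooled out-of-fold AUCs are the headline
numbers; per-fold mean AUCs are reported alongside since pooling versus
averaging is a genuine choice.

On coupled synthetic cohorts the SRF feature block outranks the IRF
block for the extendability target and vice versa for the responder
target — the directional structure the method is designed to surface —
and decoupled cohorts sit at chance.

# Problem sizes and reproducibility

The shipped configuration is the emulated trial arm itself: 270 eyes, 52
weeks, six latent classes, 2,000-tree forests, 10-fold cross-validation,
1000 bootstrap resamples. A full pipeline run takes on the order of one
to two minutes on a single CPU; the test suite uses the same cohort size
for end-to-end checks and smaller fixtures (12–500 eyes, 100–200-tree
forests) for unit-level properties. Every stochastic stage is seeded;
`run_pipeline()` writes its artifacts with MD5 hashes and reruns with
the same configuration reproduce identical hashes.

# Known limitations

* Synthetic maps are smooth Gaussian mixtures — no speckle, motion, or
  segmentation-error structure; real-data robustness is untested by
  construction.
* The generator's kinetics are phenomenological; its effect sizes (and
  hence the synthetic AUCs) are properties of the simulation, not
  estimates of real-cohort predictive performance.
* Random intercept only in the LCMM; no class-number selection beyond
  reporting BIC (K is fixed at 6 by design).
* One eye per patient; no bilateral correlation, no missed visits, no
  drug-specific pharmacokinetics.
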