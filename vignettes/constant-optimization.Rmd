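---
title: "Formula constant optimization: models, strategies, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formula constant optimization: models, strategies, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iolconst)
```

## The optical model

All four formulae in this package — SRK/T, Hoffer Q, Holladay 1 and the
simplified Haigis formula — are thin-lens vergence models of the
pseudophakic eye. Light from a distant target passes a spectacle lens at a
12 mm vertex distance, the cornea (a single refracting surface of power
`Dc`), travels a chamber distance `c` in media of refractive index 1.336,
is refracted by a thin IOL of power `P`, and must focus at the optical
axial length `L`. Solving that chain for the spectacle power gives the
predicted spherical-equivalent refraction (SEQ) for an implanted power, and
solving it for `P` gives the power needed for a target refraction; the two
directions are exact algebraic inverses, which the tests verify to
1e-6 D over thousands of random eyes.

The formulae differ only in how they fill the three slots:

* **corneal power.** Keratometric power is computed from the harmonic-mean
  corneal radius (the harmonic mean of the meridional radii corresponds to
  averaging the meridional powers). SRK/T, Hoffer Q and Holladay 1 work on
  the 1.3375 (Javal) keratometric scale; inside their vergence chains SRK/T
  and Holladay 1 convert back to a radius and apply their published
  corneal vergence powers (`333/r` and `(4/3−1)·1000/r`); Haigis converts
  the radius directly with its published index 1.3315.
* **effective lens position (ELP).** SRK/T uses the corneal-height model
  with `ACDconst = 0.62467·A − 68.747` and the long-eye axial-length
  correction; Hoffer Q uses its tangent-based chamber-depth model with the
  published axial-length clamps at 18.5 and 31 mm; Holladay 1 adds the
  surgeon factor to an anatomical ACD from a corneal-height model
  (`Rag ≥ 7` mm, `AG ≤ 13.5` mm); Haigis uses the regression
  `a0 + a1·ACD + a2·AL` with a1/a2 preset to 0.4/0.1 so that a0 is the
  single tuned constant.
* **optical axial length.** SRK/T adds its retinal-thickness term
  `0.65696 − 0.02029·AL`, Holladay 1 adds 0.2 mm, Hoffer Q and Haigis use
  the measured length (Hoffer Q places the lens plane at `ELP + 0.05` mm).

Each implementation was cross-checked against an independent verbatim
transcription of the published closed-form expressions (see
`tests/testthat/helper-oracles.R`); the two routes agree to machine
precision, which guards against the transcription slips these formulae are
notorious for.

Out-of-domain intermediates (negative corneal-height square root, extreme
axial lengths, radii below 7 mm) are clamped exactly where each
publication clamps them, and every clamp raises a classed warning
(`iolconst_clamp`) so that batch callers can count events rather than
lose them; the optimizers do exactly that and report the count in their
diagnostics.

## Two additional tuning parameters

Beyond the classical constant, two second-order constants are supported:

* **refractive offset `ro`** (D, default 0): added to the predicted SEQ as
  a terminal term. It never touches the ELP, so its effect on every
  prediction error is exactly −1·ro.
* **keratometer index `nk`** (default: each formula's working index):
  replaces the index used to convert the measured radius into keratometric
  power, uniformly rescaling corneal power. Bounds (1.30, 1.38) cover the
  physically sensible range between the corneal stromal index and the
  classical calibration indices.

## Prediction error and its metrics

The per-eye prediction error is defined as *achieved minus predicted* SEQ.
The alternative sign appears in parts of the literature; this convention
was chosen because it makes the second step of the two-step procedure read
naturally — the offset that zeroes the mean equals the mean error observed
at zero offset — and because it makes strategy (b)'s residual mean equal to
strategy (d)'s fitted offset, an identity the tests check to 1e-6 D.

`summarize_pe()` reports MPE (mean), SDPE (sample SD, n−1 denominator),
RMSPE (`sqrt(mean(PE²))`), and the median, quartiles and 2.5%/97.5%
quantiles of |PE| — the numbers needed to draw the usual absolute-error
boxplots. The decomposition `RMSPE² = MPE² + SDPE²·(n−1)/n` holds to
1e-12 by construction and is asserted over a thousand random vectors. The
denominator convention matters only for reporting: any monotone rescaling
of the SD leaves every argmin in this package unchanged. Quantiles use
linear interpolation between order statistics (R's type 7); the convention
is a documented package choice, since "2.5%/97.5% quantile" alone does not
pin down an estimator.

## The six strategies and how they are solved

For a formula, a cohort, and the objective metric `m(fc)` obtained by
recomputing the prediction errors at constant `fc`:

* **(a) zero MPE** — bracketed root finding (`uniroot` over the constant's
  plausibility bounds, followed by secant polishing until
  `|MPE| < 1e-12`). If the mean error does not change sign across the
  bounds the data cannot be zeroed by this formula and the routine refuses
  with a bracketing error.
* **(b) minimal SDPE, (c) minimal RMSPE** — a 41-point bracketing grid
  over the bounds followed by Brent refinement of the bracketing interval.
  The grid step makes the search robust should an objective develop a
  shoulder; all observed objectives are unimodal over the bounds, and the
  optimizers are compared against an exhaustive 1e-4-resolution grid
  oracle in the tests (agreement required within 1e-3).
* **(d) joint FC/RO for minimal RMSPE** — solved by profiling the offset
  out: for fixed `fc` the optimal offset is the mean residual, and the
  profiled objective is the SD of the prediction error. The joint problem
  therefore reduces to (b) followed by setting `ro` to the residual mean.
  This removes the near-degenerate ridge a naive 2-D search must crawl
  along (an ELP shift and a refraction offset are nearly collinear over a
  clinical cohort — a plausible reason why joint and two-step results can
  appear to disagree when the 2-D search stalls). The naive Nelder–Mead
  search is retained behind `profile = FALSE` and agrees with the profiled
  solution in the tests.
* **(e) joint FC/nK for minimal RMSPE** — nested bounded search: an outer
  Brent pass over the index with an inner constant minimization per
  candidate index. A solution with the index at a search bound is flagged
  not-converged rather than returned silently.
* **(f) two-step** — step 1 minimizes SDPE over the constant; step 2 sets
  the offset to the residual mean, which zeroes the MPE exactly. Because
  the offset is additive, (f) with an exact step 1 attains the same RMSPE
  as (d); the suite asserts agreement within 1e-4 D on twenty replicate
  cohorts. A `single_update` mode performs instead one damped Newton
  update of the start constant (central differences with step 1e-4,
  halved until the SD does not increase), emulating the one-iteration
  clinical variant of the procedure; it is provided as a mode rather than
  the default because the exact mode is cheap at these problem sizes.

Stopping tolerances default to 1e-10 on the constant and 1e-12 on the
objective. Start values default to nominal constants (A 119.0, pACD 5.6,
SF 1.8, a0 1.3) and the results are start-value-insensitive within
tolerance (tested); cohorts below 10 eyes are refused unless explicitly
allowed, and cohorts whose objective is flat to the function tolerance
across the bounds are refused rather than assigned an arbitrary constant.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws (AL, ACD, LT, R12) from a truncated correlated
Gaussian. The four `preset_config()` datasets reproduce the marginal means
and SDs (and sample sizes 886/613/821/467) of four published single-center
pseudophakic cohorts; a 2000-eye draw is checked against those means
within three standard errors. The joint dependence structure of the real
cohorts is not published, so the correlation matrix (AL–ACD 0.45, AL–R12
0.35, ACD–LT −0.35, others 0) is package policy taken from the general
biometry literature and is recorded in the truth record; truncation to the
plausibility limits slightly shrinks the tails relative to the source
quantiles, which is why distributional checks use means, not extreme
quantiles.

The mean radius is split into meridional radii via a half-normal corneal
astigmatism magnitude (SD 0.75 D). The implanted power is what the *true*
formula prescribes for a target drawn from a mixture (85% at −0.25 D, 15%
at −2.0 D, reflecting screened cohorts whose median achieved refraction
sits near −0.25 D), rounded to the 0.5 D labelling grid; the achieved
refraction is the true-formula prediction (including a true offset `ro`)
plus Gaussian noise, default SD 0.42 D — the scale at which the
prediction-error SD at the true constant lands in the 0.38–0.49 D range
typical of screened clinical cohorts (a propagation the tests verify).
A variance-standardized Student-t noise option exists for robustness
experiments and is off by default.

Consequently, passing tests show that the estimators recover known truth
under a well-specified generative model; they cannot show how the
strategies behave under model misspecification present in real data —
biometer-specific measurement error, surgeon-dependent ELP behaviour,
formula-inadequate eyes (post-refractive corneas, extreme lengths), or
non-Gaussian refraction noise. Recovery checks at the study scale
(20 replicate cohorts of 800 eyes, noise SD 0.42 D, true offset 0.8 D)
bound the mean offset-recovery error at 0.05 D; problem sizes in the test
suite (100–886 eyes, 20 replicates) were chosen to keep sampling error
well below the asserted tolerances.

## Known limitations

* Only the four classical single-constant formulae are implemented;
  modern undisclosed or multi-constant formulae are out of scope (the
  constant-set template makes room for them, but no hooks pretend to
  support them).
* The Haigis triplet is deliberately not jointly optimized (a1/a2 stay at
  0.4/0.1); tuning all three constants is a different estimation problem
  with different identifiability behaviour.
* Cross-validation (train/test splits, k-fold, bootstrap) is not built in;
  `run_strategy_suite()` operates on whatever cohort it is given, so a
  caller can implement resampling around it.
* The 6 m refraction lane is not modeled optically; like the source
  procedures, the refractive offset absorbs the lane-distance convention.
* Astigmatic (toric) prediction, thick-lens and raytracing models are out
  of scope.
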