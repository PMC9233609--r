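---
title: "Growth-curve registration and adult height prediction: methods"
author: "staturecast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve registration and adult height prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staturecast)
```

# The problem

Clinicians and sports scientists want two numbers for a growing child: the
adult height the child is heading for, and the height expected at some
intermediate ("stage") age — next year, or at the start of a competitive
season.  Classical tools (the mid-parental genetic formula, the
Bayley–Pinneau percentage-of-adult-height method) use one or two predictors
and carry errors of several centimetres.  `staturecast` implements a
two-part alternative:

1. **Adult height** is regressed on a six-feature encoding of a single
   measurement — bone age, chronological age, height, weight, BMI, and the
   deviation of BMI from the age- and sex-specific reference BMI — with a
   small per-sex multilayer perceptron trained under a *banded squared
   loss*.
2. **Stage height** comes from registering a population mean growth curve
   to the individual child.  With the mean height-for-age curve $f(x)$, the
   child's curve is modelled as
   $$H(x) = f(\alpha x + \beta) + \gamma,$$
   where $\alpha > 0$ is the growth *tempo* (values below 1 mean a fast,
   early-ending pubertal course), $\beta$ (years) is the *phase* (positive
   for early developers) and $\gamma$ (cm) is the *amplitude* (smaller for
   shorter children).  This is the same superimposition idea that underlies
   SITAR-style growth modelling, fitted here per child rather than as a
   mixed-effects model.

# The mean growth curve

The mean curve is a polynomial least-squares fit to a per-sex reference
grid of mean ("0 SD") height by age.  Choices that matter:

* **Degree** (`degree`, default 5, configurable): degrees 4–6 reproduce the
  smooth sigmoid shape of childhood growth — slowing in mid-childhood, a
  pubertal spurt, then a plateau.  Degree 5 is the default; nested fits are
  available and `fit_rmse` is reported so users can judge.  On the bundled
  synthetic grids the degree-5 RMSE is 0.3–0.9 cm.
* **Conditioning**: ages are centred and scaled to $[-1, 1]$ before the
  power design matrix is built, and the problem is solved by QR
  decomposition; coefficients are mapped back to the raw-age basis for
  serialization.  A raw Vandermonde over ages 0–18 at degree 5 is
  ill-conditioned and the explicit normal-equation solve is kept only as a
  test oracle.
* **Domain**: evaluation clamps ages above `age_max` to `age_max` — mean
  height plateaus at adulthood, which also anchors $\gamma$ at the age-18
  mean height.  Ages below `age_min` are an error rather than an
  extrapolation, because a polynomial's behaviour outside its fit range is
  meaningless.

The bundled reference tables are **synthetic** (the national standard-
deviation tables the method is designed for are not redistributable); any
user CSV with `age,height` columns is accepted.

# The adult-height network

A 6–100–1 ReLU network per sex, trained by full-batch gradient descent.
Height measurement itself is uncertain by roughly 0.5 cm (posture, time of
day), so residuals inside a $\pm 0.5$ cm band are treated as already
correct: the loss is
$$\mathcal{L} = \frac{1}{n}\sum_i \max(0, |d_i - y_i| - 0.5)^2 ,$$
a hinge that is continuously differentiable everywhere, reduces exactly to
mean squared error at band 0, and does not chase sub-measurement-noise
residuals (an overfitting guard).  Gradients are derived in closed form and
checked against finite differences in the tests.

Defaults and the reasoning behind them:

* `hidden_units = 100`, ReLU activation, one hidden layer.
* `learning_rate = 5e-5` with `iterations = 46000` (male) / `48500`
  (female): a long, conservative schedule of full-batch steps.  For
  reduced-cost runs the package scales the learning rate inversely with
  the iteration count so the optimisation budget
  `learning_rate * iterations` is preserved; the bundled pipeline and the
  acceptance script train for 2000 iterations at `5e-5 * 46000 / 2000`.
  Plain gradient descent at `5e-5` for only 2000 steps is still far from
  convergence and would report an undertrained model.
* **Input standardization** (`standardize_inputs = TRUE`): features are
  z-scored with training-set statistics stored in the model; raw cm/kg
  scales at this learning rate would stall.
* **Initialisation**: He-uniform, seeded, with the output bias started at
  the mean training target so early iterations refine structure instead of
  crawling toward the target scale.
* **Optimizer**: plain full-batch gradient descent is the reference
  behaviour ("all training data in every iteration"); a classical momentum
  term is available behind `momentum` and off by default.
* Training is a pure function of `(features, targets, config)`; two runs
  with the same seed produce bit-identical weights.

Sex is deliberately **not** a feature: separate male and female models are
trained and every model, curve and table in the package is keyed by sex.

# Personal-curve registration

Given a predicted (or verified) adult height $H_{\mathrm{final}}$ and one
or more observed $(x, H)$ pairs:

1. $\gamma = H_{\mathrm{final}} - f(18)$ — the amplitude is fixed first
   from the adult anchor (age 18 by default, configurable).
2. $(\alpha, \beta)$ minimise the residual sum of squares over all anchors
   (the observations plus the adult anchor).  With one observation this is
   the classical contradictory system of two nonlinear equations in two
   unknowns; additional historical measurements enter the same residual
   sum, a strict generalisation.

Numerical choices:

* **Solver**: L-BFGS-B within $\alpha \in [0.5, 1.5]$,
  $\beta \in [-4, 4]$ years, polished from $(1, 0)$ and from a
  diversity-filtered set of the best cells of a coarse grid — the
  objective can have several basins, and the best coarse cells cluster
  inside one of them, so each extra start must be well separated from
  those already chosen.  A derivative-free Nelder–Mead polish guards
  against premature termination at the clamp boundary, where the gradient
  has a kink.  Tests verify the reported optimum never exceeds a dense
  grid search (step 0.01) by more than $10^{-6}$.
* **Domain handling during search**: transformed ages above the base
  domain are clamped (the adult plateau); ages below it incur a smooth
  quadratic penalty instead of a hard failure, keeping the objective
  continuous.
* **Degeneracy**: with a single observation the adult-anchor equation is
  satisfied on a whole ridge of $(\alpha, \beta)$ values; among
  (near-)tied optima the fit prefers the solution closest to the identity
  transformation, which is the conservative choice for extrapolation.
* **Two parameterisations**: the default ($\gamma$-first) mirrors the
  two-step presentation above.  Because $\gamma$ is defined relative to
  the age-18 mean height, a *late* developer (whose transformed age-18
  position $18\alpha + \beta$ is still below 18) has part of their tempo
  absorbed into $\gamma$; the generating triple of a simulated child is
  then not exactly recoverable in this parameterisation.  `joint = TRUE`
  re-estimates all three parameters (with $\gamma$ profiled out in closed
  form) and does recover generating triples exactly from noiseless data.
  The two modes coincide for early developers.

# The synthetic cohort generator

The study data behind this class of method are private clinical records,
so the package ships a seeded longitudinal simulator that produces the
statistical structure the method assumes, with known ground truth.  Per
child: $\alpha \sim \exp N(0, 0.05)$, $\beta \sim N(0, 0.8)$ years,
$\gamma \sim N(0, 4)$ cm; visits (default two, one year apart, first visit
uniform on ages 8–13) observe $f(\alpha x + \beta) + \gamma$ plus
$N(0, 0.5)$ cm measurement noise; the true adult height is the personal
curve at 18, noise-free.

* **Bone age** is modelled as the child's *developmental age*
  $\alpha x + \beta$ (scaled by `bone_age_offset_scale`, default 1) plus
  assessment noise of sd 0.25 years — a realistic figure for
  research-grade readings.  Early developers therefore show advanced bone
  age, which is exactly the signal the network exploits.
* **Weight** is reconstructed from a per-subject BMI trajectory (reference
  BMI-for-age plus a subject offset of sd 1.5 kg/m², correlated 0.4 with
  the phase $\beta$ — heavier children tend to mature earlier) so the BMI
  features carry a maturation signal too.
* `adult_height_noise_floor()` computes the simulator's irreducible
  prediction error: a plug-in predictor that knows the true mean curve and
  the bone-age link but sees only the observable fields.  With the default
  noise levels its MAE is ≈1.2–1.5 cm, dominated by bone-age noise times
  the pubertal growth rate (≈5.5 cm/year) rather than by the 0.5 cm
  measurement noise.  This is the yardstick the end-to-end tests hold the
  trained network to (within a factor of two).

What the generator does **not** emulate: secular trends, skewed or
age-dependent measurement error, missing visits, assessment-method
differences in bone age, or the demographic structure of any real
population.  Passing tests on simulated cohorts demonstrates that the
estimation machinery recovers the model's own structure — not that the
model is adequate for any particular clinical population.

# Evaluation conventions

* Deviations are always `predicted - observed`.
* Within-`k`-cm accuracy counts `|deviation| < k` — a deviation exactly on
  the threshold is a miss.  For continuous errors the strict and inclusive
  conventions agree almost surely.
* Quartiles use linear interpolation between order statistics (R's default
  type 7), stated explicitly because boxplot IQRs and outlier sets depend
  on the convention; outliers lie beyond 1.5 IQR whiskers.
* Display rounding is half-away-from-zero to 2 decimals; internal
  arithmetic never rounds.  Published worked-example tables of this kind
  contain rows where the printed deviation differs by 0.01 from the
  difference of the printed (rounded) heights; the bundled worked-example
  fixtures reproduce exactly that behaviour.

# Problem sizes used by the tests and the acceptance script

Chosen as the package's own trade-off between statistical resolution and a
quick default test run: 400 simulated children per sex (3:1 split) for the
end-to-end adult-height check, 2000 training iterations at the scaled
learning rate, 200 children for the personal-curve recovery study, dense
grid-search cross-checks on a subset of 40 children, and 500–1000 children
for Monte-Carlo checks of the generator's moments.

# Known limitations

* With two observations one year apart and 0.5 cm noise, the tempo
  $\alpha$ is only weakly identified: its estimation error is roughly
  $\sqrt{2}\cdot 0.5 / (f' \cdot \Delta x) \approx 0.13$, so only ~40% of
  fits land within $\pm 0.05$ of the generating value.  Stage predictions
  a year ahead are nevertheless accurate (median absolute error well under
  1.5 cm) because prediction only needs the curve locally, not the
  parameters individually.  Recovering tempo reliably needs more visits or
  wider spacing.
* The $\gamma$-first parameterisation is anchored at the age-18 mean
  height; for late developers it deliberately differs from the generating
  parameters (see above).
* The network's accuracy on real cohorts depends on reference tables
  (0 SD heights, standard BMI, FP percentages) that are not
  redistributable here; the bundled tables are clearly-labelled synthetic
  stand-ins and should be replaced for any real use.
* Developmental-category assignment for the Bayley–Pinneau baseline
  (early/normal/late) is a required input, not inferred.

# A minimal worked example

```{r example, eval = FALSE}
ref <- load_reference_table(
  system.file("extdata", "reference_0sd_male_synthetic.csv",
              package = "staturecast"), sex = "male")
curve <- fit_mean_curve(ref, degree = 5)

# a 11.5-year-old boy, 146.1 cm, with a network-predicted adult height
pc <- fit_personal_curve(observations = data.frame(age = 11.5, height = 146.1),
                         adult_height = 172.4, base = curve)
predict_stage_height(pc, 12.5)
```

The full workflow — simulate, train, personalise, evaluate — is
`run_pipeline(default_run_config())`, and every pipeline stage is also a
plain exported function.
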