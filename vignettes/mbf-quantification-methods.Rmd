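---
title: "Quantifying myocardial blood flow from dynamic cardiac PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myocardial blood flow from dynamic cardiac PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbfpet)
```

## The problem

Cardiac perfusion PET with ⁸²Rb estimates myocardial blood flow (MBF), but
rubidium is only partially extracted by myocardium, and its extraction
fraction falls nonlinearly with flow. Quantitative ⁸²Rb MBF therefore rests
on three coupled pieces of machinery, all implemented here:

1. **Kinetic modeling.** The one-tissue compartment model (1TCM) fitted
   voxelwise or per region to dynamic PET time activity curves (TACs),
   yielding the influx rate constant $K_1$ (mL/min/g), the efflux rate $k_2$
   (1/min), and blood-signal fractions.
2. **Input functions.** The arterial input function (AIF), either measured by
   an arterial blood monitor (which needs background, sensitivity, decay,
   dispersion, and delay corrections) or derived from the LV blood pool of
   the image (an IDIF, which needs partial-volume/scale correction).
3. **The extraction model.** The generalized Renkin-Crone relation
   $K_1 = \mathrm{MBF}\,(1 - a\,e^{-b/\mathrm{MBF}})$ linking rubidium $K_1$
   to flow, calibrated against ¹⁵O-water flows ($\mathrm{MBF} = k_2\,p$ with
   partition coefficient $p = 0.91$ mL/g), and inverted to turn measured
   rubidium $K_1$ into flow.

A synthetic-data module generates every input with known ground truth, so the
whole chain is testable end to end without any acquisition.

## The kinetic model and its observation equation

The tissue concentration follows
$C_T(t) = K_1\, e^{-k_2 t} \otimes C_A(t)$. A measured voxel additionally
contains LV and (optionally) RV blood signal, from true blood volume and from
resolution/motion spillover:

$$C_{PET}(t) = (1 - V_A - V_{RV})\,\rho\,C_T(t) + V_A\,C_A(t) + V_{RV}\,C_{RV}(t)$$

with $V_A, V_{RV} \ge 0$, $V_A + V_{RV} \le 0.999$. Units: curves are Bq/mL;
the tissue response is per gram, so the tissue term alone carries the density
$\rho = 1.05$ g/mL. This single conversion point keeps two desirable
identities exact at once: a pure-blood voxel reproduces the input curve, and
$K_1$ comes out in mL/min/g without rescaling the data. `density_convert()`
is available for explicit unit changes of stored TACs.

**Assumptions.** Decay-corrected concentrations referenced to injection time
throughout; frames are half-open intervals $[start, end)$ in seconds from
injection, stored explicitly and never inferred; TACs are frame averages of
the underlying concentration.

### Basis function fitting

For fixed $k_2$ the model is linear in (amplitude, $V_A$[, $V_{RV}$]) with
amplitude $= (1 - V_A - V_{RV}) K_1$. `fit_tac()` therefore precomputes, for
a grid of $k_2$ values, the frame-averaged unit-$K_1$ tissue response
(`make_basis()`), solves the constrained weighted linear problem exactly at
each grid point, keeps the grid minimizer (ties to the smaller $k_2$), and
polishes $k_2$ between the neighboring grid points by golden-section search.
The default grid has 100 log-spaced points on $[0.01, 12]$ min⁻¹ — wide
enough to cover water kinetics under stress ($k_2 \approx 4$ min⁻¹) with
margin; grid granularity is otherwise not critical because of the
refinement step (a deliberately coarse 4-point grid still recovers $k_2$ to
better than 0.5%, as the tests check).

Numerical choices worth knowing:

- **Convolution is analytic.** Inputs are piecewise linear; the convolution
  with $e^{-k_2 t}$ is evaluated exactly at the input's sample nodes by a
  segmentwise recursion (series forms guard small $k_2 h$ against
  cancellation), and frame averaging integrates the result exactly. No
  discretization happens at frame scale.
- **The constrained solver enumerates active sets.** With at most 3 unknowns
  and 4 convex constraints, enumerating active sets is exact and cheap. Each
  candidate is solved by variable elimination and a QR factorization rather
  than normal-equation KKT systems: activity-scaled columns (~10⁴ Bq/mL) and
  unit-scale fractions differ by eight orders of magnitude, which destroys
  the conditioning of an augmented KKT matrix but is harmless to QR on the
  reduced design.
- **Boundary voxels.** When the blood-fraction sum constraint is active the
  voxel is numerically pure blood and $K_1$ is unidentifiable; the fit
  reports $K_1 = 0$, $k_2 =$ NA with a `boundary` flag instead of an
  arbitrary large ratio. Failures in parametric maps are flagged, never
  silently zeroed.
- **Weights.** The weighted least squares criterion uses
  noise-equivalent-count frame weights
  $w_i = \Delta t_i^2\, dcf_i^{-2} / \max(C_i \Delta t_i, \epsilon)$,
  $dcf_i = e^{\lambda t_{mid,i}}$, normalized to mean 1. The literature
  names the weight family without printing a formula, so this choice is
  isolated behind the `fit_weights` abstraction and alternatives plug in as
  plain numeric vectors.

### Image-derived inputs at frame resolution

An IDIF extracted from the LV blood pool exists only at frame resolution.
When such a TAC is used as the model input, two things are done differently:
the spillover regressor uses the TAC's exact frame values, and the
convolution uses a continuous surrogate reconstructed by differentiating a
monotone (Hyman) spline through the cumulative area at frame boundaries.
This reconstruction reproduces the observed frame averages and, unlike
midpoint interpolation, does not leak activity across the fast 3-s early
frames — with count-based weights, that leakage is heavily penalized and can
push fits into a degenerate corner ($V_A \to 0$, $k_2$ at the grid floor).

## Arterial blood processing

`process_blood_monitor()` chains the corrections for a raw monitor recording:

- **Background.** An unflushed infusion line leaves residual activity that
  decays at the tracer rate and dominates the pre-bolus readings. The model
  $A_0 e^{-\lambda t}$ (rate fixed at the tracer $\lambda$) has a closed-form
  amplitude over a caller-chosen pre-bolus window; the fitted curve is
  subtracted and negatives floored at zero — after fitting, never before.
- **Calibration.** Division by the cross-calibration sensitivity and decay
  correction $e^{+\lambda t}$ to injection time.
- **Dispersion.** External dispersion in the sampling line is modeled as
  convolution with $\tau_d^{-1} e^{-t/\tau_d}$; the correction applies the
  derivative inverse $c(t) + \tau_d\,dc/dt$ with a 3-point moving-average
  pre-smooth. The method and time constant are this package's choice
  (default $\tau_d = 2.5$ s, configurable); derivative corrections overshoot
  at sharp edges, which is acceptable for smooth bolus shapes (round-trip
  relative RMS error under 2% over the peak) but a known limitation.
  Internal-body dispersion is deliberately not corrected.
- **Delay.** The LV-to-sampling-site delay is estimated by maximizing the
  Pearson correlation between the shifted, frame-averaged blood curve and an
  LV reference TAC over a ±30 s grid at 0.5 s steps (ties to the smallest
  absolute shift); correlation is computed on the frame grid, matching the
  reference's resolution. Because the LV reference carries a tissue
  fraction that lags the blood, the correlation optimum is biased by a
  fraction of a second; `estimate_delay_mixture()` removes this by scoring
  each candidate shift with the residual of a two-regressor fit (blood +
  tissue estimate). The study harness uses the correlation estimate for a
  first pass and the mixture variant, with a first-pass tissue estimate, for
  the final alignment.

Half-lives are 76.38 s (⁸²Rb) and 122.24 s (¹⁵O), stored as configurable
constants; decay constants are derived as $\ln 2 / T_{1/2}$.

## IDIF correction models

Four corrections of the LV TAC against the AIF gold standard, all by
weighted least squares (closed forms where they exist), sharing the NEC
weights of the LV TAC since the literature specifies WLS without naming
weights for these fits:

- one-parameter recovery mixture
  $C_{LV} = \beta C_A + (1-\beta) C_T$ (`fit_pvc1()`), with the tissue
  reference $C_T$ taken from the 3-parameter arterial-input fit of the
  global myocardium TAC; $\beta$ is estimated unconstrained and flagged, not
  clipped, outside $(0, 1]$ — an out-of-range estimate is diagnostic;
- two-parameter mixture $\beta_1 C_A + \beta_2 C_T$ (`fit_pvc2()`), whose
  sum $\beta_1 + \beta_2 < 1$ signals mixing with extra-cardiac signal;
- WLS scale $\beta_s$ (`fit_scale_wls()`), the optimal scalar multiple;
- AUC-ratio scale $\beta_{AUC}$ (`fit_scale_auc()`), never better than
  $\beta_s$ in WSS by construction, but the basis of the population
  correction: IDIFs are corrected by the reciprocal of the arithmetic mean
  per-scan $\beta_{AUC}$ per tracer (`population_scale_factor()`).

Nested models are compared with `f_test_nested()`.

## Flow estimation and the extraction fit

Water: $\mathrm{MBF} = k_2\,p$, $p = 0.91$ mL/g. Rubidium: the forward
relation is inverted by bracketed root finding on $[10^{-3}, 10]$ mL/min/g
(monotonicity is verified before inverting; $|\Delta m| < 10^{-8}$).

`fit_renkin_crone()` estimates $(a, b)$ by weighted orthogonal distance
regression: the objective
$\sum_i w_{x,i}(x_i - m_i)^2 + w_{y,i}(y_i - f(m_i))^2$ is minimized jointly
over the parameters and latent true flows $m_i$. The latent flows are
profiled out by a vectorized safeguarded Newton iteration (with a scalar
minimizer as fallback for stragglers), and the outer problem runs
Nelder-Mead on $(\mathrm{logit}\,a, \log b)$ from the default start
$(0.8, 0.5)$ plus a 5×5 grid over $a \in [0.5, 0.95]$, $b \in [0.2, 1.0]$ —
the objective can have shallow valleys at small $n$, and the best final
objective wins. Weights are the reciprocals of the per-measurement VOI voxel
variances on each axis; the unweighted variant (all weights 1) is exposed
because it is known to give higher parameter estimates. Standard errors come
from the linearized (Gauss-Newton) covariance of the full parameter vector
with $\sigma^2 = \mathrm{obj}/(n-2)$; a seeded bootstrap is available for
small samples. Estimates with $a \notin (0,1)$ or $b \le 0$ are flagged
unphysical rather than constrained away.

## Agreement statistics

Two conventions coexist deliberately: input-function validation metrics use
the arterial reference as denominator ($100(\mathrm{IDIF} -
\mathrm{AIF})/\mathrm{AIF}$, `percent_difference()`), whereas method
comparison of flows uses Bland-Altman percent differences normalized to the
pair mean, with the reproducibility coefficient defined as 1.96 times their
standard deviation (`bland_altman_percent()`). Deming regression defaults to
an error-variance ratio of 1 (not stated by the reference analyses) with
jackknife standard errors, and `lin_ccc()` uses population (1/n) moments.

## What the synthetic data emulates — and what it does not

`make_input_function()` produces a gamma-variate bolus
($(t-t_0)^\alpha e^{-(t-t_0)/\beta_g}$, $\alpha = 2$) normalized to a target
peak, plus an exponential recirculation tail anchored to a fraction of the
peak at 3 min, strictly zero before arrival — the observed bolus-plus-tail
morphology of measured arterial curves. The phantom
(`phantom_spec()`) is a concentric-cylinder heart — LV cavity, 10 mm
myocardial shell, separate RV cylinder — in a 48³ grid of
2.036 × 2.036 × 2.0 mm voxels: the smallest geometry exhibiting
LV/RV/myocardium spillover structure. Resolution is a Gaussian PSF applied
per frame *before* noise; noise is Gaussian with variance
$\propto \mathrm{value} \cdot e^{\lambda t_{mid}} / \Delta t$, the same
count-statistics family as the fitting weights, rather than a full Poisson
list-mode simulation — that keeps desk-scale runtime while preserving the
variance structure the weights assume. The arterial monitor model adds
transit delay, exponential dispersion, sensitivity, decay un-correction, a
decaying residual-activity background, and Gaussian noise, all from a single
integer seed.

The study harness (`run_simulation_study()`) simulates nine subjects at rest
(flows 0.96 ± 0.20 mL/min/g) and stress (3.73 ± 0.96 mL/min/g) — the
population means and SDs of healthy volunteers — with water and rubidium
scans per condition, rubidium $K_1$ generated from the extraction relation at
$(a, b) = (0.77, 0.39)$. Simulated IDIFs are a partially recovered blood
term ($\beta = 0.92$) plus a small myocardial spill-in fraction (0.03).
Three design choices keep the zero-noise ground-truth loop *exactly*
invertible, which is what makes the recovery tests sharp:

- the default monitor applies no external dispersion (the derivative-form
  correction is only approximate, so a dispersed-then-corrected chain cannot
  close the loop below 1%; dispersion is exercised in its own analyses);
- the monitor samples at the generator's resolution, so calibration and
  alignment reproduce the true curve node for node;
- the study fits the 3-parameter model (the primary analysis route for mean
  parameters); RV spillover terms are exercised by the phantom analyses and
  module tests instead, because a 4-parameter fit driven by an IDIF input
  confounds the RV regressor with the IDIF's own blood shape.

What passing these tests does *not* show about real data: the phantom has no
cardiac or respiratory motion, no attenuation or scatter residuals, no
ringing from resolution modeling, Gaussian rather than Poisson/iterative-
reconstruction noise, and spillover generated by the same Gaussian kernel
family the PSF assumes. Agreement on synthetic data is a check of the
estimators, not a validation of the acquisition chain.

## Problem sizes and runtime

The test suite and the acceptance script run on one CPU at desk scale by
choice of problem sizes: phantom recovery uses a 24³–48³ grid with a few
hundred to a few thousand fitted voxels (identical noiseless TACs are fitted
once and reused); the subject-level study fits 108 TAC models (9 subjects ×
2 conditions × 2 tracers × 3 input-function routes); the noisy
extraction-recovery experiment uses 500 replicates of 18 points with 5%
measurement noise per axis (the population tables report only
between-subject SDs, so a per-measurement noise level had to be set once —
5% is typical of VOI-mean kinetic parameter precision at these count
levels); optimizer-equivalence checks use 50 random noiseless TACs.

## Known limitations

- The dispersion correction is the derivative inverse with fixed $\tau_d$;
  no deconvolution option is provided, and $\tau_d$ is not estimated from
  data.
- The background window is caller-supplied; the automatic bolus-arrival
  heuristic (first sample exceeding 5× the window median) is simple and can
  fail on very noisy pre-bolus segments.
- ODR standard errors are asymptotic; at $n = 18$ they are serviceable
  (replicate experiments keep the truth within one SE) but the bootstrap
  option is preferable for smaller samples.
- The phantom's RV "crescent" is a cylinder; geometric realism was traded
  for exact analytic ground truth.
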