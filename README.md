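# mbfpet

Quantification of myocardial blood flow (MBF) from dynamic cardiac PET, for
imaging scientists working with ⁸²Rb and ¹⁵O-water perfusion studies.

Rubidium is only partially extracted by myocardium, and its extraction
fraction falls with flow. Turning a measured ⁸²Rb influx rate constant into a
flow therefore requires three pieces of machinery, all implemented here as a
tested, seedable pipeline:

- **Kinetic modeling** — the one-tissue compartment model with LV/RV
  spillover terms,
  `C_PET(t) = (1 − V_A − V_RV)·K1·e^(−k2·t) ⊗ C_A(t) + V_A·C_A(t) + V_RV·C_RV(t)`,
  fitted per TAC or per voxel by the basis function method with
  noise-equivalent-count weighted least squares (`fit_tac()`,
  `fit_parametric()`).
- **Input functions** — calibration of continuously sampled arterial blood
  (background subtraction, sensitivity/decay correction, dispersion and
  delay correction; `process_blood_monitor()`), and image-derived input
  functions with four correction models (one- and two-parameter
  partial-volume mixtures, WLS and AUC scale factors; `fit_pvc1()`,
  `fit_pvc2()`, `fit_scale_wls()`, `fit_scale_auc()`), compared by nested F
  tests.
- **The extraction model** — the generalized Renkin-Crone relation
  `K1 = MBF·(1 − a·e^(−b/MBF))`, fitted to paired water-based flows
  (`MBF = k2·p`, p = 0.91 mL/g) and rubidium K1 values by weighted
  orthogonal distance regression (`fit_renkin_crone()`), and inverted to
  estimate flow from K1 (`invert_renkin_crone()`). Shipped calibration:
  a = 0.77, b = 0.39 (AUC-scaled IDIFs) and a = 0.74, b = 0.51 (uncorrected
  IDIFs); see `extraction_defaults()`.

Method agreement is assessed with Deming regression, the Lin concordance
coefficient, and Bland-Altman analysis with the reproducibility coefficient
(`agreement_report()`). A synthetic-data module (`make_input_function()`,
`phantom_spec()`, `simulate_dynamic_pet()`, `simulate_blood_monitor()`)
generates input functions, a voxelized cardiac phantom, and arterial-monitor
recordings with exactly known ground truth.

## Worked example

Simulate a rest scan with known kinetics, fit it, and convert to flow:

```r
library(mbfpet)

sched <- default_frame_schedule()        # 20 x 3 s, 6 x 10 s, 6 x 20 s
aif   <- make_input_function()           # gamma-variate bolus + tail

# a myocardial TAC with known truth: K1 = 0.45 mL/min/g, k2 = 0.11/min
myo <- model_tac(k1 = 0.45, k2 = 0.11, v_a = 0.30, aif = aif, schedule = sched)

fit <- fit_tac(myo, aif, weights = nec_weights(myo, tracer_constants("rb82")))
fit
#> <kinetic_fit> 3-parameter 1TCM: K1 = 0.45 mL/min/g, k2 = 0.11 1/min, V_A = 0.3 (WSS 4.266e-20)

# flow from rubidium K1 via the shipped extraction calibration
cal <- extraction_defaults()$rb82$scaled_idif
mbf_from_rb_k1(fit$k1, cal["a"], cal["b"])
#> # A tibble: 1 x 4
#>     mbf source     a     b
#>   <dbl> <chr>  <dbl> <dbl>
#> 1 0.898 rb_K1   0.77  0.39
```

The recovered flow (~0.90 mL/min/g) is the unique root of the forward
extraction relation at the fitted K1. The full subject-level loop — arterial
monitor simulation and processing, IDIF scale correction, per-scan fits for
three input-function routes, and the weighted-ODR extraction fit — runs with

```r
study <- run_simulation_study(study_config(seed = 1))
study
#> <simulation_study> 9 subjects, 108 scan fits
#>   Renkin-Crone [aif]: a = 0.770, b = 0.390
#>   Renkin-Crone [idif_scaled]: a = 0.764, b = 0.421
#>   Renkin-Crone [idif_uncorrected]: a = 0.754, b = 0.457
```

At zero noise the arterial route reproduces the generating (a, b) to
numerical precision; the IDIF routes show the expected correction-dependent
shifts. See the methods vignette
(`vignettes/mbf-quantification-methods.Rmd`) for the models, assumptions,
and numerical choices.

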