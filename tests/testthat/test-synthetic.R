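test_that("synthetic input function has the designed bolus shape", {
  aif <- make_input_function()
  # deterministic, zero before bolus arrival
  expect_identical(aif$activity, make_input_function()$activity)
  expect_true(all(aif$activity[aif$time_s < 10] == 0))
  # peak equals peak_amp within 0.5% at the nominal peak time
  expect_lt(abs(max(aif$activity) - 30000) / 30000, 0.005)
  expect_lt(abs(aif$time_s[which.max(aif$activity)] - 30), 1)
  # recirculation tail level at 3 min
  at180 <- aif$activity[aif$time_s == 180]
  expect_equal(at180 / 30000, 0.15, tolerance = 0.01)
})

test_that("input function scales linearly and decays without a tail", {
  a1 <- make_input_function(peak_amp = 10000)
  a2 <- make_input_function(peak_amp = 20000)
  expect_equal(a2$activity, 2 * a1$activity)

  no_tail <- make_input_function(tail_frac = 0)
  late <- no_tail$activity[no_tail$time_s >= 240]
  expect_lt(max(late), 0.01 * max(no_tail$activity))
  expect_error(make_input_function(dt_s = 0), "dt_s")
  expect_error(make_input_function(tail_frac = 1), "tail_frac")
})

test_that("phantom regions are disjoint and sized plausibly", {
  spec <- phantom_spec()
  lab <- phantom_labels(spec)
  expect_setequal(unique(as.integer(lab)), c(0L, 1L, 2L, 3L))
  # shell thickness ~10 mm: outer minus inner radius
  counts <- table(lab)
  expect_gt(counts[["3"]], counts[["1"]]) # shell bigger than cavity
  expect_error(phantom_spec(myocardium = list(k1 = 1, k2 = 1, v_a = 0.7, v_rv = 0.4)))
})

test_that("noiseless simulation reproduces the forward model exactly", {
  sched <- test_schedule()
  aif <- test_aif()
  rvif <- test_rvif()
  spec <- phantom_spec(shape = c(24, 24, 16), height_mm = 24)
  sim <- simulate_dynamic_pet(spec, aif, rvif, sched, noise_scale = 0, seed = 1)
  lab <- sim$labels
  nv <- prod(dim(lab))
  m <- spec$myocardium
  mt <- model_tac(m$k1, m$k2, m$v_a, m$v_rv, aif, rvif, sched)$value
  idx <- which(lab == 3L)[1]
  vox <- vapply(seq_len(32), function(f) sim$image[idx + (f - 1) * nv], numeric(1))
  expect_lt(max(abs(vox - mt)), 1e-9)

  # mass consistency: LV-center voxel equals the frame-averaged input
  lv <- which(lab == 1L)[1]
  voxlv <- vapply(seq_len(32), function(f) sim$image[lv + (f - 1) * nv], numeric(1))
  expect_lt(max(abs(voxlv - frame_average(aif, sched)$value)), 1e-9)
})

test_that("simulation with the same seed is bit-identical", {
  sched <- test_schedule()
  aif <- test_aif(dt = 0.5)
  rvif <- test_rvif(dt = 0.5)
  spec <- phantom_spec(shape = c(16, 16, 8), height_mm = 12, psf_sigma_mm = 3)
  s1 <- simulate_dynamic_pet(spec, aif, rvif, sched, noise_scale = 5, seed = 42)
  s2 <- simulate_dynamic_pet(spec, aif, rvif, sched, noise_scale = 5, seed = 42)
  expect_identical(s1$image, s2$image)
  s3 <- simulate_dynamic_pet(spec, aif, rvif, sched, noise_scale = 5, seed = 43)
  expect_false(identical(s1$image, s3$image))
})

test_that("resolution blur inflates fitted V_A next to the LV cavity", {
  sched <- test_schedule()
  aif <- test_aif()
  rvif <- test_rvif()
  spec <- phantom_spec(shape = c(32, 32, 12), height_mm = 16, psf_sigma_mm = 6)
  sim <- simulate_dynamic_pet(spec, aif, rvif, sched, noise_scale = 0, seed = 1)
  lab <- sim$labels
  # innermost myocardial ring: adjacent to the LV cavity
  spec0 <- spec
  mid_z <- 6L
  sl <- lab[, , mid_z]
  vx <- spec$voxel_mm
  cx <- (seq_len(32) - 16.5) * vx[1]
  cy <- (seq_len(32) - 16.5) * vx[2]
  r <- sqrt(outer((cx - spec$lv_center_mm[1])^2, (cy - spec$lv_center_mm[2])^2, `+`))
  inner <- which(sl == 3L & r < spec$lv_radius_mm + 4, arr.ind = TRUE)
  i <- inner[1, ]
  nv <- prod(dim(lab))
  flat <- (i[2] - 1) * 32 + i[1] + (mid_z - 1) * 32 * 32
  vox <- vapply(seq_len(32), function(f) sim$image[flat + (f - 1) * nv], numeric(1))
  w <- nec_weights(tac(sched, pmax(vox, 0)), tracer_constants("rb82"))
  fit <- fit_tac(tac(sched, vox), aif, weights = w)
  expect_gt(fit$v_a, spec$myocardium$v_a)
})

test_that("blood monitor identity configuration returns the decay-uncorrected input", {
  aif <- test_aif()
  tr <- tracer_constants("rb82")
  spec <- monitor_spec(delay_s = 0, tau_d_s = 0, background_a0 = 0,
    sensitivity = 1, sample_dt_s = 1, noise_sd = 0)
  raw <- simulate_blood_monitor(aif, spec, tracer = tr)
  sel <- match(raw$time_s, aif$time_s)
  expect_lt(
    max(abs(raw$activity - aif$activity[sel] * exp(-tr$lambda_s * raw$time_s))),
    1e-9 * max(aif$activity)
  )
})

test_that("monitor delay shifts the peak and background decays at lambda", {
  aif <- test_aif()
  tr <- tracer_constants("rb82")
  base <- simulate_blood_monitor(
    aif, monitor_spec(delay_s = 0, tau_d_s = 0, sample_dt_s = 0.5), tr
  )
  delayed <- simulate_blood_monitor(
    aif, monitor_spec(delay_s = 10, tau_d_s = 0, sample_dt_s = 0.5), tr
  )
  t_peak0 <- base$time_s[which.max(base$activity)]
  t_peak1 <- delayed$time_s[which.max(delayed$activity)]
  expect_equal(t_peak1 - t_peak0, 10, tolerance = 0.5)

  withbg <- simulate_blood_monitor(
    aif, monitor_spec(delay_s = 5, tau_d_s = 0, background_a0 = 800), tr
  )
  pre <- withbg$time_s < 10 # before bolus arrival at the monitor
  fitted <- 800 * exp(-tr$lambda_s * withbg$time_s[pre])
  expect_lt(max(abs(withbg$activity[pre] - fitted) / fitted), 0.01)
})

test_that("full parameter-recovery loop closes at zero noise", {
  sched <- test_schedule()
  aif <- test_aif()
  rvif <- test_rvif()
  spec <- phantom_spec(shape = c(20, 20, 8), height_mm = 12)
  sim <- simulate_dynamic_pet(spec, aif, rvif, sched, noise_scale = 0, seed = 1)
  m <- spec$myocardium
  mask <- sim$labels == 3L
  w <- nec_weights(
    tac(sched, model_tac(m$k1, m$k2, m$v_a, m$v_rv, aif, rvif, sched)$value),
    tracer_constants("rb82")
  )
  maps <- fit_parametric(sim$image, aif, rvif, mask,
    weights = w, schedule = sched
  )
  expect_lt(max(abs(maps$k1[mask] - m$k1) / m$k1), 1e-3)
  expect_lt(max(abs(maps$k2[mask] - m$k2) / m$k2), 1e-3)
  expect_lt(max(abs(maps$v_a[mask] - m$v_a) / m$v_a), 1e-3)
  expect_lt(max(abs(maps$v_rv[mask] - m$v_rv) / m$v_rv), 1e-3)
})
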