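sched <- test_schedule()
rb <- tracer_constants("rb82")

test_that("the model TAC reduces correctly in limiting cases", {
  aif <- test_aif()
  rvif <- test_rvif()
  fa_a <- frame_average(aif, sched)$value
  fa_rv <- frame_average(rvif, sched)$value

  # K1 = 0: pure blood mixture
  m0 <- model_tac(0, 0.5, 0.3, 0.1, aif, rvif, sched)
  expect_equal(m0$value, 0.3 * fa_a + 0.1 * fa_rv, tolerance = 1e-12)

  # k2 = 0: tissue term is the running integral of the input
  mk <- model_tac(1, 0, 0, 0, aif, schedule = sched)
  tt <- aif$time_s
  cumint <- c(0, cumsum((aif$activity[-1] + aif$activity[-length(tt)]) / 2 * diff(tt)))
  oracle <- vapply(seq_len(32), function(j) {
    sel <- tt >= sched$start_s[j] & tt < sched$end_s[j]
    mean(cumint[sel])
  }, numeric(1)) / 60 * 1.05
  expect_lt(max(abs(mk$value - oracle) / max(oracle)), 1e-3)
})

test_that("analytic convolution matches a 1 ms Riemann-sum oracle", {
  aif <- test_aif()
  got <- model_tac(0.8, 1.0, 0.3, 0, aif, schedule = sched)$value
  ct <- riemann_tissue_tac(aif, 1.0, sched) * 0.8 * 1.05
  oracle <- (1 - 0.3) * ct + 0.3 * frame_average(aif, sched)$value
  expect_lt(max(abs(got - oracle) / max(oracle)), 5e-4)
})

test_that("NEC weights follow the duration/decay/counts formula", {
  x <- tac(sched, rep(100, 32))
  lam0 <- tracer_constants("o15_water")
  # lambda -> 0 and equal counts: weights proportional to duration
  w <- nec_weights(x, rb)
  dcf <- exp(rb$lambda_s * sched$mid_s)
  manual <- sched$duration_s^2 / dcf^2 / (100 * sched$duration_s)
  expect_equal(w$weight, manual / mean(manual))

  # equal durations, equal counts, lambda ~ 0 -> weights equal
  eq <- frame_schedule(seq(0, 90, 10), seq(10, 100, 10))
  xeq <- tac(eq, rep(50, 10))
  slow <- tracer_constants("o15_water")
  slow$lambda_s <- 1e-12
  weq <- nec_weights(xeq, slow)
  expect_equal(weq$weight, rep(1, 10), tolerance = 1e-6)

  # doubling the TAC leaves normalized weights unchanged
  w2 <- nec_weights(tac(sched, rep(200, 32)), rb)
  expect_equal(w2$weight, w$weight)
  expect_error(nec_weights(tac(sched, rep(0, 32)), rb), "all-zero")
})

test_that("basis columns behave like tissue responses", {
  aif <- test_aif()
  grid <- c(0.05, 0.2, 1, 4)
  B <- make_basis(grid, aif, sched)
  # columns decrease with k2 at any late frame for a bolus input
  expect_true(all(diff(B[32, ]) < 0))
  expect_true(all(diff(B[25, ]) < 0))
  # basis * K1 reproduces the model's tissue term exactly for on-grid k2
  m <- model_tac(0.7, 0.2, 0, 0, aif, schedule = sched)$value
  expect_equal(B[, 2] * 0.7 * 1.05, m, tolerance = 1e-12)
  expect_error(make_basis(numeric(0), aif, sched), "empty")
})

test_that("noiseless TACs are recovered exactly, on and off the grid", {
  aif <- test_aif()
  w <- uniform_weights(sched)
  x <- model_tac(0.8, default_k2_grid()[60], 0.3, 0, aif, schedule = sched)
  fit <- fit_tac(x, aif, weights = w, refine = FALSE)
  expect_lt(abs(fit$k1 - 0.8) / 0.8, 1e-8)
  expect_lt(abs(fit$k2 - default_k2_grid()[60]) / default_k2_grid()[60], 1e-8)
  expect_lt(abs(fit$v_a - 0.3) / 0.3, 1e-8)

  # off-grid k2 recovered through golden-section refinement
  x2 <- model_tac(0.5, 0.37, 0.25, 0, aif, schedule = sched)
  fit2 <- fit_tac(x2, aif, weights = w)
  expect_lt(abs(fit2$k2 - 0.37) / 0.37, 1e-5)
  expect_lt(abs(fit2$k1 - 0.5) / 0.5, 1e-5)
})

test_that("a pure blood TAC lands on the blood-fraction boundary with K1 = 0", {
  aif <- test_aif()
  w <- uniform_weights(sched)
  x <- frame_average(aif, sched)
  fit <- fit_tac(x, aif, weights = w)
  expect_true(fit$boundary)
  expect_equal(fit$k1, 0)
  expect_equal(fit$v_a, 0.999, tolerance = 1e-6)
})

test_that("basis-function fits agree with the brute-force nonlinear optimizer", {
  aif <- test_aif()
  w <- uniform_weights(sched)$weight
  basis <- make_basis(default_k2_grid(), aif, sched)
  set.seed(11)
  for (i in 1:12) {
    k1 <- runif(1, 0.2, 2)
    k2 <- runif(1, 0.05, 4)
    va <- runif(1, 0.05, 0.5)
    x <- model_tac(k1, k2, va, 0, aif, schedule = sched)
    fit <- fit_tac(x, aif, weights = w, basis = basis)
    oracle <- brute_fit_1tcm(x$value, aif, w, sched)
    expect_lt(abs(fit$k1 - oracle$k1) / oracle$k1, 1e-3)
    expect_lt(abs(fit$k2 - oracle$k2) / oracle$k2, 1e-3)
    expect_lt(abs(fit$wss - oracle$wss), 1e-10 * sum(w * x$value^2))
  }
})

test_that("adding the RV term never increases the weighted residual", {
  aif <- test_aif()
  rvif <- test_rvif()
  w <- uniform_weights(sched)
  set.seed(5)
  for (i in 1:8) {
    vals <- model_tac(runif(1, 0.3, 1.5), runif(1, 0.1, 2), runif(1, 0.1, 0.4),
      runif(1, 0, 0.2), aif, rvif, sched)$value
    vals <- pmax(vals * (1 + rnorm(32, 0, 0.05)), 0)
    x <- tac(sched, vals)
    f3 <- fit_tac(x, aif, weights = w, refine = FALSE)
    f4 <- fit_tac(x, aif, rvif = rvif, weights = w, refine = FALSE)
    expect_lte(f4$wss, f3$wss + 1e-9 * (1 + f3$wss))
  }
})

test_that("fits are equivariant under joint rescaling of TAC and input", {
  aif <- test_aif()
  w <- uniform_weights(sched)
  x <- model_tac(0.9, 0.5, 0.2, 0, aif, schedule = sched)
  f1 <- fit_tac(x, aif, weights = w)
  c0 <- 3.7
  aif2 <- blood_curve(aif$time_s, aif$activity * c0)
  x2 <- tac(sched, x$value * c0)
  f2 <- fit_tac(x2, aif2, weights = w)
  expect_equal(f2$k1, f1$k1, tolerance = 1e-8)
  expect_equal(f2$k2, f1$k2, tolerance = 1e-8)
  expect_equal(f2$v_a, f1$v_a, tolerance = 1e-8)
})

test_that("median K1 bias stays small on noisy simulated myocardial TACs", {
  aif <- test_aif()
  truth <- model_tac(0.6, 0.2, 0.3, 0, aif, schedule = sched)$value
  basis <- make_basis(default_k2_grid(), aif, sched)
  w <- nec_weights(tac(sched, truth), rb)
  set.seed(99)
  n <- 100
  k1s <- numeric(n)
  for (i in seq_len(n)) {
    sd_f <- 0.05 * sqrt(pmax(truth, 0) * exp(rb$lambda_s * sched$mid_s) / sched$duration_s)
    noisy <- pmax(truth + rnorm(32, 0, sd_f), 0)
    k1s[i] <- fit_tac(tac(sched, noisy), aif,
      weights = w, basis = basis,
      refine = FALSE
    )$k1
  }
  expect_lt(abs(median(k1s) - 0.6) / 0.6, 0.03)
})

test_that("parametric fitting matches single-TAC fits and is deterministic", {
  aif <- test_aif()
  rvif <- test_rvif()
  spec <- phantom_spec(shape = c(12, 12, 6), height_mm = 8)
  sim <- simulate_dynamic_pet(spec, aif, rvif, sched, noise_scale = 2, seed = 3)
  w <- nec_weights(
    tac(sched, frame_average(aif, sched)$value), rb
  )
  mask <- array(FALSE, dim = dim(sim$labels))
  vox <- which(sim$labels == 3L)[1]
  mask[vox] <- TRUE
  maps <- fit_parametric(sim$image, aif, rvif, mask, weights = w, schedule = sched)
  nv <- prod(dim(sim$labels))
  tacvals <- vapply(seq_len(32), function(f) sim$image[vox + (f - 1) * nv], numeric(1))
  single <- fit_tac(tac(sched, tacvals), aif, rvif = rvif, weights = w)
  expect_equal(maps$k1[vox], single$k1)
  expect_equal(maps$k2[vox], single$k2)
  expect_equal(maps$v_rv[vox], single$v_rv)

  maps2 <- fit_parametric(sim$image, aif, rvif, mask, weights = w, schedule = sched)
  expect_identical(maps$k1, maps2$k1)
  expect_error(
    fit_parametric(sim$image, aif, rvif, array(FALSE, dim(sim$labels)),
      weights = w, schedule = sched
    ),
    "empty mask"
  )
})

test_that("VOI statistics match direct formulas", {
  vol <- array(0, dim = c(4, 4, 2))
  vol[1, 1, 1] <- 0.4
  vol[2, 1, 1] <- 0.6
  voi <- array(FALSE, dim = dim(vol))
  voi[1:2, 1, 1] <- TRUE
  s <- voi_stats(vol, voi)
  expect_equal(s$mean, 0.5)
  expect_equal(s$variance, 0.02)
  expect_equal(s$n_voxels, 2L)

  set.seed(2)
  vol2 <- array(rnorm(32), dim = c(4, 4, 2))
  voi2 <- array(runif(32) > 0.5, dim = dim(vol2))
  s2 <- voi_stats(vol2, voi2)
  expect_equal(s2$mean, mean(vol2[voi2]))
  expect_equal(s2$variance, var(vol2[voi2]))

  # constant map: zero variance; failures excluded
  vol3 <- array(2, dim = c(2, 2, 1))
  vol3[1, 1, 1] <- NA
  s3 <- voi_stats(vol3, array(TRUE, dim = dim(vol3)))
  expect_equal(s3$mean, 2)
  expect_equal(s3$variance, 0)
  expect_equal(s3$n_voxels, 3L)
  expect_error(voi_stats(vol3 * NA, array(TRUE, dim = dim(vol3))), "empty VOI")
})
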