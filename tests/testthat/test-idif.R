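sched <- test_schedule()
rb <- tracer_constants("rb82")

test_that("VOI TAC extraction averages the selected voxels per frame", {
  img <- array(0, dim = c(4, 4, 2, 32))
  for (f in 1:32) img[, , , f] <- f * 2
  voi <- array(TRUE, dim = c(4, 4, 2))
  x <- extract_voi_tac(img, voi, sched)
  expect_equal(x$value, (1:32) * 2)
  expect_error(extract_voi_tac(img, array(FALSE, dim = c(4, 4, 2)), sched), "empty")
})

test_that("an LV-center VOI in the unblurred phantom returns the input exactly", {
  aif <- test_aif()
  rvif <- test_rvif()
  spec <- phantom_spec(shape = c(20, 20, 8), height_mm = 10)
  sim <- simulate_dynamic_pet(spec, aif, rvif, sched, noise_scale = 0, seed = 1)
  x <- extract_voi_tac(sim$image, sim$labels, sched, label = 1L)
  expect_lt(
    max(abs(x$value - frame_average(aif, sched)$value)),
    1e-9 * max(aif$activity)
  )
})

test_that("a 6.5 mL VOI at scanner voxel size holds 784 voxels", {
  expect_equal(voi_voxel_count(6.5), 784)
})

test_that("the reference tissue curve is recovered from a clean myocardial TAC", {
  aif <- test_aif()
  k1 <- 0.7
  k2 <- 0.4
  myo <- model_tac(k1, k2, 0.25, 0, aif, schedule = sched)
  w <- nec_weights(myo, rb)
  ct <- estimate_reference_tissue(myo, aif, w)
  truth <- model_tac(k1, k2, 0, 0, aif, schedule = sched)$value
  expect_lt(max(abs(ct$value - truth)) / max(truth), 1e-3)
  expect_true(all(ct$value >= 0))

  # pure blood input: tissue component collapses to zero
  blood <- frame_average(aif, sched)
  ct0 <- estimate_reference_tissue(blood, aif, nec_weights(blood, rb))
  expect_lt(max(ct0$value) / max(blood$value), 1e-3)
})

test_that("the one-parameter recovery model estimates beta exactly", {
  aif <- test_aif()
  ca <- frame_average(aif, sched)$value
  ct <- tac(sched, model_tac(0.7, 0.4, 0, 0, aif, schedule = sched)$value)
  w <- uniform_weights(sched)

  lv <- tac(sched, 0.85 * ca + 0.15 * ct$value)
  f <- fit_pvc1(lv, aif, ct, w)
  expect_equal(unname(f$coef["beta"]), 0.85, tolerance = 1e-10)
  expect_false(f$out_of_range)

  f1 <- fit_pvc1(tac(sched, ca), aif, ct, w)
  expect_equal(unname(f1$coef["beta"]), 1, tolerance = 1e-10)
  expect_error(fit_pvc1(lv, aif, tac(sched, ca), w), "degenerate")
})

test_that("the two-parameter model frees the coefficient sum and nests pvc1", {
  aif <- test_aif()
  ca <- frame_average(aif, sched)$value
  ct <- tac(sched, model_tac(0.7, 0.4, 0, 0, aif, schedule = sched)$value)
  w <- uniform_weights(sched)

  lv <- tac(sched, 0.8 * ca + 0.1 * ct$value)
  f <- fit_pvc2(lv, aif, ct, w)
  expect_equal(unname(f$coef["beta1"]), 0.8, tolerance = 1e-8)
  expect_equal(unname(f$coef["beta2"]), 0.1, tolerance = 1e-8)
  expect_equal(unname(f$coef["beta_sum"]), 0.9, tolerance = 1e-8)

  pure <- fit_pvc2(tac(sched, ca), aif, ct, w)
  expect_equal(unname(pure$coef["beta1"]), 1, tolerance = 1e-8)
  expect_equal(unname(pure$coef["beta2"]), 0, tolerance = 1e-8)

  # algebraic nesting: an exact pvc1 mixture is fitted identically by pvc2
  lvn <- tac(sched, 0.85 * ca + 0.15 * ct$value)
  f1 <- fit_pvc1(lvn, aif, ct, w)
  f2 <- fit_pvc2(lvn, aif, ct, w)
  expect_equal(f2$wss, f1$wss, tolerance = 1e-9)
  expect_equal(unname(f2$coef["beta_sum"]), 1, tolerance = 1e-8)
})

test_that("the WLS scale factor is the weighted projection and optimal", {
  # hand-computed 3-frame example: beta_s = (1 + 4 + 6)/(1 + 4 + 4) = 11/9
  s3 <- frame_schedule(0:2, 1:3)
  lv <- tac(s3, c(1, 2, 3))
  a3 <- tac(s3, c(1, 2, 2))
  f <- fit_scale_wls(lv, a3, uniform_weights(s3))
  expect_equal(unname(f$coef["beta_s"]), 11 / 9, tolerance = 1e-12)

  # optimality among all scalar multiples, by grid scan
  cand <- seq(0.5, 2, by = 1e-3)
  sse <- vapply(cand, function(b) sum((c(1, 2, 3) - b * c(1, 2, 2))^2), numeric(1))
  expect_equal(unname(f$coef["beta_s"]), cand[which.min(sse)], tolerance = 1e-3)

  aif <- test_aif()
  lv9 <- tac(sched, 0.9 * frame_average(aif, sched)$value)
  f9 <- fit_scale_wls(lv9, aif, uniform_weights(sched))
  expect_equal(unname(f9$coef["beta_s"]), 0.9, tolerance = 1e-10)
})

test_that("the AUC scale factor is the area ratio, never beating WLS on WSS", {
  aif <- test_aif()
  ca <- frame_average(aif, sched)$value
  w <- nec_weights(tac(sched, ca), rb)

  same <- fit_scale_auc(tac(sched, ca), aif, w)
  expect_equal(unname(same$coef["beta_auc"]), 1, tolerance = 1e-12)

  lv <- tac(sched, 0.92 * ca)
  f <- fit_scale_auc(lv, aif, w)
  expect_equal(unname(f$coef["beta_auc"]), 0.92, tolerance = 1e-10)
  expect_equal(round(1 / unname(f$coef["beta_auc"]), 2), 1.09)

  # WSS(auc) >= WSS(wls) for mixtures that are not pure rescalings
  ct <- model_tac(0.7, 0.4, 0, 0, aif, schedule = sched)$value
  mix <- tac(sched, 0.9 * ca + 0.08 * ct)
  expect_gte(
    fit_scale_auc(mix, aif, w)$wss,
    fit_scale_wls(mix, aif, w)$wss - 1e-9
  )
})

test_that("scale application is multiplicative and idempotent at scan level", {
  aif <- test_aif()
  ca <- frame_average(aif, sched)$value
  lv <- tac(sched, 0.92 * ca)
  expect_equal(apply_scale(lv, 1)$value, lv$value)

  b <- unname(fit_scale_auc(lv, aif)$coef["beta_auc"])
  corrected <- apply_scale(lv, 1 / b)
  expect_equal(
    unname(fit_scale_auc(corrected, aif)$coef["beta_auc"]), 1,
    tolerance = 1e-10
  )
  expect_error(apply_scale(lv, 0), "positive")

  expect_equal(population_scale_factor(c(0.92, 0.92)), 1 / 0.92)
})

test_that("consistent estimators on an exact recovery-mixture scan", {
  aif <- test_aif()
  ca <- frame_average(aif, sched)$value
  ct <- tac(sched, model_tac(0.6, 0.3, 0, 0, aif, schedule = sched)$value)
  beta <- 0.88
  lv <- tac(sched, beta * ca + (1 - beta) * ct$value)
  w <- uniform_weights(sched)
  expect_equal(unname(fit_pvc1(lv, aif, ct, w)$coef["beta"]), beta, tolerance = 1e-9)
  p2 <- fit_pvc2(lv, aif, ct, w)
  expect_equal(unname(p2$coef["beta1"]), beta, tolerance = 1e-7)
  expect_equal(unname(p2$coef["beta2"]), 1 - beta, tolerance = 1e-7)
  implied_auc <- sum(lv$value * sched$duration_s) / sum(ca * sched$duration_s)
  expect_equal(unname(fit_scale_auc(lv, aif)$coef["beta_auc"]), implied_auc)
})

test_that("nested F tests follow the ratio-of-variances formula", {
  r <- list(wss = 2, n_params = 1L)
  f <- list(wss = 1, n_params = 2L)
  res <- f_test_nested(r, f, 32)
  expect_equal(res$f_statistic, 30)
  expect_equal(res$df1, 1L)
  expect_equal(res$df2, 30L)
  # reference distribution oracle
  expect_equal(res$p_value, pf(30, 1, 30, lower.tail = FALSE))
  expect_lt(res$p_value, 0.001)

  tie <- f_test_nested(list(wss = 1, n_params = 1L), list(wss = 1, n_params = 2L), 32)
  expect_equal(tie$f_statistic, 0)
  expect_equal(tie$p_value, 1)
  expect_error(f_test_nested(f, r, 32), "more parameters")
  expect_error(f_test_nested(r, f, 2), "frames")
})
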