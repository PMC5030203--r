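# Shared fixtures and independent oracles used across the suite.

test_schedule <- function() default_frame_schedule()

test_aif <- function(dt = 0.1) {
  make_input_function(dt_s = dt)
}

test_rvif <- function(dt = 0.1) {
  make_input_function(peak_time_s = 25, peak_amp = 25000, dt_s = dt)
}

# Left-Riemann-sum oracle for the exponential convolution at fine dt,
# independent of the package's analytic segment integration. Returns the
# frame-averaged tissue curve for unit K1 (per-minute time base).
riemann_tissue_tac <- function(aif, k2_per_min, schedule, dt = 0.001) {
  tt <- seq(0, max(schedule$end_s), by = dt)
  ca <- approx(aif$time_s, aif$activity, xout = tt, yleft = 0, rule = 2)$y
  k <- k2_per_min / 60
  dec <- exp(-k * dt)
  conv <- numeric(length(tt))
  acc <- 0
  for (i in seq_along(tt)[-1]) {
    acc <- acc * dec + ca[i - 1] * dt
    conv[i] <- acc
  }
  conv <- conv / 60
  vapply(seq_len(nrow(schedule)), function(j) {
    sel <- tt >= schedule$start_s[j] & tt < schedule$end_s[j]
    mean(conv[sel])
  }, numeric(1))
}

# Brute-force nonlinear WLS oracle for the 3-parameter compartment fit:
# direct simplex minimization over (K1, k2, V_A) with multi-start, using the
# forward model only (no basis-function linearization).
brute_fit_1tcm <- function(tacv, aif, w, schedule,
                           starts = list(c(0.5, 0.5, 0.2), c(1, 2, 0.4),
                             c(0.2, 0.1, 0.1), c(2, 5, 0.3))) {
  obj <- function(par) {
    k1 <- exp(par[1])
    k2 <- exp(par[2])
    va <- plogis(par[3]) * 0.999
    pred <- model_tac(k1, k2, va, aif = aif, schedule = schedule)$value
    sum(w * (tacv - pred)^2)
  }
  best <- NULL
  for (s in starts) {
    par0 <- c(log(s[1]), log(s[2]), qlogis(s[3] / 0.999))
    opt <- optim(par0, obj, method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  list(
    k1 = exp(best$par[1]), k2 = exp(best$par[2]),
    v_a = plogis(best$par[3]) * 0.999, wss = best$value
  )
}
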