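# Run code with a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Synthetic arterial input function
#'
#' Generates a deterministic ground-truth input function: a gamma-variate
#' bolus \eqn{(t - t_0)^\alpha e^{-(t - t_0)/\beta_g}}, scaled so its maximum
#' equals `peak_amp` at `peak_time_s`, plus an exponential recirculation tail
#' that switches on after the bolus (logistic onset) and equals
#' `tail_frac * peak_amp` at 3 minutes. The curve is zero before bolus
#' arrival. This emulates the bolus-plus-tail morphology of measured arterial
#' curves.
#'
#' @param peak_time_s Time of the bolus peak, s.
#' @param peak_amp Peak activity, Bq/mL (> 0).
#' @param tail_frac Recirculation tail level at 3 min as a fraction of the
#'   peak, in `[0, 1)`.
#' @param tracer [tracer_constants()] metadata attached to the curve.
#' @param dt_s Sampling interval, s (> 0).
#' @param duration_s Total curve duration, s.
#' @param onset_s Bolus arrival time \eqn{t_0}, s.
#' @param alpha Gamma-variate shape exponent.
#' @param tail_decay_s Recirculation tail decay time constant, s.
#' @return A [blood_curve()] sampled at `dt_s`.
#' @export
make_input_function <- function(peak_time_s = 30, peak_amp = 30000,
                                tail_frac = 0.15,
                                tracer = tracer_constants("rb82"),
                                dt_s = 0.1, duration_s = 300,
                                onset_s = 10, alpha = 2,
                                tail_decay_s = 600) {
  if (dt_s <= 0) stop("dt_s must be positive")
  if (peak_amp <= 0) stop("peak_amp must be positive")
  if (tail_frac < 0 || tail_frac >= 1) stop("tail_frac must be in [0, 1)")
  if (peak_time_s <= onset_s) stop("peak must come after bolus onset")
  time_s <- seq(0, duration_s, by = dt_s)
  beta_g <- (peak_time_s - onset_s) / alpha
  u <- pmax(time_s - onset_s, 0)
  bolus <- (u / (alpha * beta_g))^alpha * exp(alpha - u / beta_g)
  bolus[u == 0] <- 0
  # recirculation: logistic onset well after the peak, slow exponential decay,
  # anchored to tail_frac * peak_amp at t = 180 s
  onset <- 1 / (1 + exp(-(time_s - (peak_time_s + 60)) / 10))
  tail <- tail_frac * onset * exp(-(time_s - 180) / tail_decay_s)
  tail[u == 0] <- 0 # strictly zero before bolus arrival
  blood_curve(time_s, peak_amp * (bolus + tail),
    tracer = tracer, calibrated = TRUE
  )
}

#' Specification of the digital cardiac phantom
#'
#' A concentric-cylinder cardiac phantom: an LV cavity cylinder surrounded by
#' a myocardial shell, with a separate RV cavity cylinder beside it, embedded
#' in a zero background. Each region carries true one-tissue-compartment
#' parameters, so simulated images have exactly known ground truth.
#'
#' @param shape Grid dimensions in voxels (length 3).
#' @param voxel_mm Voxel size, mm.
#' @param lv_center_mm x/y offset of the LV axis from grid center, mm.
#' @param lv_radius_mm LV cavity radius, mm.
#' @param shell_thickness_mm Myocardial shell thickness, mm.
#' @param rv_center_mm x/y offset of the RV cavity axis, mm.
#' @param rv_radius_mm RV cavity radius, mm (0 disables the RV region).
#' @param height_mm Cylinder height, mm.
#' @param myocardium Named list of true myocardial parameters `k1` (mL/min/g),
#'   `k2` (1/min), `v_a`, `v_rv`.
#' @param psf_sigma_mm Gaussian blur sigma, mm (resolution/spillover model).
#' @param density_g_ml Tissue density, g/mL.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(shape = c(48, 48, 48),
                         voxel_mm = c(2.036, 2.036, 2.0),
                         lv_center_mm = c(12, 0),
                         lv_radius_mm = 14,
                         shell_thickness_mm = 10,
                         rv_center_mm = c(-24, 0),
                         rv_radius_mm = 10,
                         height_mm = 60,
                         myocardium = list(k1 = 0.8, k2 = 1.0, v_a = 0.3, v_rv = 0.05),
                         psf_sigma_mm = 0,
                         density_g_ml = 1.05) {
  stopifnot(
    length(shape) == 3, all(shape >= 4), length(voxel_mm) == 3,
    all(voxel_mm > 0), lv_radius_mm > 0, shell_thickness_mm > 0,
    rv_radius_mm >= 0, height_mm > 0, psf_sigma_mm >= 0
  )
  m <- myocardium
  stopifnot(
    m$k1 >= 0, m$k2 >= 0, m$v_a >= 0, m$v_rv >= 0,
    m$v_a + m$v_rv < 1
  )
  structure(
    list(
      shape = as.integer(shape), voxel_mm = as.double(voxel_mm),
      lv_center_mm = lv_center_mm, lv_radius_mm = lv_radius_mm,
      shell_thickness_mm = shell_thickness_mm,
      rv_center_mm = rv_center_mm, rv_radius_mm = rv_radius_mm,
      height_mm = height_mm, myocardium = m,
      psf_sigma_mm = psf_sigma_mm, density_g_ml = density_g_ml
    ),
    class = "phantom_spec"
  )
}

#' Region label volume of the phantom
#'
#' @param spec A [phantom_spec()].
#' @return Integer 3D array: 0 background, 1 LV cavity, 2 RV cavity,
#'   3 myocardial shell. Regions are disjoint by construction.
#' @export
phantom_labels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$shape
  vx <- spec$voxel_mm
  cx <- (seq_len(n[1]) - (n[1] + 1) / 2) * vx[1]
  cy <- (seq_len(n[2]) - (n[2] + 1) / 2) * vx[2]
  cz <- (seq_len(n[3]) - (n[3] + 1) / 2) * vx[3]
  lab <- array(0L, dim = n)
  in_z <- abs(cz) <= spec$height_mm / 2
  r_lv <- sqrt(outer((cx - spec$lv_center_mm[1])^2, (cy - spec$lv_center_mm[2])^2, `+`))
  r_rv <- sqrt(outer((cx - spec$rv_center_mm[1])^2, (cy - spec$rv_center_mm[2])^2, `+`))
  outer_r <- spec$lv_radius_mm + spec$shell_thickness_mm
  for (k in which(in_z)) {
    sl <- lab[, , k]
    sl[r_lv <= spec$lv_radius_mm] <- 1L
    sl[r_lv > spec$lv_radius_mm & r_lv <= outer_r] <- 3L
    if (spec$rv_radius_mm > 0) sl[r_rv <= spec$rv_radius_mm & sl == 0L] <- 2L
    lab[, , k] <- sl
  }
  lab
}

# Separable 3D Gaussian blur, sigma in mm per axis; zero padding outside the
# grid (kernel normalized to unit sum, so interior regions are conserved).
gaussian_blur_3d <- function(vol, sigma_mm, voxel_mm) {
  if (all(sigma_mm <= 0)) return(vol)
  if (length(sigma_mm) == 1L) sigma_mm <- rep(sigma_mm, 3L)
  d <- dim(vol)
  for (ax in 1:3) {
    sig <- sigma_mm[ax] / voxel_mm[ax]
    if (sig <= 0) next
    r <- max(1L, ceiling(4 * sig))
    kern <- stats::dnorm(seq(-r, r), sd = sig)
    kern <- kern / sum(kern)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1L & j <= n
      K[i, j[ok]] <- kern[ok]
    }
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    dv <- dim(v)
    v <- K %*% matrix(v, nrow = n)
    dim(v) <- dv
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Simulate a dynamic PET acquisition of the cardiac phantom
#'
#' Builds the noiseless per-voxel TACs from the spillover observation model
#' with each region's true parameters (LV cavity: pure arterial blood; RV
#' cavity: pure RV blood; myocardial shell: one-tissue-compartment kinetics
#' plus blood fractions), applies Gaussian spatial blur per frame (the
#' resolution/spillover model) before noise, then adds Gaussian noise with
#' variance proportional to \eqn{value \, e^{\lambda t_{mid}} / \Delta t}
#' scaled by `noise_scale`. Fully seeded and reproducible.
#'
#' @param spec A [phantom_spec()].
#' @param aif,rvif Arterial and RV input [blood_curve()]s (Bq/mL).
#' @param schedule A [frame_schedule()].
#' @param noise_scale Noise magnitude; 0 gives the noiseless forward model.
#' @param seed Integer seed; all stochastic draws derive from it.
#' @param tracer [tracer_constants()] for the decay term of the noise model.
#' @return A list of class `dynamic_sim`: `image` (4D array, Bq/mL), `labels`
#'   (region labels), `truth` (true parameter maps `k1`, `k2`, `v_a`, `v_rv`),
#'   `schedule`, `spec`.
#' @export
simulate_dynamic_pet <- function(spec, aif, rvif, schedule, noise_scale = 0,
                                 seed = 1L, tracer = tracer_constants("rb82")) {
  stopifnot(inherits(spec, "phantom_spec"), noise_scale >= 0)
  assert_schedule(schedule)
  lab <- phantom_labels(spec)
  nf <- nrow(schedule)
  m <- spec$myocardium

  fa_a <- frame_average(aif, schedule)$value
  fa_rv <- frame_average(rvif, schedule)$value
  myo <- model_tac(
    k1 = m$k1, k2 = m$k2, v_a = m$v_a, v_rv = m$v_rv,
    aif = aif, rvif = rvif, schedule = schedule,
    density_g_ml = spec$density_g_ml
  )$value

  region_tacs <- rbind(
    background = rep(0, nf),
    lv = fa_a,
    rv = fa_rv,
    myo = myo
  )

  img <- array(0, dim = c(spec$shape, nf))
  idx <- as.integer(lab) + 1L # 1..4 into region_tacs rows
  for (f in seq_len(nf)) {
    vol <- array(region_tacs[idx, f], dim = spec$shape)
    if (spec$psf_sigma_mm > 0) {
      vol <- gaussian_blur_3d(vol, spec$psf_sigma_mm, spec$voxel_mm)
    }
    img[, , , f] <- vol
  }

  if (noise_scale > 0) {
    with_seed(seed, {
      for (f in seq_len(nf)) {
        sd_f <- noise_scale * sqrt(
          pmax(img[, , , f], 0) *
            exp(tracer$lambda_s * schedule$mid_s[f]) / schedule$duration_s[f]
        )
        img[, , , f] <- img[, , , f] +
          array(stats::rnorm(prod(spec$shape)), dim = spec$shape) * sd_f
      }
    })
  }

  truth <- list(
    k1 = array(ifelse(lab == 3L, m$k1, 0), dim = spec$shape),
    k2 = array(ifelse(lab == 3L, m$k2, 0), dim = spec$shape),
    v_a = array(ifelse(lab == 3L, m$v_a, ifelse(lab == 1L, 1, 0)), dim = spec$shape),
    v_rv = array(ifelse(lab == 3L, m$v_rv, ifelse(lab == 2L, 1, 0)), dim = spec$shape)
  )
  structure(
    list(image = img, labels = lab, truth = truth, schedule = schedule, spec = spec),
    class = "dynamic_sim"
  )
}

#' Specification of the simulated arterial blood monitor
#'
#' Describes how the arterial sampling site sees the true input function: a
#' transit delay from the LV, exponential external dispersion in the sampling
#' line, detector sensitivity, physical decay (monitors count un-decayed
#' activity), a residual-activity background decaying at the tracer rate
#' (unflushed infusion line), and Gaussian counting noise.
#'
#' @param delay_s Delay between LV and the sampling site, s.
#' @param tau_d_s Dispersion time constant, s (>= 0).
#' @param background_a0 Background amplitude at t = 0, counts.
#' @param sensitivity Detector sensitivity factor (> 0).
#' @param sample_dt_s Monitor sampling interval, s.
#' @param noise_sd Additive Gaussian noise SD, counts.
#' @param seed Integer seed.
#' @return A `monitor_spec` object.
#' @export
monitor_spec <- function(delay_s = 5, tau_d_s = 2.5, background_a0 = 0,
                         sensitivity = 1, sample_dt_s = 1, noise_sd = 0,
                         seed = 1L) {
  stopifnot(tau_d_s >= 0, sensitivity > 0, sample_dt_s > 0, noise_sd >= 0,
    background_a0 >= 0)
  structure(
    list(
      delay_s = delay_s, tau_d_s = tau_d_s, background_a0 = background_a0,
      sensitivity = sensitivity, sample_dt_s = sample_dt_s,
      noise_sd = noise_sd, seed = seed
    ),
    class = "monitor_spec"
  )
}

#' Simulate raw arterial-monitor counts from a true input function
#'
#' Applies, in order: time shift by the LV-to-site delay, exponential
#' dispersion (convolution with \eqn{\tau_d^{-1} e^{-t/\tau_d}}), sensitivity
#' scaling, decay un-correction (\eqn{e^{-\lambda t}}), the decaying
#' residual-activity background, and additive Gaussian noise.
#'
#' @param aif True (decay-corrected, calibrated) [blood_curve()].
#' @param spec A [monitor_spec()].
#' @param tracer [tracer_constants()] for the decay constant.
#' @param duration_s Monitor recording duration, s.
#' @return A [blood_curve()] of raw counts at the monitor sampling interval
#'   (units `"counts"`, `calibrated = FALSE`).
#' @export
simulate_blood_monitor <- function(aif, spec, tracer = tracer_constants("rb82"),
                                   duration_s = max(aif$time_s)) {
  stopifnot(inherits(spec, "monitor_spec"))
  shifted_t <- aif$time_s + spec$delay_s
  act <- aif$activity
  if (spec$tau_d_s > 0) {
    act <- exp_conv(shifted_t, act, 1 / spec$tau_d_s) / spec$tau_d_s
  }
  grid <- seq(0, duration_s, by = spec$sample_dt_s)
  vals <- stats::approx(shifted_t, act, xout = grid, yleft = 0, yright = 0)$y
  vals <- spec$sensitivity * vals * exp(-tracer$lambda_s * grid) +
    spec$background_a0 * exp(-tracer$lambda_s * grid)
  if (spec$noise_sd > 0) {
    vals <- with_seed(spec$seed, vals + stats::rnorm(length(vals), sd = spec$noise_sd))
  }
  blood_curve(grid, vals, tracer = tracer, calibrated = FALSE, units = "counts")
}
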