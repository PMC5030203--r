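# Input functions may be supplied either as finely sampled curves or as
# frame-resolution TACs (image-derived inputs). The spillover regressor uses
# the exact frame values when available; the convolution falls back to the
# midpoint-interpolated curve, the best available continuous surrogate.
input_frame_values <- function(input, schedule) {
  if (is_tac(input)) {
    assert_same_schedule(input, schedule)
    input$value
  } else {
    frame_average(input, schedule)$value
  }
}

input_as_curve <- function(input) {
  if (!is_tac(input)) return(input)
  # Reconstruct a continuous curve whose frame averages reproduce the TAC:
  # monotone (Hyman) spline through the cumulative area at frame boundaries,
  # differentiated. Much more faithful on fast early frames than midpoint
  # interpolation, which leaks activity across frame edges.
  knots <- c(input$start_s[1L], input$end_s)
  q <- c(0, cumsum(input$value * input$duration_s))
  tt <- seq(knots[1L], knots[length(knots)], by = 0.25)
  vals <- tryCatch({
    f <- stats::splinefun(knots, q, method = "hyman")
    pmax(f(tt, deriv = 1), 0)
  }, error = function(e) {
    stats::approx(input$mid_s, input$value, xout = tt, rule = 2)$y
  })
  blood_curve(tt, vals)
}

#' Model TAC of the one-tissue compartment model with spillover
#'
#' Computes the frame-averaged model curve
#' \deqn{C_{PET}(t) = (1 - V_A - V_{RV}) K_1 e^{-k_2 t} \otimes C_A(t)
#'   + V_A C_A(t) + V_{RV} C_{RV}(t)}
#' where the tissue term is the one-tissue compartment response to the
#' arterial input and the \eqn{V_A}, \eqn{V_{RV}} terms account for LV/RV
#' blood volume and spillover. The convolution is evaluated analytically for
#' the piecewise-linear input (no discretization at frame scale), then
#' frame-averaged by exact integration.
#'
#' @param k1 Influx rate constant, mL/min/g.
#' @param k2 Efflux rate constant, 1/min.
#' @param v_a LV arterial blood fraction (unitless).
#' @param v_rv RV blood fraction (unitless); 0 for the 3-parameter model.
#' @param aif Arterial input [blood_curve()] (Bq/mL).
#' @param rvif RV input [blood_curve()] or `NULL` when `v_rv = 0`.
#' @param schedule A [frame_schedule()].
#' @param density_g_ml Tissue density converting the per-gram tissue response
#'   to the per-mL concentration the scanner measures. The tissue term alone
#'   carries the density factor, so a pure-blood voxel (`v_a = 1` limit)
#'   reproduces the input curve exactly.
#' @return A [tac()] with units `"Bq/mL"`.
#' @export
model_tac <- function(k1, k2, v_a, v_rv = 0, aif, rvif = NULL, schedule,
                      density_g_ml = 1.05) {
  stopifnot(k1 >= 0, k2 >= 0, v_a >= 0, v_rv >= 0, v_a + v_rv <= 1)
  assert_schedule(schedule)
  if (v_rv > 0 && is.null(rvif)) stop("rvif required when v_rv > 0")
  ct <- tissue_basis_tac(aif, k2, schedule) * k1 * density_g_ml
  vals <- (1 - v_a - v_rv) * ct + v_a * frame_average(aif, schedule)$value
  if (!is.null(rvif)) vals <- vals + v_rv * frame_average(rvif, schedule)$value
  tac(schedule, vals, units = "Bq/mL")
}

#' Noise-equivalent-count frame weights for weighted least squares
#'
#' Frame weights proportional to the reciprocal variance expected from
#' counting statistics: \eqn{w_i = \Delta t_i^2 \, dcf_i^{-2} /
#' \max(C_i \Delta t_i, \epsilon)} with decay-correction factor
#' \eqn{dcf_i = e^{\lambda t_{mid,i}}}, normalized to mean 1. Long late
#' frames gain weight through \eqn{\Delta t^2} but are penalized by decay;
#' high-count frames are down-weighted in proportion to their counts.
#'
#' @param total_tac A [tac()] of (non-negative, decay-corrected) activity used
#'   as the counts proxy.
#' @param tracer [tracer_constants()] supplying the decay constant.
#' @return A `fit_weights` object: tibble with columns `frame`, `weight`.
#' @export
nec_weights <- function(total_tac, tracer) {
  if (!is_tac(total_tac)) stop("expected a tac")
  if (!is_tracer(tracer)) stop("expected tracer_constants")
  if (any(total_tac$value < 0)) stop("total_tac must be non-negative")
  if (all(total_tac$value == 0)) stop("all-zero TAC: weights undefined")
  dt <- total_tac$duration_s
  dcf <- exp(tracer$lambda_s * total_tac$mid_s)
  counts <- total_tac$value * dt
  eps <- 1e-10 * max(counts)
  w <- dt^2 / dcf^2 / pmax(counts, eps)
  w <- w / mean(w)
  tibble::new_tibble(
    tibble::tibble(frame = total_tac$frame, weight = w),
    class = "fit_weights"
  )
}

#' Uniform (unweighted) frame weights
#'
#' @param schedule A [frame_schedule()].
#' @return A `fit_weights` object with all weights 1.
#' @export
uniform_weights <- function(schedule) {
  assert_schedule(schedule)
  tibble::new_tibble(
    tibble::tibble(frame = schedule$frame, weight = rep(1, nrow(schedule))),
    class = "fit_weights"
  )
}

as_weight_vector <- function(weights, n_frames) {
  if (inherits(weights, "fit_weights")) weights <- weights$weight
  weights <- as.double(weights)
  if (length(weights) != n_frames) stop("weights length must equal frame count")
  if (any(!is.finite(weights)) || any(weights < 0)) stop("weights must be finite and >= 0")
  if (all(weights == 0)) stop("weights must not be all zero")
  weights
}

#' Basis matrix for the basis function method
#'
#' Precomputes, for each candidate efflux rate on a grid, the frame-averaged
#' unit-\eqn{K_1} tissue response \eqn{e^{-k_2 t} \otimes C_A(t)}. Fitting the
#' compartment model then reduces to a linear problem per grid point.
#'
#' @param k2_grid Candidate \eqn{k_2} values, 1/min, sorted non-negative.
#' @param aif Arterial input [blood_curve()].
#' @param schedule A [frame_schedule()].
#' @return A numeric matrix, frames x grid points, with `k2_grid` attached as
#'   the `"k2_grid"` attribute.
#' @export
make_basis <- function(k2_grid, aif, schedule) {
  if (length(k2_grid) < 1L) stop("empty k2 grid")
  if (any(k2_grid < 0) || is.unsorted(k2_grid)) stop("k2_grid must be sorted and non-negative")
  assert_schedule(schedule)
  aif <- input_as_curve(aif)
  B <- vapply(
    k2_grid,
    function(k2) tissue_basis_tac(aif, k2, schedule),
    numeric(nrow(schedule))
  )
  B <- matrix(B, nrow = nrow(schedule))
  attr(B, "k2_grid") <- as.double(k2_grid)
  B
}

#' Default log-spaced efflux-rate grid
#'
#' 100 log-spaced points spanning 0.01 to 12 per minute, wide enough to cover
#' water kinetics under stress (\eqn{k_2 \approx 4} per minute) with margin.
#'
#' @param n Number of grid points.
#' @param lo,hi Grid limits, 1/min.
#' @return Numeric vector of length `n`.
#' @export
default_k2_grid <- function(n = 100, lo = 0.01, hi = 12) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# Active-set solver for the small weighted least-squares problem
# min ||sqrt(w) (y - X b)||^2 subject to b >= 0 and sum(b[sum_idx]) <= sum_max.
# With <= 3 unknowns and <= 4 convex constraints, enumerating active sets is
# exact and cheap. Each candidate set is solved by variable elimination (zero
# variables dropped, the active sum constraint substituted out) and a QR
# solve of the reduced design, which stays stable across the huge dynamic
# range between activity-scaled columns and the unit-scale fractions.
wls_nonneg <- function(X, y, w, sum_idx = integer(0), sum_max = 0.999) {
  p <- ncol(X)
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  wss_of <- function(beta) sum((yw - Xw %*% beta)^2)
  feasible <- function(beta) {
    all(beta >= -1e-9) &&
      (length(sum_idx) == 0L || sum(beta[sum_idx]) <= sum_max + 1e-9)
  }
  solve_candidate <- function(zeros, sum_active) {
    free <- setdiff(seq_len(p), zeros)
    beta <- numeric(p)
    if (!sum_active) {
      if (length(free)) {
        cf <- tryCatch(
          qr.coef(qr(Xw[, free, drop = FALSE]), yw),
          error = function(e) NULL
        )
        if (is.null(cf) || anyNA(cf)) return(NULL)
        beta[free] <- cf
      }
      return(beta)
    }
    sv <- intersect(sum_idx, free)
    if (length(sv) == 0L) return(NULL) # sum constraint unsatisfiable
    pivot <- sv[1L]
    rest <- setdiff(free, pivot)
    y2 <- yw - sum_max * Xw[, pivot]
    if (length(rest)) {
      X2 <- Xw[, rest, drop = FALSE]
      in_sum <- rest %in% sum_idx
      X2[, in_sum] <- X2[, in_sum, drop = FALSE] - Xw[, pivot]
      cf <- tryCatch(qr.coef(qr(X2), y2), error = function(e) NULL)
      if (is.null(cf) || anyNA(cf)) return(NULL)
      beta[rest] <- cf
    }
    beta[pivot] <- sum_max - sum(beta[setdiff(sum_idx, pivot)])
    beta
  }
  best <- NULL
  n_sum <- as.integer(length(sum_idx) > 0L)
  for (mask in 0:(2^(p + n_sum) - 1L)) {
    zeros <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    sum_active <- n_sum == 1L && bitwAnd(mask, bitwShiftL(1L, p)) != 0L
    if (length(zeros) + sum_active > p) next
    beta <- solve_candidate(zeros, sum_active)
    if (is.null(beta) || any(!is.finite(beta)) || !feasible(beta)) next
    wss <- wss_of(beta)
    if (is.null(best) || wss < best$wss - 1e-12 * (1 + best$wss)) {
      best <- list(beta = pmax(as.numeric(beta), 0), wss = wss,
        active = c(zeros, if (sum_active) p + 1L))
    }
  }
  if (is.null(best)) stop("degenerate design: constrained WLS has no solution")
  best
}

solve_linear_step <- function(btac, fa_a, fa_rv, y, w, density_g_ml = 1.05,
                              sum_max = 0.999) {
  bt <- btac * density_g_ml
  X <- if (is.null(fa_rv)) cbind(bt, fa_a) else cbind(bt, fa_a, fa_rv)
  sum_idx <- if (is.null(fa_rv)) 2L else 2:3
  wls_nonneg(X, y, w, sum_idx = sum_idx, sum_max = sum_max)
}

#' Fit the one-tissue compartment model to a TAC by the basis function method
#'
#' For each candidate \eqn{k_2} on a grid, the model is linear in
#' (amplitude, \eqn{V_A}\[, \eqn{V_{RV}}\]) with amplitude
#' \eqn{= (1 - V_A - V_{RV}) K_1}; the constrained weighted linear problem is
#' solved exactly per grid point and the grid point with minimal weighted sum
#' of squares wins (ties go to the smaller \eqn{k_2}). A golden-section
#' refinement between the neighboring grid points then polishes \eqn{k_2} off
#' the grid. Constraints: amplitude, \eqn{V_A}, \eqn{V_{RV} \ge 0} and
#' \eqn{V_A + V_{RV} \le 0.999}.
#'
#' When the blood-fraction sum constraint is active the voxel is effectively
#' pure blood: the tissue fraction is numerically zero and \eqn{K_1} is
#' unidentifiable, so the fit is reported with \eqn{K_1 = 0} and flagged as a
#' boundary solution.
#'
#' @param x A [tac()] of measured concentration, Bq/mL.
#' @param aif,rvif Input functions, each a [blood_curve()] or a
#'   frame-resolution [tac()] (e.g. an image-derived input); omit `rvif` for
#'   the 3-parameter fit.
#' @param weights A `fit_weights` object (see [nec_weights()]) or numeric
#'   vector.
#' @param k2_grid Candidate \eqn{k_2} grid, 1/min.
#' @param refine Golden-section \eqn{k_2} refinement between grid neighbors.
#' @param basis Optional precomputed [make_basis()] for `aif` on `k2_grid`
#'   (reused across voxels).
#' @param density_g_ml Tissue density folding the per-gram tissue response
#'   into the per-mL observation model; the single point where units convert.
#' @return A `kinetic_fit` object with elements `k1` (mL/min/g), `k2` (1/min),
#'   `v_a`, `v_rv` (`NA` in 3-parameter mode), `wss`, `n_params`, `converged`
#'   and `boundary` flags.
#' @export
fit_tac <- function(x, aif, rvif = NULL, weights, k2_grid = default_k2_grid(),
                    refine = TRUE, basis = NULL, density_g_ml = 1.05) {
  if (!is_tac(x)) stop("expected a tac")
  schedule <- tac_schedule(x)
  w <- as_weight_vector(weights, nrow(schedule))
  fa_a <- input_frame_values(aif, schedule)
  if (all(fa_a == 0)) stop("degenerate design: aif is identically zero")
  fa_rv <- if (is.null(rvif)) NULL else input_frame_values(rvif, schedule)
  if (is.null(basis)) basis <- make_basis(k2_grid, aif, schedule)
  aif <- input_as_curve(aif)
  k2_grid <- attr(basis, "k2_grid")
  y <- x$value

  sols <- lapply(seq_along(k2_grid), function(j) {
    solve_linear_step(basis[, j], fa_a, fa_rv, y, w, density_g_ml)
  })
  wss_grid <- vapply(sols, `[[`, numeric(1), "wss")
  j <- which.min(wss_grid)
  k2_hat <- k2_grid[j]
  sol <- sols[[j]]

  if (isTRUE(refine) && length(k2_grid) > 1L) {
    lo <- k2_grid[max(j - 1L, 1L)]
    hi <- k2_grid[min(j + 1L, length(k2_grid))]
    if (hi > lo) {
      obj <- function(k2) {
        solve_linear_step(
          tissue_basis_tac(aif, k2, schedule), fa_a, fa_rv, y, w, density_g_ml
        )$wss
      }
      opt <- stats::optimize(obj, interval = c(lo, hi), tol = 1e-6)
      if (opt$objective < sol$wss) {
        k2_hat <- opt$minimum
        sol <- solve_linear_step(
          tissue_basis_tac(aif, k2_hat, schedule), fa_a, fa_rv, y, w, density_g_ml
        )
      }
    }
  }

  finish_kinetic_fit(sol, k2_hat, fa_a, fa_rv, y, w, schedule, is.null(rvif))
}

finish_kinetic_fit <- function(sol, k2_hat, fa_a, fa_rv, y, w, schedule,
                               three_param) {
  beta <- sol$beta
  amp <- beta[1L]
  v_a <- beta[2L]
  v_rv <- if (three_param) 0 else beta[3L]
  frac <- 1 - v_a - v_rv
  boundary <- frac <= 1e-3 + 1e-9 || amp <= 1e-12
  if (frac <= 1e-3 + 1e-9) {
    # pure-blood boundary: tissue fraction numerically zero, K1 unidentifiable
    k1 <- 0
    k2_hat <- NA_real_
    blood_vals <- v_a * fa_a + if (is.null(fa_rv)) 0 else v_rv * fa_rv
    wss <- sum(w * (y - blood_vals)^2)
  } else {
    k1 <- amp / frac
    wss <- sol$wss
  }
  structure(
    list(
      k1 = k1, k2 = k2_hat, v_a = v_a,
      v_rv = if (three_param) NA_real_ else v_rv,
      amplitude = amp,
      wss = wss, n_params = if (three_param) 3L else 4L,
      converged = TRUE, boundary = boundary,
      schedule = schedule
    ),
    class = "kinetic_fit"
  )
}

#' Voxelwise parametric fitting of a dynamic image
#'
#' Applies [fit_tac()] to every voxel TAC inside a mask (measured Bq/mL; the
#' density conversion happens inside the fit). Voxels with identical TACs (common in
#' noiseless simulations) are fitted once and the result reused. Failed fits
#' are flagged in a failure mask, never silently zeroed.
#'
#' @param image4d 4D numeric array (x, y, z, frame), Bq/mL.
#' @param aif,rvif Input [blood_curve()]s.
#' @param mask Logical or 0/1 3D array selecting voxels to fit.
#' @param k2_grid Candidate \eqn{k_2} grid, 1/min.
#' @param weights Shared frame weights (see [nec_weights()]).
#' @param schedule A [frame_schedule()] matching the 4th dimension.
#' @param refine Passed to [fit_tac()].
#' @param density_g_ml Tissue density, passed through to [fit_tac()].
#' @return A `parametric_maps` object: list of 3D arrays `k1`, `k2`, `v_a`
#'   (and `v_rv` for 4-parameter fits), `boundary` and `failed` masks.
#' @export
fit_parametric <- function(image4d, aif, rvif = NULL, mask, k2_grid = default_k2_grid(),
                           weights, schedule, refine = TRUE, density_g_ml = 1.05) {
  d <- dim(image4d)
  if (length(d) != 4L) stop("image4d must be a 4D array")
  assert_schedule(schedule)
  if (d[4L] != nrow(schedule)) stop("4th dimension must equal frame count")
  mask <- array(as.logical(mask), dim = d[1:3])
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask")
  w <- as_weight_vector(weights, nrow(schedule))
  basis <- make_basis(k2_grid, aif, schedule)

  nvox <- prod(d[1:3])
  Y <- matrix(image4d, nrow = nvox, ncol = d[4L])[idx, , drop = FALSE]

  key <- apply(Y, 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  lookup <- match(key, key[first])

  three_param <- is.null(rvif)
  fits <- vector("list", sum(first))
  uY <- Y[first, , drop = FALSE]
  for (i in seq_len(nrow(uY))) {
    fits[[i]] <- tryCatch(
      fit_tac(
        tac(schedule, uY[i, ], units = "Bq/mL"),
        aif = aif, rvif = rvif, weights = w, k2_grid = k2_grid,
        refine = refine, basis = basis, density_g_ml = density_g_ml
      ),
      error = function(e) NULL
    )
  }

  blank <- array(NA_real_, dim = d[1:3])
  maps <- list(k1 = blank, k2 = blank, v_a = blank)
  if (!three_param) maps$v_rv <- blank
  boundary <- array(FALSE, dim = d[1:3])
  failed <- array(FALSE, dim = d[1:3])
  for (v in seq_along(idx)) {
    f <- fits[[lookup[v]]]
    if (is.null(f)) {
      failed[idx[v]] <- TRUE
      next
    }
    maps$k1[idx[v]] <- f$k1
    maps$k2[idx[v]] <- f$k2
    maps$v_a[idx[v]] <- f$v_a
    if (!three_param) maps$v_rv[idx[v]] <- f$v_rv
    boundary[idx[v]] <- f$boundary
  }
  structure(
    c(maps, list(boundary = boundary, failed = failed, mask = mask)),
    class = "parametric_maps"
  )
}

#' Mean, variance and voxel count of a parametric map over a VOI
#'
#' Arithmetic mean and unbiased variance of map values over the voxels of a
#' labelled VOI, excluding flagged failures (`NA` values).
#'
#' @param map 3D numeric array (one parametric map).
#' @param voi Logical/0-1 3D array, or an integer label volume combined with
#'   `label`.
#' @param label When `voi` is a label volume, the label to select.
#' @return A tibble with columns `mean`, `variance`, `n_voxels`.
#' @export
voi_stats <- function(map, voi, label = NULL) {
  sel <- if (is.null(label)) as.logical(voi) else voi == label
  vals <- map[sel]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("empty VOI after exclusions")
  tibble::tibble(
    mean = mean(vals),
    variance = if (length(vals) > 1L) stats::var(vals) else 0,
    n_voxels = length(vals)
  )
}
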