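#' Extract a VOI-mean TAC from a dynamic image
#'
#' @param image4d 4D numeric array (x, y, z, frame), Bq/mL.
#' @param voi Logical/0-1 3D array, or label volume combined with `label`.
#' @param schedule A [frame_schedule()] matching the 4th dimension.
#' @param label Optional label value selecting a region of `voi`.
#' @return A [tac()] of per-frame VOI means.
#' @export
extract_voi_tac <- function(image4d, voi, schedule, label = NULL) {
  d <- dim(image4d)
  if (length(d) != 4L) stop("image4d must be a 4D array")
  assert_schedule(schedule)
  if (d[4L] != nrow(schedule)) stop("4th dimension must equal frame count")
  sel <- if (is.null(label)) as.logical(voi) else voi == label
  if (!any(sel)) stop("empty VOI")
  Y <- matrix(image4d, nrow = prod(d[1:3]), ncol = d[4L])
  tac(schedule, colMeans(Y[sel, , drop = FALSE]), units = "Bq/mL")
}

#' Number of voxels of a fixed-volume VOI
#'
#' @param volume_ml VOI volume in mL.
#' @param voxel_mm Voxel size in mm.
#' @return Integer voxel count (rounded).
#' @examples
#' voi_voxel_count(6.5) # 6.5 mL cylinder at default voxel size: 784 voxels
#' @export
voi_voxel_count <- function(volume_ml, voxel_mm = c(2.036, 2.036, 2.0)) {
  round(volume_ml * 1000 / prod(voxel_mm))
}

#' Estimate the reference tissue curve from a global myocardium TAC
#'
#' Fits the 3-parameter compartment model (no RV term) to a mean global
#' myocardium TAC using the arterial input, and returns the fitted tissue
#' component \eqn{K_1 e^{-k_2 t} \otimes C_A(t)} (frame-averaged, expressed
#' per mL via the tissue density). This serves as the "true" tissue curve
#' \eqn{C_T} in the partial-volume correction models.
#'
#' @param myo_tac Global myocardium [tac()], Bq/mL.
#' @param aif Arterial input [blood_curve()].
#' @inheritParams fit_tac
#' @return A [tac()] of the tissue component (Bq/mL equivalents); never
#'   negative.
#' @export
estimate_reference_tissue <- function(myo_tac, aif, weights,
                                      k2_grid = default_k2_grid(),
                                      density_g_ml = 1.05) {
  fit <- fit_tac(myo_tac, aif,
    rvif = NULL, weights = weights,
    k2_grid = k2_grid, density_g_ml = density_g_ml
  )
  schedule <- tac_schedule(myo_tac)
  if (fit$boundary && fit$k1 == 0) {
    return(tac(schedule, rep(0, nrow(schedule)), units = "Bq/mL"))
  }
  vals <- tissue_basis_tac(input_as_curve(aif), fit$k2, schedule) * fit$k1 * density_g_ml
  tac(schedule, vals, units = "Bq/mL")
}

new_if_correction <- function(kind, coef, wss, n_params, flag = FALSE) {
  structure(
    list(kind = kind, coef = coef, wss = wss, n_params = n_params,
      out_of_range = flag),
    class = "if_correction"
  )
}

#' One-parameter partial-volume correction of the LV input function
#'
#' Models the LV blood-pool TAC as a recovery-coefficient mixture of arterial
#' blood and myocardial tissue,
#' \eqn{C_{PET,LV}(t) = \beta C_A(t) + (1 - \beta) C_T(t)}, and estimates the
#' LV recovery coefficient \eqn{\beta} by weighted least squares (closed
#' form). \eqn{\beta} is estimated freely and flagged, not clipped, when it
#' falls outside (0, 1].
#'
#' @param lv_tac LV blood-pool [tac()].
#' @param aif Arterial input [blood_curve()].
#' @param c_t Reference tissue [tac()] (see [estimate_reference_tissue()]).
#' @param weights Frame weights ([nec_weights()] of the LV TAC, or a vector).
#' @return An `if_correction` with coefficient `beta`.
#' @export
fit_pvc1 <- function(lv_tac, aif, c_t, weights) {
  schedule <- tac_schedule(lv_tac)
  assert_same_schedule(lv_tac, c_t)
  w <- as_weight_vector(weights, nrow(schedule))
  ca <- input_frame_values(aif, schedule)
  d <- ca - c_t$value
  if (sum(w * d^2) == 0) stop("degenerate design: C_A equals C_T")
  beta <- sum(w * (lv_tac$value - c_t$value) * d) / sum(w * d^2)
  resid <- lv_tac$value - (beta * ca + (1 - beta) * c_t$value)
  new_if_correction(
    "pvc1", c(beta = beta), sum(w * resid^2), 1L,
    flag = beta <= 0 || beta > 1
  )
}

#' Two-parameter partial-volume correction of the LV input function
#'
#' As [fit_pvc1()] but without constraining the coefficients to sum to 1:
#' \eqn{C_{PET,LV}(t) = \beta_1 C_A(t) + \beta_2 C_T(t)}. A sum below 1
#' indicates mixing with signal outside the heart.
#'
#' @inheritParams fit_pvc1
#' @return An `if_correction` with coefficients `beta1`, `beta2` and their
#'   sum `beta_sum`.
#' @export
fit_pvc2 <- function(lv_tac, aif, c_t, weights) {
  schedule <- tac_schedule(lv_tac)
  assert_same_schedule(lv_tac, c_t)
  w <- as_weight_vector(weights, nrow(schedule))
  ca <- input_frame_values(aif, schedule)
  X <- cbind(ca, c_t$value)
  XtWX <- crossprod(X * sqrt(w))
  if (abs(det(XtWX)) < 1e-12 * prod(diag(XtWX) + 1e-300)) {
    stop("collinear design: C_A and C_T are proportional")
  }
  beta <- solve(XtWX, crossprod(X, w * lv_tac$value))
  resid <- lv_tac$value - X %*% beta
  new_if_correction(
    "pvc2",
    c(beta1 = beta[1L], beta2 = beta[2L], beta_sum = sum(beta)),
    sum(w * resid^2), 2L
  )
}

#' Weighted-least-squares scale correction of the LV input function
#'
#' Single scale factor \eqn{C_{PET,LV}(t) = \beta_s C_A(t)} with the
#' closed-form weighted projection
#' \eqn{\beta_s = \sum w \, C_{LV} C_A / \sum w \, C_A^2}; the
#' WSS-minimizing scalar multiple by construction.
#'
#' @inheritParams fit_pvc1
#' @return An `if_correction` with coefficient `beta_s`.
#' @export
fit_scale_wls <- function(lv_tac, aif, weights) {
  schedule <- tac_schedule(lv_tac)
  w <- as_weight_vector(weights, nrow(schedule))
  ca <- input_frame_values(aif, schedule)
  denom <- sum(w * ca^2)
  if (denom == 0) stop("degenerate design: aif identically zero")
  beta <- sum(w * lv_tac$value * ca) / denom
  resid <- lv_tac$value - beta * ca
  new_if_correction("scale_wls", c(beta_s = beta), sum(w * resid^2), 1L)
}

#' AUC-ratio scale correction of the LV input function
#'
#' \eqn{\beta_{AUC}} is the ratio of the IDIF area under the curve to the AIF
#' area under the curve over the acquisition. Its WSS can never beat the
#' weighted projection of [fit_scale_wls()], but a population mean
#' \eqn{\beta_{AUC}} is the basis of the tracer-specific correction factor.
#'
#' @param lv_tac LV blood-pool [tac()].
#' @param aif Arterial input [blood_curve()].
#' @param weights Optional frame weights used only to report a comparable WSS.
#' @return An `if_correction` with coefficient `beta_auc`.
#' @export
fit_scale_auc <- function(lv_tac, aif, weights = NULL) {
  schedule <- tac_schedule(lv_tac)
  ca <- input_frame_values(aif, schedule)
  auc_a <- sum(ca * schedule$duration_s)
  if (auc_a == 0) stop("AIF AUC is zero")
  beta <- sum(lv_tac$value * schedule$duration_s) / auc_a
  w <- if (is.null(weights)) rep(1, nrow(schedule)) else {
    as_weight_vector(weights, nrow(schedule))
  }
  resid <- lv_tac$value - beta * ca
  new_if_correction("scale_auc", c(beta_auc = beta), sum(w * resid^2), 1L)
}

#' Apply a multiplicative scale correction to an IDIF
#'
#' In the population workflow the factor is the reciprocal of the mean
#' per-scan \eqn{\beta_{AUC}} for the tracer.
#'
#' @param idif A [tac()].
#' @param factor Positive multiplicative factor.
#' @return The scaled [tac()].
#' @export
apply_scale <- function(idif, factor) {
  if (!is_tac(idif)) stop("expected a tac")
  if (factor <= 0) stop("scale factor must be positive")
  tac(tac_schedule(idif), idif$value * factor, units = tac_units(idif))
}

#' Population scale factor from per-scan AUC ratios
#'
#' @param beta_auc Vector of per-scan \eqn{\beta_{AUC}} estimates.
#' @return The correction factor, `1 / mean(beta_auc)`.
#' @export
population_scale_factor <- function(beta_auc) {
  m <- mean(beta_auc)
  if (m <= 0) stop("mean beta_auc must be positive")
  1 / m
}

#' F test comparing nested input-function correction models
#'
#' \deqn{F = \frac{(WSS_r - WSS_f)/(p_f - p_r)}{WSS_f/(n - p_f)}}
#' with the p-value from the F distribution with \eqn{(p_f - p_r, n - p_f)}
#' degrees of freedom. F is floored at 0 if the full model fits worse.
#'
#' @param fit_reduced,fit_full `if_correction` objects (or any lists with
#'   `wss` and `n_params`); the full model must have more parameters.
#' @param n_frames Number of frames used in both fits.
#' @return A tibble with columns `f_statistic`, `p_value`, `df1`, `df2`.
#' @export
f_test_nested <- function(fit_reduced, fit_full, n_frames) {
  pr <- fit_reduced$n_params
  pf <- fit_full$n_params
  if (pf <= pr) stop("full model must have more parameters than the reduced model")
  if (n_frames <= pf) stop("need more frames than full-model parameters")
  num <- max(fit_reduced$wss - fit_full$wss, 0) / (pf - pr)
  den <- fit_full$wss / (n_frames - pf)
  f <- if (den == 0) {
    if (num == 0) 0 else Inf
  } else {
    num / den
  }
  tibble::tibble(
    f_statistic = f,
    p_value = stats::pf(f, pf - pr, n_frames - pf, lower.tail = FALSE),
    df1 = pf - pr,
    df2 = n_frames - pf
  )
}
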