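#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a one-tissue-compartment fit
#'
#' @param x A `kinetic_fit` from [fit_tac()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `unit`, `role`.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  terms <- tibble::tribble(
    ~term, ~estimate, ~unit, ~role,
    "K1", x$k1, "mL/min/g", "influx rate constant",
    "k2", x$k2, "1/min", "efflux rate constant",
    "V_A", x$v_a, "unitless", "LV blood volume + spillover fraction"
  )
  if (x$n_params == 4L) {
    terms <- dplyr::bind_rows(terms, tibble::tibble(
      term = "V_RV", estimate = x$v_rv, unit = "unitless",
      role = "RV spillover fraction"
    ))
  }
  terms
}

#' @rdname tidy.kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    wss = x$wss, n_params = x$n_params,
    converged = x$converged, boundary = x$boundary
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> %d-parameter 1TCM: K1 = %.4g mL/min/g, k2 = %.4g 1/min, V_A = %.3g%s (WSS %.4g%s)\n",
    x$n_params, x$k1, x$k2, x$v_a,
    if (x$n_params == 4L) sprintf(", V_RV = %.3g", x$v_rv) else "",
    x$wss, if (x$boundary) ", boundary" else ""
  ))
  invisible(x)
}

#' Tidy a Renkin-Crone extraction fit
#'
#' @param x A `renkin_crone_fit` from [fit_renkin_crone()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.renkin_crone_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b),
    std.error = c(x$se_a, x$se_b)
  )
}

#' @rdname tidy.renkin_crone_fit
#' @export
glance.renkin_crone_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, n_points = x$n_points,
    converged = x$converged, physical = x$physical
  )
}

#' @export
print.renkin_crone_fit <- function(x, ...) {
  cat(sprintf(
    "<renkin_crone_fit> a = %.3f +/- %.3f, b = %.3f +/- %.3f mL/min/g (n = %d%s)\n",
    x$a, x$se_a, x$b, x$se_b, x$n_points,
    if (x$converged) "" else ", NOT converged"
  ))
  invisible(x)
}

#' Tidy an input-function correction fit
#'
#' @param x An `if_correction`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @export
tidy.if_correction <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @rdname tidy.if_correction
#' @export
glance.if_correction <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, wss = x$wss, n_params = x$n_params,
    out_of_range = x$out_of_range
  )
}

#' @export
print.if_correction <- function(x, ...) {
  cat(sprintf(
    "<if_correction> %s: %s (WSS %.4g)%s\n",
    x$kind,
    paste(sprintf("%s = %.4g", names(x$coef), x$coef), collapse = ", "),
    x$wss, if (x$out_of_range) " [outside (0, 1]]" else ""
  ))
  invisible(x)
}

#' Tidy a Deming regression fit
#'
#' @param x A `deming_fit` from [deming_regression()].
#' @param ... Unused.
#' @return One row per term: `term`, `estimate`, `std.error`.
#' @export
tidy.deming_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    std.error = c(x$se_slope, x$se_intercept)
  )
}

#' @rdname tidy.deming_fit
#' @export
glance.deming_fit <- function(x, ...) {
  tibble::tibble(n = x$n, variance_ratio = x$variance_ratio)
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf(
    "<deming_fit> y = %.3f x + %.3f (SEs %.3f, %.3f; n = %d, delta = %g)\n",
    x$slope, x$intercept, x$se_slope, x$se_intercept, x$n, x$variance_ratio
  ))
  invisible(x)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat(sprintf(
    "  Deming: slope %.3f +/- %.3f, intercept %.3f +/- %.3f\n",
    x$deming$slope, x$deming$se_slope, x$deming$intercept, x$deming$se_intercept
  ))
  cat(sprintf("  Lin CCC: %.3f\n", x$lin_ccc))
  cat(sprintf(
    "  Bland-Altman: mean %.2f%% [%.2f%%, %.2f%%], RPC %.2f%%\n",
    x$bland_altman$mean_pct, x$bland_altman$lower_loa,
    x$bland_altman$upper_loa, x$bland_altman$rpc
  ))
  invisible(x)
}

#' @export
print.background_fit <- function(x, ...) {
  cat(sprintf(
    "<background_fit> A0 = %.4g counts (lambda %.5g 1/s, window [%g, %g] s, RMS %.3g, n = %d)\n",
    x$a0, x$lambda_s, x$window[1], x$window[2], x$residual_rms, x$n_samples
  ))
  invisible(x)
}

#' @export
print.simulation_study <- function(x, ...) {
  cat(sprintf(
    "<simulation_study> %d subjects, %d scan fits\n",
    x$config$n_subjects, nrow(x$scans)
  ))
  for (rt in names(x$rc_fits)) {
    f <- x$rc_fits[[rt]]
    cat(sprintf("  Renkin-Crone [%s]: a = %.3f, b = %.3f\n", rt, f$a, f$b))
  }
  invisible(x)
}
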