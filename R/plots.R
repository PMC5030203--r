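#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a blood curve
#'
#' @param object A [blood_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.blood_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$activity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (s)",
      y = paste0("Activity (", attr(object, "units") %||% "Bq/mL", ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a frame-resolution TAC as duration-weighted steps
#'
#' @param object A [tac()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tac <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start_s, xend = .data$end_s,
      y = .data$value, yend = .data$value
    )) +
    ggplot2::geom_point(ggplot2::aes(x = .data$mid_s, y = .data$value), size = 0.8) +
    ggplot2::labs(
      x = "Time (s)",
      y = paste0("Activity (", tac_units(object) %||% "Bq/mL", ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Renkin-Crone fit with its data points
#'
#' Shows the measured (MBF, K1) pairs, the fitted extraction curve, and the
#' identity line (full extraction).
#'
#' @param object A `renkin_crone_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.renkin_crone_fit <- function(object, ...) {
  grid <- tibble::tibble(
    mbf = seq(max(min(object$data$mbf) * 0.5, 0.05),
      max(object$data$mbf) * 1.1,
      length.out = 200
    )
  )
  grid$k1 <- renkin_crone_k1(grid$mbf, object$a, object$b)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mbf, y = .data$k1)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "MBF (mL/min/g)", y = expression(K[1] ~ "(mL/min/g)"),
      title = sprintf("Renkin-Crone fit: a = %.2f, b = %.2f", object$a, object$b)
    ) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of an agreement report
#'
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @return A ggplot of paired percent differences against pair means, with
#'   the mean difference and 95% limits of agreement.
#' @export
autoplot.agreement_report <- function(object, ...) {
  ba <- object$bland_altman
  df <- dplyr::mutate(
    object$data,
    pair_mean = (.data$x + .data$y) / 2,
    pct_diff = 100 * (.data$y - .data$x) / .data$pair_mean
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_mean, y = .data$pct_diff)) +
    ggplot2::geom_hline(yintercept = ba$mean_pct, colour = "steelblue") +
    ggplot2::geom_hline(
      yintercept = c(ba$lower_loa, ba$upper_loa),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Pair mean", y = "Percent difference (%)",
      title = sprintf("Mean %.1f%%, RPC %.1f%%", ba$mean_pct, ba$rpc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a mid-axial slice of a parametric map
#'
#' @param maps A `parametric_maps` object from [fit_parametric()].
#' @param which Map name (`"k1"`, `"k2"`, `"v_a"`, `"v_rv"`).
#' @param slice Axial slice index; default the middle slice.
#' @return A ggplot raster of the slice.
#' @export
plot_parametric_slice <- function(maps, which = "k1", slice = NULL) {
  stopifnot(inherits(maps, "parametric_maps"), which %in% names(maps))
  vol <- maps[[which]]
  if (is.null(slice)) slice <- ceiling(dim(vol)[3] / 2)
  sl <- vol[, , slice]
  df <- tidyr::expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- sl[cbind(df$x, df$y)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s (slice %d)", which, slice), fill = which) +
    ggplot2::theme_minimal()
}
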