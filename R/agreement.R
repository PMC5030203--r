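#' Deming regression (errors in both variables)
#'
#' Closed-form Deming estimates of slope and intercept under an assumed ratio
#' \eqn{\delta} of error variances (y over x):
#' \deqn{\hat\beta = \frac{s_{yy} - \delta s_{xx} +
#'   \sqrt{(s_{yy} - \delta s_{xx})^2 + 4 \delta s_{xy}^2}}{2 s_{xy}}}
#' As \eqn{\delta \to \infty} this approaches ordinary least squares of y on
#' x; as \eqn{\delta \to 0}, the inverse regression. Standard errors are
#' computed by the jackknife.
#'
#' @param x,y Paired measurements, n >= 3, x not constant.
#' @param variance_ratio Error-variance ratio \eqn{\delta =
#'   \sigma^2_y / \sigma^2_x}; default 1.
#' @return A `deming_fit` object: `slope`, `intercept`, `se_slope`,
#'   `se_intercept`, `n`, `variance_ratio`.
#' @export
deming_regression <- function(x, y, variance_ratio = 1) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need >= 3 paired points")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) stop("x and y are both constant")
  est <- deming_point(x, y, variance_ratio)
  jack <- vapply(
    seq_len(n),
    function(i) deming_point(x[-i], y[-i], variance_ratio),
    numeric(2)
  )
  se <- sqrt((n - 1) / n * rowSums((jack - rowMeans(jack))^2))
  structure(
    list(
      slope = est[1], intercept = est[2],
      se_slope = se[1], se_intercept = se[2],
      n = n, variance_ratio = variance_ratio,
      data = tibble::tibble(x = x, y = y)
    ),
    class = "deming_fit"
  )
}

deming_point <- function(x, y, delta) {
  mx <- mean(x)
  my <- mean(y)
  sxx <- mean((x - mx)^2)
  syy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  slope <- if (sxy == 0) {
    if (syy >= delta * sxx) Inf else 0
  } else {
    (syy - delta * sxx + sqrt((syy - delta * sxx)^2 + 4 * delta * sxy^2)) /
      (2 * sxy)
  }
  c(slope, my - slope * mx)
}

#' Lin concordance correlation coefficient
#'
#' Absolute-agreement measure penalizing both scale and location departures
#' from the identity line:
#' \deqn{\rho_c = \frac{2 \,\mathrm{cov}(x, y)}
#'   {\mathrm{var}(x) + \mathrm{var}(y) + (\bar x - \bar y)^2}}
#' with population (1/n) moments. Bounded by the Pearson correlation in
#' absolute value, with equality iff means and variances match.
#'
#' @param x,y Paired measurements, n >= 2, not both constant.
#' @return The concordance coefficient in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  n <- length(x)
  if (n < 2L || length(y) != n) stop("need >= 2 paired points")
  mx <- mean(x)
  my <- mean(y)
  vx <- mean((x - mx)^2)
  vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) stop("x and y are both constant")
  2 * cxy / denom
}

#' Bland-Altman analysis on paired percent differences
#'
#' Per-pair percent differences are normalized to the pair mean,
#' \eqn{d_i = 100 (y_i - x_i) / \frac{x_i + y_i}{2}}; reported are the mean
#' difference, the 95% limits of agreement (mean +/- 1.96 SD), and the
#' reproducibility coefficient RPC = 1.96 SD. A paired t-test p-value on the
#' raw differences is included as a companion bias test (p = 1 for identical
#' vectors).
#'
#' @param x,y Paired measurements, n >= 2; no pair may average zero.
#' @return A tibble with columns `mean_pct`, `lower_loa`, `upper_loa`, `rpc`,
#'   `sd_pct`, `n`, `t_test_p`.
#' @export
bland_altman_percent <- function(x, y) {
  n <- length(x)
  if (n < 2L || length(y) != n) stop("need >= 2 paired points")
  pm <- (x + y) / 2
  if (any(pm == 0)) stop("a pair mean is zero: percent difference undefined")
  d <- 100 * (y - x) / pm
  m <- mean(d)
  s <- stats::sd(d)
  raw_diff <- y - x
  t_p <- if (stats::sd(raw_diff) == 0) {
    if (mean(raw_diff) == 0) 1 else 0
  } else {
    stats::t.test(y, x, paired = TRUE)$p.value
  }
  tibble::tibble(
    mean_pct = m,
    lower_loa = m - 1.96 * s,
    upper_loa = m + 1.96 * s,
    rpc = 1.96 * s,
    sd_pct = s,
    n = n,
    t_test_p = t_p
  )
}

#' Full method-agreement report for two sets of paired estimates
#'
#' Bundles Deming regression (slope and intercept with jackknife SEs), the
#' Lin concordance coefficient, and the Bland-Altman percent-difference
#' analysis with reproducibility coefficient.
#'
#' @inheritParams deming_regression
#' @return An `agreement_report` object.
#' @export
agreement_report <- function(x, y, variance_ratio = 1) {
  dem <- deming_regression(x, y, variance_ratio)
  ba <- bland_altman_percent(x, y)
  structure(
    list(deming = dem, lin_ccc = lin_ccc(x, y), bland_altman = ba,
      data = tibble::tibble(x = x, y = y)),
    class = "agreement_report"
  )
}
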