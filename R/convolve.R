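# Exact convolution of a piecewise-linear input with an exponential kernel.
#
# I(t) = integral_0^t exp(-k (t - s)) C(s) ds, evaluated exactly at the
# sample nodes of the input curve by the segmentwise recursion
#   I(t_{j+1}) = I(t_j) e^{-k h} + S_j
# where, for C(s) = c0 + c1 (s - t_j) on a segment of width h,
#   S_j = (c0 + c1 h) (1 - E)/k - c1 (1 - E (1 + k h))/k^2,  E = e^{-k h}.
# The k -> 0 and k h -> 0 limits use series forms to avoid cancellation.
exp_conv <- function(time_s, values, k_per_s) {
  n <- length(time_s)
  out <- numeric(n)
  if (k_per_s < 0) stop("rate constant must be non-negative")
  h <- diff(time_s)
  c0 <- values[-n]
  c1 <- diff(values) / h
  if (k_per_s == 0) {
    seg <- c0 * h + c1 * h^2 / 2
    out <- c(0, cumsum(seg))
    return(out)
  }
  k <- k_per_s
  kh <- k * h
  E <- exp(-kh)
  i1 <- -expm1(-kh) / k # integral of e^{-ku} over [0, h]
  # integral of u e^{-ku} over [0, h]; series for small kh avoids cancellation
  i2 <- ifelse(
    kh < 1e-4,
    h^2 / 2 - k * h^3 / 3 + k^2 * h^4 / 8,
    (1 - E * (1 + kh)) / k^2
  )
  seg <- (c0 + c1 * h) * i1 - c1 * i2
  acc <- 0
  for (j in seq_len(n - 1L)) {
    acc <- acc * E[j] + seg[j]
    out[j + 1L] <- acc
  }
  out
}

# Tissue impulse response convolved with the input curve, frame-averaged.
# Time base is minutes for the kinetic rate constants (K1 mL/min/g, k2 1/min)
# while curves are sampled in seconds, hence the 1/60 factor.
tissue_basis_tac <- function(aif, k2_per_min, schedule) {
  conv <- exp_conv(aif$time_s, aif$activity, k2_per_min / 60)
  cv <- blood_curve(aif$time_s, conv / 60, units = attr(aif, "units") %||% "Bq/mL")
  frame_average(cv, schedule)$value
}
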