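#' Autoregressive power spectrum by Burg's method
#'
#' Fits an AR(`order`) model by Burg's recursion (reflection coefficients
#' minimizing the combined forward and backward prediction error; via
#' [stats::ar.burg()]) and evaluates the parametric power spectral density
#' on `n_freq` equally spaced frequencies spanning `[0, fs/2]`:
#' `P(f) = sigma^2 / (fs * |1 - sum_k a_k exp(-2 pi i f k / fs)|^2)`.
#' The signal mean is removed before fitting, so a constant (in particular
#' all-zero) signal returns an all-zero spectrum by convention.
#'
#' @param x Numeric signal, longer than `order`.
#' @param order AR model order (default 20).
#' @param n_freq Number of frequency-grid points (default 512).
#' @param fs Sampling rate in Hz.
#' @return A tibble with columns `frequency` (Hz) and `power` (>= 0).
#' @export
burg_psd <- function(x, order = 20, n_freq = 512, fs = 500) {
  stopifnot(is.numeric(x), order >= 1, n_freq >= 2, fs > 0)
  if (length(x) <= order) {
    abort(sprintf("signal length (%d) must exceed the AR order (%d)",
                  length(x), order))
  }
  freq <- seq(0, fs / 2, length.out = n_freq)
  if (all(x == x[1])) {
    return(tibble(frequency = freq, power = numeric(n_freq)))
  }
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  a <- fit$ar
  # |1 - sum a_k z^-k|^2 on the unit circle, z = exp(2 pi i f / fs)
  k <- seq_along(a)
  denom <- vapply(freq, function(f) {
    z <- exp(-2i * pi * f * k / fs)
    Mod(1 - sum(a * z))^2
  }, numeric(1))
  power <- as.numeric(fit$var.pred) / (fs * denom)
  tibble(frequency = freq, power = pmax(power, 0))
}

#' Spectral summary features
#'
#' Reduces a power spectrum to the three frequency-domain features:
#' `f_max`, the frequency of maximum power; `f_mean`, the power-weighted
#' mean frequency; and `A_lf`, the rectangle-rule power in the low band
#' containing the P300 (bin power times bin width, summed over
#' `band_lo <= f <= band_hi`). An all-zero spectrum returns `(0, 0, 0)` by
#' convention.
#'
#' @param spectrum A tibble with `frequency` and `power` columns (from
#'   [burg_psd()]).
#' @param band_lo,band_hi Low-band limits in Hz; the defaults match the
#'   0.1-3.9 Hz band of the level-6 wavelet approximation.
#' @return Named numeric vector `(f_max, f_mean, A_lf)`.
#' @export
frequency_features <- function(spectrum, band_lo = 0.1, band_hi = 3.9) {
  stopifnot(all(c("frequency", "power") %in% names(spectrum)))
  f <- spectrum$frequency
  p <- spectrum$power
  if (any(p < 0) || anyNA(p)) abort("spectrum powers must be finite and >= 0")
  tot <- sum(p)
  if (tot == 0) {
    return(c(f_max = 0, f_mean = 0, A_lf = 0))
  }
  bin_width <- if (length(f) > 1) f[2] - f[1] else 1
  in_band <- f >= band_lo & f <= band_hi
  c(f_max = f[which.max(p)],
    f_mean = sum(f * p) / tot,
    A_lf = sum(p[in_band]) * bin_width)
}
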