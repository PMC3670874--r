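# Discrete wavelet decomposition used for the 22 low-band features.
#
# The analysis cascade repeatedly convolves with the low-pass analysis
# filter (full convolution over a zero-padded signal) and downsamples by
# two, keeping even output positions; one level maps a length-n signal to
# floor((n + L - 1)/2) approximation coefficients for a length-L filter.
# Six levels of a length-16 filter applied to a 500-sample epoch give
# 500 -> 257 -> 136 -> 75 -> 45 -> 30 -> 22 coefficients, and the level-6
# approximation band is [0, (fs/2)/2^6] = [0, 3.90625] Hz at fs = 500 --
# the frequency range that carries the P300.

# Orthonormal Daubechies extremal-phase analysis low-pass filter with 8
# vanishing moments (16 taps). Sums to sqrt(2), unit Euclidean norm,
# orthogonal to its even shifts.
db8_dec_lo <- function() {
  c(-1.17476784124769535e-04, 6.75449406450569331e-04,
    -3.91740373376947050e-04, -4.87035299345157414e-03,
    8.74609404740577662e-03, 1.39810279173982824e-02,
    -4.40882539307947546e-02, -1.73693010018075474e-02,
    1.28747426620478472e-01, 4.72484573913282795e-04,
    -2.84015542961546907e-01, -1.58291052563493059e-02,
    5.85354683654206731e-01, 6.75630736297289758e-01,
    3.12871590914299946e-01, 5.44158422431040081e-02)
}

# One analysis step: zero-padded full convolution then dyadic downsampling.
dwt_step <- function(x, h) {
  full <- stats::convolve(x, rev(h), type = "open")
  full[seq(2, length(full), by = 2)]
}

# Number of coefficients after one level (zero-padding mode).
dwt_coeff_len <- function(n, filter_len) (n + filter_len - 1) %/% 2

#' Level-`levels` approximation coefficients of a response
#'
#' Runs the low-pass branch of a `levels`-deep discrete wavelet
#' decomposition (zero-padding boundary handling) and returns the final
#' approximation coefficient set. With the default length-16 Daubechies
#' filter, 6 levels and a 500-sample epoch this set has exactly 22
#' coefficients covering the 0-3.9 Hz band.
#'
#' @param x Numeric signal (one response's samples).
#' @param levels Decomposition depth.
#' @param filter Low-pass analysis filter coefficients.
#' @return Numeric vector of approximation coefficients.
#' @export
dwt_approx <- function(x, levels = 6, filter = db8_dec_lo()) {
  stopifnot(is.numeric(x), length(x) > 0, levels >= 1)
  a <- as.numeric(x)
  for (i in seq_len(levels)) a <- dwt_step(a, filter)
  a
}

#' The 22 wavelet features of a response
#'
#' Wrapper around [dwt_approx()] that enforces the feature contract: the
#' approximation set must have exactly `n_expected` coefficients (22 for a
#' 500-sample epoch, 6 levels, a 16-tap filter), returned as named features
#' `W_1 ... W_22`. A signal/filter/levels combination yielding a different
#' count raises an error stating the computed count.
#'
#' @inheritParams dwt_approx
#' @param n_expected Required coefficient count.
#' @return Named numeric vector `W_1 ... W_{n_expected}`.
#' @export
wavelet_features <- function(x, levels = 6, filter = db8_dec_lo(),
                             n_expected = 22) {
  a <- dwt_approx(x, levels = levels, filter = filter)
  if (length(a) != n_expected) {
    abort(sprintf(
      "wavelet configuration yields %d approximation coefficients, not %d (signal length %d, filter length %d, %d levels)",
      length(a), n_expected, length(x), length(filter), levels))
  }
  setNames(a, paste0("W_", seq_along(a)))
}
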