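#' Names of the 31 response features, in canonical column order
#'
#' Six time-domain features (`V_max`, `t_max`, `R_LA`, `V_min`, `V_ptp`,
#' `A_p`), three frequency-domain features from the Burg spectrum
#' (`f_max`, `f_mean`, `A_lf`) and the 22 level-6 wavelet approximation
#' coefficients (`W_1 ... W_22`).
#'
#' @return Character vector of length 31.
#' @export
feature_names <- function() {
  c("V_max", "t_max", "R_LA", "V_min", "V_ptp", "A_p",
    "f_max", "f_mean", "A_lf", paste0("W_", 1:22))
}

#' Time-domain features of one response
#'
#' Computed over the post-stimulus window (time >= 0): `V_max`/`V_min` are
#' the extremes in microvolts, `t_max` the time of the maximum in seconds
#' from stimulus onset, `R_LA = t_max / V_max` (0 by convention when
#' `V_max = 0`), `V_ptp = V_max - V_min`, and `A_p` the positive area
#' `sum(max(sample, 0)) / fs` in microvolt-seconds.
#'
#' @param samples Numeric amplitude vector.
#' @param times Time of each sample, seconds relative to stimulus onset.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of the six features.
#' @export
time_domain_features <- function(samples, times, fs) {
  stopifnot(length(samples) == length(times), fs > 0)
  post <- times >= 0
  if (!any(post)) abort("empty post-stimulus analysis window")
  x <- samples[post]
  tt <- times[post]
  v_max <- max(x)
  v_min <- min(x)
  t_max <- tt[which.max(x)]
  c(V_max = v_max,
    t_max = t_max,
    R_LA = if (v_max == 0) 0 else t_max / v_max,
    V_min = v_min,
    V_ptp = v_max - v_min,
    A_p = sum(pmax(x, 0)) / fs)
}

#' Extract the 31-feature table from averaged responses
#'
#' Builds one feature row per response: time-domain features on the
#' post-stimulus window, frequency-domain features from the Burg spectrum
#' of the full epoch, and the 22 wavelet approximation coefficients of the
#' full epoch. Deterministic; labels and subject IDs are carried through.
#'
#' @param epochs An [erp_epochs] tibble of (typically averaged) responses.
#' @param burg_order AR order for the Burg spectrum.
#' @param n_freq Frequency-grid size for the spectrum.
#' @param band_lo,band_hi Low band for `A_lf`, Hz.
#' @param levels,filter Wavelet decomposition depth and analysis filter.
#' @return A tibble with columns `subject_id`, `label` and the 31 features
#'   of [feature_names()], in order.
#' @export
extract_features <- function(epochs, burg_order = 20, n_freq = 512,
                             band_lo = 0.1, band_hi = 3.9,
                             levels = 6, filter = db8_dec_lo()) {
  stopifnot(inherits(epochs, "erp_epochs"))
  fs <- epochs_fs(epochs)
  tt <- epoch_times(epochs)
  m <- epoch_matrix(epochs)
  empty <- as_tibble(matrix(numeric(0), 0, length(feature_names()),
                            dimnames = list(NULL, feature_names())))
  if (nrow(m) == 0) {
    return(dplyr::bind_cols(tibble(subject_id = character(), label = integer()),
                            empty))
  }
  feats <- lapply(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    row <- tryCatch({
      td <- time_domain_features(x, tt, fs)
      fd <- frequency_features(burg_psd(x, order = burg_order,
                                        n_freq = n_freq, fs = fs),
                               band_lo = band_lo, band_hi = band_hi)
      wv <- wavelet_features(x, levels = levels, filter = filter)
      c(td, fd, wv)
    }, error = function(e) {
      abort(sprintf("feature extraction failed on response row %d: %s",
                    i, conditionMessage(e)))
    })
    row
  })
  fm <- do.call(rbind, feats)
  dplyr::bind_cols(
    tibble(subject_id = epochs$subject_id, label = epochs$label),
    as_tibble(fm[, feature_names(), drop = FALSE])
  )
}

#' Min-max feature normalization to \[-1, 1\]
#'
#' `normalizer_fit()` learns the per-feature minimum and maximum from a
#' training table; `normalizer_apply()` maps each feature through
#' `x' = 2 (x - min) / (max - min) - 1`, so training values land in
#' `[-1, 1]` (training min at -1, max at +1). A constant training feature
#' maps to 0. Values of unseen rows outside the training range are not
#' clipped and may fall outside `[-1, 1]`.
#'
#' @param table A feature table (output of [extract_features()]).
#' @param columns Feature columns to normalize (default: all 31).
#' @return `normalizer_fit()`: an object of class `feature_normalizer`;
#'   `normalizer_apply()`: the table with normalized feature columns.
#' @export
normalizer_fit <- function(table, columns = feature_names()) {
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols) > 0) {
    abort(paste("table is missing feature columns:",
                paste(missing_cols, collapse = ", ")))
  }
  if (nrow(table) == 0) abort("cannot fit a normalizer on an empty table")
  mins <- vapply(table[columns], min, numeric(1))
  maxs <- vapply(table[columns], max, numeric(1))
  structure(list(min = mins, max = maxs, columns = columns),
            class = "feature_normalizer")
}

#' @rdname normalizer_fit
#' @param normalizer A fitted `feature_normalizer`.
#' @export
normalizer_apply <- function(normalizer, table) {
  if (!inherits(normalizer, "feature_normalizer")) {
    abort("`normalizer` must come from normalizer_fit()")
  }
  out <- table
  for (col in normalizer$columns) {
    lo <- normalizer$min[[col]]
    hi <- normalizer$max[[col]]
    out[[col]] <- if (hi == lo) {
      rep(0, nrow(table))
    } else {
      2 * (table[[col]] - lo) / (hi - lo) - 1
    }
  }
  out
}

#' @method tidy feature_normalizer
#' @export
tidy.feature_normalizer <- function(x, ...) {
  tibble(feature = x$columns,
         min = unname(x$min[x$columns]),
         max = unname(x$max[x$columns]))
}
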