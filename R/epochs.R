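#' ERP epoch tables
#'
#' An epoch table is a tibble with one row per epoched response and columns
#' `subject_id`, `label` (+1 for the P3 / guilty-probe class, -1 for the
#' non-P3 / innocent-probe class) and fixed-length sample columns
#' `s0 ... s{N-1}` holding amplitudes in microvolts. Two pieces of metadata
#' ride along as attributes: the sampling rate `fs` (Hz) and the epoch start
#' time `t0` (seconds relative to stimulus onset; negative when a
#' pre-stimulus baseline exists). Sample `i` covers time `t0 + i/fs`.
#'
#' @param x A data frame with `subject_id`, `label` and `s0...` columns.
#' @param fs Sampling rate in Hz.
#' @param t0 Epoch start time in seconds relative to stimulus onset.
#'
#' @return A tibble of class `erp_epochs`.
#' @export
erp_epochs <- function(x, fs, t0) {
  x <- as_tibble(x)
  if (!all(c("subject_id", "label") %in% names(x))) {
    abort("epoch table needs `subject_id` and `label` columns")
  }
  sc <- sample_cols(x)
  if (length(sc) == 0) abort("epoch table has no sample columns (s0, s1, ...)")
  if (!all(x$label %in% c(-1, 1))) abort("labels must be +1 or -1")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) abort("`fs` must be a positive number")
  if (!is.numeric(t0) || length(t0) != 1) abort("`t0` must be a number")
  x$label <- as.integer(x$label)
  structure(x, fs = fs, t0 = t0, class = c("erp_epochs", class(x)))
}

sample_cols <- function(x) grep("^s[0-9]+$", names(x), value = TRUE)

epochs_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) abort("epoch table lost its `fs` attribute; rebuild with erp_epochs()")
  fs
}

epochs_t0 <- function(x) {
  t0 <- attr(x, "t0")
  if (is.null(t0)) abort("epoch table lost its `t0` attribute; rebuild with erp_epochs()")
  t0
}

#' Extract the sample matrix and time axis of an epoch table
#'
#' @param x An `erp_epochs` tibble.
#' @return `epoch_matrix()`: a numeric matrix, one row per response.
#'   `epoch_times()`: the time in seconds of each sample column, relative to
#'   stimulus onset.
#' @export
epoch_matrix <- function(x) {
  as.matrix(x[sample_cols(x)])
}

#' @rdname epoch_matrix
#' @export
epoch_times <- function(x) {
  n <- length(sample_cols(x))
  fs <- epochs_fs(x)
  t0 <- epochs_t0(x)
  # when t0 falls on the sample grid, compute times as exact sample ratios
  # so the stimulus-onset sample is exactly 0 (not -2.8e-17)
  k0 <- t0 * fs
  if (abs(k0 - round(k0)) < 1e-6) k0 <- round(k0)
  (k0 + seq_len(n) - 1) / fs
}

# Rebuilds the class/attributes after internal manipulation.
rebuild_epochs <- function(x, template) {
  erp_epochs(x, fs = epochs_fs(template), t0 = epochs_t0(template))
}

#' Write / read epoch tables as tab-delimited text
#'
#' The on-disk format is a TSV with two comment header lines `#fs=` and
#' `#t0=` carrying the sampling metadata, then a header row
#' `subject_id  label  s0 ... s{N-1}`. Values round-trip within text-float
#' precision.
#'
#' @param x An `erp_epochs` tibble.
#' @param path File path.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()`
#'   returns an `erp_epochs` tibble.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "erp_epochs"))
  con <- file(path, "w")
  writeLines(c(
    sprintf("#fs=%.10g", epochs_fs(x)),
    sprintf("#t0=%.10g", epochs_t0(x))
  ), con)
  close(con)
  readr::write_tsv(as_tibble(unclass_epochs(x)), path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

unclass_epochs <- function(x) {
  attr(x, "fs") <- NULL
  attr(x, "t0") <- NULL
  class(x) <- setdiff(class(x), "erp_epochs")
  x
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, "="))]
    if (length(ln) != 1) abort(sprintf("epoch file is missing the #%s= header", key))
    as.numeric(sub(paste0("#", key, "="), "", ln, fixed = TRUE))
  }
  fs <- get_meta("fs")
  t0 <- get_meta("t0")
  # parsing problems (e.g. short rows) surface as NAs and are reported below
  x <- suppressWarnings(readr::read_tsv(path, comment = "#", progress = FALSE,
                                        show_col_types = FALSE))
  if (!"label" %in% names(x)) abort("epoch file has no `label` column")
  if (anyNA(x[sample_cols(x)])) {
    abort("epoch file has ragged or non-numeric sample rows")
  }
  erp_epochs(x, fs = fs, t0 = t0)
}

#' Plot class-average waveforms of an epoch table
#'
#' Averages all responses within each class and draws the two grand-average
#' waveforms against time, with stimulus onset marked.
#'
#' @param object An `erp_epochs` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot erp_epochs
#' @export
autoplot.erp_epochs <- function(object, ...) {
  tt <- epoch_times(object)
  m <- epoch_matrix(object)
  cls <- ifelse(object$label == 1, "P3 (guilty probe)", "non-P3 (innocent probe)")
  df <- tibble(
    time = rep(tt, times = 2),
    amplitude = c(
      colMeans(m[cls == "P3 (guilty probe)", , drop = FALSE]),
      colMeans(m[cls != "P3 (guilty probe)", , drop = FALSE])
    ),
    class = rep(c("P3 (guilty probe)", "non-P3 (innocent probe)"), each = length(tt))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$amplitude, colour = .data$class)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time relative to stimulus onset (s)",
                  y = expression("amplitude (" * mu * "V)"),
                  colour = NULL)
}
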