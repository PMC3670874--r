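#' Baseline-correct epochs on the pre-stimulus interval
#'
#' Subtracts, from every sample of a response, the mean of that response's
#' pre-stimulus samples (time < 0). Idempotent: correcting twice equals
#' correcting once.
#'
#' @param epochs An [erp_epochs] tibble with `t0 < 0` so a pre-stimulus
#'   interval exists.
#' @return The baseline-corrected [erp_epochs] tibble.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "erp_epochs"))
  if (epochs_t0(epochs) >= 0) {
    abort("no pre-stimulus interval: epoch starts at or after stimulus onset")
  }
  tt <- epoch_times(epochs)
  pre <- tt < 0
  m <- epoch_matrix(epochs)
  base <- rowMeans(m[, pre, drop = FALSE])
  m <- m - base
  out <- epochs
  out[sample_cols(epochs)] <- as_tibble(m)
  rebuild_epochs(out, epochs)
}

#' Average consecutive trials within each subject
#'
#' Pools consecutive, non-overlapping groups of `group_size` trials of the
#' same subject into sample-wise averages, enhancing the signal-to-noise
#' ratio of the P300. Trials left over after the last complete group are
#' dropped (`floor(n / group_size)` averages per subject). Grouping follows
#' the input row order.
#'
#' @param epochs An [erp_epochs] tibble; may hold several subjects, each
#'   with a single class label.
#' @param group_size Trials per average (the study design uses 5).
#' @return An [erp_epochs] tibble of averaged responses.
#' @export
average_trials <- function(epochs, group_size = 5) {
  stopifnot(inherits(epochs, "erp_epochs"))
  if (!is.numeric(group_size) || group_size < 1 || group_size != round(group_size)) {
    abort("`group_size` must be a positive whole number")
  }
  lab <- tapply(epochs$label, epochs$subject_id, function(l) length(unique(l)))
  if (any(lab > 1)) {
    abort("a subject carries more than one class label; cannot group trials")
  }
  sc <- sample_cols(epochs)
  out <- epochs %>%
    as_tibble() %>%
    group_by(.data$subject_id) %>%
    mutate(.grp = (row_number() - 1) %/% group_size,
           .keep_grp = .data$.grp < n() %/% group_size) %>%
    filter(.data$.keep_grp) %>%
    group_by(.data$subject_id, .data$.grp) %>%
    summarise(label = .data$label[1],
              across(all_of(sc), mean),
              .groups = "drop") %>%
    arrange(.data$subject_id, .data$.grp) %>%
    select(-".grp")
  rebuild_epochs(out[c("subject_id", "label", sc)], epochs)
}
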