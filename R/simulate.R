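#' Simulation configuration for synthetic probe-response epochs
#'
#' Builds and validates the parameter set for [simulate_epochs()]. The
#' defaults emulate a guilty-knowledge-test recording at the Pz electrode:
#' 14 subjects per class, 1-second epochs sampled at 500 Hz running from
#' 0.2 s before to 0.8 s after stimulus onset, and a P300 positivity in the
#' guilty-probe class peaking near 350 ms. With the default 105 trials per
#' subject and downstream 5-trial averaging this yields 21 averaged
#' responses per subject, i.e. 294 per class — roughly 300 per group.
#'
#' @param n_subjects_per_class Subjects in each of the guilty (P3) and
#'   innocent (non-P3) groups.
#' @param trials_per_subject Single-trial epochs recorded per subject.
#' @param avg_group_size Number of consecutive trials pooled into one
#'   average downstream (metadata here; the averaging itself is
#'   [average_trials()]).
#' @param fs Sampling rate in Hz.
#' @param epoch_start,epoch_end Epoch limits in seconds relative to
#'   stimulus onset; the epoch holds `round((epoch_end - epoch_start) * fs)`
#'   samples (500 at the defaults).
#' @param p3_amplitude_mean,p3_amplitude_sd Mean and trial-level SD of the
#'   P300 peak amplitude, microvolts.
#' @param p3_latency_mean,p3_latency_sd Mean and trial-level SD of the P300
#'   peak latency, seconds.
#' @param p3_width Full width of the raised-cosine P300 bump, seconds.
#' @param noise_sd Single-trial background noise SD, microvolts. For the
#'   AR(1) model this is the marginal (stationary) SD.
#' @param noise_model `"white"` for white Gaussian noise, `"ar1"` for an
#'   AR(1) background that mimics the low-pass character of bandpassed EEG.
#' @param ar1_coeff AR(1) coefficient, used when `noise_model = "ar1"`.
#' @param subject_amplitude_sd Between-subject SD of the P300 amplitude
#'   offset, microvolts.
#' @param seed Integer seed; fixed seed gives bit-identical datasets.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects_per_class = 14,
                       trials_per_subject = 105,
                       avg_group_size = 5,
                       fs = 500,
                       epoch_start = -0.2,
                       epoch_end = 0.8,
                       p3_amplitude_mean = 8,
                       p3_amplitude_sd = 2,
                       p3_latency_mean = 0.35,
                       p3_latency_sd = 0.03,
                       p3_width = 0.3,
                       noise_sd = 5,
                       noise_model = c("white", "ar1"),
                       ar1_coeff = 0.9,
                       subject_amplitude_sd = 2,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  cfg <- list(
    n_subjects_per_class = n_subjects_per_class,
    trials_per_subject = trials_per_subject,
    avg_group_size = avg_group_size,
    fs = fs, epoch_start = epoch_start, epoch_end = epoch_end,
    p3_amplitude_mean = p3_amplitude_mean, p3_amplitude_sd = p3_amplitude_sd,
    p3_latency_mean = p3_latency_mean, p3_latency_sd = p3_latency_sd,
    p3_width = p3_width, noise_sd = noise_sd, noise_model = noise_model,
    ar1_coeff = ar1_coeff, subject_amplitude_sd = subject_amplitude_sd,
    seed = as.integer(seed)
  )
  counts <- c("n_subjects_per_class", "trials_per_subject", "avg_group_size")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      abort(sprintf("`%s` must be a positive whole number", nm))
    }
  }
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be positive")
  if (epoch_end <= epoch_start) abort("`epoch_end` must exceed `epoch_start`")
  sds <- c("p3_amplitude_sd", "p3_latency_sd", "noise_sd", "subject_amplitude_sd")
  for (nm in sds) {
    if (cfg[[nm]] < 0) abort(sprintf("`%s` must be >= 0", nm))
  }
  if (p3_width <= 0) abort("`p3_width` must be positive")
  if (abs(ar1_coeff) >= 1) abort("`ar1_coeff` must lie in (-1, 1)")
  structure(cfg, class = "sim_config")
}

n_epoch_samples <- function(cfg) {
  as.integer(round((cfg$epoch_end - cfg$epoch_start) * cfg$fs))
}

# Raised-cosine (Hann) bump: amplitude `a`, centre `lat`, full width `width`.
# Smooth, compactly supported, monophasic -- a stylized P300.
raised_cosine <- function(t, a, lat, width) {
  inside <- abs(t - lat) <= width / 2
  out <- numeric(length(t))
  out[inside] <- a * 0.5 * (1 + cos(2 * pi * (t[inside] - lat) / width))
  out
}

sim_noise <- function(n, cfg) {
  if (cfg$noise_sd == 0) return(numeric(n))
  if (cfg$noise_model == "white") {
    rnorm(n, sd = cfg$noise_sd)
  } else {
    # innovations scaled so the stationary SD equals noise_sd
    innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar1_coeff^2)
    x <- numeric(n)
    x[1] <- rnorm(1, sd = cfg$noise_sd)
    e <- rnorm(n - 1, sd = innov_sd)
    for (i in seq_len(n - 1)) x[i + 1] <- cfg$ar1_coeff * x[i] + e[i]
    x
  }
}

#' Simulate single-trial probe-response epochs
#'
#' Generates single-trial epochs for `2 * n_subjects_per_class` subjects.
#' Guilty-class (`label = +1`) trials carry a raised-cosine P300 positivity
#' whose amplitude has a per-subject offset and whose latency jitters per
#' trial; innocent-class (`label = -1`) trials are background noise only.
#'
#' @param config A [sim_config()] object.
#' @return An [erp_epochs] tibble, one row per single trial, subjects
#'   `G01...` (label +1) and `I01...` (label -1).
#' @export
simulate_epochs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- n_epoch_samples(config)
  tt <- config$epoch_start + (seq_len(n) - 1) / config$fs
  with_seed(config$seed, {
    rows <- vector("list", 2 * config$n_subjects_per_class)
    k <- 0
    for (cls in c(1L, -1L)) {
      prefix <- if (cls == 1L) "G" else "I"
      for (s in seq_len(config$n_subjects_per_class)) {
        subj_amp <- config$p3_amplitude_mean +
          rnorm(1, sd = config$subject_amplitude_sd)
        m <- matrix(0, config$trials_per_subject, n)
        for (tr in seq_len(config$trials_per_subject)) {
          x <- sim_noise(n, config)
          if (cls == 1L) {
            amp <- subj_amp + rnorm(1, sd = config$p3_amplitude_sd)
            lat <- config$p3_latency_mean + rnorm(1, sd = config$p3_latency_sd)
            x <- x + raised_cosine(tt, amp, lat, config$p3_width)
          }
          m[tr, ] <- x
        }
        colnames(m) <- paste0("s", seq_len(n) - 1)
        k <- k + 1
        rows[[k]] <- dplyr::bind_cols(
          tibble(subject_id = sprintf("%s%02d", prefix, s),
                 label = cls),
          as_tibble(m)
        )
      }
    }
    erp_epochs(dplyr::bind_rows(rows), fs = config$fs, t0 = config$epoch_start)
  })
}

#' Simulate a feature table directly
#'
#' Bypasses the waveform stage and draws the 31 named features directly:
#' `n_informative` of the columns separate the classes (unit within-class
#' SD, class mean difference `effect_size`, a per-subject random offset of
#' SD `subject_sd`), the rest are pure standard-normal noise. Which columns
#' are informative is drawn at random from the 31 names. Useful for
#' stress-testing the ranking and the grid search with a known ground
#' truth. The default effect size puts the classes in the high-separability
#' regime characteristic of averaged P300 recordings.
#'
#' @param n_subjects_per_class Subjects per class.
#' @param responses_per_class Feature rows (averaged responses) per class,
#'   split evenly over subjects (remainder dropped).
#' @param n_informative Number of class-separating feature columns (0 for a
#'   pure-noise table).
#' @param effect_size Class mean difference of an informative column, in
#'   within-class SD units.
#' @param subject_sd Between-subject SD of the informative-column offset.
#' @param seed Integer seed.
#'
#' @return A list with `table` (a feature table: `subject_id`, `label`, 31
#'   feature columns) and `informative` (the informative column names).
#' @export
simulate_feature_table <- function(n_subjects_per_class = 10,
                                   responses_per_class = 200,
                                   n_informative = 3,
                                   effect_size = 3,
                                   subject_sd = 0.5,
                                   seed = 1L) {
  stopifnot(n_informative >= 0, n_informative <= length(feature_names()))
  per_subj <- responses_per_class %/% n_subjects_per_class
  if (per_subj < 1) abort("fewer responses than subjects per class")
  nms <- feature_names()
  with_seed(seed, {
    informative <- sort(sample(nms, n_informative))
    rows <- list()
    k <- 0
    for (cls in c(1L, -1L)) {
      prefix <- if (cls == 1L) "G" else "I"
      for (s in seq_len(n_subjects_per_class)) {
        m <- matrix(rnorm(per_subj * length(nms)), per_subj)
        colnames(m) <- nms
        for (col in informative) {
          shift <- (cls == 1L) * effect_size + rnorm(1, sd = subject_sd)
          m[, col] <- m[, col] + shift
        }
        k <- k + 1
        rows[[k]] <- dplyr::bind_cols(
          tibble(subject_id = sprintf("%s%02d", prefix, s), label = cls),
          as_tibble(m)
        )
      }
    }
    list(table = dplyr::bind_rows(rows), informative = informative)
  })
}
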