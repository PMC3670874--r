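# Shared fixtures and independent oracle implementations.

# Small, fast simulated dataset: 4 subjects per class, 20 trials each.
tiny_epochs <- function(seed = 42, ...) {
  simulate_epochs(sim_config(n_subjects_per_class = 4, trials_per_subject = 20,
                             seed = seed, ...))
}

# Naive two-pass implementation of the F-score formula, written directly
# from its definition as an independent oracle.
fscore_oracle <- function(values, labels) {
  xp <- values[labels == 1]
  xn <- values[labels == -1]
  m <- mean(values)
  mp <- mean(xp)
  mn <- mean(xn)
  num <- (mp - m)^2 + (mn - m)^2
  den <- sum((xp - mp)^2) / (length(xp) - 1) + sum((xn - mn)^2) / (length(xn) - 1)
  if (den == 0) {
    if (num == 0) 0 else Inf
  } else {
    num / den
  }
}

# Independent least-squares oracle: QR-based basic solution. Same residual
# as any LS solution; its Euclidean norm is >= the minimal-norm solution's.
lsq_oracle <- function(h, y) {
  fit <- qr(h)
  beta <- qr.coef(fit, y)
  beta[is.na(beta)] <- 0
  beta
}

# An erp_epochs table built by hand from a matrix of samples.
epochs_from_matrix <- function(m, fs, t0, label = 1L, subject_id = "S01") {
  colnames(m) <- paste0("s", seq_len(ncol(m)) - 1)
  erp_epochs(dplyr::bind_cols(
    tibble::tibble(subject_id = rep(subject_id, nrow(m)),
                   label = rep(as.integer(label), nrow(m))),
    tibble::as_tibble(m)
  ), fs = fs, t0 = t0)
}

# Data whose sample covariance is exactly [[2,1],[1,2]]: eigenvalues 3 and
# 1, first axis along (1,1)/sqrt(2).
cov_2_1_data <- function() {
  z <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))  # cov(z) = 2/3 * I
  v <- cbind(c(1, 1) / sqrt(2), c(1, -1) / sqrt(2))
  sweep(z, 2, sqrt(c(3, 1) * 3 / 2), "*") %*% t(v)
}

# Raised-cosine bump evaluated on a time axis (mirrors the simulator shape).
hann_bump <- function(tt, a, lat, width) {
  out <- numeric(length(tt))
  inside <- abs(tt - lat) <= width / 2
  out[inside] <- a * 0.5 * (1 + cos(2 * pi * (tt[inside] - lat) / width))
  out
}
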