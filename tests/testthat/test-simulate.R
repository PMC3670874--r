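test_that("epoch geometry follows the sampling configuration", {
  ep <- tiny_epochs()
  expect_equal(length(sample_cols(ep)), 500)
  expect_equal(nrow(ep), 2 * 4 * 20)
  expect_setequal(unique(ep$label), c(1L, -1L))
  tt <- epoch_times(ep)
  expect_equal(tt[1], -0.2)
  expect_equal(tt[2] - tt[1], 1 / 500)
  expect_lt(max(tt), 0.8)  # half-open epoch [t0, t0 + N/fs)
})

test_that("a fixed seed regenerates the dataset bit-identically", {
  a <- tiny_epochs(seed = 9)
  b <- tiny_epochs(seed = 9)
  expect_identical(a, b)
  expect_false(identical(epoch_matrix(a), epoch_matrix(tiny_epochs(seed = 10))))
})

test_that("noiseless construction puts the P3 peak at the configured point", {
  cfg <- sim_config(n_subjects_per_class = 2, trials_per_subject = 4,
                    noise_sd = 0, p3_amplitude_mean = 10, p3_amplitude_sd = 0,
                    p3_latency_mean = 0.35, p3_latency_sd = 0,
                    subject_amplitude_sd = 0, seed = 1)
  ep <- simulate_epochs(cfg)
  m <- epoch_matrix(ep)
  tt <- epoch_times(ep)
  p3 <- ep$label == 1
  expect_equal(unname(apply(m[p3, ], 1, max)), rep(10, sum(p3)))
  peak_t <- tt[apply(m[p3, ], 1, which.max)]
  expect_equal(unname(peak_t), rep(0.35, sum(p3)), tolerance = 1e-8)
  expect_true(all(m[!p3, ] == 0))
})

test_that("default design yields about 300 averaged responses per class", {
  cfg <- sim_config()
  expect_equal(cfg$n_subjects_per_class, 14)
  expect_equal(cfg$trials_per_subject %/% cfg$avg_group_size, 21)
  expect_equal(14 * 21, 294)
})

test_that("class-mean amplitude difference at the latency mean recovers the configured amplitude", {
  # amplitude calibration check: latency jitter off (jitter shifts the peak
  # away from the latency mean and would bias the peak-sample average low),
  # no subject-level variability, many trials from one subject pair
  cfg <- sim_config(n_subjects_per_class = 1, trials_per_subject = 2000,
                    subject_amplitude_sd = 0, p3_latency_sd = 0, seed = 33)
  ep <- simulate_epochs(cfg)
  m <- epoch_matrix(ep)
  at_lat <- which.min(abs(epoch_times(ep) - cfg$p3_latency_mean))
  p3 <- m[ep$label == 1, at_lat]
  np3 <- m[ep$label == -1, at_lat]
  diff <- mean(p3) - mean(np3)
  se <- sqrt(var(p3) / length(p3) + var(np3) / length(np3))
  expect_lt(abs(diff - cfg$p3_amplitude_mean), 3 * se)
  # noise-only trials average to zero
  expect_lt(abs(mean(np3)), 3 * sd(np3) / sqrt(length(np3)))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_subjects_per_class = 0), "positive whole")
  expect_error(sim_config(trials_per_subject = 2.5), "positive whole")
  expect_error(sim_config(fs = -1), "positive")
  expect_error(sim_config(noise_sd = -1), ">= 0")
  expect_error(sim_config(epoch_end = -0.3), "exceed")
  expect_error(sim_config(ar1_coeff = 1.2), "ar1")
})

test_that("AR(1) noise has the configured stationary spread", {
  cfg <- sim_config(n_subjects_per_class = 1, trials_per_subject = 200,
                    noise_model = "ar1", ar1_coeff = 0.9, noise_sd = 5,
                    seed = 4)
  ep <- simulate_epochs(cfg)
  x <- as.numeric(epoch_matrix(ep)[ep$label == -1, ])
  expect_equal(sd(x), 5, tolerance = 0.1)
  # successive samples are positively correlated, unlike white noise
  m <- epoch_matrix(ep)[ep$label == -1, ]
  r <- cor(as.numeric(m[, -1]), as.numeric(m[, -ncol(m)]))
  expect_gt(r, 0.8)
})

test_that("the direct feature-table generator marks its informative columns", {
  sim <- simulate_feature_table(n_subjects_per_class = 4,
                                responses_per_class = 40, n_informative = 3,
                                seed = 2)
  expect_equal(nrow(sim$table), 80)
  expect_length(sim$informative, 3)
  expect_true(all(sim$informative %in% feature_names()))
  gap <- vapply(feature_names(), function(col) {
    mean(sim$table[[col]][sim$table$label == 1]) -
      mean(sim$table[[col]][sim$table$label == -1])
  }, numeric(1))
  expect_setequal(names(sort(gap, decreasing = TRUE)[1:3]), sim$informative)
  noise_free <- simulate_feature_table(n_subjects_per_class = 4,
                                       responses_per_class = 40,
                                       n_informative = 0, seed = 2)
  expect_length(noise_free$informative, 0)
})
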