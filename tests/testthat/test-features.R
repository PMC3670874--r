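test_that("time-domain features match noiseless constructions", {
  fs <- 500
  tt <- -0.2 + (0:499) / fs
  bump <- hann_bump(tt, a = 1, lat = 0.3, width = 0.2)
  td <- time_domain_features(bump, tt, fs)
  expect_equal(td[["V_max"]], 1)
  expect_equal(td[["t_max"]], 0.3, tolerance = 1e-8)
  expect_equal(td[["R_LA"]], 0.3, tolerance = 1e-8)
  expect_equal(td[["V_min"]], 0)
  expect_equal(td[["V_ptp"]], 1)

  zero <- time_domain_features(rep(0, 500), tt, fs)
  expect_equal(unname(zero[c("V_max", "V_min", "V_ptp", "A_p", "R_LA")]),
               rep(0, 5))

  # +2 uV over a full 1-second window integrates to 2 uV.s
  tt1 <- (0:499) / fs
  expect_equal(time_domain_features(rep(2, 500), tt1, fs)[["A_p"]], 2)

  expect_error(time_domain_features(1:5, seq(-5, -1) / 10, 10), "post-stimulus")
})

test_that("Burg spectrum localizes a pure sinusoid and stays flat on white noise", {
  fs <- 500
  x <- sin(2 * pi * 5 * (0:499) / fs)
  spec <- burg_psd(x, order = 20, n_freq = 512, fs = fs)
  bin <- spec$frequency[2] - spec$frequency[1]
  expect_lt(abs(spec$frequency[which.max(spec$power)] - 5), bin + 1e-9)
  expect_true(all(spec$power >= 0))

  # flatness: no bin dominates the median by 10x for low-order white noise
  set.seed(8)
  ratios <- replicate(20, {
    s <- burg_psd(rnorm(500), order = 4, n_freq = 256, fs = fs)
    max(s$power) / median(s$power)
  })
  expect_lt(median(ratios), 10)

  zero <- burg_psd(rep(0, 100), order = 10, n_freq = 64, fs = fs)
  expect_true(all(zero$power == 0))
  expect_error(burg_psd(rnorm(10), order = 10), "exceed")
})

test_that("spectral summary features follow their definitions", {
  spec <- tibble::tibble(frequency = c(0, 1, 2, 3, 4, 5, 6),
                         power = c(0, 0, 0, 2, 0, 0, 0))
  f <- frequency_features(spec)
  expect_equal(f[["f_max"]], 3)
  expect_equal(f[["f_mean"]], 3)
  expect_equal(f[["A_lf"]], 2 * 1)  # bin power x 1 Hz bin width

  two <- tibble::tibble(frequency = 0:6, power = c(0, 0, 1, 0, 0, 0, 1))
  f2 <- frequency_features(two)
  expect_equal(f2[["f_mean"]], 4)      # equal bins at 2 and 6 Hz
  expect_equal(f2[["A_lf"]], 1)        # only the 2 Hz bin is in [0.1, 3.9]

  zero <- tibble::tibble(frequency = 0:6, power = rep(0, 7))
  expect_equal(unname(frequency_features(zero)), c(0, 0, 0))
})

test_that("the wavelet cascade count follows the zero-padding recursion", {
  # oracle: n_j = floor((n_{j-1} + L - 1) / 2)
  count_oracle <- function(n, L, levels) {
    for (i in seq_len(levels)) n <- (n + L - 1) %/% 2
    n
  }
  expect_equal(count_oracle(500, 16, 6), 22)
  for (n in c(100, 250, 500, 777)) {
    for (lv in c(1, 3, 6)) {
      expect_length(dwt_approx(rnorm(n), levels = lv), count_oracle(n, 16, lv))
    }
  }
  expect_length(wavelet_features(rnorm(500)), 22)
  expect_equal(names(wavelet_features(rep(0, 500))), paste0("W_", 1:22))
})

test_that("a mismatched wavelet configuration reports the computed count", {
  expect_error(wavelet_features(rnorm(400)), "21")
  expect_error(wavelet_features(rnorm(500), levels = 5), "30")
})

test_that("the analysis filter is orthonormal and the transform is linear", {
  h <- p300elm:::db8_dec_lo()
  expect_length(h, 16)
  expect_equal(sum(h), sqrt(2), tolerance = 1e-12)
  expect_equal(sum(h^2), 1, tolerance = 1e-12)
  for (k in 1:7) {  # orthogonal to its even shifts
    expect_equal(sum(h[seq_len(16 - 2 * k)] * h[seq_len(16 - 2 * k) + 2 * k]),
                 0, tolerance = 1e-12)
  }
  x <- rnorm(500)
  expect_equal(dwt_approx(3.5 * x), 3.5 * dwt_approx(x), tolerance = 1e-10)
  expect_equal(dwt_approx(rep(0, 500)), rep(0, 22))
})

test_that("level-6 approximation coefficients agree with an independent DWT", {
  # frozen from PyWavelets 1.9.0: pywt.wavedec(x, 'db8', mode='zero', level=6)[0]
  # with x = sin(2*pi*3*t/500) + 0.5*cos(2*pi*11*t/500), t = 0..499
  t <- 0:499
  x <- sin(2 * pi * 3 * t / 500) + 0.5 * cos(2 * pi * 11 * t / 500)
  expected <- c(-0.000000000000, 0.000000000163, -0.000000027051, 0.000002970837,
                -0.000024138649, -0.000100228268, 0.001756149046, -0.012727157994,
                0.065791677254, -0.251425980754, 0.745547153966, -1.891100789056,
                4.792156691725, 2.535971189416, -6.699468126371, 7.493385707815,
                -4.554216520756, -0.489220196792, 4.795418167359, -5.437970216732,
                -1.092762154980, -0.001014170177)
  expect_equal(unname(dwt_approx(x)), expected, tolerance = 1e-9)
})

test_that("the level-6 band edge matches the 0.1-3.9 Hz label", {
  # six halvings of the 250 Hz Nyquist band leave [0, 3.90625] Hz
  expect_equal((500 / 2) / 2^6, 3.90625)
})

test_that("extract_features builds a 31-column table and is deterministic", {
  ep <- average_trials(baseline_correct(tiny_epochs(seed = 6)), 5)
  ft <- extract_features(ep)
  expect_equal(names(ft), c("subject_id", "label", feature_names()))
  expect_equal(nrow(ft), nrow(ep))
  expect_length(feature_names(), 31)
  expect_length(grep("^W_", feature_names()), 22)
  expect_identical(ft, extract_features(ep))
  expect_equal(ft$V_ptp, ft$V_max - ft$V_min)
  expect_true(all(ft$A_p >= 0))
  expect_true(all(ft$A_lf >= 0))
  expect_true(all(ft$f_max >= 0 & ft$f_max <= 250))

  empty <- extract_features(ep[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), c("subject_id", "label", feature_names()))

  dup <- erp_epochs(ep[c(1, 1), ], fs = 500, t0 = -0.2)
  rows <- extract_features(dup)
  expect_equal(rows[1, ], rows[2, ])
})

test_that("P3 responses have larger mean V_max than non-P3 responses", {
  ep <- average_trials(baseline_correct(tiny_epochs(seed = 12)), 5)
  ft <- extract_features(ep)
  expect_gt(mean(ft$V_max[ft$label == 1]), mean(ft$V_max[ft$label == -1]))
})

test_that("min-max normalization maps training range to [-1, 1] without clipping", {
  tab <- tibble::tibble(label = c(1, 1, -1, -1), a = c(0, 10, 5, 2),
                        b = c(5, 5, 5, 5))
  norm <- normalizer_fit(tab, columns = c("a", "b"))
  out <- normalizer_apply(norm, tab)
  expect_equal(range(out$a), c(-1, 1))
  expect_equal(out$b, rep(0, 4))  # constant column convention

  unseen <- normalizer_apply(norm, tibble::tibble(a = 20, b = 9))
  expect_equal(unseen$a, 3)  # outside the training range, not clipped

  expect_error(normalizer_apply(list(), tab), "normalizer_fit")
  expect_error(normalizer_fit(tab[0, ], columns = "a"), "empty")
  expect_error(normalizer_fit(tab, columns = "missing"), "missing")
})
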