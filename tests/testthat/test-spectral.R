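# Build a minimal epoch_set directly from a signal matrix (trials x ch x t).
as_epochs <- function(arr, fs = 1000, t0 = 0) {
  n <- dim(arr)[1]
  structure(list(data = list(tf = arr),
                 windows = list(tf = c(t0, t0 + dim(arr)[3] / fs)),
                 fs = fs,
                 trials = data.frame(session_idx = rep(0L, n),
                                     trial_idx = seq_len(n) - 1L,
                                     t_step1_peck = rep(10, n),
                                     t_step2_peck = rep(11, n)),
                 excluded = NULL),
            class = "epoch_set")
}

test_that("a pure tone peaks at the nearest frequency bin (FFT cross-check)", {
  fs <- 1000
  t <- (0:(2 * fs - 1)) / fs
  x <- array(sin(2 * pi * 20 * t), c(1, 1, length(t)))
  tf <- morlet_power(as_epochs(x, fs), freqs = log_freqs())
  prof <- apply(tf$power[1, 1, , ], 1, mean)
  peak_freq <- tf$freqs[which.max(prof)]
  # FFT oracle for the true spectral peak
  sp <- abs(fft(x[1, 1, ]))^2
  f_axis <- (seq_along(sp) - 1) * fs / length(sp)
  fft_peak <- f_axis[which.max(sp[f_axis <= fs / 2])]
  expect_lt(abs(log(peak_freq / fft_peak)), log(log_freqs()[2] / log_freqs()[1]) * 1.5)
  expect_gt(prof[which.max(prof)] /
              prof[which.min(abs(tf$freqs - 5))], 10)
  # monotone decay of tone power over +/- one octave around the peak
  oct <- which(tf$freqs >= 10 & tf$freqs <= 40)
  ppk <- which.max(prof)
  expect_true(all(diff(prof[oct[oct <= ppk]]) >= 0))
  expect_true(all(diff(prof[oct[oct >= ppk]]) <= 0))
})

test_that("the transform is zero on silence and quadratic in amplitude", {
  fs <- 500
  z <- array(0, c(1, 2, fs))
  tfz <- morlet_power(as_epochs(z, fs), freqs = c(4, 10, 25))
  expect_true(all(tfz$power == 0))
  set.seed(51)
  x <- array(rnorm(2 * 1 * fs), c(1, 2, fs))
  tf1 <- morlet_power(as_epochs(x, fs), freqs = c(4, 10, 25))
  tf2 <- morlet_power(as_epochs(2 * x, fs), freqs = c(4, 10, 25))
  expect_equal(tf2$power, 4 * tf1$power, tolerance = 1e-12)
})

test_that("peck masking blanks +/- 50 ms and propagates as missing", {
  fs <- 1000
  x <- array(1, c(1, 1, 2 * fs))
  tf <- morlet_power(as_epochs(x, fs, t0 = -1), freqs = c(5, 20))
  tfm <- mask_peck_artifacts(tf, peck_times = list(0))
  hit <- abs(tfm$times - 0) <= 0.05 + 1e-12
  expect_true(all(is.na(tfm$power[1, 1, , hit])))
  expect_false(anyNA(tfm$power[1, 1, , !hit]))
  expect_identical(sum(hit), 101L)
  # no pecks in span: identity
  tfi <- mask_peck_artifacts(tf, peck_times = list(numeric(0)))
  expect_identical(tfi$power, tf$power)
})

test_that("masked averages ignore artifact samples instead of absorbing them", {
  # the 7-cycle wavelet at 45 Hz has a ~25 ms envelope SD, so a mask of
  # +/- 0.1 s (4 SD) contains the smeared transient energy
  fs <- 1000
  t <- (0:(2 * fs - 1)) / fs - 1
  clean <- 10 * sin(2 * pi * 45 * (t + 1))
  dirty <- clean
  dirty[abs(t) <= 0.01] <- dirty[abs(t) <= 0.01] + 500  # transient at 0
  arr <- array(NA_real_, c(2, 1, length(t)))
  arr[1, 1, ] <- clean; arr[2, 1, ] <- dirty
  tf <- morlet_power(as_epochs(arr, fs, t0 = -1), freqs = c(45))
  tfm <- mask_peck_artifacts(tf, peck_times = list(numeric(0), 0),
                             half_width = 0.1)
  win <- tfm$times >= -0.4 & tfm$times < 0.4
  truth <- mean(tf$power[1, 1, 1, win])
  masked_mean <- mean(tfm$power[2, 1, 1, win], na.rm = TRUE)
  unmasked_mean <- mean(tf$power[2, 1, 1, win])
  expect_lt(abs(masked_mean - truth) / truth, 0.05)
  expect_gt(unmasked_mean, 2 * truth)
})

test_that("baseline normalisation is a ratio and cancels global scaling", {
  fs <- 200
  set.seed(52)
  x <- array(rnorm(3 * 2 * 3 * fs), c(3, 2, 3 * fs))
  tf <- morlet_power(as_epochs(x, fs, t0 = -2.5), freqs = c(5, 20, 40))
  tfn <- baseline_normalize(tf, c(-2.5, -2.0))
  expect_true(tfn$normalized)
  # statistically identical epoch: normalised power near 1 on average
  expect_lt(abs(mean(tfn$power) - 1), 0.35)
  # constant scaling cancels exactly
  tf2 <- morlet_power(as_epochs(5 * x, fs, t0 = -2.5), freqs = c(5, 20, 40))
  tfn2 <- baseline_normalize(tf2, c(-2.5, -2.0))
  expect_equal(tfn2$power, tfn$power, tolerance = 1e-12)
})

test_that("band averaging respects the printed band edges", {
  bands <- lfp_bands()
  expect_identical(bands$f_lo, c(1, 4, 8, 12, 30, 60))
  expect_identical(bands$f_hi, c(4, 8, 12, 30, 60, 100))
  freqs <- log_freqs()
  expect_identical(length(freqs), 50L)
  expect_equal(freqs[1], 1); expect_equal(freqs[50], 100)
  rat <- diff(log(freqs))
  expect_lt(max(abs(rat - rat[1])), 1e-9)  # log-spaced
  # uniform power of 1 gives band means of 1
  fs <- 100
  tf <- structure(list(power = array(1, c(2, 3, 50, 100)), freqs = freqs,
                       times = seq(0, 0.99, by = 0.01), fs = fs,
                       normalized = TRUE,
                       trials = data.frame(t_step1_peck = c(1, 2),
                                           t_step2_peck = c(2, 3))),
                  class = "epoched_tf")
  bp <- band_average(tf, c(0, 1))
  expect_true(all(bp$bands == 1))
  expect_true(all(bp$groups == 1))
  # power concentrated at 45 Hz shows up in low gamma, not delta
  tf2 <- tf
  tf2$power[, , , ] <- 0
  k45 <- which.min(abs(freqs - 45))
  tf2$power[, , k45, ] <- 7
  bp2 <- band_average(tf2, c(0, 1))
  expect_gt(mean(bp2$bands[, , "low_gamma"]), 50 * mean(bp2$bands[, , "delta"]) + 0.5)
  expect_true(all(bp2$bands[, , "delta"] == 0))
})

test_that("session means are linear in trial values and smoothing behaves", {
  x <- c(1, 2, 3, 4, 5, 6)
  sess <- c(0, 0, 0, 1, 1, 1)
  pd <- power_dynamics(x, sess, k = 5)
  expect_equal(pd$mean, c(2, 5))
  # smoother preserves constants
  expect_equal(moving_average(rep(3.3, 10)), rep(3.3, 10))
  # step input stays monotone through the step
  step <- c(rep(0, 10), rep(1, 10))
  sm <- moving_average(step, 5)
  expect_true(all(diff(sm) >= 0))
  expect_equal(sm[1], 0); expect_equal(sm[20], 1)
})
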