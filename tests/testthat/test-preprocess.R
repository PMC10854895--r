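make_rec <- function(signal, fs = 2000) lfp_recording(signal, fs)

test_that("median down-sampling reduces blocks to their medians", {
  # constant signal is unchanged
  rec <- make_rec(matrix(3.5, 2, 4000))
  out <- median_downsample(rec, 1000)
  expect_identical(out$fs, 1000)
  expect_true(all(out$signal == 3.5))
  expect_identical(ncol(out$signal), 2000L)
  # hand-computed 2-blocks
  rec2 <- make_rec(matrix(c(1, 3, 2, 100), 1, 4))
  expect_equal(as.numeric(median_downsample(rec2, 1000)$signal), c(2, 51))
  # general factor path agrees with apply/median
  set.seed(41)
  x <- matrix(rnorm(2 * 4000), 2, 4000)
  rec4 <- make_rec(x, fs = 4000)
  out4 <- median_downsample(rec4, 1000)
  oracle <- t(apply(x, 1, function(r) apply(matrix(r, 4), 2, median)))
  expect_equal(out4$signal, oracle, ignore_attr = TRUE)
  expect_error(median_downsample(make_rec(x, 2500), 1000), "integer multiple")
})

test_that("CAR removes common mode and preserves independent components", {
  fs <- 1000
  t <- (0:(4 * fs - 1)) / fs
  common <- 30 * sin(2 * pi * 7 * t)
  set.seed(42)
  indep <- matrix(rnorm(8 * length(t), sd = 5), 8)
  rec <- make_rec(sweep(indep, 2, common, "+"), fs)
  out <- adaptive_car(rec)
  # identical channels -> all zero
  same <- make_rec(matrix(rep(common, each = 4), 4, byrow = FALSE), fs)
  expect_lt(max(abs(adaptive_car(same)$signal)), 1e-9)
  # spectral oracle: power at 7 Hz before/after via matched sinusoid fit
  pow7 <- function(x) {
    s <- sin(2 * pi * 7 * t); cs <- cos(2 * pi * 7 * t)
    (2 * mean(x * s))^2 + (2 * mean(x * cs))^2
  }
  att <- 10 * log10(mean(apply(rec$signal, 1, pow7)) /
                      mean(apply(out$signal, 1, pow7)))
  expect_gt(att, 20)
  # independent (broadband) component preserved within 1 dB
  rms_in <- sqrt(mean(indep^2))
  expect_lt(abs(20 * log10(sqrt(mean(out$signal^2)) / rms_in)), 1)
  # zero input stays zero; single channel no-op with warning
  z <- make_rec(matrix(0, 3, 100), fs)
  expect_true(all(adaptive_car(z)$signal == 0))
  expect_warning(one <- adaptive_car(make_rec(matrix(1:10, 1), fs)), "single")
  expect_identical(one$signal, matrix(1:10, 1), ignore_attr = TRUE)
})

test_that("LMS notch cancels 50 Hz and leaves 45 Hz intact", {
  fs <- 1000
  t <- (0:(6 * fs - 1)) / fs
  tone50 <- 20 * sin(2 * pi * 50 * t + 0.7)
  out <- lms_notch_50hz(make_rec(matrix(tone50, 1), fs))
  late <- out$signal[1, (2 * fs):(6 * fs)]
  expect_lt(sqrt(mean(late^2)), 0.05 * sqrt(mean(tone50^2)))
  tone45 <- 20 * sin(2 * pi * 45 * t)
  out45 <- lms_notch_50hz(make_rec(matrix(tone45, 1), fs))
  late45 <- out45$signal[1, (2 * fs):(6 * fs)]
  att45 <- 20 * log10(sqrt(mean(tone45[(2 * fs):(6 * fs)]^2)) /
                        sqrt(mean(late45^2)))
  expect_lt(att45, 1)
  z <- lms_notch_50hz(make_rec(matrix(0, 2, 500), fs))
  expect_true(all(z$signal == 0))
  expect_error(lms_notch_50hz(make_rec(matrix(0, 1, 10), fs), mu = 2.5),
               "stable range")
  expect_error(lms_notch_50hz(make_rec(matrix(0, 1, 10), fs = 80)),
               "sampling rate")
})

test_that("QC drops fast reactions strictly below 0.5 s and flagged trials", {
  tr <- build_timeline(toy_trials(10), task_config(), seed = 43)
  tr$reaction_time_s[1] <- 0.49
  tr$reaction_time_s[2] <- 0.50
  tr$artifact <- c(rep(FALSE, 7), TRUE, TRUE, TRUE)
  out <- qc_filter(tr)
  expect_identical(nrow(out$retained), 6L)
  expect_identical(nrow(out$excluded), 4L)
  expect_true(out$excluded$reason[1] == "reaction_time")
  expect_true(all(out$excluded$reason[2:4] == "artifact"))
  expect_true(0.50 %in% out$retained$reaction_time_s)  # boundary retained
})

test_that("epoching is half-open, aligned, and excludes out-of-bounds trials", {
  fs <- 1000
  tr <- build_timeline(toy_trials(5), task_config(iti_s = 5), seed = 44)
  n <- ceiling((max(tr$t_step2_peck) + 2) * fs)
  sig <- matrix(0, 2, n)
  # plant a burst 0.5 s before trial 3's step-1 peck
  center <- round((tr$t_step1_peck[3] - 0.5) * fs)
  sig[, (center - 25):(center + 25)] <- 100
  rec <- make_rec(sig, fs)
  ep <- epoch_lfp(rec, tr)
  expect_identical(dim(ep$data$choice), c(5L, 2L, 1000L))
  expect_identical(dim(ep$data$baseline), c(5L, 2L, 500L))
  expect_gt(max(abs(ep$data$choice[3, 1, ])), 50)     # burst in choice window
  expect_equal(max(abs(ep$data$baseline[3, 1, ])), 0) # not in baseline
  # a trial whose baseline precedes the recording start is excluded
  tr2 <- tr
  tr2$t_step1_peck[1] <- 1.0
  ep2 <- epoch_lfp(rec, tr2)
  expect_identical(nrow(ep2$trials), 4L)
  expect_identical(ep2$excluded$reason, "window_out_of_bounds")
})

test_that("notch is idempotent on cleaned output", {
  chain <- small_lfp_chain()
  # re-running the notch on already-clean data changes RMS by < 1%
  rec <- make_rec(matrix(rnorm(2 * 4000, sd = 10), 2), 1000)
  once <- lms_notch_50hz(rec)
  twice <- lms_notch_50hz(once)
  r1 <- sqrt(mean(once$signal^2)); r2 <- sqrt(mean(twice$signal^2))
  expect_lt(abs(r1 - r2) / r1, 0.01)
})
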