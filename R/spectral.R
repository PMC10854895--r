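#' Analysis frequency grid and canonical band table
#'
#' `log_freqs()` returns the 50 analysis frequencies, logarithmically spaced
#' on 1-100 Hz. `lfp_bands()` returns the canonical band table; the `low`
#' and `high` aggregate groups span 1-12 Hz and 12-100 Hz.
#'
#' @param n number of frequency steps.
#' @param lo,hi grid limits, Hz.
#' @return numeric vector / data.frame.
#' @export
log_freqs <- function(n = 50, lo = 1, hi = 100) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' @rdname log_freqs
#' @export
lfp_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta",
                      "low_gamma", "high_gamma"),
             f_lo = c(1, 4, 8, 12, 30, 60),
             f_hi = c(4, 8, 12, 30, 60, 100),
             group = c("low", "low", "low", "high", "high", "high"),
             stringsAsFactors = FALSE)
}

band_members <- function(freqs, f_lo, f_hi, last = FALSE) {
  if (last) which(freqs >= f_lo & freqs <= f_hi) else
    which(freqs >= f_lo & freqs < f_hi)
}

#' Morlet wavelet time-frequency power
#'
#' Squared magnitude of the continuous Morlet transform (fixed number of
#' cycles at every frequency), computed in the frequency domain per trial
#' and electrode. Epochs are reflection-padded to the wavelet support at the
#' lowest frequency, so edge bins are usable but flagged.
#'
#' @param epochs an `epoch_set` (see [epoch_lfp()]).
#' @param window name of the epoch window to transform.
#' @param freqs analysis frequencies, Hz.
#' @param n_cycles wavelet width (cycles), constant across frequencies.
#' @param time_decim keep every `time_decim`-th output sample (power
#'   envelopes are smooth; decimation bounds memory).
#' @return An `epoched_tf`: list with `power` (trials x channels x
#'   frequencies x time), `freqs`, `times` (s, relative to the alignment
#'   event), `fs`, `normalized = FALSE` and the trial table.
#' @export
morlet_power <- function(epochs, window = "tf", freqs = log_freqs(),
                         n_cycles = 7, time_decim = 1L) {
  if (!window %in% names(epochs$data))
    stop("window '", window, "' not present in the epoch set", call. = FALSE)
  arr <- epochs$data[[window]]
  fs <- epochs$fs
  n_tr <- dim(arr)[1]; n_ch <- dim(arr)[2]; len <- dim(arr)[3]
  support <- ceiling(3.5 * n_cycles / (2 * pi * min(freqs)) * fs)
  pad <- min(len, support)
  padded_short <- pad < support
  L <- len + 2L * pad
  N <- stats::nextn(L, c(2, 3, 5))
  fbins <- (0:(N - 1)) * fs / N
  H <- vapply(freqs, function(f0) {
    sf <- f0 / n_cycles
    h <- 2 * exp(-0.5 * ((fbins - f0) / sf)^2)
    h[seq.int(N %/% 2 + 2, N)] <- 0  # analytic: kill negative frequencies
    h
  }, numeric(N))

  tidx <- seq.int(1L, len, by = as.integer(time_decim))
  nt <- length(tidx)
  power <- array(NA_real_, c(n_tr, n_ch, length(freqs), nt))
  xpad <- matrix(0, N, n_ch)
  for (j in seq_len(n_tr)) {
    x <- t(arr[j, , , drop = TRUE])
    if (n_ch == 1L) x <- matrix(arr[j, 1, ], ncol = 1)
    xpad[seq_len(L), ] <- rbind(x[pad:1, , drop = FALSE], x,
                                x[len:(len - pad + 1), , drop = FALSE])
    if (L < N) xpad[(L + 1):N, ] <- 0
    F <- mvfft(xpad)
    for (k in seq_along(freqs)) {
      env <- mvfft(F * H[, k], inverse = TRUE) / N
      power[j, , k, ] <- t(Mod(env[pad + tidx, , drop = FALSE])^2)
    }
  }
  w <- epochs$windows[[window]]
  structure(list(power = power, freqs = freqs,
                 times = w[1] + (tidx - 1) / fs, fs = fs / time_decim,
                 normalized = FALSE, trials = epochs$trials,
                 window = w, n_cycles = n_cycles,
                 edge_padded_short = padded_short),
            class = "epoched_tf")
}

#' Mask peck artifacts in a time-frequency object
#'
#' Samples within `half_width` seconds of any peck are set to missing and
#' excluded from all downstream averages (never zero-filled).
#'
#' @param tf an `epoched_tf`.
#' @param peck_times optional list (one numeric vector per trial) of peck
#'   times relative to the alignment event; by default both pecks are taken
#'   from the trial table (step-1 peck at 0).
#' @param half_width mask half-width, seconds.
#' @return the masked `epoched_tf`.
#' @export
mask_peck_artifacts <- function(tf, peck_times = NULL, half_width = 0.05) {
  if (is.null(peck_times)) {
    dt2 <- tf$trials$t_step2_peck - tf$trials$t_step1_peck
    peck_times <- lapply(seq_len(nrow(tf$trials)), function(i) c(0, dt2[i]))
  }
  for (j in seq_along(peck_times)) {
    for (p in peck_times[[j]]) {
      hit <- abs(tf$times - p) <= half_width + 1e-12
      if (any(hit)) tf$power[j, , , hit] <- NA_real_
    }
  }
  tf
}

#' Baseline normalisation of time-frequency power
#'
#' Divides each trial's power by that trial's baseline power, where the
#' divisor is the mean over *all electrodes* and baseline time samples, per
#' trial and frequency. This removes per-trial global drifts in the
#' baseline. Scaling a whole recording by any constant leaves the result
#' unchanged.
#'
#' @param tf an `epoched_tf` (unnormalised).
#' @param baseline_window `c(t0, t1)` seconds relative to the alignment.
#' @param baseline_tf optional separate `epoched_tf` holding the baseline
#'   period; defaults to `tf` itself.
#' @return normalised `epoched_tf` (`normalized = TRUE`).
#' @export
baseline_normalize <- function(tf, baseline_window = c(-2.5, -2.0),
                               baseline_tf = tf) {
  bidx <- which(baseline_tf$times >= baseline_window[1] &
                  baseline_tf$times < baseline_window[2])
  if (length(bidx) == 0) stop("empty baseline window", call. = FALSE)
  n_tr <- dim(tf$power)[1]
  for (j in seq_len(n_tr)) {
    m <- apply(baseline_tf$power[j, , , bidx, drop = FALSE], 3, mean,
               na.rm = TRUE)
    if (any(!is.finite(m)) || any(m <= 0))
      stop("degenerate baseline power in trial ", j, call. = FALSE)
    tf$power[j, , , ] <- sweep(
      array(tf$power[j, , , ], dim(tf$power)[2:4]), 2, m, "/")
  }
  tf$normalized <- TRUE
  tf
}

#' Band-averaged power
#'
#' Mean normalised power over the unmasked time samples of a window and
#' over the frequencies of each canonical band, plus the low (1-12 Hz) and
#' high (12-100 Hz) aggregate groups.
#'
#' @param tf a normalised `epoched_tf`.
#' @param window `c(t0, t1)` in seconds relative to the alignment event, or
#'   a trials x 2 matrix of per-trial windows (e.g. pre-peck windows of the
#'   variable step-2 peck).
#' @param bands band table (see [lfp_bands()]).
#' @return A `band_power` object: list with `bands` (trials x channels x
#'   band array), `groups` (trials x channels x 2, `low`/`high`), the trial
#'   table and the window.
#' @export
band_average <- function(tf, window, bands = lfp_bands()) {
  if (!isTRUE(tf$normalized))
    warning("band_average called on unnormalised power")
  n_tr <- dim(tf$power)[1]; n_ch <- dim(tf$power)[2]
  if (is.matrix(window)) {
    stopifnot(nrow(window) == n_tr)
    wins <- window
  } else {
    wins <- matrix(rep(window, each = n_tr), n_tr, 2)
  }
  nb <- nrow(bands)
  bidx <- lapply(seq_len(nb), function(b)
    band_members(tf$freqs, bands$f_lo[b], bands$f_hi[b], last = b == nb))
  gidx <- list(low = which(tf$freqs >= 1 & tf$freqs < 12),
               high = which(tf$freqs >= 12 & tf$freqs <= 100))
  out_b <- array(NA_real_, c(n_tr, n_ch, nb),
                 dimnames = list(NULL, NULL, bands$band))
  out_g <- array(NA_real_, c(n_tr, n_ch, 2),
                 dimnames = list(NULL, NULL, c("low", "high")))
  n_all_masked <- 0L
  for (j in seq_len(n_tr)) {
    tsel <- which(tf$times >= wins[j, 1] & tf$times < wins[j, 2])
    slab <- array(tf$power[j, , , tsel], c(n_ch, length(tf$freqs),
                                           length(tsel)))
    tm <- apply(slab, c(1, 2), mean, na.rm = TRUE)  # channel x freq
    if (all(is.na(tm))) n_all_masked <- n_all_masked + 1L
    for (b in seq_len(nb))
      out_b[j, , b] <- rowMeans(tm[, bidx[[b]], drop = FALSE], na.rm = TRUE)
    out_g[j, , 1] <- rowMeans(tm[, gidx$low, drop = FALSE], na.rm = TRUE)
    out_g[j, , 2] <- rowMeans(tm[, gidx$high, drop = FALSE], na.rm = TRUE)
  }
  out_b[is.nan(out_b)] <- NA_real_
  out_g[is.nan(out_g)] <- NA_real_
  structure(list(bands = out_b, groups = out_g, band_table = bands,
                 trials = tf$trials, window = wins,
                 n_fully_masked = n_all_masked),
            class = "band_power")
}

#' Centred moving average with shrinking edges
#' @param x numeric vector.
#' @param k window length (odd).
#' @export
moving_average <- function(x, k = 5) {
  h <- (k - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)], na.rm = TRUE), numeric(1))
}

#' Session-wise power dynamics
#'
#' Session means of a per-trial quantity, smoothed with a centred 5-point
#' moving average (shrinking at the edges).
#'
#' @param x per-trial values (e.g. a band-group mean power).
#' @param session_idx per-trial session index.
#' @param k smoothing window.
#' @return data.frame with `session`, `mean`, `smoothed`.
#' @export
power_dynamics <- function(x, session_idx, k = 5) {
  m <- tapply(x, session_idx, mean, na.rm = TRUE)
  data.frame(session = as.integer(names(m)), mean = as.numeric(m),
             smoothed = moving_average(as.numeric(m), k))
}
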