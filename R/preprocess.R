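#' Median down-sampling
#'
#' Reduces the sampling rate by replacing each non-overlapping block of
#' `fs / target_fs` input samples with its median. Robust to impulsive
#' artifacts, unlike plain decimation. Events are unchanged.
#'
#' @param rec an [lfp_recording()].
#' @param target_fs target sampling rate; `rec$fs` must be an integer
#'   multiple of it.
#' @return down-sampled `lfp_recording`.
#' @export
median_downsample <- function(rec, target_fs = 1000) {
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9)
    stop("fs (", rec$fs, ") is not an integer multiple of target_fs (",
         target_fs, ")", call. = FALSE)
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  n <- ncol(rec$signal)
  nb <- n %/% factor
  # channel-wise to bound peak memory on long recordings
  out <- matrix(0, nrow(rec$signal), nb)
  if (factor == 2L) {
    # median of two values is their mean: vectorised fast path
    odd <- seq(1, nb * 2, by = 2)
    for (c in seq_len(nrow(rec$signal)))
      out[c, ] <- (rec$signal[c, odd] + rec$signal[c, odd + 1]) / 2
  } else {
    for (c in seq_len(nrow(rec$signal)))
      out[c, ] <- block_median_cpp(rec$signal[c, seq_len(nb * factor)], factor)
  }
  rownames(out) <- rownames(rec$signal)
  rec$signal <- out
  rec$fs <- target_fs
  rec
}

#' Adaptive common average reference
#'
#' Removes cross-channel correlated (common-mode) noise. Within contiguous
#' 1 s blocks, each channel's weight is its correlation with the plain
#' common average over that block (negative correlations clipped to zero,
#' weights renormalised to mean 1), and `weight * common_average` is
#' subtracted. With `adaptive = FALSE` this degrades to the standard CAR
#' (all weights 1).
#'
#' @param rec an [lfp_recording()].
#' @param block_s adaptation block length, seconds.
#' @param adaptive use correlation-adapted weights?
#' @return re-referenced `lfp_recording`.
#' @export
adaptive_car <- function(rec, block_s = 1, adaptive = TRUE) {
  n_ch <- nrow(rec$signal)
  if (n_ch < 2L) {
    warning("single channel: common average reference is a no-op")
    return(rec)
  }
  n <- ncol(rec$signal)
  bl <- max(2L, round(block_s * rec$fs))
  starts <- seq(1L, n, by = bl)
  for (s in starts) {
    idx <- s:min(s + bl - 1L, n)
    block <- rec$signal[, idx, drop = FALSE]
    avg <- colMeans(block)
    if (adaptive) {
      sa <- stats::sd(avg)
      w <- vapply(seq_len(n_ch), function(c) {
        sc <- stats::sd(block[c, ])
        if (is.na(sa) || sa == 0 || sc == 0) 1 else
          max(0, stats::cor(block[c, ], avg))
      }, numeric(1))
      if (mean(w) > 0) w <- w / mean(w) else w <- rep(1, n_ch)
    } else {
      w <- rep(1, n_ch)
    }
    rec$signal[, idx] <- block - w %o% avg
  }
  rec
}

#' Adaptive LMS notch filter for mains interference
#'
#' Per channel, a two-weight least-mean-squares canceller with a sine/cosine
#' reference pair at `f0` adapts to the instantaneous mains amplitude and
#' phase and subtracts it. Narrow-band by construction: neighbouring bands
#' are preserved.
#'
#' @param rec an [lfp_recording()].
#' @param mu adaptation step; must lie in `(0, 2)` (the reference pair has
#'   unit power). The default gives a ~1.6 Hz equivalent notch bandwidth at
#'   1 kHz.
#' @param f0 interference frequency, Hz.
#' @return filtered `lfp_recording`.
#' @export
lms_notch_50hz <- function(rec, mu = 0.005, f0 = 50) {
  if (rec$fs <= 2 * f0)
    stop("sampling rate must exceed twice the notch frequency", call. = FALSE)
  if (mu <= 0 || mu >= 2)
    stop("mu outside the stable range (0, 2)", call. = FALSE)
  for (c in seq_len(nrow(rec$signal)))
    rec$signal[c, ] <- lms_notch_cpp(rec$signal[c, ], rec$fs, f0, mu)
  rec
}

#' Trial quality-control filter
#'
#' Drops trials with a step-1 reaction time below `rt_min` (strict: exactly
#' `rt_min` is retained) and trials carrying a motion-artifact flag; every
#' exclusion is logged with its reason.
#'
#' @param trials trial table with `reaction_time_s` and optionally a logical
#'   `artifact` column.
#' @param rt_min reaction-time bound, seconds.
#' @return list with `retained` (trial table) and `excluded`
#'   (data.frame `session_idx`, `trial_idx`, `reason`).
#' @export
qc_filter <- function(trials, rt_min = 0.5) {
  artifact <- if (is.null(trials$artifact)) rep(FALSE, nrow(trials)) else
    isTRUE_vec(trials$artifact)
  fast <- trials$reaction_time_s < rt_min
  drop <- fast | artifact
  reason <- ifelse(fast, "reaction_time", "artifact")[drop]
  list(retained = trials[!drop, , drop = FALSE],
       excluded = data.frame(session_idx = trials$session_idx[drop],
                             trial_idx = trials$trial_idx[drop],
                             reason = reason))
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Epoch a recording around the step-1 peck
#'
#' Extracts fixed windows (seconds, relative to each trial's step-1 peck)
#' as half-open sample spans `[start, end)`. Trials whose windows fall
#' outside the recording are excluded with a logged reason.
#'
#' @param rec a preprocessed [lfp_recording()].
#' @param trials QC-retained trial table.
#' @param windows named list of `c(t0, t1)` windows; defaults are the
#'   baseline (`[-2.5, -2]`), choice (`[-1, 0]`) and S2 (`[0, 1]`) periods.
#' @param align name of the trial column holding the alignment time.
#' @return An `epoch_set`: list with `data` (one trials x channels x samples
#'   array per window), `windows`, `fs`, `trials` (the retained rows) and
#'   `excluded`.
#' @export
epoch_lfp <- function(rec, trials,
                      windows = list(baseline = c(-2.5, -2.0),
                                     choice = c(-1, 0), s2 = c(0, 1)),
                      align = "t_step1_peck") {
  fs <- rec$fs
  n <- ncol(rec$signal)
  n_ch <- nrow(rec$signal)
  t0 <- trials[[align]]
  ok <- rep(TRUE, nrow(trials))
  spans <- lapply(windows, function(w) {
    i0 <- round((t0 + w[1]) * fs) + 1L
    len <- round((w[2] - w[1]) * fs)
    cbind(i0, i0 + len - 1L)
  })
  for (sp in spans) ok <- ok & sp[, 1] >= 1L & sp[, 2] <= n
  excluded <- data.frame(session_idx = trials$session_idx[!ok],
                         trial_idx = trials$trial_idx[!ok],
                         reason = rep("window_out_of_bounds", sum(!ok)))
  keep <- which(ok)
  data <- lapply(seq_along(windows), function(k) {
    len <- round((windows[[k]][2] - windows[[k]][1]) * fs)
    arr <- array(NA_real_, c(length(keep), n_ch, len))
    for (j in seq_along(keep)) {
      i <- keep[j]
      arr[j, , ] <- rec$signal[, spans[[k]][i, 1]:spans[[k]][i, 2]]
    }
    arr
  })
  names(data) <- names(windows)
  structure(list(data = data, windows = windows, fs = fs,
                 trials = trials[keep, , drop = FALSE], excluded = excluded,
                 align = align),
            class = "epoch_set")
}
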