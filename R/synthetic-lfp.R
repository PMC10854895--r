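#' Synthetic LFP generator configuration
#'
#' Effect sizes and nuisance amplitudes (microvolts) of the synthetic
#' 16-channel recording. The generator plants four ground-truth effects on
#' top of a 1/f background: (i) high-band bursts (20 and 45 Hz carriers,
#' Hann envelope, 1 s) in the pre-peck windows whose amplitude grows
#' linearly with the model-based value of the current option/state;
#' (ii) a 6 Hz component in the two temporal-context windows around the
#' step-1 peck (`[-1, 0]` and `[0, 1]` s) whose spatial amplitude pattern
#' across channels is shared between the two windows on common-transition
#' trials after learning (independent patterns otherwise); (iii) 50 Hz line
#' noise and a
#' broadband common-mode component shared across channels; (iv) 20 ms
#' biphasic peck artifacts.
#'
#' @param fs sampling rate (Hz).
#' @param n_channels channel count (4x4 grid).
#' @param pink_sd standard deviation of the per-channel 1/f background.
#' @param pink_bandlimit upper band limit of the background (emulates the
#'   acquisition low-pass), Hz.
#' @param line_amp,line_freq amplitude and frequency of the mains component.
#' @param common_sd standard deviation of the shared broadband component.
#' @param burst_carriers high-band burst carrier frequencies, Hz.
#' @param burst_len_s burst (Hann envelope) length, seconds.
#' @param a0,a1 high-band burst amplitude = `a0 + a1 * Q`.
#' @param low_freq,low_amp,low_len_s the shared low-band component.
#' @param artifact_amp,artifact_len_s peck transient amplitude and length.
#' @param learned_boundary 1-based global trial index after which
#'   common-transition trials share the low-band spatial pattern between the
#'   S1 and S2 windows; `NULL` = first trial of the first session whose S1+
#'   choice rate exceeds 0.9.
#' @param tail_s recording tail after the last event, seconds.
#' @return A `synth_config` object.
#' @export
synth_config <- function(fs = 2000, n_channels = 16,
                         pink_sd = 20, pink_bandlimit = 250,
                         line_amp = 15, line_freq = 50,
                         common_sd = 15,
                         burst_carriers = c(20, 45), burst_len_s = 1,
                         a0 = 2, a1 = 12,
                         low_freq = 6, low_amp = 25, low_len_s = 1,
                         artifact_amp = 200, artifact_len_s = 0.02,
                         learned_boundary = NULL, tail_s = 2) {
  structure(as.list(environment()), class = "synth_config")
}

#' First trial index at which the agent counts as having learned
#'
#' The boundary is the first trial of the first session whose S1+ choice
#' rate exceeds `threshold`; `Inf` when no session qualifies.
#'
#' @param trials trial table.
#' @param threshold session choice-rate criterion.
#' @return 1-based global trial index (or `Inf`).
#' @export
learned_boundary <- function(trials, threshold = 0.9) {
  rates <- tapply(trials$choice == "S1_PLUS", trials$session_idx, mean)
  hit <- names(rates)[rates > threshold]
  if (length(hit) == 0) return(Inf)
  min(which(trials$session_idx == as.integer(hit[1])))
}

# 1/f ("pink") background noise, band-limited, unit variance rescaled to sd.
# Intermediates are released eagerly: recordings run to hours and the FFT
# temporaries dominate peak memory.
pink_noise <- function(n, fs, sd = 1, bandlimit = 250) {
  N <- stats::nextn(n, c(2, 3, 5))
  X <- fft(rnorm(N))
  f <- pmin(0:(N - 1), N:1) * fs / N
  scale <- 1 / sqrt(pmax(f, 1))   # flat below 1 Hz
  scale[f > bandlimit] <- 0
  rm(f)
  X <- X * scale
  rm(scale)
  X <- fft(X, inverse = TRUE)
  x <- Re(X)[seq_len(n)] / N
  rm(X)
  x * (sd / stats::sd(x))
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Generate a synthetic multichannel LFP recording
#'
#' Builds a continuous recording whose event-locked structure mirrors the
#' supplied behavioural trial table, with known, configurable ground truth
#' (see [synth_config()]).
#'
#' @param trials trial table with timestamps (see [build_timeline()]) and,
#'   unless `values` is given, per-trial value columns `q_s1_plus`,
#'   `q_s1_minus`, `q_s2_plus`, `q_s2_minus` (as produced by
#'   [simulate_agent()] or [replay_values()]).
#' @param values optional data.frame with those four value columns, aligned
#'   to `trials`.
#' @param cfg a [synth_config()].
#' @param seed integer seed; the ground truth is reproducible from it.
#' @return list with elements `recording` (an [lfp_recording()]) and
#'   `ground_truth` (per-trial data.frame of injected amplitudes and
#'   shared-pattern flags, plus the channel patterns as attributes).
#' @export
generate_recording <- function(trials, values = NULL, cfg = synth_config(),
                               seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  n_tr <- nrow(trials)
  if (is.null(values)) values <- trials
  if (nrow(values) != n_tr)
    stop("trials and values must have the same number of rows", call. = FALSE)
  need <- c("q_s1_plus", "q_s1_minus", "q_s2_plus", "q_s2_minus")
  if (!all(need %in% names(values)))
    stop("values must provide columns ", paste(need, collapse = ", "),
         call. = FALSE)
  fs <- cfg$fs
  n_ch <- cfg$n_channels
  dur <- max(trials$t_step2_peck) + cfg$tail_s
  n <- ceiling(dur * fs)

  boundary <- if (is.null(cfg$learned_boundary)) learned_boundary(trials) else
    cfg$learned_boundary
  gains <- runif(n_ch, 0.8, 1.2)

  # background + nuisance components, channel by channel (stepwise sums so
  # at most one full-length temporary is alive at a time)
  common <- pink_noise(n, fs, sd = cfg$common_sd, bandlimit = cfg$pink_bandlimit)
  signal <- matrix(0, n_ch, n)
  for (c in seq_len(n_ch)) {
    ch <- pink_noise(n, fs, sd = cfg$pink_sd, bandlimit = cfg$pink_bandlimit)
    ch <- ch + common
    ch <- ch + cfg$line_amp *
      sin(2 * pi * cfg$line_freq * (0:(n - 1)) / fs + runif(1, 0, 2 * pi))
    signal[c, ] <- ch
    rm(ch)
  }

  # value-coupled quantities per trial
  q_choice <- ifelse(trials$choice == "S1_PLUS",
                     values$q_s1_plus, values$q_s1_minus)
  q_state <- ifelse(trials$second_state == "S2_PLUS",
                    values$q_s2_plus, values$q_s2_minus)
  amp_s1 <- cfg$a0 + cfg$a1 * q_choice
  amp_s2 <- cfg$a0 + cfg$a1 * q_state
  common_tr <- (trials$choice == "S1_PLUS" & trials$second_state == "S2_PLUS") |
    (trials$choice == "S1_MINUS" & trials$second_state == "S2_MINUS")
  shared_low <- common_tr & seq_len(n_tr) >= boundary

  nb <- round(cfg$burst_len_s * fs)
  env <- hann_window(nb)
  tb <- (0:(nb - 1)) / fs
  nl <- round(cfg$low_len_s * fs)
  env_l <- hann_window(nl)
  tl <- (0:(nl - 1)) / fs
  na_samp <- round(cfg$artifact_len_s * fs)
  art_wave <- cfg$artifact_amp * sin(2 * pi * (0:(na_samp - 1)) / na_samp)

  pat_s1 <- matrix(runif(n_tr * n_ch), n_tr, n_ch)
  pat_s2 <- matrix(runif(n_tr * n_ch), n_tr, n_ch)
  pat_s2[shared_low, ] <- pat_s1[shared_low, , drop = FALSE]

  # subassignment is kept inline so the (large) signal matrix is modified in
  # place rather than copied per burst
  for (i in seq_len(n_tr)) {
    for (w in 1:2) {
      t_peck <- if (w == 1) trials$t_step1_peck[i] else trials$t_step2_peck[i]
      amp <- if (w == 1) amp_s1[i] else amp_s2[i]
      # high-band burst, 1 s pre-peck; carrier phase and channel loading are
      # randomised per window so the burst is neither a pure common mode
      # (CAR must not eat it) nor a spatial pattern shared across windows
      # (the cross-state similarity analysis must not see it)
      loading <- runif(n_ch, 0.6, 1.4)
      burst <- matrix(0, n_ch, nb)
      for (f in cfg$burst_carriers)
        burst <- burst + sin(outer(runif(n_ch, 0, 2 * pi), 2 * pi * f * tb, "+"))
      burst <- (amp * loading) * burst * rep(env, each = n_ch)
      i0 <- round((t_peck - cfg$burst_len_s) * fs) + 1
      idx <- i0:(i0 + nb - 1)
      ok <- idx >= 1 & idx <= n
      signal[, idx[ok]] <- signal[, idx[ok]] + burst[, ok, drop = FALSE]
      # low-band component: shared spatial-amplitude pattern, random phase
      # per channel (phase diversity keeps it out of the common average).
      # Anchored to the S1/S2 context windows around the step-1 peck
      # ([-1, 0] and [0, 1] s), not to the pecks themselves: it models the
      # temporal-context state representation, not motor preparation.
      pat <- if (w == 1) pat_s1[i, ] else pat_s2[i, ]
      lburst <- (cfg$low_amp * pat) *
        sin(outer(runif(n_ch, 0, 2 * pi), 2 * pi * cfg$low_freq * tl, "+")) *
        rep(env_l, each = n_ch)
      t1 <- trials$t_step1_peck[i]
      low_anchor <- if (w == 1) t1 else t1 + cfg$low_len_s
      i0 <- round((low_anchor - cfg$low_len_s) * fs) + 1
      idx <- i0:(i0 + nl - 1)
      ok <- idx >= 1 & idx <= n
      signal[, idx[ok]] <- signal[, idx[ok]] + lburst[, ok, drop = FALSE]
      # biphasic peck transient
      i0 <- round((t_peck - cfg$artifact_len_s / 2) * fs) + 1
      idx <- i0:(i0 + na_samp - 1)
      ok <- idx >= 1 & idx <= n
      signal[, idx[ok]] <- signal[, idx[ok]] + (gains %o% art_wave)[, ok, drop = FALSE]
    }
  }

  ev <- data.frame(
    time_s = c(trials$t_s1_onset, trials$t_step1_peck,
               trials$t_s2_onset, trials$t_step2_peck),
    label = rep(c("s1_onset", "step1_peck", "s2_onset", "step2_peck"),
                each = n_tr),
    trial = rep(seq_len(n_tr) - 1L, 4))
  ev <- ev[order(ev$time_s), ]
  rec <- lfp_recording(signal, fs, events = ev)

  gt <- data.frame(trial = seq_len(n_tr) - 1L,
                   amp_s1 = amp_s1, amp_s2 = amp_s2,
                   common_transition = common_tr, shared_low = shared_low,
                   q_choice = q_choice, q_state = q_state)
  attr(gt, "learned_boundary") <- boundary
  attr(gt, "channel_gains") <- gains
  attr(gt, "low_pattern_s1") <- pat_s1
  attr(gt, "low_pattern_s2") <- pat_s2
  attr(gt, "seed") <- seed
  list(recording = rec, ground_truth = gt)
}
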