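#' @useDynLib twostepSR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom optim dgamma dbeta sd t.test wilcox.test
#'   lm anova pt qt var median complete.cases setNames aggregate fft mvfft rnorm
#' @importFrom utils write.csv read.csv head tail
"_PACKAGE"

# Canonical labels for first-step options and second-step states.
CHOICES <- c("S1_PLUS", "S1_MINUS")
STATES  <- c("S2_PLUS", "S2_MINUS")

match_labels <- function(x, levels) {
  x <- as.character(x)
  bad <- !(x %in% levels)
  if (any(bad))
    stop("invalid label(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected ", paste(levels, collapse = "/"), ")", call. = FALSE)
  x
}

#' Two-step task configuration
#'
#' Defines the transition structure (first-step option -> second-step state)
#' and the reward structure (second-step state -> reward) of the two-step
#' probabilistic decision task, together with the session layout and trial
#' timing. Defaults are the canonical 80/20 contingencies: choosing the
#' high-value option `S1_PLUS` leads to the common state `S2_PLUS` with
#' probability 0.8, and pecking `S2_PLUS` is rewarded with probability 0.8.
#'
#' @param transition_probs 2x2 row-stochastic matrix; rows = options
#'   (`S1_PLUS`, `S1_MINUS`), columns = states (`S2_PLUS`, `S2_MINUS`).
#' @param reward_probs length-2 vector of reward probabilities per state.
#' @param iti_s inter-trial interval, seconds.
#' @param response_window_s maximum reaction time for a valid peck, seconds.
#' @param reward_duration_s reward (feeder access) duration, seconds.
#' @param trials_per_session,n_sessions session layout.
#' @param rt_range_s range of simulated step-1 reaction times, seconds.
#' @param rt2_range_s range of simulated step-2 reaction times, seconds.
#'   The default places the step-2 peck (and the burst preceding it) after
#'   the fixed `[0, 1]` s S2 analysis window around the step-1 peck.
#' @param transition_delay_s latency between the step-1 peck and the S2
#'   marker onset, seconds.
#' @return A `task_config` object (list).
#' @export
task_config <- function(transition_probs = matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2,
                                                  byrow = TRUE,
                                                  dimnames = list(CHOICES, STATES)),
                        reward_probs = c(S2_PLUS = 0.8, S2_MINUS = 0.2),
                        iti_s = 5,
                        response_window_s = 2,
                        reward_duration_s = 3,
                        trials_per_session = 50,
                        n_sessions = 60,
                        rt_range_s = c(0.5, 2.0),
                        rt2_range_s = c(1.2, 1.6),
                        transition_delay_s = 0.3) {
  transition_probs <- as.matrix(transition_probs)
  if (!all(dim(transition_probs) == c(2L, 2L)))
    stop("transition_probs must be a 2x2 matrix", call. = FALSE)
  if (any(transition_probs < 0) || any(transition_probs > 1))
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(transition_probs) - 1) > 1e-9))
    stop("each transition row must sum to 1 (tolerance 1e-9)", call. = FALSE)
  if (length(reward_probs) != 2L || any(reward_probs < 0) || any(reward_probs > 1))
    stop("reward_probs must be two probabilities in [0, 1]", call. = FALSE)
  if (iti_s <= 0 || response_window_s <= 0)
    stop("iti_s and response_window_s must be positive", call. = FALSE)
  dimnames(transition_probs) <- list(CHOICES, STATES)
  names(reward_probs) <- STATES
  structure(list(transition_probs = transition_probs,
                 reward_probs = reward_probs,
                 iti_s = iti_s,
                 response_window_s = response_window_s,
                 reward_duration_s = reward_duration_s,
                 trials_per_session = trials_per_session,
                 n_sessions = n_sessions,
                 rt_range_s = rt_range_s,
                 rt2_range_s = rt2_range_s,
                 transition_delay_s = transition_delay_s),
            class = "task_config")
}

#' Sample the second-step state following a first-step choice
#'
#' @param choice `"S1_PLUS"` or `"S1_MINUS"` (vectorised).
#' @param cfg a [task_config()].
#' @return character vector of `"S2_PLUS"` / `"S2_MINUS"`.
#' @export
sample_transition <- function(choice, cfg = task_config()) {
  choice <- match_labels(choice, CHOICES)
  if (any(abs(rowSums(cfg$transition_probs) - 1) > 1e-9))
    stop("malformed transition row: does not sum to 1", call. = FALSE)
  p_plus <- cfg$transition_probs[choice, "S2_PLUS"]
  ifelse(runif(length(choice)) < p_plus, "S2_PLUS", "S2_MINUS")
}

#' Sample the reward outcome of a second-step peck
#'
#' @param second_state `"S2_PLUS"` or `"S2_MINUS"` (vectorised).
#' @param cfg a [task_config()].
#' @return logical vector, `TRUE` when rewarded.
#' @export
sample_reward <- function(second_state, cfg = task_config()) {
  second_state <- match_labels(second_state, STATES)
  p <- cfg$reward_probs[second_state]
  if (any(p < 0) || any(p > 1))
    stop("reward probability outside [0, 1]", call. = FALSE)
  runif(length(second_state)) < unname(p)
}

#' Lay out event timestamps for a sequence of trials
#'
#' Given per-trial choices and outcomes, attaches a globally monotone event
#' timeline: S1 onset, step-1 peck, S2 onset, step-2 peck. Reaction times are
#' drawn uniformly from `cfg$rt_range_s` (step 1) and `cfg$rt2_range_s`
#' (step 2) so every generated trial clears the downstream reaction-time QC
#' unless deliberately flagged `slow`.
#'
#' @param trials data.frame with columns `choice`, `second_state`, `rewarded`
#'   and optionally `session_idx`, `trial_idx`, `slow` (logical: force an
#'   invalid, slower-than-window step-1 response), `artifact` (logical motion
#'   flag carried through to QC).
#' @param cfg a [task_config()].
#' @param seed optional integer seed.
#' @return The trial table augmented with `t_s1_onset`, `t_step1_peck`,
#'   `t_s2_onset`, `t_step2_peck`, `reaction_time_s`, `valid`.
#' @export
build_timeline <- function(trials, cfg = task_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trials)
  if (is.null(n) || n < 1L) stop("trial count must be positive", call. = FALSE)
  if (cfg$iti_s <= 0 || cfg$response_window_s <= 0)
    stop("non-positive ITI or response window", call. = FALSE)
  if (is.null(trials$session_idx))
    trials$session_idx <- (seq_len(n) - 1L) %/% cfg$trials_per_session
  if (is.null(trials$trial_idx))
    trials$trial_idx <- stats::ave(seq_len(n), trials$session_idx,
                                   FUN = seq_along) - 1L
  slow <- if (is.null(trials$slow)) rep(FALSE, n) else trials$slow
  if (is.null(trials$artifact)) trials$artifact <- FALSE

  rt1 <- runif(n, cfg$rt_range_s[1], cfg$rt_range_s[2])
  rt1[slow] <- cfg$response_window_s + runif(sum(slow), 0.1, 1.0)
  rt2 <- runif(n, cfg$rt2_range_s[1], cfg$rt2_range_s[2])

  t_s1 <- numeric(n)
  cursor <- cfg$iti_s
  for (i in seq_len(n)) {
    t_s1[i] <- cursor
    cursor <- t_s1[i] + rt1[i] + cfg$transition_delay_s + rt2[i] +
      cfg$reward_duration_s + cfg$iti_s
  }
  trials$t_s1_onset <- t_s1
  trials$t_step1_peck <- t_s1 + rt1
  trials$t_s2_onset <- trials$t_step1_peck + cfg$transition_delay_s
  trials$t_step2_peck <- trials$t_s2_onset + rt2
  trials$reaction_time_s <- rt1
  trials$valid <- rt1 <= cfg$response_window_s & rt2 <= cfg$response_window_s
  trials
}

#' Write / read a trial table as CSV
#'
#' Times are written in seconds with 6 decimal places.
#' @param trials trial table (see [build_timeline()]).
#' @param path file path.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  time_cols <- grep("^t_|^reaction_time_s$", names(out), value = TRUE)
  for (cl in time_cols) out[[cl]] <- sprintf("%.6f", out[[cl]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  time_cols <- grep("^t_|^reaction_time_s$", names(tr), value = TRUE)
  for (cl in time_cols) tr[[cl]] <- as.numeric(tr[[cl]])
  tr
}
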