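#' Successor-representation agent state
#'
#' Holds the running estimate of the transition matrix `T` (discounted
#' expected visit frequencies of the second-step states from each first-step
#' option) and the reward vector `R` (discounted expected immediate reward
#' per second-step state), plus the values derived from them.
#'
#' With the one-step horizon used throughout, option values are the inner
#' product of each option's transition row with `R`, and state values equal
#' `R` itself.
#'
#' @param T 2x2 matrix (rows: options, columns: states).
#' @param R length-2 reward vector.
#' @param gamma discount/forgetting parameter used for default initialisation.
#' @return An `sr_state` object with fields `T`, `R`, `q_s1`, `q_s2`.
#' @export
sr_state <- function(T = matrix(0.5, 2, 2, dimnames = list(CHOICES, STATES)) * gamma,
                     R = c(S2_PLUS = 0.5, S2_MINUS = 0.5) * gamma,
                     gamma = 1) {
  T <- as.matrix(T)
  dimnames(T) <- list(CHOICES, STATES)
  R <- setNames(as.numeric(R), STATES)
  st <- structure(list(T = T, R = R, q_s1 = NULL, q_s2 = NULL),
                  class = "sr_state")
  compute_values(st)
}

#' Agent parameters
#'
#' @param gamma discount/forgetting parameter in `[0, 1]`.
#' @param beta softmax inverse temperature, `>= 0` (0 = random responding,
#'   large = greedy).
#' @param alpha_T,alpha_R learning rates of the transition and reward
#'   estimators, in `(0, 1]`. These are estimator step sizes, not fitted
#'   quantities.
#' @return An `agent_params` object.
#' @export
agent_params <- function(gamma = 1, beta = 0, alpha_T = 0.1, alpha_R = 0.1) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]", call. = FALSE)
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  if (alpha_T <= 0 || alpha_T > 1 || alpha_R <= 0 || alpha_R > 1)
    stop("learning rates must lie in (0, 1]", call. = FALSE)
  structure(list(gamma = gamma, beta = beta,
                 alpha_T = alpha_T, alpha_R = alpha_R),
            class = "agent_params")
}

#' Derive option and state values from an SR state
#'
#' `q_s1[j] = sum_k T[j, k] * R[k]` (option values) and `q_s2 = R`
#' (state values).
#'
#' @param state an [sr_state()].
#' @return The state with `q_s1` and `q_s2` populated.
#' @export
compute_values <- function(state) {
  state$q_s1 <- setNames(as.numeric(state$T %*% state$R), CHOICES)
  state$q_s2 <- state$R
  state
}

#' Softmax choice probabilities
#'
#' `P[j] = exp(beta * Q[j]) / sum_k exp(beta * Q[k])`, computed with
#' max-subtraction for numerical stability.
#'
#' @param q numeric vector of option values.
#' @param beta inverse temperature, `>= 0`.
#' @return probability vector of the same length as `q`.
#' @export
softmax_choice_prob <- function(q, beta) {
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  z <- beta * q
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Delta-rule update of the SR state after one trial
#'
#' The chosen option's transition row is moved toward `gamma` at the observed
#' state and toward 0 at the other state; the observed state's reward entry
#' is moved toward `gamma * I(reward)`. Rows of unchosen options and the
#' unvisited reward entry are untouched.
#'
#' @param state an [sr_state()].
#' @param params an [agent_params()].
#' @param choice,observed_s2 trial outcome labels.
#' @param reward logical.
#' @return updated `sr_state` (values recomputed).
#' @export
sr_update <- function(state, params, choice, observed_s2, reward) {
  choice <- match_labels(choice, CHOICES)
  observed_s2 <- match_labels(observed_s2, STATES)
  g <- params$gamma
  aT <- params$alpha_T
  aR <- params$alpha_R
  other <- setdiff(STATES, observed_s2)
  state$T[choice, observed_s2] <- (1 - aT) * state$T[choice, observed_s2] + aT * g
  state$T[choice, other] <- (1 - aT) * state$T[choice, other]
  state$R[observed_s2] <- (1 - aR) * state$R[observed_s2] +
    aR * g * as.numeric(isTRUE(as.logical(reward)))
  compute_values(state)
}

#' Simulate a closed-loop SR agent through the two-step task
#'
#' Per trial: derive values, draw a softmax choice, sample the transition and
#' the reward, then update the SR state. Parameters may vary over trials
#' (windowed schedules) to emulate a learning course.
#'
#' @param params either an [agent_params()] (constant) or a data.frame with
#'   columns `gamma`, `beta` (and optionally `alpha_T`, `alpha_R`), one row
#'   per trial or one row per window of equal trial count.
#' @param cfg a [task_config()]; `trials_per_session * n_sessions` trials are
#'   simulated.
#' @param init optional initial [sr_state()]; default is the uninformative
#'   `0.5 * gamma` initialisation at the first trial's gamma.
#' @param seed optional integer seed.
#' @param timeline attach event timestamps via [build_timeline()]?
#' @return Trial table with columns `session_idx`, `trial_idx`, `choice`,
#'   `second_state`, `rewarded`, per-trial applied `gamma`/`beta`, the
#'   pre-choice value estimates (`q_s1_plus`, `q_s1_minus`, `q_s2_plus`,
#'   `q_s2_minus`) and `p_s1_plus`, plus timestamps when `timeline = TRUE`.
#' @export
simulate_agent <- function(params, cfg = task_config(), init = NULL,
                           seed = NULL, timeline = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$trials_per_session * cfg$n_sessions
  sched <- expand_schedule(params, n)
  st <- if (is.null(init)) sr_state(gamma = sched$gamma[1]) else compute_values(init)

  choice <- character(n); second <- character(n); rew <- logical(n)
  qmat <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("q_s1_plus", "q_s1_minus",
                                         "q_s2_plus", "q_s2_minus")))
  p_plus <- numeric(n)
  for (i in seq_len(n)) {
    p <- agent_params(sched$gamma[i], sched$beta[i],
                      sched$alpha_T[i], sched$alpha_R[i])
    st <- compute_values(st)
    qmat[i, ] <- c(st$q_s1, st$q_s2)
    pr <- softmax_choice_prob(st$q_s1, p$beta)
    p_plus[i] <- pr[1]
    choice[i] <- if (runif(1) < pr[1]) "S1_PLUS" else "S1_MINUS"
    second[i] <- sample_transition(choice[i], cfg)
    rew[i] <- sample_reward(second[i], cfg)
    st <- sr_update(st, p, choice[i], second[i], rew[i])
  }
  tr <- data.frame(session_idx = (seq_len(n) - 1L) %/% cfg$trials_per_session,
                   trial_idx = (seq_len(n) - 1L) %% cfg$trials_per_session,
                   choice = choice, second_state = second, rewarded = rew,
                   gamma = sched$gamma, beta = sched$beta,
                   p_s1_plus = p_plus, stringsAsFactors = FALSE)
  tr <- cbind(tr, as.data.frame(qmat))
  if (timeline) tr <- build_timeline(tr, cfg) else tr
}

# Expand constant / per-window / per-trial parameter schedules to one row
# per trial.
expand_schedule <- function(params, n_trials) {
  if (inherits(params, "agent_params")) {
    return(data.frame(gamma = rep(params$gamma, n_trials),
                      beta = rep(params$beta, n_trials),
                      alpha_T = rep(params$alpha_T, n_trials),
                      alpha_R = rep(params$alpha_R, n_trials)))
  }
  params <- as.data.frame(params)
  if (is.null(params$alpha_T)) params$alpha_T <- 0.1
  if (is.null(params$alpha_R)) params$alpha_R <- 0.1
  if (nrow(params) == n_trials) return(params)
  if (n_trials %% nrow(params) == 0) {
    k <- n_trials %/% nrow(params)
    return(params[rep(seq_len(nrow(params)), each = k), , drop = FALSE])
  }
  stop("parameter schedule (", nrow(params),
       " rows) does not cover ", n_trials, " trials", call. = FALSE)
}
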