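#' Fitting configuration
#'
#' Maximum a posteriori fitting of the SR agent's `(gamma, beta)` to observed
#' choice sequences, with weakly informative priors: `beta ~ Gamma(shape =
#' 1.2, scale = 5.0)` and `gamma ~ Beta(1.1, 1.1)`.
#'
#' @param n_windows 1 for a static fit, `> 1` for a windowed (dynamic) fit
#'   over contiguous equal blocks of trials.
#' @param prior_beta `c(shape, scale)` of the Gamma prior on beta.
#' @param prior_gamma `c(a, b)` of the Beta prior on gamma.
#' @param gamma_bounds,beta_bounds optimiser box constraints.
#' @param n_restarts jittered restarts per window.
#' @param alpha_T,alpha_R fixed agent learning rates used in the replay
#'   (not fitted).
#' @param seed seed for the restart jitter.
#' @return A `fit_config` object.
#' @export
fit_config <- function(n_windows = 1, prior_beta = c(shape = 1.2, scale = 5.0),
                       prior_gamma = c(a = 1.1, b = 1.1),
                       gamma_bounds = c(1e-6, 1 - 1e-6),
                       beta_bounds = c(1e-6, 50),
                       n_restarts = 5, alpha_T = 0.1, alpha_R = 0.1,
                       seed = 1L) {
  if (any(c(prior_beta, prior_gamma) <= 0))
    stop("prior parameters must be positive", call. = FALSE)
  if (n_windows < 1) stop("n_windows must be >= 1", call. = FALSE)
  structure(list(n_windows = as.integer(n_windows), prior_beta = prior_beta,
                 prior_gamma = prior_gamma, gamma_bounds = gamma_bounds,
                 beta_bounds = beta_bounds, n_restarts = n_restarts,
                 alpha_T = alpha_T, alpha_R = alpha_R, seed = seed),
            class = "fit_config")
}

encode_trials <- function(trials) {
  list(choice = as.integer(match_labels(trials$choice, CHOICES) == "S1_MINUS"),
       s2 = as.integer(match_labels(trials$second_state, STATES) == "S2_MINUS"),
       reward = as.integer(as.logical(trials$rewarded)))
}

sr_init_vectors <- function(gamma, init = NULL) {
  if (is.null(init)) {
    list(T = rep(0.5 * gamma, 4), R = rep(0.5 * gamma, 2))
  } else {
    list(T = as.numeric(t(init$T)), R = as.numeric(init$R))
  }
}

#' Negative log-likelihood of observed choices under the SR agent
#'
#' Replays the agent deterministically over the observed trial sequence with
#' fixed `(gamma, beta)`: values are recomputed before each trial, the
#' softmax probability of the observed choice is accumulated, and the SR
#' state is updated with the observed transition and reward.
#'
#' @param trials trial table with `choice`, `second_state`, `rewarded`.
#' @param gamma,beta parameters at which to evaluate.
#' @param cfg a [fit_config()] (supplies learning rates).
#' @param span optional `c(first, last)` 1-based trial indices over which the
#'   log-likelihood is accumulated; earlier trials are still replayed to set
#'   the agent state (window warm start).
#' @param init optional initial [sr_state()].
#' @return scalar negative log-likelihood.
#' @export
choice_negloglik <- function(trials, gamma, beta, cfg = fit_config(),
                             span = NULL, init = NULL) {
  n <- nrow(trials)
  if (is.null(n) || n < 1L) stop("empty trial list", call. = FALSE)
  if (is.null(span)) span <- c(1L, n)
  enc <- encode_trials(trials)
  iv <- sr_init_vectors(gamma, init)
  sr_negloglik_cpp(enc$choice, enc$s2, enc$reward, gamma, beta,
                   cfg$alpha_T, cfg$alpha_R,
                   as.integer(span[1]), as.integer(span[2]), iv$T, iv$R)
}

neg_log_posterior <- function(trials, gamma, beta, cfg, span = NULL) {
  choice_negloglik(trials, gamma, beta, cfg, span) -
    dgamma(beta, shape = cfg$prior_beta[[1]], scale = cfg$prior_beta[[2]],
           log = TRUE) -
    dbeta(gamma, cfg$prior_gamma[[1]], cfg$prior_gamma[[2]], log = TRUE)
}

map_fit_window <- function(trials, cfg, span) {
  obj <- function(par) neg_log_posterior(trials, par[1], par[2], cfg, span)
  lower <- c(cfg$gamma_bounds[1], cfg$beta_bounds[1])
  upper <- c(cfg$gamma_bounds[2], cfg$beta_bounds[2])
  starts <- rbind(c(0.5, 2))
  if (cfg$n_restarts > 1) {
    extra <- cbind(runif(cfg$n_restarts - 1, 0.05, 0.95),
                   runif(cfg$n_restarts - 1, 0.2, 15))
    starts <- rbind(starts, extra)
  }
  best <- NULL
  conv <- FALSE
  for (k in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[k, ], obj, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all optimizer restarts failed", call. = FALSE)
  list(gamma_hat = best$par[1], beta_hat = best$par[2],
       log_posterior = -best$value, converged = conv)
}

#' Static MAP fit of (gamma, beta)
#'
#' @inheritParams choice_negloglik
#' @return An `sr_fit` object; `$windows` is a one-row data.frame with
#'   `gamma_hat`, `beta_hat`, `log_posterior`, `converged`.
#' @export
fit_map <- function(trials, cfg = fit_config()) {
  if (is.null(nrow(trials)) || nrow(trials) < 1L)
    stop("empty trial list", call. = FALSE)
  set.seed(cfg$seed)
  w <- map_fit_window(trials, cfg, c(1L, nrow(trials)))
  structure(list(windows = data.frame(window = 1L, first = 1L,
                                      last = nrow(trials),
                                      gamma_hat = w$gamma_hat,
                                      beta_hat = w$beta_hat,
                                      log_posterior = w$log_posterior,
                                      converged = w$converged),
                 cfg = cfg, dynamic = FALSE),
            class = "sr_fit")
}

#' Windowed (dynamic) MAP fit
#'
#' Splits the trial sequence into `cfg$n_windows` contiguous blocks and fits
#' `(gamma, beta)` independently per block. The agent state at a window's
#' start is produced by replaying all earlier trials under the candidate
#' gamma being evaluated, avoiding discontinuities at window edges.
#'
#' @inheritParams choice_negloglik
#' @return An `sr_fit` with one `$windows` row per window.
#' @export
fit_dynamic <- function(trials, cfg = fit_config(n_windows = 12)) {
  n <- nrow(trials)
  if (is.null(n) || n < 1L) stop("empty trial list", call. = FALSE)
  if (cfg$n_windows == 1L) return(fit_map(trials, cfg))
  bounds <- as.integer(floor(seq(0, n, length.out = cfg$n_windows + 1)))
  set.seed(cfg$seed)
  rows <- vector("list", cfg$n_windows)
  for (w in seq_len(cfg$n_windows)) {
    first <- bounds[w] + 1L
    last <- bounds[w + 1]
    if (last < first) stop("window ", w, " is empty", call. = FALSE)
    if (last - first + 1L < 20L)
      warning("window ", w, " has fewer than 20 trials; fit attempted anyway",
              call. = FALSE)
    res <- map_fit_window(trials, cfg, c(first, last))
    rows[[w]] <- data.frame(window = w, first = as.integer(first),
                            last = as.integer(last),
                            gamma_hat = res$gamma_hat, beta_hat = res$beta_hat,
                            log_posterior = res$log_posterior,
                            converged = res$converged)
  }
  structure(list(windows = do.call(rbind, rows), cfg = cfg, dynamic = TRUE),
            class = "sr_fit")
}

#' Per-trial value estimates implied by a fit
#'
#' Replays the SR agent over the observed sequence using each window's fitted
#' gamma, returning the pre-choice option and state value estimates.
#'
#' @param trials observed trial table.
#' @param fit an `sr_fit`.
#' @return data.frame with `q_s1_plus`, `q_s1_minus`, `q_s2_plus`,
#'   `q_s2_minus` and the applied `gamma`/`beta` per trial.
#' @export
replay_values <- function(trials, fit) {
  n <- nrow(trials)
  gamma <- numeric(n)
  beta <- numeric(n)
  for (w in seq_len(nrow(fit$windows))) {
    idx <- fit$windows$first[w]:fit$windows$last[w]
    gamma[idx] <- fit$windows$gamma_hat[w]
    beta[idx] <- fit$windows$beta_hat[w]
  }
  enc <- encode_trials(trials)
  iv <- sr_init_vectors(gamma[1])
  q <- sr_replay_values_cpp(enc$choice, enc$s2, enc$reward, gamma,
                            fit$cfg$alpha_T, fit$cfg$alpha_R, iv$T, iv$R)
  colnames(q) <- c("q_s1_plus", "q_s1_minus", "q_s2_plus", "q_s2_minus")
  out <- as.data.frame(q)
  out$gamma <- gamma
  out$beta <- beta
  out
}

#' Simulated choice-rate trajectories under fitted parameterisations
#'
#' Simulates `n_rounds` closed-loop agents under the dynamic and static
#' fitted parameter schedules and returns session-wise S1+ choice-rate
#' curves (mean and SD across rounds) for overlay against the empirical
#' curve.
#'
#' @param trials observed trial table (supplies the session layout and the
#'   empirical curve).
#' @param fit_dyn,fit_stat `sr_fit` objects.
#' @param cfg a [task_config()] matching the trial layout.
#' @param n_rounds simulation rounds per model.
#' @param seed integer seed.
#' @return list with `sessions`, `empirical`, and per-model matrices
#'   `dynamic`/`static` (`n_rounds` x sessions) plus their `*_mean` and
#'   `*_sd` summaries.
#' @export
compare_dynamic_static <- function(trials, fit_dyn, fit_stat,
                                   cfg = task_config(), n_rounds = 50,
                                   seed = 1L) {
  n <- nrow(trials)
  sess <- trials$session_idx
  n_sess <- length(unique(sess))
  sim_cfg <- cfg
  sim_cfg$trials_per_session <- as.integer(round(n / n_sess))
  sim_cfg$n_sessions <- n_sess

  schedule_of <- function(fit) {
    g <- numeric(n); b <- numeric(n)
    for (w in seq_len(nrow(fit$windows))) {
      idx <- fit$windows$first[w]:fit$windows$last[w]
      g[idx] <- fit$windows$gamma_hat[w]
      b[idx] <- fit$windows$beta_hat[w]
    }
    data.frame(gamma = g, beta = b,
               alpha_T = fit$cfg$alpha_T, alpha_R = fit$cfg$alpha_R)
  }
  run_model <- function(fit, seed0) {
    sched <- schedule_of(fit)
    out <- matrix(NA_real_, n_rounds, n_sess)
    for (r in seq_len(n_rounds)) {
      sim <- simulate_agent(sched, sim_cfg, seed = seed0 + r, timeline = FALSE)
      out[r, ] <- tapply(sim$choice == "S1_PLUS", sim$session_idx, mean)
    }
    out
  }
  dyn <- run_model(fit_dyn, seed)
  sta <- run_model(fit_stat, seed + 100003L)
  emp <- as.numeric(tapply(trials$choice == "S1_PLUS", sess, mean))
  list(sessions = sort(unique(sess)), empirical = emp,
       dynamic = dyn, dynamic_mean = colMeans(dyn),
       dynamic_sd = apply(dyn, 2, sd),
       static = sta, static_mean = colMeans(sta),
       static_sd = apply(sta, 2, sd))
}

#' Serialise a fit to JSON
#' @param fit an `sr_fit`.
#' @param path output path.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(list(dynamic = fit$dynamic, windows = fit$windows),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
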