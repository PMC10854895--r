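# Straight-line likelihood oracle: replays the agent in plain R, recomputing
# the SR state from scratch for every trial (no incremental reuse).
nll_oracle <- function(trials, gamma, beta, alpha = 0.1) {
  replay_state <- function(upto) {
    T <- matrix(0.5 * gamma, 2, 2, dimnames = list(CHOICES <- c("S1_PLUS", "S1_MINUS"),
                                                   c("S2_PLUS", "S2_MINUS")))
    R <- c(S2_PLUS = 0.5 * gamma, S2_MINUS = 0.5 * gamma)
    if (upto >= 1) for (i in seq_len(upto)) {
      c_i <- trials$choice[i]; o <- trials$second_state[i]
      u <- setdiff(colnames(T), o)
      T[c_i, o] <- 0.9 * T[c_i, o] + 0.1 * gamma
      T[c_i, u] <- 0.9 * T[c_i, u]
      R[o] <- 0.9 * R[o] + 0.1 * gamma * as.numeric(trials$rewarded[i])
    }
    list(T = T, R = R)
  }
  nll <- 0
  for (i in seq_len(nrow(trials))) {
    st <- replay_state(i - 1)
    q <- as.numeric(st$T %*% st$R)
    p <- exp(beta * q) / sum(exp(beta * q))
    nll <- nll - log(p[if (trials$choice[i] == "S1_PLUS") 1 else 2])
  }
  nll
}

test_that("choice likelihood is exact at beta = 0 and matches the brute-force oracle", {
  cfg <- task_config(n_sessions = 1, trials_per_session = 10)
  tr <- simulate_agent(agent_params(gamma = 0.8, beta = 3), cfg, seed = 21,
                       timeline = FALSE)
  expect_equal(choice_negloglik(tr, 0.7, 0), 10 * log(2))
  for (par in list(c(0.3, 1), c(0.8, 4), c(0.99, 10))) {
    expect_equal(choice_negloglik(tr, par[1], par[2]),
                 nll_oracle(tr, par[1], par[2]), tolerance = 1e-10)
  }
  expect_error(choice_negloglik(tr[0, ], 0.5, 1), "empty")
})

test_that("the likelihood prefers the generating parameters on average", {
  set.seed(22)
  cfg <- task_config(n_sessions = 10, trials_per_session = 50)
  diffs <- replicate(30, {
    tr <- simulate_agent(agent_params(gamma = 0.9, beta = 5), cfg,
                         seed = sample.int(1e6, 1), timeline = FALSE)
    choice_negloglik(tr, 0.2, 0.5) - choice_negloglik(tr, 0.9, 5)
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("static MAP fit recovers generating parameters on one dataset", {
  cfg <- task_config(n_sessions = 20, trials_per_session = 50)
  tr <- simulate_agent(agent_params(gamma = 0.9, beta = 5), cfg, seed = 23,
                       timeline = FALSE)
  f <- fit_map(tr)
  expect_true(f$windows$converged)
  expect_lt(abs(f$windows$gamma_hat - 0.9), 0.1)
  expect_lt(abs(f$windows$beta_hat - 5) / 5, 0.3)
  expect_error(fit_map(tr[0, ]), "empty")
})

test_that("an overwhelming prior pins gamma at the analytic prior mode", {
  cfg <- task_config(n_sessions = 1, trials_per_session = 10)
  tr <- simulate_agent(agent_params(gamma = 0.5, beta = 1), cfg, seed = 24,
                       timeline = FALSE)
  fc <- fit_config(prior_gamma = c(a = 1000, b = 10))
  f <- fit_map(tr, fc)
  mode <- (1000 - 1) / (1000 + 10 - 2)
  expect_lt(abs(f$windows$gamma_hat - mode), 0.02)
})

test_that("a single window reduces the dynamic fit to the static fit", {
  cfg <- task_config(n_sessions = 5, trials_per_session = 40)
  tr <- simulate_agent(agent_params(gamma = 0.8, beta = 4), cfg, seed = 25,
                       timeline = FALSE)
  f1 <- fit_map(tr, fit_config())
  f2 <- fit_dynamic(tr, fit_config(n_windows = 1))
  expect_equal(f1$windows, f2$windows)
})

test_that("windowed fits of constant-parameter data scatter around the static fit", {
  cfg <- task_config(n_sessions = 24, trials_per_session = 50)
  tr <- simulate_agent(agent_params(gamma = 0.9, beta = 5), cfg, seed = 26,
                       timeline = FALSE)
  fs <- fit_map(tr)
  fd <- fit_dynamic(tr, fit_config(n_windows = 6))
  expect_identical(nrow(fd$windows), 6L)
  expect_lt(abs(median(fd$windows$gamma_hat) - fs$windows$gamma_hat), 0.15)
  expect_lt(abs(median(fd$windows$beta_hat) - fs$windows$beta_hat),
            0.5 * fs$windows$beta_hat)
  # windows partition the sequence
  expect_identical(fd$windows$first[1], 1L)
  expect_identical(fd$windows$last[6], nrow(tr))
  expect_true(all(fd$windows$first[-1] == fd$windows$last[-6] + 1L))
})

test_that("short windows warn but still fit", {
  cfg <- task_config(n_sessions = 1, trials_per_session = 30)
  tr <- simulate_agent(agent_params(gamma = 0.7, beta = 2), cfg, seed = 27,
                       timeline = FALSE)
  expect_warning(fit_dynamic(tr, fit_config(n_windows = 2)), "fewer than 20")
})

test_that("fitted-model trajectory simulation is deterministic per seed", {
  cfg <- task_config(n_sessions = 4, trials_per_session = 25)
  tr <- simulate_agent(agent_params(gamma = 0.9, beta = 5), cfg, seed = 28,
                       timeline = FALSE)
  f <- fit_map(tr)
  c1 <- compare_dynamic_static(tr, f, f, cfg, n_rounds = 1, seed = 7)
  c2 <- compare_dynamic_static(tr, f, f, cfg, n_rounds = 1, seed = 7)
  expect_identical(c1$dynamic, c2$dynamic)
  expect_identical(dim(c1$dynamic), c(1L, 4L))
  expect_equal(length(c1$empirical), 4L)
})

test_that("replayed values follow the fitted window schedule", {
  cfg <- task_config(n_sessions = 4, trials_per_session = 50)
  tr <- simulate_agent(agent_params(gamma = 1, beta = 8), cfg,
                       init = asymptote_state(), seed = 29, timeline = FALSE)
  f <- fit_map(tr)
  v <- replay_values(tr, f)
  expect_identical(nrow(v), nrow(tr))
  # late estimates approach the asymptotic structure scaled by gamma_hat
  g <- f$windows$gamma_hat
  expect_lt(abs(mean(tail(v$q_s2_plus, 50)) - 0.8 * g), 0.12)
})
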