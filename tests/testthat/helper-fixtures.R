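# Shared fixtures. The LFP chain fixture is expensive, so it is built once
# per session and cached.
.fixture_cache <- new.env(parent = emptyenv())

asymptote_state <- function() {
  sr_state(T = matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2, byrow = TRUE),
           R = c(0.8, 0.2), gamma = 1)
}

# 40-trial converged-agent session with a full synthetic LFP chain:
# recording -> preprocess -> normalised masked TF -> feature epochs.
small_lfp_chain <- function() {
  if (!is.null(.fixture_cache$chain)) return(.fixture_cache$chain)
  cfg <- task_config(n_sessions = 2, trials_per_session = 20)
  tr <- simulate_agent(agent_params(gamma = 1, beta = 8), cfg,
                       init = asymptote_state(), seed = 501)
  gen <- generate_recording(tr, cfg = synth_config(learned_boundary = 1),
                            seed = 502)
  rec <- lms_notch_50hz(adaptive_car(median_downsample(gen$recording, 1000)))
  ep <- epoch_lfp(rec, tr, windows = list(tf = c(-2.5, 2.0)))
  tf <- baseline_normalize(mask_peck_artifacts(
    morlet_power(ep, "tf", time_decim = 10)))
  .fixture_cache$chain <- list(trials = ep$trials, gen = gen, ep = ep, tf = tf,
                               fe = build_epochs(tf))
  .fixture_cache$chain
}

# Deterministic trial table without simulation, for timeline/QC tests.
toy_trials <- function(n = 10, choice = rep("S1_PLUS", n)) {
  data.frame(choice = choice,
             second_state = rep(c("S2_PLUS", "S2_MINUS"), length.out = n),
             rewarded = rep(c(TRUE, FALSE), length.out = n))
}
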