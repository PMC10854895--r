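#' End-to-end run configuration
#'
#' Bundles every stage's settings and a single root seed. Per-stage random
#' streams are derived deterministically from the root seed, so a run is
#' reproducible bit-for-bit from (config, seed) and stages can be re-run in
#' isolation.
#'
#' @param seed root integer seed.
#' @param task a [task_config()].
#' @param schedule generating-agent parameter schedule (data.frame with
#'   `gamma`, `beta`, one row per window); `NULL` = a learning course from
#'   near-random to near-greedy (gamma 0.3 to 0.98, beta 0.5 to 8 over 12
#'   windows).
#' @param fit a [fit_config()] for the dynamic fit (the static fit reuses it
#'   with `n_windows = 1`).
#' @param synth a [synth_config()].
#' @param stage_n trials per learning stage for stage-based contrasts.
#' @param choice_window,s2_pre_peck_s analysis windows: fixed pre-step-1-peck
#'   window and length of the per-trial pre-step-2-peck window, seconds.
#' @param tf_window continuous span transformed per trial, seconds relative
#'   to the step-1 peck.
#' @param time_decim time decimation of the stored time-frequency power.
#' @param n_perm cluster-permutation count.
#' @param decode_repeats decoding split rounds.
#' @param keep_recording also write the raw synthetic recording?
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1L, task = task_config(), schedule = NULL,
                       fit = fit_config(n_windows = 12), synth = synth_config(),
                       stage_n = 100, choice_window = c(-0.5, 0),
                       s2_pre_peck_s = 0.5, tf_window = c(-2.5, 2.0),
                       time_decim = 10L, n_perm = 1000, decode_repeats = 10,
                       keep_recording = FALSE) {
  if (is.null(schedule))
    schedule <- data.frame(gamma = seq(0.3, 0.98, length.out = 12),
                           beta = seq(0.5, 8, length.out = 12))
  structure(as.list(environment()), class = "run_config")
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full synthetic-replay pipeline
#'
#' Executes behaviour simulation, QC, model fitting (static and dynamic),
#' synthetic LFP generation, preprocessing (median down-sampling, adaptive
#' CAR, LMS notch), Morlet time-frequency estimation with baseline
#' normalisation, band power, representational similarity with
#' cluster-permutation contrasts, value regression and choice decoding.
#' Writes all stage outputs plus a manifest (md5 per file) and a summary
#' marking the four planted qualitative signatures:
#'
#' 1. high-band power increases from the early to the late learning stage
#'    (S1+ and S2+ conditions);
#' 2. high-band S2+ power regresses significantly and positively on the
#'    fitted state value;
#' 3. high-band choice decoding beats low-band by at least 0.1;
#' 4. a significant low-band common-vs-uncommon late-stage similarity
#'    cluster, with no high-band counterpart.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created).
#' @return (invisibly) the summary list; artifacts under `out_dir`.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = tempfile("tsrun")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log <- function(...) message(sprintf(...))

  ## behaviour ---------------------------------------------------------
  log("stage behavior: %d sessions x %d trials",
      cfg$task$n_sessions, cfg$task$trials_per_session)
  trials <- simulate_agent(cfg$schedule, cfg$task, seed = cfg$seed)
  files <- c(files, write_stage_csv(trials, out_dir, "trials.csv"))

  ## QC ----------------------------------------------------------------
  qc <- qc_filter(trials)
  files <- c(files, write_stage_csv(qc$excluded, out_dir, "exclusions.csv"))
  log("stage qc: %d retained, %d excluded", nrow(qc$retained), nrow(qc$excluded))

  ## model fitting ------------------------------------------------------
  log("stage fit: static + dynamic (%d windows)", cfg$fit$n_windows)
  stat_cfg <- cfg$fit; stat_cfg$n_windows <- 1L
  fit_stat <- fit_map(qc$retained, stat_cfg)
  fit_dyn <- fit_dynamic(qc$retained, cfg$fit)
  files <- c(files, write_fit(fit_stat, file.path(out_dir, "fit_static.json")),
             write_fit(fit_dyn, file.path(out_dir, "fit_dynamic.json")))
  vals <- replay_values(qc$retained, fit_dyn)

  ## synthetic LFP ------------------------------------------------------
  log("stage synth: generating %d-channel recording", cfg$synth$n_channels)
  gen <- generate_recording(qc$retained, cfg = cfg$synth, seed = cfg$seed + 1L)
  if (cfg$keep_recording) {
    write_recording(gen$recording, file.path(out_dir, "recording"))
  }

  ## preprocessing ------------------------------------------------------
  log("stage preprocess: downsample + CAR + notch + epoch")
  rec <- median_downsample(gen$recording, 1000)
  gen$recording <- NULL; gc(FALSE)  # drop the 2 kHz original
  rec <- adaptive_car(rec)
  rec <- lms_notch_50hz(rec)
  ep <- epoch_lfp(rec, qc$retained, windows = list(tf = cfg$tf_window))
  rm(rec, gen); gc(FALSE)
  used <- ep$trials
  used_vals <- vals[match(interaction(used$session_idx, used$trial_idx),
                          interaction(qc$retained$session_idx,
                                      qc$retained$trial_idx)), ]

  ## spectral -----------------------------------------------------------
  log("stage spectral: Morlet power on %d trials", nrow(used))
  tf <- morlet_power(ep, "tf", time_decim = cfg$time_decim)
  rm(ep); gc(FALSE)
  tf <- mask_peck_artifacts(tf)
  tf <- baseline_normalize(tf)
  bp_s1 <- band_average(tf, cfg$choice_window)
  dt2 <- used$t_step2_peck - used$t_step1_peck
  bp_s2 <- band_average(tf, cbind(dt2 - cfg$s2_pre_peck_s, dt2))
  bp_df <- data.frame(session_idx = used$session_idx,
                      trial_idx = used$trial_idx,
                      choice = used$choice, second_state = used$second_state,
                      s1_low = rowMeans(bp_s1$groups[, , "low"], na.rm = TRUE),
                      s1_high = rowMeans(bp_s1$groups[, , "high"], na.rm = TRUE),
                      s2_low = rowMeans(bp_s2$groups[, , "low"], na.rm = TRUE),
                      s2_high = rowMeans(bp_s2$groups[, , "high"], na.rm = TRUE))
  files <- c(files, write_stage_csv(bp_df, out_dir, "bandpower.csv"))

  ## stage selection ----------------------------------------------------
  early <- select_stage_trials(used, "early", n = cfg$stage_n)
  late <- select_stage_trials(used, "late", n = cfg$stage_n)

  ## signature 1: learning-course power increase ------------------------
  s1p <- used$choice == "S1_PLUS"
  s2p <- used$second_state == "S2_PLUS"
  inc_s1 <- stat_tests(bp_df$s1_high[intersect(late, which(s1p))],
                       bp_df$s1_high[intersect(early, which(s1p))])
  inc_s2 <- stat_tests(bp_df$s2_high[intersect(late, which(s2p))],
                       bp_df$s2_high[intersect(early, which(s2p))])
  sig_power <- inc_s1$p_value < 0.05 && inc_s1$mean_diff > 0 &&
    inc_s2$p_value < 0.05 && inc_s2$mean_diff > 0

  ## signature 2: value regression --------------------------------------
  sess <- sort(unique(used$session_idx))
  reg_of <- function(ycol, qcol, sel, cond, grp) {
    y <- session_means(bp_df[[ycol]], used$session_idx, sel, sess)
    x <- session_means(used_vals[[qcol]], used$session_idx, sel, sess)
    session_value_regression(y, x, condition = cond, band_group = grp)
  }
  reg_s2_high <- reg_of("s2_high", "q_s2_plus", s2p, "S2_PLUS", "high")
  reg_s2_low <- reg_of("s2_low", "q_s2_plus", s2p, "S2_PLUS", "low")
  reg_s1_high <- reg_of("s1_high", "q_s1_plus", s1p, "S1_PLUS", "high")
  reg_df <- do.call(rbind, lapply(list(reg_s1_high, reg_s2_high, reg_s2_low),
                                  function(r)
    data.frame(condition = r$condition, band_group = r$band_group,
               beta1 = r$beta1, r_squared = r$r_squared,
               f_statistic = r$f_statistic, p_value = r$p_value, n = r$n)))
  files <- c(files, write_stage_csv(reg_df, out_dir, "regression.csv"))
  sig_regression <- reg_s2_high$p_value < 0.05 && reg_s2_high$beta1 > 0

  ## signature 3: decoding ----------------------------------------------
  ## Decoded on the second half of the learning course (values, hence the
  ## planted amplitudes, differ between options only once learned), with
  ## classes balanced by subsampling so chance is 0.5.
  log("stage link: decoding + regression")
  half <- used$session_idx >= stats::median(unique(used$session_idx))
  if (min(table(factor(used$choice[half], levels = CHOICES))) < 5)
    half <- rep(TRUE, nrow(used))  # tiny runs: use the whole course
  idx_by_class <- split(which(half), used$choice[half])
  n_min <- min(lengths(idx_by_class))
  set.seed(cfg$seed + 7L)
  dec_idx <- sort(unlist(lapply(idx_by_class, sample, size = n_min)))
  dec_high <- decode_choice(decode_features(bp_s1, "high")[dec_idx, ],
                            used$choice[dec_idx],
                            n_repeats = cfg$decode_repeats,
                            seed = cfg$seed + 2L)
  dec_low <- decode_choice(decode_features(bp_s1, "low")[dec_idx, ],
                           used$choice[dec_idx],
                           n_repeats = cfg$decode_repeats,
                           seed = cfg$seed + 3L)
  dec_df <- data.frame(band_group = c("high", "low"),
                       accuracy_mean = c(dec_high$mean, dec_low$mean),
                       accuracy_sd = c(dec_high$sd, dec_low$sd),
                       n_rounds = c(dec_high$n_rounds, dec_low$n_rounds))
  files <- c(files, write_stage_csv(dec_df, out_dir, "decoding.csv"))
  sig_decoding <- (dec_high$mean - dec_low$mean) >= 0.1

  ## signature 4: similarity --------------------------------------------
  log("stage rsa: similarity maps + cluster contrasts")
  fe <- build_epochs(tf)
  late_s1p <- intersect(late, which(s1p))
  common_late <- intersect(late_s1p, which(s2p))
  uncommon_late <- intersect(late_s1p, which(!s2p))
  maps_low_c <- similarity_maps(fe, common_late, "low")
  maps_low_u <- similarity_maps(fe, uncommon_late, "low")
  ct_low <- cluster_contrast(maps_low_c, maps_low_u, n_perm = cfg$n_perm,
                             seed = cfg$seed + 4L)
  maps_high_c <- similarity_maps(fe, common_late, "high")
  maps_high_u <- similarity_maps(fe, uncommon_late, "high")
  ct_high <- cluster_contrast(maps_high_c, maps_high_u, n_perm = cfg$n_perm,
                              seed = cfg$seed + 5L)
  low_sig <- nrow(ct_low$clusters) > 0 && any(ct_low$clusters$p_corr < 0.05)
  high_sig <- nrow(ct_high$clusters) > 0 && any(ct_high$clusters$p_corr < 0.05)
  sig_similarity <- low_sig && !high_sig
  cl_df <- rbind(
    if (nrow(ct_low$clusters)) cbind(band_group = "low", ct_low$clusters),
    if (nrow(ct_high$clusters)) cbind(band_group = "high", ct_high$clusters))
  if (is.null(cl_df)) cl_df <- data.frame(band_group = character(0))
  files <- c(files, write_stage_csv(cl_df, out_dir, "similarity_clusters.csv"))
  files <- c(files, write_stage_csv(
    as.data.frame(ct_low$sig_mask), out_dir, "similarity_sigmask_low.csv"))

  ## summary + manifest -------------------------------------------------
  summary <- list(
    seed = cfg$seed,
    n_trials = nrow(trials), n_retained = nrow(used),
    fit = list(static = fit_stat$windows, dynamic = fit_dyn$windows),
    signatures = list(
      high_band_power_increase = sig_power,
      high_band_value_regression = sig_regression,
      high_over_low_decoding = sig_decoding,
      low_band_similarity_cluster = sig_similarity),
    detail = list(
      power_increase = list(s1 = inc_s1, s2 = inc_s2),
      regression = reg_df,
      decoding = dec_df,
      similarity = list(low_best_p = if (nrow(ct_low$clusters))
        min(ct_low$clusters$p_corr) else NA,
        high_best_p = if (nrow(ct_high$clusters))
          min(ct_high$clusters$p_corr) else NA)))
  sum_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, dataframe = "rows")
  files <- c(files, sum_path)
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  log("run complete: %s", out_dir)
  invisible(summary)
}
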