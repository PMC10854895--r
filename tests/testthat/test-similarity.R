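# Small synthetic epoched_tf with controllable power values.
toy_tf <- function(n_tr = 2, n_ch = 3, freqs = log_freqs(), fs = 100,
                   t0 = -1, t1 = 1, fill = NULL) {
  nt <- round((t1 - t0) * fs)
  power <- if (is.null(fill)) {
    array(abs(rnorm(n_tr * n_ch * length(freqs) * nt)) + 0.1,
          c(n_tr, n_ch, length(freqs), nt))
  } else array(fill, c(n_tr, n_ch, length(freqs), nt))
  structure(list(power = power, freqs = freqs,
                 times = seq(t0, t1 - 1 / fs, by = 1 / fs), fs = fs,
                 normalized = TRUE,
                 trials = data.frame(t_step1_peck = seq_len(n_tr) * 10,
                                     t_step2_peck = seq_len(n_tr) * 10 + 1)),
            class = "epoched_tf")
}

test_that("epoch tiling yields 46 epochs per 1 s window at 100 ms / 20 ms", {
  set.seed(61)
  fe <- build_epochs(toy_tf(), window = c(-1, 1))
  s1 <- fe$starts >= -1 & fe$starts + fe$epoch_len <= 0 + 1e-9
  s2 <- fe$starts >= 0 & fe$starts + fe$epoch_len <= 1 + 1e-9
  expect_identical(sum(s1), 46L)
  expect_identical(sum(s2), 46L)
  expect_equal(fe$centers[s2][1], 0.05)
  expect_equal(fe$centers[s2][46], 0.95)
  expect_identical(dim(fe$features)[3], 3L * 6L)
  expect_error(build_epochs(toy_tf(), window = c(0, 0.05)), "shorter")
})

test_that("z-transform has mean 0, SD 1 per frequency per trial; constants give zero", {
  set.seed(62)
  tf <- toy_tf(n_tr = 2, n_ch = 4, freqs = c(2, 6, 20))
  # reach into the internal epoch z-values through band means of a
  # single-frequency band: delta band holds only the 2 Hz step here
  fe <- build_epochs(tf, window = c(-1, 1))
  delta_cols <- which(fe$band_of == "delta")
  v <- fe$features[1, , delta_cols]  # epochs x channels, all from 2 Hz z
  expect_lt(abs(mean(v)), 1e-10)
  expect_equal(sd(as.vector(v)), 1, tolerance = 1e-6)
  # constant power: zero variance guard -> all z = 0
  fe0 <- build_epochs(toy_tf(fill = 2), window = c(-1, 1))
  expect_true(all(fe0$features == 0))
})

test_that("cosine similarity obeys identity, orthogonality, anti-alignment and scale invariance", {
  v <- matrix(c(1, 2, 3, 4,
                0, 0, 0, 0,
                1, -1, 0, 0), 3, 4, byrow = TRUE)
  u <- matrix(c(1, 2, 3, 4,
                -1, -2, -3, -4,
                0, 0, 2, -1), 3, 4, byrow = TRUE)
  rho <- cosine_map(v[c(1, 3), ], u)
  expect_equal(rho[1, 1], 1)
  expect_equal(rho[1, 2], -1)
  expect_equal(rho[2, 3], 0)
  expect_equal(cosine_map(5 * v[c(1, 3), ], 0.1 * u), rho, tolerance = 1e-12)
  expect_error(cosine_map(v, u[, 1:2]), "mismatch")
  # NA dimensions are dropped pairwise; all-NA rows give missing cells
  v2 <- rbind(v[1, ], v[3, ])
  v2[2, ] <- NA
  rho2 <- cosine_map(v2, u)
  expect_equal(rho2[1, 1], 1)
  expect_true(all(is.na(rho2[2, ])))
})

test_that("condition averages are cell-wise and missing-aware", {
  m <- array(NA_real_, c(2, 2, 2))
  m[1, , ] <- 1; m[2, , ] <- 3
  expect_equal(condition_average(m), matrix(2, 2, 2))
  expect_equal(condition_average(m, 1), matrix(1, 2, 2))
  m[2, 1, 1] <- NA
  expect_equal(condition_average(m)[1, 1], 1)
  expect_error(condition_average(m, integer(0)), "empty condition")
})

test_that("stage selection follows session choice rates and stays disjoint", {
  tr <- data.frame(session_idx = rep(0:3, each = 50),
                   choice = c(rep(c("S1_PLUS", "S1_MINUS"), 25),       # 50%
                              rep(c("S1_PLUS", "S1_MINUS"), 25),       # 50%
                              rep("S1_PLUS", 50),                      # 100%
                              rep("S1_PLUS", 50)),                     # 100%
                   valid = TRUE)
  early <- select_stage_trials(tr, "early", n = 80)
  late <- select_stage_trials(tr, "late", n = 80)
  expect_identical(length(intersect(early, late)), 0L)
  expect_true(all(tr$session_idx[early] %in% 0:1))
  expect_true(all(tr$session_idx[late] %in% 2:3))
  expect_identical(early, 1:80)
  expect_identical(late, 121:200)
  # a 75% plateau qualifies for neither stage
  tr75 <- data.frame(session_idx = rep(0:1, each = 100),
                     choice = rep(rep(c("S1_PLUS", "S1_MINUS"), c(3, 1)), 50),
                     valid = TRUE)
  expect_error(select_stage_trials(tr75, "early", n = 10), "0 qualifying")
  expect_error(select_stage_trials(tr75, "late", n = 10), "0 qualifying")
})

test_that("cluster contrast recovers a planted block and is seed-deterministic", {
  set.seed(63)
  nA <- 25; nB <- 25
  A <- array(rnorm(nA * 20 * 20, sd = 0.5), c(nA, 20, 20))
  B <- array(rnorm(nB * 20 * 20, sd = 0.5), c(nB, 20, 20))
  A[, 5:10, 5:10] <- A[, 5:10, 5:10] + 1.2   # planted block in group A
  ct <- cluster_contrast(A, B, n_perm = 300, seed = 64)
  expect_gt(nrow(ct$clusters), 0)
  top <- ct$clusters[1, ]
  expect_lt(top$p_corr, 0.05)
  expect_identical(top$sign, 1)
  # the top cluster covers the planted block
  lab_block <- ct$labels[5:10, 5:10]
  expect_gt(mean(lab_block == top$id), 0.8)
  ct2 <- cluster_contrast(A, B, n_perm = 300, seed = 64)
  expect_identical(ct$clusters, ct2$clusters)
  expect_identical(ct$null_max, ct2$null_max)
  # excluded cells never enter clusters
  excl <- matrix(FALSE, 20, 20); excl[5:10, 5:10] <- TRUE
  ct3 <- cluster_contrast(A, B, n_perm = 100, seed = 65, exclude = excl)
  if (nrow(ct3$clusters) > 0) expect_true(all(ct3$labels[excl] == 0))
})

test_that("disjointness of contrast groups is enforced", {
  chain <- small_lfp_chain()
  m1 <- similarity_maps(chain$fe, 1:25, "low")
  m2 <- similarity_maps(chain$fe, 20:40, "low")
  expect_error(cluster_contrast(m1, m2, n_perm = 100), "share trials")
})

test_that("band-restricted features partition the full feature set", {
  chain <- small_lfp_chain()
  fe <- chain$fe
  lo <- which(fe$group_of == "low")
  hi <- which(fe$group_of == "high")
  expect_identical(sort(c(lo, hi)), seq_along(fe$group_of))
  m_all <- similarity_maps(fe, 1:4, "all")
  # computing on the union of low+high columns equals the full computation
  f <- fe$features[1, , c(lo, hi)]
  s1 <- which(fe$starts >= -1 & fe$starts + fe$epoch_len <= 0 + 1e-9)
  s2 <- which(fe$starts >= 0 & fe$starts + fe$epoch_len <= 1 + 1e-9)
  rho_manual <- cosine_map(f[s1, ], f[s2, ])
  expect_equal(m_all$rho[1, , ], rho_manual, tolerance = 1e-12)
  # map geometry is fully determined by (window, epoch_len, step)
  expect_identical(dim(m_all$rho)[2:3], c(46L, 46L))
  expect_equal(m_all$s1_centers, seq(-0.95, -0.05, by = 0.02))
})

test_that("planted shared spatial patterns raise low-band cross-state similarity", {
  chain <- small_lfp_chain()
  gt <- chain$gen$ground_truth
  shared <- which(gt$shared_low)
  unshared <- which(!gt$shared_low)
  m_s <- similarity_maps(chain$fe, shared, "low")
  m_u <- similarity_maps(chain$fe, unshared, "low")
  i_sel <- m_s$s1_centers > -0.9 & m_s$s1_centers < -0.1
  j_sel <- m_s$s2_centers > 0.2 & m_s$s2_centers < 0.9
  expect_gt(mean(m_s$rho[, i_sel, j_sel], na.rm = TRUE),
            mean(m_u$rho[, i_sel, j_sel], na.rm = TRUE) + 0.02)
  # no such effect in the high band (no shared high-band pattern planted)
  mh_s <- similarity_maps(chain$fe, shared, "high")
  mh_u <- similarity_maps(chain$fe, unshared, "high")
  expect_lt(mean(mh_s$rho[, i_sel, j_sel], na.rm = TRUE) -
              mean(mh_u$rho[, i_sel, j_sel], na.rm = TRUE), 0.05)
})

test_that("tROI means have one value per trial", {
  chain <- small_lfp_chain()
  m <- similarity_maps(chain$fe, 1:5, "low")
  mask <- matrix(FALSE, 46, 46); mask[10:20, 25:40] <- TRUE
  v <- troi_mean(m, mask)
  expect_identical(length(v), 5L)
  expect_true(all(is.finite(v)))
})
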