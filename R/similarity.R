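#' Feature epochs for representational similarity
#'
#' Tiles overlapping 100 ms epochs (20 ms step, 80% overlap) across the
#' analysis span, averages instantaneous power over each epoch, z-scores per
#' frequency and trial across that trial's epoch population pooled over
#' electrodes (zero-variance guard: SD below `1e-12` gives z = 0), then
#' averages the z-scores into the six canonical bands. One feature vector of
#' length `K = channels x bands` per epoch. Pooling the z-transform over
#' electrodes preserves spatial power patterns, which is what the
#' cross-state similarity is meant to detect.
#'
#' @param tf a normalised, artifact-masked `epoched_tf`.
#' @param window full analysis span `c(t0, t1)` over which epochs are tiled
#'   (z-scoring uses all these epochs jointly).
#' @param epoch_len,step epoch length and spacing, seconds.
#' @param bands band table, see [lfp_bands()].
#' @return A `feature_epochs` object: `features` (trials x epochs x K array,
#'   K columns named `chNN.band`), `centers` (epoch centre times), `starts`,
#'   `band_of` / `channel_of` (K-length layout vectors) and the trial table.
#' @export
build_epochs <- function(tf, window = c(-1, 1), epoch_len = 0.1, step = 0.02,
                         bands = lfp_bands()) {
  if (diff(window) < epoch_len - 1e-12)
    stop("window shorter than one epoch", call. = FALSE)
  starts <- seq(window[1], window[2] - epoch_len + 1e-9, by = step)
  centers <- starts + epoch_len / 2
  n_ep <- length(starts)
  n_tr <- dim(tf$power)[1]; n_ch <- dim(tf$power)[2]
  nfreq <- length(tf$freqs)
  nb <- nrow(bands)
  bidx <- lapply(seq_len(nb), function(b)
    band_members(tf$freqs, bands$f_lo[b], bands$f_hi[b], last = b == nb))
  K <- n_ch * nb
  feats <- array(NA_real_, c(n_tr, n_ep, K))
  ep_sel <- lapply(seq_len(n_ep), function(e)
    which(tf$times >= starts[e] - 1e-9 & tf$times < starts[e] + epoch_len - 1e-9))
  for (j in seq_len(n_tr)) {
    slab <- array(tf$power[j, , , ], c(n_ch, nfreq, length(tf$times)))
    ep <- array(NA_real_, c(n_ep, n_ch, nfreq))
    for (e in seq_len(n_ep)) {
      sel <- ep_sel[[e]]
      m <- rowMeans(array(slab[, , sel], c(n_ch, nfreq, length(sel))),
                    dims = 2, na.rm = TRUE)
      ep[e, , ] <- m
    }
    ep[is.nan(ep)] <- NA_real_
    # z per frequency per trial, across this trial's epoch population
    # (pooled over electrodes), so spatial power patterns survive
    for (f in seq_len(nfreq)) {
      v <- ep[, , f]
      mu <- mean(v, na.rm = TRUE)
      sdv <- sd(v, na.rm = TRUE)
      ep[, , f] <- if (is.na(sdv) || sdv < 1e-12) 0 else (v - mu) / sdv
    }
    for (c in seq_len(n_ch)) {
      for (b in seq_len(nb))
        feats[j, , (c - 1) * nb + b] <-
          rowMeans(ep[, c, bidx[[b]], drop = FALSE], na.rm = TRUE)
    }
  }
  feats[is.nan(feats)] <- NA_real_
  dimnames(feats)[[3]] <- paste(rep(sprintf("ch%02d", seq_len(n_ch)), each = nb),
                                rep(bands$band, n_ch), sep = ".")
  structure(list(features = feats, centers = centers, starts = starts,
                 epoch_len = epoch_len, step = step,
                 band_of = rep(bands$band, n_ch),
                 group_of = rep(bands$group, n_ch),
                 channel_of = rep(seq_len(n_ch), each = nb),
                 trials = tf$trials),
            class = "feature_epochs")
}

#' Cosine similarity map between two epoch sets
#'
#' `rho(i, j) = <v_i, u_j> / (|v_i| |u_j|)` for every pair of S1-epoch and
#' S2-epoch feature vectors. Missing feature dimensions are dropped
#' pairwise; zero-norm (or all-missing) vectors yield missing entries.
#'
#' @param s1_feats,s2_feats epochs x K matrices.
#' @return matrix of cosine similarities (S1 epochs x S2 epochs).
#' @export
cosine_map <- function(s1_feats, s2_feats) {
  if (ncol(s1_feats) != ncol(s2_feats))
    stop("feature dimension mismatch", call. = FALSE)
  if (!anyNA(s1_feats) && !anyNA(s2_feats)) {
    n1 <- sqrt(rowSums(s1_feats^2))
    n2 <- sqrt(rowSums(s2_feats^2))
    rho <- (s1_feats %*% t(s2_feats)) / (n1 %o% n2)
    rho[!is.finite(rho)] <- NA_real_
    return(rho)
  }
  n_i <- nrow(s1_feats); n_j <- nrow(s2_feats)
  rho <- matrix(NA_real_, n_i, n_j)
  for (i in seq_len(n_i)) {
    for (j in seq_len(n_j)) {
      ok <- !is.na(s1_feats[i, ]) & !is.na(s2_feats[j, ])
      if (sum(ok) < 4) next
      v <- s1_feats[i, ok]; u <- s2_feats[j, ok]
      nv <- sqrt(sum(v^2)); nu <- sqrt(sum(u^2))
      if (nv == 0 || nu == 0) next
      rho[i, j] <- sum(v * u) / (nv * nu)
    }
  }
  rho
}

#' Per-trial similarity maps from feature epochs
#'
#' Splits each trial's epochs into the S1 set (epochs wholly inside
#' `s1_window`) and the S2 set (inside `s2_window`) and computes the cosine
#' map per trial, optionally on a band-restricted feature subset.
#'
#' @param fe a `feature_epochs` object.
#' @param trial_idx rows (trials) to use; default all.
#' @param band_group `"all"`, `"low"` (1-12 Hz bands) or `"high"`
#'   (12-100 Hz bands).
#' @param s1_window,s2_window epoch windows relative to the step-1 peck.
#' @return A `similarity_maps` object: `rho` (trials x S1-epochs x
#'   S2-epochs array), epoch centre axes, the band group and trial rows.
#' @export
similarity_maps <- function(fe, trial_idx = NULL,
                            band_group = c("all", "low", "high"),
                            s1_window = c(-1, 0), s2_window = c(0, 1)) {
  band_group <- match.arg(band_group)
  if (is.null(trial_idx)) trial_idx <- seq_len(dim(fe$features)[1])
  cols <- if (band_group == "all") seq_along(fe$group_of) else
    which(fe$group_of == band_group)
  if (length(cols) == 0) stop("empty band selection", call. = FALSE)
  e1 <- which(fe$starts >= s1_window[1] - 1e-9 &
                fe$starts + fe$epoch_len <= s1_window[2] + 1e-9)
  e2 <- which(fe$starts >= s2_window[1] - 1e-9 &
                fe$starts + fe$epoch_len <= s2_window[2] + 1e-9)
  rho <- array(NA_real_, c(length(trial_idx), length(e1), length(e2)))
  for (t in seq_along(trial_idx)) {
    f <- fe$features[trial_idx[t], , cols]
    rho[t, , ] <- cosine_map(f[e1, , drop = FALSE], f[e2, , drop = FALSE])
  }
  structure(list(rho = rho, s1_centers = fe$centers[e1],
                 s2_centers = fe$centers[e2], band_group = band_group,
                 trial_idx = trial_idx),
            class = "similarity_maps")
}

#' Cell-wise mean similarity map over a condition
#'
#' @param maps a `similarity_maps` object (or trials x i x j array).
#' @param which_trials logical/integer selector into the maps' trials.
#' @return mean map (missing-aware).
#' @export
condition_average <- function(maps, which_trials = NULL) {
  rho <- if (inherits(maps, "similarity_maps")) maps$rho else maps
  if (!is.null(which_trials)) rho <- rho[which_trials, , , drop = FALSE]
  if (dim(rho)[1] == 0)
    stop("empty condition: no trials selected", call. = FALSE)
  out <- apply(rho, c(2, 3), mean, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Select early / late learning-stage trials
#'
#' Early = the first `n` valid trials drawn from sessions whose S1+ choice
#' rate is below `early_thresh`; late = the last `n` valid trials from
#' sessions above `late_thresh`. The two sets are disjoint by construction.
#'
#' @param trials trial table (with `valid`).
#' @param stage `"early"` or `"late"`.
#' @param n trials per stage.
#' @param early_thresh,late_thresh session choice-rate criteria.
#' @return integer row indices into `trials`.
#' @export
select_stage_trials <- function(trials, stage = c("early", "late"), n = 100,
                                early_thresh = 0.65, late_thresh = 0.90) {
  stage <- match.arg(stage)
  valid <- if (is.null(trials$valid)) rep(TRUE, nrow(trials)) else trials$valid
  rates <- tapply(trials$choice == "S1_PLUS", trials$session_idx, mean)
  if (stage == "early") {
    sess <- as.integer(names(rates)[rates < early_thresh])
    pool <- which(trials$session_idx %in% sess & valid)
    if (length(pool) < n)
      stop("only ", length(pool), " qualifying early-stage trials (need ", n,
           ")", call. = FALSE)
    head(pool, n)
  } else {
    sess <- as.integer(names(rates)[rates > late_thresh])
    pool <- which(trials$session_idx %in% sess & valid)
    if (length(pool) < n)
      stop("only ", length(pool), " qualifying late-stage trials (need ", n,
           ")", call. = FALSE)
    tail(pool, n)
  }
}

# Pooled two-sample t statistics per map cell, missing-aware.
cellwise_tstats <- function(X, idxA, idxB, ok) {
  Xz <- X; Xz[!ok] <- 0
  nA <- colSums(ok[idxA, , drop = FALSE])
  nB <- colSums(ok[idxB, , drop = FALSE])
  sA <- colSums(Xz[idxA, , drop = FALSE]); sB <- colSums(Xz[idxB, , drop = FALSE])
  qA <- colSums(Xz[idxA, , drop = FALSE]^2); qB <- colSums(Xz[idxB, , drop = FALSE]^2)
  mA <- sA / nA; mB <- sB / nB
  vA <- (qA - nA * mA^2) / pmax(nA - 1, 1)
  vB <- (qB - nB * mB^2) / pmax(nB - 1, 1)
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / pmax(df, 1)
  t <- (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
  t[nA < 2 | nB < 2 | !is.finite(t)] <- NA_real_
  list(t = t, df = df)
}

max_cluster_mass <- function(tmat, thr, exclude = NULL) {
  supra <- !is.na(tmat) & abs(tmat) > thr
  if (!is.null(exclude)) supra[exclude] <- FALSE
  best <- 0
  for (sgn in c(1, -1)) {
    m <- supra & sign(tmat) == sgn
    if (!any(m)) next
    lab <- label_components_cpp(m)
    if (max(lab) == 0) next
    masses <- tapply(abs(tmat)[lab > 0], lab[lab > 0], sum)
    best <- max(best, masses)
  }
  best
}

#' Cluster-based permutation contrast between two sets of similarity maps
#'
#' Cell-wise two-sample t statistics; 4-connected supra-threshold clusters
#' (positive and negative separately) scored by mass (sum of `|t|`); null
#' distribution of the maximum cluster mass from random permutations of the
#' trial-to-group assignment; corrected p = fraction of permutation maxima
#' at or above each observed cluster's mass.
#'
#' @param mapsA,mapsB `similarity_maps` objects or trials x i x j arrays
#'   (the two conditions; trial sets must be disjoint).
#' @param n_perm number of label permutations.
#' @param cell_alpha cell-forming threshold (two-sided).
#' @param seed integer seed (fixed seed gives identical results).
#' @param exclude optional logical i x j matrix of cells to drop before
#'   clustering (e.g. peck-artifact bands).
#' @return A `cluster_contrast` object: `diff` (mean difference map), `t`
#'   map, `clusters` data.frame (`id`, `sign`, `n_cells`, `mass`, `p_corr`),
#'   `sig_mask` at p(corr) < 0.05, and the permutation null.
#' @export
cluster_contrast <- function(mapsA, mapsB, n_perm = 1000, cell_alpha = 0.05,
                             seed = 1L, exclude = NULL) {
  if (n_perm < 100) warning("n_perm < 100: corrected p-values are coarse")
  if (inherits(mapsA, "similarity_maps") && inherits(mapsB, "similarity_maps") &&
      length(intersect(mapsA$trial_idx, mapsB$trial_idx)) > 0)
    stop("groups share trials: conditions must be disjoint", call. = FALSE)
  A <- if (inherits(mapsA, "similarity_maps")) mapsA$rho else mapsA
  B <- if (inherits(mapsB, "similarity_maps")) mapsB$rho else mapsB
  di <- dim(A)[2]; dj <- dim(A)[3]
  stopifnot(dim(B)[2] == di, dim(B)[3] == dj)
  if (dim(A)[1] < 20 || dim(B)[1] < 20)
    warning("fewer than 20 maps in a group; contrast is unstable")
  nA <- dim(A)[1]; nB <- dim(B)[1]
  X <- rbind(matrix(A, nA, di * dj), matrix(B, nB, di * dj))
  ok <- !is.na(X)
  idxA <- seq_len(nA); idxB <- nA + seq_len(nB)
  obs <- cellwise_tstats(X, idxA, idxB, ok)
  thr_vec <- qt(1 - cell_alpha / 2, pmax(obs$df, 1))
  tmat <- matrix(obs$t, di, dj)
  thr <- matrix(thr_vec, di, dj)
  excl_mat <- if (is.null(exclude)) matrix(FALSE, di, dj) else exclude

  supra <- !is.na(tmat) & abs(tmat) > thr & !excl_mat
  clusters <- data.frame(id = integer(0), sign = integer(0),
                         n_cells = integer(0), mass = numeric(0))
  lab_full <- matrix(0L, di, dj)
  next_id <- 0L
  for (sgn in c(1, -1)) {
    m <- supra & sign(tmat) == sgn
    if (!any(m)) next
    lab <- label_components_cpp(m)
    for (l in seq_len(max(lab))) {
      next_id <- next_id + 1L
      cells <- lab == l
      lab_full[cells] <- next_id
      clusters <- rbind(clusters,
                        data.frame(id = next_id, sign = sgn,
                                   n_cells = sum(cells),
                                   mass = sum(abs(tmat)[cells])))
    }
  }

  set.seed(seed)
  null_max <- numeric(n_perm)
  n_tot <- nA + nB
  for (p in seq_len(n_perm)) {
    perm <- sample.int(n_tot)
    pt <- cellwise_tstats(X, perm[idxA], perm[idxB], ok)
    null_max[p] <- max_cluster_mass(matrix(pt$t, di, dj), thr,
                                    exclude = excl_mat)
  }
  if (nrow(clusters) > 0) {
    clusters$p_corr <- vapply(clusters$mass, function(m)
      (1 + sum(null_max >= m)) / (n_perm + 1), numeric(1))
    clusters <- clusters[order(clusters$p_corr, -clusters$mass), ]
  } else {
    clusters$p_corr <- numeric(0)
  }
  sig_ids <- clusters$id[clusters$p_corr < 0.05]
  structure(list(diff = matrix(colMeans(X[idxA, , drop = FALSE], na.rm = TRUE) -
                                 colMeans(X[idxB, , drop = FALSE], na.rm = TRUE),
                               di, dj),
                 t = tmat, labels = lab_full, clusters = clusters,
                 sig_mask = matrix(lab_full %in% sig_ids, di, dj),
                 null_max = null_max, n_perm = n_perm,
                 cell_alpha = cell_alpha, seed = seed),
            class = "cluster_contrast")
}

#' Band-restricted similarity maps
#'
#' Repeats the full similarity computation using only the selected band
#' group's features (`K = channels x bands_in_group`).
#'
#' @inheritParams similarity_maps
#' @export
band_restricted_similarity <- function(fe, band_group, trial_idx = NULL,
                                       s1_window = c(-1, 0),
                                       s2_window = c(0, 1)) {
  similarity_maps(fe, trial_idx = trial_idx, band_group = band_group,
                  s1_window = s1_window, s2_window = s2_window)
}

#' Mean similarity over a cluster's cells, per trial
#'
#' Quantifies a time region of interest (tROI): for each trial's map, the
#' mean rho over the cluster's member cells.
#'
#' @param maps a `similarity_maps` object.
#' @param mask logical i x j matrix (e.g. `contrast$sig_mask`).
#' @return numeric vector, one value per trial.
#' @export
troi_mean <- function(maps, mask) {
  vapply(seq_len(dim(maps$rho)[1]), function(t) {
    m <- maps$rho[t, , ][mask]
    mean(m, na.rm = TRUE)
  }, numeric(1))
}
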