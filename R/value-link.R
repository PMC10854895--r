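#' Session-wise regression of band power on model-based value
#'
#' Ordinary least squares `y = beta0 + beta1 * x`, where `y` is the
#' session-mean normalised band power of one condition (0.5 s pre-peck
#' window) and `x` the session-mean model-derived value of the matching
#' option/state. Significance of the regression is the one-way ANOVA F test
#' with (1, n - 2) degrees of freedom.
#'
#' @param y per-session mean power.
#' @param x per-session mean value.
#' @param condition,band_group labels carried into the result.
#' @return A `regression_result` (list): `beta0`, `beta1`, `r_squared`,
#'   `f_statistic`, `df`, `p_value`, `n`.
#' @export
session_value_regression <- function(y, x, condition = "", band_group = "") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 sessions", call. = FALSE)
  if (var(x) == 0) stop("value series is degenerate (zero variance)",
                        call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  f <- unname(sm$fstatistic)
  structure(list(beta0 = unname(coef(fit)[1]), beta1 = unname(coef(fit)[2]),
                 r_squared = sm$r.squared, f_statistic = f[1],
                 df = c(f[2], f[3]),
                 p_value = pf(f[1], f[2], f[3], lower.tail = FALSE),
                 n = length(x), condition = condition,
                 band_group = band_group),
            class = "regression_result")
}

#' @importFrom stats coef pf predict
NULL

#' Decode the step-1 choice from band-power features
#'
#' Linear maximum-margin classification (SVM, linear kernel) of the step-1
#' choice from per-trial electrode x band normalised power. Repeated
#' stratified 70/30 splits; feature standardisation is fit on each training
#' split only. Rounds continue past `n_repeats` (up to `max_repeats`) until
#' every trial has appeared in at least one test set.
#'
#' @param features trials x K numeric matrix.
#' @param labels per-trial choice labels (2 classes).
#' @param n_repeats nominal number of split rounds.
#' @param train_frac training fraction.
#' @param cost SVM regularisation constant.
#' @param seed integer seed.
#' @param max_repeats hard cap on rounds.
#' @param splits optional list of explicit splits, each a list with `train`
#'   and `test` integer index vectors (overrides the random split stream).
#' @return A `decode_result` (list): per-round `accuracies`, `mean`, `sd`,
#'   `n_trials`, `config`.
#' @export
decode_choice <- function(features, labels, n_repeats = 10, train_frac = 0.7,
                          cost = 1, seed = 1L, max_repeats = 50,
                          splits = NULL) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("single-class input", call. = FALSE)
  keep <- complete.cases(features)
  features <- features[keep, , drop = FALSE]
  labels <- droplevels(labels[keep])
  counts <- table(labels)
  if (any(counts < 20))
    warning("fewer than 20 trials in a class; decoding is unstable")
  set.seed(seed)
  n <- nrow(features)
  tested <- rep(FALSE, n)
  acc <- numeric(0)
  r <- 0L
  n_target <- if (is.null(splits)) n_repeats else length(splits)
  while (r < n_target || (is.null(splits) && any(!tested) && r < max_repeats)) {
    r <- r + 1L
    if (is.null(splits)) {
      tr_idx <- unlist(lapply(levels(labels), function(l) {
        idx <- which(labels == l)
        sample(idx, round(train_frac * length(idx)))
      }))
      te_idx <- setdiff(seq_len(n), tr_idx)
    } else {
      tr_idx <- splits[[r]]$train
      te_idx <- splits[[r]]$test
    }
    mu <- colMeans(features[tr_idx, , drop = FALSE])
    sdv <- apply(features[tr_idx, , drop = FALSE], 2, sd)
    sdv[sdv < 1e-12] <- 1
    scale_rows <- function(m) sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
    fit <- e1071::svm(scale_rows(features[tr_idx, , drop = FALSE]),
                      labels[tr_idx], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- predict(fit, scale_rows(features[te_idx, , drop = FALSE]))
    acc <- c(acc, mean(pred == labels[te_idx]))
    tested[te_idx] <- TRUE
  }
  structure(list(accuracies = acc, mean = mean(acc), sd = sd(acc),
                 n_trials = n, n_rounds = r, all_tested = all(tested),
                 config = list(n_repeats = n_repeats,
                               train_frac = train_frac, cost = cost,
                               kernel = "linear", seed = seed)),
            class = "decode_result")
}

#' Normality-gated two-sample / paired comparison
#'
#' Assesses normality with the Lilliefors test at `alpha = 0.05` (on the
#' paired differences, or on each group); normal data are compared with a
#' t test, non-normal data with the Wilcoxon test (rank-sum when unpaired,
#' signed-rank when paired). The Lilliefors test requires n >= 5; smaller
#' samples route to the non-parametric branch.
#'
#' @param x,y numeric samples.
#' @param paired paired comparison?
#' @param alpha normality-gate level.
#' @return list: `test` ("t" or "wilcoxon"), `normal` (gate outcome),
#'   `statistic`, `df` (t only), `p_value`, `mean_diff`.
#' @export
stat_tests <- function(x, y, paired = FALSE, alpha = 0.05) {
  if (paired && length(x) != length(y))
    stop("paired test requires equal lengths", call. = FALSE)
  if (length(x) < 3 || length(y) < 3)
    stop("need at least 3 observations per sample", call. = FALSE)
  if (sd(c(x, y)) == 0 || (paired && sd(x - y) == 0)) {
    # degenerate comparison (e.g. x identical to y): no evidence of a
    # difference, reported as a null t result
    return(list(test = "t", normal = TRUE, statistic = 0,
                df = if (paired) length(x) - 1 else length(x) + length(y) - 2,
                p_value = 1, mean_diff = mean(x) - mean(y)))
  }
  lillie_ok <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 5 || sd(v) == 0) return(NA)
    nortest::lillie.test(v)$p.value >= alpha
  }
  normal <- if (paired) lillie_ok(x - y) else
    isTRUE(lillie_ok(x)) && isTRUE(lillie_ok(y))
  normal <- isTRUE(normal)
  if (normal) {
    tt <- t.test(x, y, paired = paired)
    list(test = "t", normal = TRUE,
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_diff = mean(x) - mean(y))
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, paired = paired, exact = FALSE))
    list(test = "wilcoxon", normal = FALSE,
         statistic = unname(wt$statistic), df = NA_real_,
         p_value = wt$p.value, mean_diff = mean(x) - mean(y))
  }
}

#' Session means of a per-trial quantity for one condition
#'
#' @param values per-trial values.
#' @param session_idx per-trial session index.
#' @param select logical selector of condition trials.
#' @param sessions session ids to report (default: all present).
#' @return numeric vector of session means (NA where a session has no
#'   selected trials).
#' @export
session_means <- function(values, session_idx, select = NULL,
                          sessions = sort(unique(session_idx))) {
  if (!is.null(select)) {
    values <- values[select]
    session_idx <- session_idx[select]
  }
  m <- tapply(values, session_idx, mean, na.rm = TRUE)
  out <- setNames(rep(NA_real_, length(sessions)), sessions)
  out[names(m)] <- as.numeric(m)
  out
}

#' Flatten band-power features for decoding
#'
#' @param bp a `band_power` object.
#' @param band_group `"low"`, `"high"` or `"all"` (all six bands).
#' @return trials x (channels x bands) matrix.
#' @export
decode_features <- function(bp, band_group = c("high", "low", "all")) {
  band_group <- match.arg(band_group)
  sel <- if (band_group == "all") seq_len(dim(bp$bands)[3]) else
    which(bp$band_table$group == band_group)
  arr <- bp$bands[, , sel, drop = FALSE]
  matrix(arr, nrow = dim(arr)[1])
}
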