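#' Default gradient-boosting learner configuration
#'
#' Fixed, documented hyperparameters for the underlying XGBoost
#' classifier: logistic objective, depth 6, 200 boosting rounds, learning
#' rate 0.1, single thread (for bit-reproducibility), no class-imbalance
#' weighting. Any element can be overridden by passing a partial list to
#' the scoring functions.
#'
#' @return A named list of learner settings.
#' @export
default_learner_config <- function() {
  list(nrounds = 200L, max_depth = 6L, eta = 0.1,
       objective = "binary:logistic", nthread = 1L, tree_method = "hist")
}

merge_learner_config <- function(config) {
  out <- default_learner_config()
  out[names(config)] <- config
  out
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin across folds. Returns an integer vector in 1..n_folds.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Train-on-complement / predict-held-out over a given fold assignment.
# `y_train` are the labels the learner sees; errors if any training
# complement is single-class.
oof_predict <- function(X, y_train, fold, config, seed) {
  cfg <- merge_learner_config(config)
  Xc <- methods::as(X, "CsparseMatrix")
  scores <- numeric(length(y_train))
  for (k in sort(unique(fold))) {
    tr <- fold != k
    if (length(unique(y_train[tr])) < 2L) {
      stop("training fold ", k, " contains a single class")
    }
    dtrain <- xgboost::xgb.DMatrix(Xc[tr, , drop = FALSE],
                                   label = y_train[tr])
    params <- list(objective = cfg$objective, max_depth = cfg$max_depth,
                   eta = cfg$eta, nthread = cfg$nthread,
                   tree_method = cfg$tree_method, seed = seed)
    bst <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = cfg$nrounds, verbose = 0)
    scores[!tr] <- predict(bst, xgboost::xgb.DMatrix(Xc[!tr, , drop = FALSE]))
  }
  scores
}

#' Out-of-fold classifier scores for a PU dataset
#'
#' Splits the dataset into stratified folds; for each fold a
#' gradient-boosted classifier is trained on the complement (labeled
#' positives as class 1, unlabeled as class 0) and predicts held-out
#' probabilities, so every instance is scored exactly once by a model that
#' never saw it. If a training complement ends up single-class the split
#' is redrawn once with a perturbed seed, then a hard error is raised.
#'
#' @param dataset A `pu_dataset`.
#' @param n_folds Number of folds (>= 2).
#' @param learner_config Partial override of [default_learner_config()].
#' @param seed Integer seed controlling the split and the learner.
#' @return A list of class `score_set`: `scores_pos`, `scores_unl` (named
#'   by gene id), `fold_assignment`, `seed`.
#' @export
oof_scores <- function(dataset, n_folds = 5L, learner_config = list(),
                       seed = 1L) {
  stopifnot(inherits(dataset, "pu_dataset"), n_folds >= 2L)
  if (length(unique(dataset$y)) < 2L) {
    stop("dataset must contain both labeled positives and unlabeled genes")
  }
  set.seed(seed)
  fold <- stratified_folds(dataset$y, n_folds)
  scores <- tryCatch(
    oof_predict(dataset$X, dataset$y, fold, learner_config, seed),
    error = function(e) {
      set.seed(seed + 1000003L)
      fold2 <- stratified_folds(dataset$y, n_folds)
      fold <<- fold2
      oof_predict(dataset$X, dataset$y, fold2, learner_config, seed)
    }
  )
  pos <- dataset$y == 1L
  structure(list(scores_pos = setNames(scores[pos], dataset$row_ids[pos]),
                 scores_unl = setNames(scores[!pos], dataset$row_ids[!pos]),
                 fold_assignment = fold, seed = seed),
            class = "score_set")
}

trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)
}

#' Boundary-corrected kernel density on \[0, 1\]
#'
#' Gaussian kernel density estimate for data supported on the unit
#' interval, with reflection at both boundaries so that probability mass
#' near 0 and 1 is not leaked outside the support. Bandwidth defaults to
#' Silverman's rule on the raw scores; the result is renormalized to
#' integrate to 1 (trapezoid rule) on a uniform grid.
#'
#' @param scores Numeric vector in \[0, 1\], length >= 10.
#' @param grid_size Number of grid points (default 1001).
#' @param bandwidth Positive bandwidth, or `"auto"` for Silverman's rule.
#' @return A list of class `bounded_kde`: `x` (grid), `y` (density values),
#'   `bw` (bandwidth used).
#' @export
bounded_kde <- function(scores, grid_size = 1001L, bandwidth = "auto") {
  if (length(scores) < 10L) stop("need at least 10 scores for a density")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  if (identical(bandwidth, "auto")) {
    bw <- if (stats::sd(scores) == 0) 1 / grid_size else stats::bw.nrd0(scores)
    bw <- max(bw, 1e-4)
  } else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bw <- bandwidth
  }
  aug <- c(scores, -scores, 2 - scores)  # reflect about both boundaries
  d <- stats::density(aug, bw = bw, from = 0, to = 1, n = grid_size)
  y <- 3 * d$y
  y <- y / trapz(d$x, y)
  structure(list(x = d$x, y = y, bw = bw), class = "bounded_kde")
}

#' Estimate the class prior among unlabeled instances (SCAR)
#'
#' Under the two-component mixture f_u = alpha * f_p + (1 - alpha) * f_n,
#' with the positive score density f_p estimated from the labeled
#' positives (the SCAR assumption makes labeled positives representative
#' of all positives), the estimator returns the largest alpha on a
#' uniform grid for which the excess mass
#' err(alpha) = integral of max(0, alpha * fhat_p - fhat_u)
#' stays within a tolerance tied to the density-estimation noise: the
#' mean, over bootstrap resamples of the unlabeled scores, of the
#' one-sided discrepancy integral max(0, fhat_u - fhat_u_boot). This is
#' the largest mixing proportion still feasible given the spurious excess
#' the KDE shows from sampling noise alone.
#'
#' @param scores_pos,scores_unl Out-of-fold probabilities in \[0, 1\].
#' @param grid_size Density/alpha grid resolution (default 1001).
#' @param n_boot Bootstrap resamples for the tolerance (default 100).
#' @param bandwidth Passed to [bounded_kde()].
#' @return Estimated alpha in \[0, 1\].
#' @export
estimate_alpha <- function(scores_pos, scores_unl, grid_size = 1001L,
                           n_boot = 100L, bandwidth = "auto") {
  if (identical(bandwidth, "auto")) {
    # one shared bandwidth for both mixture components: the excess-mass
    # comparison alpha * f_p vs f_u is only meaningful when both densities
    # resolve the same scale, so take the sharper of the two Silverman rules
    bandwidth <- min(bounded_kde(scores_pos, grid_size)$bw,
                     bounded_kde(scores_unl, grid_size)$bw)
  }
  fp <- bounded_kde(scores_pos, grid_size, bandwidth)
  fu <- bounded_kde(scores_unl, grid_size, bandwidth)

  boot_excess <- vapply(seq_len(n_boot), function(b) {
    res <- sample(scores_unl, replace = TRUE)
    fub <- bounded_kde(res, grid_size, bandwidth = fu$bw)
    trapz(fu$x, pmax(0, fu$y - fub$y))
  }, numeric(1L))
  eps <- mean(boot_excess)

  alphas <- seq(0, 1, length.out = grid_size)
  err <- vapply(alphas, function(a) trapz(fu$x, pmax(0, a * fp$y - fu$y)),
                numeric(1L))
  max(alphas[err <= eps])  # err(0) = 0, so the feasible set is non-empty
}

#' Classical SCAR prior estimate from mean scores
#'
#' The ratio estimator: the labeling propensity is estimated as the mean
#' out-of-fold score of labeled positives, and the prior among unlabeled
#' instances as the mean unlabeled score divided by that propensity,
#' clipped to \[0, 1\]. Used as an internal cross-check on
#' [estimate_alpha()].
#'
#' @param scores_pos,scores_unl Score vectors in \[0, 1\].
#' @return Estimated alpha in \[0, 1\].
#' @export
elkan_noto_alpha <- function(scores_pos, scores_unl) {
  c_hat <- mean(scores_pos)
  if (!is.finite(c_hat) || c_hat <= 0) stop("mean positive score must be > 0")
  min(1, max(0, mean(scores_unl) / c_hat))
}

#' Calibrate unlabeled scores to a given class prior
#'
#' Monotone (rank-preserving) rescaling of the unlabeled scores so that
#' the mean calibrated probability equals `alpha`: empirical ranks are
#' mapped to (0, 1), scaled by a constant, and clipped at 1; the constant
#' is solved so the mean matches `alpha` to within 1e-6. Ties in the raw
#' scores receive identical calibrated values.
#'
#' @param scores_unl Raw scores in \[0, 1\].
#' @param alpha Target mean probability in \[0, 1\].
#' @return Calibrated probabilities in \[0, 1\], same order as input.
#' @export
calibrate_probabilities <- function(scores_unl, alpha) {
  stopifnot(alpha >= 0, alpha <= 1, length(scores_unl) >= 1L)
  n <- length(scores_unl)
  if (alpha == 0) {
    message("alpha = 0: all calibrated probabilities are 0")
    return(rep(0, n))
  }
  if (alpha == 1) {
    message("alpha = 1: all calibrated probabilities are 1")
    return(rep(1, n))
  }
  u <- rank(scores_unl, ties.method = "average") / (n + 1)
  k_max <- 1 / min(u)  # all values clipped to 1
  f <- function(k) mean(pmin(1, k * u)) - alpha
  if (f(k_max) <= 0) return(pmin(1, k_max * u))
  k <- uniroot(f, c(0, k_max), tol = 1e-12)$root
  pmin(1, k * u)
}

#' Impute probable positives from calibrated probabilities
#'
#' Promotes the `ceiling(alpha * n)` unlabeled genes with the highest mean
#' calibrated probability to probable positives; ties at the cutoff are
#' broken lexicographically by gene id.
#'
#' @param gene_ids Unlabeled gene ids.
#' @param calibrated_mean Mean calibrated probabilities, same length.
#' @param alpha Estimated class prior.
#' @return Character vector of imputed gene ids (sorted lexicographically).
#' @export
impute_probable_positives <- function(gene_ids, calibrated_mean, alpha) {
  stopifnot(length(gene_ids) == length(calibrated_mean),
            alpha >= 0, alpha <= 1)
  n_imp <- ceiling(alpha * length(gene_ids))
  if (n_imp == 0L) {
    warning("alpha * n rounds to 0: no genes imputed")
    return(character(0))
  }
  ord <- order(-calibrated_mean, gene_ids)
  sort(gene_ids[ord[seq_len(n_imp)]])
}

#' Repeated PU estimation: alpha, calibrated probabilities, imputation
#'
#' Runs the full SCAR estimation loop `n_iterations` times with seeds
#' `base_seed + i`: out-of-fold scoring, prior estimation, calibration.
#' Per-iteration alphas are aggregated into a mean with a normal 95%
#' interval; per-gene calibrated probabilities are averaged over
#' iterations, and probable positives are imputed from the mean
#' probabilities using the mean alpha.
#'
#' @param dataset A `pu_dataset`.
#' @param n_iterations Number of independent repetitions (default 40).
#' @param n_folds Folds for out-of-fold scoring (default 5).
#' @param base_seed Base seed; iteration i uses `base_seed + i`.
#' @param learner_config Partial override of [default_learner_config()].
#' @return A list with elements `alpha` (class `alpha_estimate`: `alpha`,
#'   `per_iteration_alphas`, `ci95`) and `scores` (class
#'   `calibrated_gene_scores`: `gene_ids`, `calibrated` (iterations x
#'   genes), `mean_calibrated`, `imputed_positives`).
#' @export
run_pu_iterations <- function(dataset, n_iterations = 40L, n_folds = 5L,
                              base_seed = 1L, learner_config = list()) {
  stopifnot(inherits(dataset, "pu_dataset"), n_iterations >= 1L)
  unl_ids <- dataset$row_ids[dataset$y == 0L]
  alphas <- numeric(n_iterations)
  calib <- matrix(NA_real_, nrow = n_iterations, ncol = length(unl_ids),
                  dimnames = list(NULL, unl_ids))
  for (i in seq_len(n_iterations)) {
    seed_i <- base_seed + i
    res <- tryCatch({
      ss <- oof_scores(dataset, n_folds, learner_config, seed = seed_i)
      a <- estimate_alpha(ss$scores_pos, ss$scores_unl)
      list(a = a, cal = calibrate_probabilities(ss$scores_unl, a))
    }, error = function(e) {
      stop("PU iteration ", i, " failed: ", conditionMessage(e))
    })
    alphas[i] <- res$a
    calib[i, ] <- res$cal
  }
  mean_alpha <- mean(alphas)
  mean_cal <- colMeans(calib)
  alpha_est <- structure(
    list(alpha = mean_alpha, per_iteration_alphas = alphas,
         ci95 = ci95(alphas)),
    class = "alpha_estimate"
  )
  scores <- structure(
    list(gene_ids = unl_ids, calibrated = calib, mean_calibrated = mean_cal,
         imputed_positives = suppressWarnings(
           impute_probable_positives(unl_ids, mean_cal, mean_alpha))),
    class = "calibrated_gene_scores"
  )
  list(alpha = alpha_est, scores = scores)
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat(sprintf("<alpha_estimate> alpha = %.4f (95%% CI %.4f, %.4f) over %d iterations\n",
              x$alpha, x$ci95[1L], x$ci95[2L], length(x$per_iteration_alphas)))
  invisible(x)
}
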