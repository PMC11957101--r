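test_that("out-of-fold scores separate a separable dataset and respect limits", {
  ds <- small_pu_dataset(n_pos = 50, n_unl = 100, p_pos = 0.9, p_neg = 0.02,
                         seed = 2)
  ss <- oof_scores(ds, n_folds = 5, learner_config = fast_learner, seed = 3)
  expect_gt(mean(ss$scores_pos), 0.9)
  expect_lt(mean(ss$scores_unl), 0.1)
  expect_true(all(c(ss$scores_pos, ss$scores_unl) >= 0 &
                  c(ss$scores_pos, ss$scores_unl) <= 1))
  expect_length(ss$fold_assignment, 150L)

  # no signal: identical rows => every score near the positive base rate
  n <- 150L
  X <- methods::as(methods::as(Matrix::Matrix(1, n, 3, sparse = TRUE),
                               "generalMatrix"), "RsparseMatrix")
  dimnames(X) <- list(sprintf("G%03d", 1:n), c("E1", "E2", "E3"))
  flat <- structure(list(X = X, y = c(rep(1L, 50L), rep(0L, 100L)),
                         row_ids = rownames(X), col_ids = colnames(X)),
                    class = "pu_dataset")
  ss2 <- oof_scores(flat, n_folds = 5, learner_config = fast_learner, seed = 3)
  expect_lt(max(abs(c(ss2$scores_pos, ss2$scores_unl) - 1 / 3)), 0.05)
})

test_that("scoring is bit-reproducible given the seed", {
  ds <- small_pu_dataset(seed = 5)
  s1 <- oof_scores(ds, learner_config = fast_learner, seed = 17)
  s2 <- oof_scores(ds, learner_config = fast_learner, seed = 17)
  expect_identical(s1, s2)
  s3 <- oof_scores(ds, learner_config = fast_learner, seed = 18)
  expect_false(identical(s1$scores_unl, s3$scores_unl))
})

test_that("the bounded density integrates to one and tracks known densities", {
  set.seed(42)
  u <- runif(10000)
  ku <- bounded_kde(u)
  expect_lt(abs(pukg:::trapz(ku$x, ku$y) - 1), 1e-3)
  interior <- ku$x > 0.05 & ku$x < 0.95
  expect_lt(max(abs(ku$y[interior] - 1)), 0.1)

  b <- rbeta(10000, 2, 5)
  kb <- bounded_kde(b)
  interior <- kb$x >= 0.05 & kb$x <= 0.95
  expect_lt(max(abs(kb$y[interior] - dbeta(kb$x[interior], 2, 5))), 0.15)

  spike <- bounded_kde(rep(0.5, 100))
  expect_lt(abs(pukg:::trapz(spike$x, spike$y) - 1), 1e-3)
  expect_equal(spike$x[which.max(spike$y)], 0.5, tolerance = 0.01)

  expect_error(bounded_kde(runif(5)), "at least 10")
  expect_error(bounded_kde(c(runif(20), 1.5)), "0, 1")
})

test_that("the prior estimator respects degenerate limits", {
  set.seed(101)
  sp <- rbeta(5000, 20, 2)
  expect_lte(estimate_alpha(sp, rbeta(5000, 2, 20)), 0.02)
  expect_gte(estimate_alpha(sp, rbeta(5000, 20, 2)), 0.95)
})

test_that("the prior estimator recovers a planted Beta mixture fraction", {
  set.seed(77)
  errs <- vapply(1:5, function(i) {
    sp <- rbeta(5000, 8, 2)
    su <- c(rbeta(1500, 8, 2), rbeta(3500, 2, 8))
    abs(estimate_alpha(sp, su) - 0.3)
  }, numeric(1L))
  expect_lt(mean(errs), 0.05)
})

test_that("both estimators agree with the planted fraction when scores separate", {
  # negatives scoring essentially 0 is the regime where the mean-ratio
  # estimator is unbiased; both should then land on the planted fraction
  set.seed(78)
  sp <- rbeta(10000, 60, 2)
  su <- c(rbeta(3000, 60, 2), rbeta(7000, 1, 400))
  a_kde <- estimate_alpha(sp, su)
  a_en <- elkan_noto_alpha(sp, su)
  expect_lt(abs(a_kde - 0.3), 0.02)
  expect_lt(abs(a_en - 0.3), 0.02)
  expect_lt(abs(a_kde - a_en), 0.02)
})

test_that("the mean-ratio cross-check tracks the density estimator on mixtures", {
  set.seed(79)
  sp <- rbeta(5000, 20, 2)
  su <- c(rbeta(1500, 20, 2), rbeta(3500, 1, 50))
  expect_lt(abs(elkan_noto_alpha(sp, su) - estimate_alpha(sp, su)), 0.1)
})

test_that("increasing planted contamination never decreases the estimate", {
  set.seed(55)
  sp <- rbeta(4000, 8, 2)
  est <- vapply(c(0.1, 0.3, 0.5), function(a) {
    su <- c(rbeta(round(a * 4000), 8, 2), rbeta(round((1 - a) * 4000), 2, 8))
    estimate_alpha(sp, su)
  }, numeric(1L))
  expect_true(all(diff(est) >= 0))
})

test_that("the mean-ratio cross-check estimator does its arithmetic", {
  expect_equal(elkan_noto_alpha(rep(0.8, 20), rep(0.24, 20)), 0.3)
  expect_equal(elkan_noto_alpha(rep(0.4, 20), rep(0.6, 20)), 1.0)
  expect_error(elkan_noto_alpha(rep(0, 20), rep(0.2, 20)), "> 0")
})

test_that("calibration hits the target mean, preserves ranks, handles edges", {
  expect_equal(suppressMessages(calibrate_probabilities(runif(50), 0)),
               rep(0, 50))
  expect_equal(suppressMessages(calibrate_probabilities(runif(50), 1)),
               rep(1, 50))
  expect_equal(calibrate_probabilities(rep(0.42, 30), 0.3), rep(0.3, 30),
               tolerance = 1e-6)
  set.seed(8)
  for (i in 1:20) {
    s <- runif(sample(20:500, 1))
    a <- runif(1, 0.01, 0.99)
    cal <- calibrate_probabilities(s, a)
    expect_lt(abs(mean(cal) - a), 1e-6)
    expect_true(all(cal >= 0 & cal <= 1))
    # nondecreasing in the raw score; strict order kept where unclipped
    o <- order(s)
    expect_true(all(diff(cal[o]) >= 0))
    unclipped <- cal[o] < 1
    expect_true(all(diff(cal[o][unclipped]) > 0 | diff(s[o][unclipped]) == 0))
  }
})

test_that("imputation takes the ceiling-count top genes with lexicographic ties", {
  ids <- sprintf("G%02d", 1:10)
  p <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  expect_setequal(impute_probable_positives(ids, p, 0.3), ids[1:3])
  # tie at the cutoff: the lexicographically smaller id wins
  p2 <- c(0.9, 0.5, 0.5, 0.5, rep(0.1, 6))
  ids2 <- c("G10", "G03", "G01", "G02", sprintf("G%02d", 4:9))
  expect_setequal(impute_probable_positives(ids2, p2, 0.2), c("G10", "G01"))
  set.seed(12)
  for (i in 1:10) {
    pr <- round(runif(40), 2)
    a <- runif(1)
    got <- impute_probable_positives(ids <- sprintf("X%02d", 1:40), pr, a)
    ord <- order(-pr, ids)
    expect_setequal(got, ids[ord[seq_len(ceiling(a * 40))]])
  }
  expect_warning(out <- impute_probable_positives("G1", 0.5, 0), "no genes")
  expect_length(out, 0L)
})

test_that("repeated PU runs aggregate, conserve calibration, and reproduce", {
  ds <- small_pu_dataset(n_pos = 60, n_unl = 120, hidden_frac = 0.3, seed = 31)
  res <- run_pu_iterations(ds, n_iterations = 3, n_folds = 4, base_seed = 9,
                           learner_config = fast_learner)
  expect_length(res$alpha$per_iteration_alphas, 3L)
  expect_true(res$alpha$ci95[1] <= res$alpha$alpha &&
              res$alpha$alpha <= res$alpha$ci95[2])
  # per-iteration calibration conservation at 1e-6
  for (i in 1:3) {
    expect_lt(abs(mean(res$scores$calibrated[i, ]) -
                  res$alpha$per_iteration_alphas[i]), 1e-6)
  }
  expect_equal(length(res$scores$imputed_positives),
               ceiling(res$alpha$alpha * 120))

  res2 <- run_pu_iterations(ds, n_iterations = 3, n_folds = 4, base_seed = 9,
                            learner_config = fast_learner)
  expect_identical(res$alpha, res2$alpha)
  expect_identical(res$scores, res2$scores)

  one <- run_pu_iterations(ds, n_iterations = 1, n_folds = 4, base_seed = 9,
                           learner_config = fast_learner)
  expect_equal(one$alpha$ci95, rep(one$alpha$alpha, 2L))
})
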