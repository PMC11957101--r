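#' Normal-approximation 95% confidence interval
#'
#' Mean plus/minus 1.96 standard errors; a single value yields the
#' degenerate interval (v, v).
#'
#' @param values Numeric vector, length >= 1.
#' @param method `"normal"` (default) or `"bootstrap"` (percentile, 2000
#'   resamples).
#' @return Numeric vector `c(low, high)`.
#' @export
ci95 <- function(values, method = c("normal", "bootstrap")) {
  if (length(values) == 0L) stop("ci95 needs at least one value")
  method <- match.arg(method)
  if (length(values) == 1L) return(c(values, values))
  if (method == "normal") {
    se <- stats::sd(values) / sqrt(length(values))
    mean(values) + c(-1.96, 1.96) * se
  } else {
    bs <- vapply(seq_len(2000L),
                 function(i) mean(sample(values, replace = TRUE)),
                 numeric(1L))
    unname(quantile(bs, c(0.025, 0.975)))
  }
}

#' Evaluation configuration
#'
#' @param n_folds Folds per cross-validation run (default 5).
#' @param n_iterations Repetitions over which the 95% CI is taken
#'   (default 40).
#' @param decision_threshold Probability above which an instance is called
#'   class 1 (default 0.5).
#' @param base_seed Base seed; iteration i uses `base_seed + i`.
#' @param learner_config Partial override of [default_learner_config()].
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(n_folds = 5L, n_iterations = 40L,
                        decision_threshold = 0.5, base_seed = 1L,
                        learner_config = list()) {
  stopifnot(n_folds >= 2L, n_iterations >= 1L,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_iterations = as.integer(n_iterations),
                 decision_threshold = decision_threshold,
                 base_seed = as.integer(base_seed),
                 learner_config = learner_config),
            class = "eval_config")
}

# simple trapezoid AUROC over score/label vectors
auroc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Shared repeated-CV engine. `train_y` are the labels the learner sees;
# recall (and precision/AUROC) are always computed against the ORIGINAL
# labeled positives, because no reliable negatives exist.
run_eval <- function(dataset, train_y, config, model_name) {
  thr <- config$decision_threshold
  lab_pos <- dataset$y == 1L
  rec <- prec <- auc <- numeric(config$n_iterations)
  for (i in seq_len(config$n_iterations)) {
    seed_i <- config$base_seed + i
    set.seed(seed_i)
    fold <- stratified_folds(train_y, config$n_folds)
    scores <- tryCatch(
      oof_predict(dataset$X, train_y, fold, config$learner_config, seed_i),
      error = function(e) {
        set.seed(seed_i + 1000003L)
        oof_predict(dataset$X, train_y, stratified_folds(train_y, config$n_folds),
                    config$learner_config, seed_i)
      }
    )
    pred1 <- scores >= thr
    rec[i] <- mean(pred1[lab_pos])
    prec[i] <- if (any(pred1)) sum(pred1 & lab_pos) / sum(pred1) else NA_real_
    auc[i] <- auroc(scores, as.integer(lab_pos))
  }
  structure(
    list(model_name = model_name,
         per_iteration_recall = rec,
         recall_mean = mean(rec), recall_ci95 = ci95(rec),
         precision_mean = mean(prec, na.rm = TRUE),
         precision_ci95 = ci95(prec[!is.na(prec)]),
         auroc_mean = mean(auc, na.rm = TRUE),
         auroc_ci95 = ci95(auc[!is.na(auc)]),
         threshold = thr),
    class = "eval_report"
  )
}

#' Baseline repeated-CV classification (all unlabeled as class 0)
#'
#' Repeated stratified k-fold cross-validation of the gradient-boosted
#' classifier with labeled positives as class 1 and every unlabeled gene
#' as class 0. Recall is the fraction of labeled positives whose
#' out-of-fold probability reaches the decision threshold, averaged over
#' iterations with a normal 95% CI.
#'
#' @param dataset A `pu_dataset`.
#' @param config An [eval_config()].
#' @return An `eval_report`.
#' @export
run_model1 <- function(dataset, config = eval_config()) {
  stopifnot(inherits(dataset, "pu_dataset"), inherits(config, "eval_config"))
  run_eval(dataset, dataset$y, config, "model1_xgboost_only")
}

#' PU-augmented repeated-CV classification
#'
#' Identical protocol to [run_model1()] except that imputed probable
#' positives join the labeled positives as class 1 during training; the
#' remaining unlabeled genes stay class 0. Recall is still computed only
#' over the originally labeled positives, so the two models are directly
#' comparable. With `imputed` empty and the same seeds the result is
#' bit-identical to [run_model1()].
#'
#' @param dataset A `pu_dataset`.
#' @param imputed Character vector of imputed gene ids (subset of the
#'   unlabeled genes).
#' @param config An [eval_config()].
#' @return An `eval_report`.
#' @export
run_model2 <- function(dataset, imputed, config = eval_config()) {
  stopifnot(inherits(dataset, "pu_dataset"), inherits(config, "eval_config"))
  unl <- dataset$row_ids[dataset$y == 0L]
  if (length(setdiff(imputed, unl))) {
    stop("imputed genes must be a subset of the unlabeled genes")
  }
  y2 <- dataset$y
  y2[dataset$row_ids %in% imputed] <- 1L
  run_eval(dataset, y2, config, "model2_xgboost_plus_pu")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: recall %.4f (95%% CI %.4f, %.4f) over %d iterations\n",
              x$model_name, x$recall_mean, x$recall_ci95[1L], x$recall_ci95[2L],
              length(x$per_iteration_recall)))
  cat(sprintf("  precision %.4f, AUROC %.4f (vs labeled positives, threshold %.2f)\n",
              x$precision_mean, x$auroc_mean, x$threshold))
  invisible(x)
}

#' Top-k report of probable disease-associated genes
#'
#' The k unlabeled genes with the highest mean calibrated probability,
#' sorted descending with lexicographic tie-break; probabilities are also
#' given rounded to 4 decimals for printing.
#'
#' @param scores A `calibrated_gene_scores` object.
#' @param k Number of genes to report (default 15).
#' @return A data.frame with columns `gene_id`,
#'   `mean_calibrated_probability`, `printed_probability`.
#' @export
top_k_report <- function(scores, k = 15L) {
  stopifnot(inherits(scores, "calibrated_gene_scores"))
  n <- length(scores$gene_ids)
  if (k > n) stop("k = ", k, " exceeds the number of unlabeled genes (", n, ")")
  ord <- order(-scores$mean_calibrated, scores$gene_ids)[seq_len(k)]
  data.frame(gene_id = scores$gene_ids[ord],
             mean_calibrated_probability = scores$mean_calibrated[ord],
             printed_probability = sprintf("%.4f", scores$mean_calibrated[ord]),
             row.names = NULL)
}
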