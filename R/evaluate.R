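# Metric suite: recall, specificity, ROC AUC, majority-class bias
# (specificity - recall) and overfit score (train recall - test recall),
# plus feature-importance analyses (impurity VIP for forests, permutation
# importance for any model).

#' Recall and specificity from binary predictions
#'
#' @param y_true Binary ground-truth vector (0/1) with both classes present.
#' @param y_pred Binary predictions of the same length.
#' @return Named list with `recall` = TP/(TP+FN) and
#'   `specificity` = TN/(TN+FP), exact rational values from counts.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred),
            all(y_true %in% c(0L, 1L)), all(y_pred %in% c(0L, 1L)))
  if (length(unique(y_true)) < 2) {
    stop("y_true contains a single class; recall/specificity undefined")
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  list(recall = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' ROC AUC by the rank (Mann-Whitney) statistic
#'
#' Equals the probability that a random positive scores above a random
#' negative, with ties counted half:
#' `P(s_pos > s_neg) + 0.5 * P(s_pos == s_neg)`.
#'
#' @param y_true Binary vector with both classes present.
#' @param scores Real-valued scores of the same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores), all(y_true %in% c(0L, 1L)))
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("y_true contains a single class; AUC undefined")
  r <- rank(scores)  # average ranks handle ties
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Majority-class bias
#'
#' Defined as specificity minus recall; large positive values mean the
#' classifier collapses toward the (negative) majority class.
#'
#' @param report An evaluation report data.frame (or any list-like with
#'   `specificity` and `recall`).
#' @return Numeric bias value(s) in `[-1, 1]`.
#' @export
majority_bias <- function(report) {
  report$specificity - report$recall
}

#' Overfit score between train and test phases
#'
#' Train recall minus test recall; negative values indicate underfitting.
#'
#' @param train_report,test_report Evaluation reports for the same flavor at
#'   phases train-cv and test.
#' @return Numeric overfit value(s) in `[-1, 1]`.
#' @export
overfit_score <- function(train_report, test_report) {
  train_report$recall - test_report$recall
}

# one evaluation-report row
evaluation_report <- function(flavor, phase, recall, specificity, auc,
                              n_pos, n_neg) {
  data.frame(flavor = flavor, phase = phase,
             recall = recall, specificity = specificity, roc_auc = auc,
             bias = specificity - recall, overfit = NA_real_,
             n_pos = n_pos, n_neg = n_neg,
             stringsAsFactors = FALSE)
}

#' Evaluate a trained model on labelled data
#'
#' @param model A `trained_flavor_model`.
#' @param X Feature matrix with the model's feature columns.
#' @param y Binary labels.
#' @param phase Label for the report row (`"test"` or `"train-cv"`).
#' @param threshold Probability threshold for the binary call.
#' @return A one-row evaluation report data.frame.
#' @export
evaluate_model <- function(model, X, y, phase = "test", threshold = 0.5) {
  probs <- predict_proba(model, X)
  cm <- confusion_metrics(y, as.integer(probs >= threshold))
  evaluation_report(model$spec$flavor, phase, cm$recall, cm$specificity,
                    roc_auc(y, probs), sum(y == 1), sum(y == 0))
}

#' Impurity-based variable importance (VIP) for forest models
#'
#' Importances are normalized to sum to 1 and ranked; only defined for the
#' random-forest algorithm.
#'
#' @param model A `trained_flavor_model` with algorithm `"random-forest"`.
#' @return An importance table: `feature`, `score`, `rank`,
#'   `method = "vip"`, sorted by rank.
#' @export
vip_importance <- function(model) {
  stopifnot(inherits(model, "trained_flavor_model"))
  if (model$spec$algorithm != "random-forest") {
    stop("VIP scores are only defined for random-forest models; ",
         "use permutation_importance() instead")
  }
  imp <- model$fit$variable.importance
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  o <- order(imp, decreasing = TRUE)
  data.frame(feature = names(imp)[o], score = unname(imp[o]),
             rank = seq_along(imp), method = "vip",
             stringsAsFactors = FALSE)
}

#' Permutation importance on held-out data
#'
#' Score of a feature = mean drop in ROC AUC over `n_repeats` random
#' shuffles of that column (clamped at 0, so scores are non-negative and a
#' constant column scores exactly 0).
#'
#' @param model A `trained_flavor_model`.
#' @param X Held-out feature matrix.
#' @param y Held-out binary labels.
#' @param n_repeats Number of shuffles per column (default 10).
#' @param seed Integer seed.
#' @return An importance table: `feature`, `score`, `rank`,
#'   `method = "permutation"`.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 10, seed = 1) {
  stopifnot(inherits(model, "trained_flavor_model"))
  baseline <- roc_auc(y, predict_proba(model, X))
  set.seed(seed)
  drops <- vapply(seq_len(ncol(X)), function(j) {
    if (length(unique(X[, j])) == 1) return(0)
    mean(vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, j] <- sample(Xp[, j])
      baseline - roc_auc(y, predict_proba(model, Xp))
    }, numeric(1)))
  }, numeric(1))
  drops <- pmax(drops, 0)
  o <- order(drops, decreasing = TRUE)
  data.frame(feature = colnames(X)[o], score = drops[o],
             rank = seq_along(drops), method = "permutation",
             stringsAsFactors = FALSE)
}
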