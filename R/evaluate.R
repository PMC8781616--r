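#' Confusion-count metrics
#'
#' Exact arithmetic on true/false positive/negative counts:
#' `accuracy = (TP + TN) / (TP + FN + FP + TN)`,
#' `sensitivity = TP / (TP + FN)` (the true-positive rate) and
#' `specificity = 1 - FP / (FP + TN)`.  A metric whose denominator is zero
#' is returned as `NA` and named in `undefined` rather than propagating
#' NaN.
#'
#' @param tp,fn,fp,tn Non-negative integer counts (total > 0).
#' @return List with `accuracy`, `sensitivity`, `specificity`,
#'   `undefined` (character vector of undefined metric names).
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be non-negative with a positive total")
  undefined <- character()
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "sensitivity"); NA_real_ }
  spec <- if (fp + tn > 0) 1 - fp / (fp + tn) else {
    undefined <- c(undefined, "specificity"); NA_real_ }
  list(accuracy = (tp + tn) / sum(counts),
       sensitivity = sens, specificity = spec, undefined = undefined)
}

#' ROC curve, AUC and Youden-optimal operating point
#'
#' Builds the ROC curve over every score threshold, computes the AUC by
#' the trapezoid rule, and reports sensitivity/specificity/accuracy at the
#' threshold maximising Youden's J (`sens + spec - 1`).
#'
#' @param scores Numeric positive-class scores, one per record.
#' @param truth Binary ground truth (logical, 0/1, or two-level factor);
#'   both classes must be present.
#' @return Object of class `"roc_result"`: list with `sensitivity`,
#'   `specificity`, `accuracy`, `auc`, `threshold`, and `curve`
#'   (data frame `fpr`, `tpr`, monotone with endpoints (0,0) and (1,1)).
#' @export
roc_auc <- function(scores, truth) {
  if (is.factor(truth)) truth <- as.integer(truth) - 1L
  truth <- as.integer(as.logical(truth))
  if (length(unique(truth)) < 2L) stop("both classes must be present")
  r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), , drop = FALSE]
  rownames(curve) <- NULL
  j <- which.max(r$sensitivities + r$specificities)
  sens <- r$sensitivities[j]; spec <- r$specificities[j]
  P <- sum(truth == 1); N <- sum(truth == 0)
  structure(list(sensitivity = sens, specificity = spec,
                 accuracy = (sens * P + spec * N) / (P + N),
                 auc = as.numeric(r$auc),
                 threshold = r$thresholds[j],
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f | sens %.3f spec %.3f acc %.3f (Youden)\n",
              x$auc, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

pattern_name <- function(a, b) {
  if (a > 0) paste0(symptom_names[a], "-", symptom_names[b])
  else paste0(symptom_names[b], "-rest")
}

#' Pairwise-pattern and one-versus-rest evaluation report
#'
#' Trains one multiclass model on `train_features` and evaluates it on
#' `test_features`: for every unordered symptom pair present (the
#' "patterns", e.g. NSR--VT) the test set is restricted to the pair's two
#' classes and scored with the renormalised pairwise class scores (the
#' second-listed, higher-ID symptom is the positive class); additionally
#' each class is evaluated one-versus-rest on the full test set.
#'
#' @param train_features,test_features Labelled [feature_table()]s sharing
#'   a label space.
#' @param config A [model_config()].
#' @param model Optional pre-trained model (skips training).
#' @return Data frame with columns `pattern`, `method`, `sensitivity`,
#'   `specificity`, `accuracy`, `auc`, `n_test`.
#' @export
evaluate_patterns <- function(train_features, test_features,
                              config = model_config(), model = NULL) {
  if (is.null(model)) model <- train_model(train_features, config)
  preds <- predict(model, test_features)
  y <- as.integer(test_features$label)
  cls <- model$classes
  score_of <- function(c) preds[[paste0("score_", c)]]
  rows <- list()
  if (length(cls) >= 2L) {
    cmb <- utils::combn(cls, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      idx <- y %in% c(a, b)
      if (!any(idx)) stop("empty pattern subset in test data: ",
                          pattern_name(a, b))
      if (length(unique(y[idx])) < 2L) next    # one-sided subset: no ROC
      s <- score_of(b)[idx] / (score_of(a)[idx] + score_of(b)[idx])
      rr <- roc_auc(s, y[idx] == b)
      rows[[length(rows) + 1L]] <-
        data.frame(pattern = pattern_name(a, b), method = config$method,
                   sensitivity = rr$sensitivity, specificity = rr$specificity,
                   accuracy = rr$accuracy, auc = rr$auc, n_test = sum(idx))
    }
  }
  for (c in cls) {
    if (length(unique(y == c)) < 2L) next
    rr <- roc_auc(score_of(c), y == c)
    rows[[length(rows) + 1L]] <-
      data.frame(pattern = pattern_name(-1L, c), method = config$method,
                 sensitivity = rr$sensitivity, specificity = rr$specificity,
                 accuracy = rr$accuracy, auc = rr$auc, n_test = length(y))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Deterministic stratified fold assignment: within each class, records are
# ordered by a stable key (their feature values), so the assignment is
# invariant to input row order under the same seed.
stratified_folds <- function(features, k, seed) {
  y <- as.integer(features$label)
  fold <- integer(length(y))
  set.seed(as.integer(seed))
  for (c in sort(unique(y))) {
    idx <- which(y == c)
    key <- do.call(order, as.list(features[idx, feature_cols, drop = FALSE]))
    ids <- rep_len(seq_len(k), length(idx))
    fold[idx[key]] <- sample(ids)
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into `k` class-stratified folds (fold sizes within each
#' class differ by at most one; assignment is reproducible under `seed`
#' and invariant to row order), trains on `k - 1` folds and evaluates the
#' pattern report on the held-out fold.
#'
#' @param features Labelled [feature_table()]; every class needs at least
#'   `k` records.
#' @param config A [model_config()].
#' @param k Number of folds (default 5, i.e. 80%/20% splits).
#' @param seed Integer seed for the fold assignment.
#' @return List with `folds` (per-fold report data frames), `summary`
#'   (mean of each metric per pattern across folds), `best_fold` (index of
#'   the fold with the highest mean AUC) and `assignment`.
#' @export
cross_validate <- function(features, config = model_config(), k = 5,
                           seed = 1) {
  if (k < 2) stop("k must be >= 2")
  y <- as.integer(features$label)
  if (any(table(y) < k)) stop("every class needs at least k records")
  fold <- stratified_folds(features, k, seed)
  reports <- lapply(seq_len(k), function(f) {
    evaluate_patterns(features[fold != f, , drop = FALSE],
                      features[fold == f, , drop = FALSE], config)
  })
  all <- do.call(rbind, Map(function(r, f) cbind(r, fold = f),
                            reports, seq_len(k)))
  summary <- stats::aggregate(
    all[c("sensitivity", "specificity", "accuracy", "auc")],
    by = list(pattern = all$pattern, method = all$method), FUN = mean)
  mean_auc <- vapply(reports, function(r) mean(r$auc), numeric(1))
  list(folds = reports, summary = summary,
       best_fold = which.max(mean_auc), assignment = fold)
}

#' Two-sample significance test of one feature between two symptoms
#'
#' Two-sided location test on the named feature between two symptom
#' groups; Welch's t-test by default, with the Mann-Whitney U test as an
#' option.  Degenerate inputs (zero variance in both groups) yield p = 1
#' when the group means are equal and p = 0 otherwise.
#'
#' @param features Labelled [feature_table()] (>= 2 records per group).
#' @param feature Feature column name, e.g. `"f1_freq"`.
#' @param class_a,class_b Symptom IDs.
#' @param method `"welch"` (default) or `"wilcoxon"`.
#' @return The p-value.
#' @export
pairwise_feature_test <- function(features, feature, class_a, class_b,
                                  method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  va <- features[features$label == class_a, feature]
  vb <- features[features$label == class_b, feature]
  if (length(va) < 2L || length(vb) < 2L)
    stop("both classes need at least 2 records")
  if (stats::sd(va) == 0 && stats::sd(vb) == 0)
    return(if (mean(va) == mean(vb)) 1 else 0)
  if (method == "welch")
    stats::t.test(va, vb, var.equal = FALSE)$p.value
  else
    stats::wilcox.test(va, vb, exact = FALSE)$p.value
}

#' Full pairwise feature significance table
#'
#' Applies [pairwise_feature_test()] to every unordered symptom pair and
#' every feature present.
#'
#' @inheritParams pairwise_feature_test
#' @return Data frame `pattern`, `feature`, `p_value`.
#' @export
feature_significance_table <- function(features,
                                       method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  cls <- sort(unique(as.integer(features$label)))
  cmb <- utils::combn(cls, 2)
  rows <- list()
  for (j in seq_len(ncol(cmb))) for (f in feature_cols) {
    rows[[length(rows) + 1L]] <- data.frame(
      pattern = pattern_name(cmb[1, j], cmb[2, j]), feature = f,
      p_value = pairwise_feature_test(features, f, cmb[1, j], cmb[2, j],
                                      method))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
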