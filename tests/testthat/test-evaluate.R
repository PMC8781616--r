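test_that("confusion metrics follow the defining arithmetic", {
  m <- confusion_metrics(tp = 9, fn = 1, fp = 2, tn = 8)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.80)
  expect_length(m$undefined, 0)

  perfect <- confusion_metrics(5, 0, 0, 5)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))

  no_pos <- confusion_metrics(0, 0, 2, 8)
  expect_true("sensitivity" %in% no_pos$undefined)
  expect_true(is.na(no_pos$sensitivity))
  expect_false(is.nan(no_pos$accuracy))
  expect_error(confusion_metrics(0, 0, 0, 0), "positive total")
})

test_that("ROC analysis matches brute-force pair counting", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  # property: AUC == concordant-pair probability on random small inputs
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(6:50, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # induces ties
    expect_equal(roc_auc(scores, truth)$auc, brute_force_auc(scores, truth),
                 tolerance = 1e-12)
  }

  # chance-level scores give AUC near one half
  set.seed(3)
  truth <- rbinom(2000, 1, 0.5)
  expect_equal(roc_auc(runif(2000), truth)$auc, 0.5, tolerance = 0.1)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("ROC curves are monotone with anchored endpoints", {
  set.seed(12)
  for (rep in 1:10) {
    scores <- runif(40); truth <- rbinom(40, 1, 0.4)
    if (length(unique(truth)) < 2) next
    cv <- roc_auc(scores, truth)$curve
    expect_true(all(diff(cv$fpr) >= -1e-12))
    expect_true(all(diff(cv$tpr) >= -1e-12))
    expect_equal(unlist(cv[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(cv[nrow(cv), ]), c(fpr = 1, tpr = 1))
  }
})

test_that("cross-validation folds are stratified, sized 80/20 and stable", {
  feats <- simulate_features(default_table1_model(), 60, seed = 30)  # 300 rows
  cv <- cross_validate(feats, model_config("nb", seed = 1), k = 5, seed = 9)
  expect_length(cv$folds, 5)
  for (f in 1:5) {
    expect_equal(sum(cv$assignment == f), 60)   # validates on 60, trains on 240
    per_class <- table(feats$label[cv$assignment == f])
    expect_true(all(abs(per_class - 12) <= 1))
  }
  # fold sizes within each class differ by <= 1
  for (s in 1:5) {
    sizes <- table(cv$assignment[feats$label == s])
    expect_lte(diff(range(sizes)), 1)
  }
  expect_error(cross_validate(feats, model_config("nb"), k = 1), "k must be")

  # shuffling row order does not change the assignment (stable keys)
  perm <- sample(nrow(feats))
  cv2 <- cross_validate(feats[perm, ], model_config("nb", seed = 1),
                        k = 5, seed = 9)
  expect_equal(cv2$assignment, cv$assignment[perm])
})

test_that("pattern evaluation emits 10 pairwise + 5 OVR reports per method", {
  feats <- simulate_features(default_table1_model(), 40, seed = 18)
  test_set <- simulate_features(default_table1_model(), 30, seed = 19)
  rep <- evaluate_patterns(feats, test_set, model_config("nb", seed = 18))
  expect_equal(nrow(rep), choose(5, 2) + 5)
  expect_equal(unique(rep$method), "nb")
  expect_true(all(c("pattern", "sensitivity", "specificity",
                    "accuracy", "auc", "n_test") %in% names(rep)))
  expect_true("NSR-VT" %in% rep$pattern && "VT-rest" %in% rep$pattern)

  # serialises to a table-shaped CSV and back
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rep, tmp, row.names = FALSE)
  back <- utils::read.csv(tmp)
  expect_equal(back$auc, rep$auc, tolerance = 1e-12)

  # train == test on a fully separable fixture: essentially perfect AUCs
  sep <- separable_features(30)
  rep2 <- evaluate_patterns(sep, sep, model_config("nb", seed = 2))
  expect_true(all(rep2$auc >= 0.99))

  # missing pattern classes in the test set are an error
  missing <- test_set[!test_set$label %in% c(4, 5), ]
  expect_error(evaluate_patterns(feats, missing, model_config("nb")),
               "empty pattern subset")
})

test_that("the pairwise feature test follows the Welch formula", {
  a <- c(1.1, 2.3, 1.9, 2.5, 1.7)
  b <- c(3.2, 4.1, 3.7, 4.4, 3.9)
  feats <- feature_table(as.data.frame(matrix(rep(c(a, b), 6), ncol = 6)),
                         rep(c(1L, 2L), each = 5))
  # hand computation: t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2),
  # Welch-Satterthwaite df
  t_stat <- (mean(a) - mean(b)) / sqrt(var(a) / 5 + var(b) / 5)
  df <- (var(a) / 5 + var(b) / 5)^2 /
    ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  p_hand <- 2 * pt(-abs(t_stat), df)
  expect_equal(pairwise_feature_test(feats, "f1_freq", 1, 2), p_hand,
               tolerance = 1e-12)

  # identical groups: no evidence at all
  same <- feature_table(as.data.frame(matrix(rep(a, 12), ncol = 6)),
                        rep(c(1L, 2L), each = 5))
  expect_equal(pairwise_feature_test(same, "f1_freq", 1, 2), 1)

  # overwhelming separation: group means 10 sd apart, n = 100 per group
  big <- separable_features(100)
  expect_lt(pairwise_feature_test(big, "f1_freq", 1, 2), 0.001)

  # full table covers every pair x feature
  tab <- feature_significance_table(
    simulate_features(default_table1_model(), 20, seed = 44))
  expect_equal(nrow(tab), 10 * 6)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})
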