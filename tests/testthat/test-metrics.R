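# Evaluation metrics against closed forms, a pairwise-ranking oracle, and
# established library implementations.

test_that("accuracy matches the confusion-count formula", {
  # TP=3 TN=5 FP=1 FN=1 -> (3+5)/10 = 0.8
  y_true <- c(rep("pos", 4), rep("neg", 6))
  y_pred <- c("pos", "pos", "pos", "neg",       # 3 TP, 1 FN
              "pos", rep("neg", 5))             # 1 FP, 5 TN
  expect_equal(accuracy(y_true, y_pred), 0.8)
  expect_equal(accuracy(y_true, y_true), 1.0)
  expect_equal(accuracy(c("a", "b"), c("b", "a")), 0.0)
  expect_error(accuracy(character(0), character(0)), "empty")
  expect_error(accuracy(c("a"), c("a", "b")), "length")
})

test_that("binary F1 matches precision/recall closed forms", {
  # TP=8 FP=2 FN=2 -> P = R = 0.8 -> F1 = 0.8
  y_true <- c(rep("pos", 10), rep("neg", 10))
  y_pred <- c(rep("pos", 8), "neg", "neg", "pos", "pos", rep("neg", 8))
  expect_equal(f1_score(y_true, y_pred, positive_label = "pos"), 0.8)
  expect_equal(f1_score(y_true, y_true, positive_label = "pos"), 1.0)
  # degenerate: no true positives found
  expect_warning(
    f0 <- f1_score(c("pos", "neg"), c("neg", "pos"), positive_label = "pos"),
    "undefined")
  expect_equal(f0, 0)
  expect_error(f1_score(y_true, y_pred, positive_label = "zzz"), "unknown")
})

test_that("macro F1 averages per-class binary F1 without weights", {
  y_true <- c("a", "a", "a", "b", "c")
  y_pred <- c("a", "a", "b", "b", "c")
  per_class <- vapply(c("a", "b", "c"),
                      function(cl) f1_score(y_true, y_pred, cl), 0)
  expect_equal(f1_score(y_true, y_pred, average = "macro"),
               mean(per_class))
})

test_that("accuracy and F1 agree with established library implementations", {
  skip_if_not_installed("caret")
  set.seed(20)
  for (rep in 1:5) {
    y_true <- factor(sample(c("pos", "neg"), 60, replace = TRUE),
                     levels = c("pos", "neg"))
    y_pred <- factor(sample(c("pos", "neg"), 60, replace = TRUE),
                     levels = c("pos", "neg"))
    expect_equal(accuracy(y_true, y_pred), mean(y_true == y_pred),
                 tolerance = 1e-12)
    f_ref <- caret::F_meas(y_pred, y_true, relevant = "pos")
    f_ours <- suppressWarnings(f1_score(y_true, y_pred, positive_label = "pos"))
    if (is.nan(f_ref)) f_ref <- 0
    expect_equal(f_ours, f_ref, tolerance = 1e-12)
  }
})

# brute-force Mann-Whitney oracle: mean over all (pos, neg) pairs of
# [score_pos > score_neg] + 0.5 [tie]
auc_oracle <- function(labels, scores) {
  sp <- scores[labels]
  sn <- scores[!labels]
  total <- 0
  for (a in sp) for (b in sn) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}

test_that("trapezoidal AUC equals the pairwise oracle exactly, ties included", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(5:120, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
    # coarse rounding forces plenty of ties
    scores <- round(stats::rnorm(n), sample(0:1, 1))
    roc <- roc_auc(labels, scores)
    expect_equal(roc$auc, auc_oracle(labels, scores), tolerance = 1e-12)
  }
})

test_that("ROC curve endpoints, monotonicity and edge cases hold", {
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  perfect <- roc_auc(labels, c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$tpr[1], 0); expect_equal(perfect$fpr[1], 0)
  expect_equal(utils::tail(perfect$tpr, 1), 1)
  expect_equal(utils::tail(perfect$fpr, 1), 1)
  expect_false(is.unsorted(perfect$tpr))
  expect_false(is.unsorted(perfect$fpr))
  allties <- roc_auc(labels, rep(0.5, 4))
  expect_equal(allties$auc, 0.5)
  expect_error(roc_auc(c(TRUE, TRUE), c(0.1, 0.2)), "both classes")
})

test_that("AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(15)
  labels <- sample(c(TRUE, FALSE), 80, replace = TRUE)
  labels[1:2] <- c(TRUE, FALSE)
  scores <- round(stats::rnorm(80), 1)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(labels, scores)$auc, ref, tolerance = 1e-12)
})

test_that("confusion matrix counts, normalizes and validates labels", {
  # true (a,a,b) vs predicted (a,b,b): one a->a, one a->b, one b->b;
  # row sums equal the per-class supports (2, 1)
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
  expect_identical(unname(cm), matrix(c(1L, 0L, 1L, 1L), 2L))
  expect_identical(unname(rowSums(cm)), c(2, 1))
  ident <- confusion_matrix(c("a", "b", "c"), c("a", "b", "c"))
  expect_identical(unname(ident), diag(1L, 3L) * 1L)
  norm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"),
                           normalize = TRUE)
  expect_equal(unname(rowSums(norm)), c(1, 1))
  expect_error(confusion_matrix(c("a", "z"), c("a", "a"), labels = c("a", "b")),
               "outside")
  # multiclass accuracy equals trace over total
  y_true <- sample(letters[1:4], 50, replace = TRUE)
  y_pred <- sample(letters[1:4], 50, replace = TRUE)
  cm4 <- confusion_matrix(y_true, y_pred)
  expect_equal(sum(diag(cm4)) / sum(cm4), accuracy(y_true, y_pred))
})

test_that("PR curve recall is monotone and average precision is sane", {
  set.seed(16)
  labels <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  labels[1:2] <- c(TRUE, FALSE)
  scores <- stats::rnorm(40)
  pr <- pr_curve(labels, scores)
  expect_false(is.unsorted(pr$recall))
  expect_true(pr$average_precision >= 0 && pr$average_precision <= 1)
  perfect <- pr_curve(labels, ifelse(labels, 1, 0))
  expect_equal(perfect$average_precision, 1)
})
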