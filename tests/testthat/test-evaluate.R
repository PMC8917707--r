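test_that("confusion matrix and accuracy match hand counts", {
  truth <- c(rep("a", 10), rep("b", 10))
  pred <- c(rep("a", 8), rep("b", 2), "a", rep("b", 9))
  cm <- confusion_and_accuracy(truth, pred, classes = c("a", "b"))
  expect_equal(cm$counts, matrix(c(8L, 1L, 2L, 9L), 2,
                                 dimnames = list(truth = c("a", "b"),
                                                 predicted = c("a", "b"))))
  expect_equal(cm$accuracy, 17 / 20)
  m <- class_metrics(cm, "a")
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$n_obs, 10)
  ident <- confusion_and_accuracy(truth, truth)
  expect_equal(ident$accuracy, 1)
  expect_equal(sum(ident$counts) - sum(diag(ident$counts)), 0)
  expect_error(confusion_and_accuracy(truth, pred[1:5]), "lengths differ")
})

test_that("metrics for an absent class are flagged NA, not coerced to 0", {
  cm <- confusion_and_accuracy(c("a", "a"), c("a", "b"), classes = c("a", "b"))
  expect_warning(m <- class_metrics(cm, "b"), "undefined")
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 0.5)
})

test_that("AUC equals the Mann-Whitney enumeration on hand cases", {
  # perfect separation
  r <- roc_and_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$variance, 0)
  # 4 pairs: psi = 1, 1, 1, 0
  r2 <- roc_and_auc(c(0.9, 0.8, 0.85, 0.7), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 3 / 4)
  # a single tied pair
  r3 <- roc_and_auc(c(0.5, 0.5), c(TRUE, FALSE))
  expect_equal(r3$auc, 0.5)
  expect_error(roc_and_auc(c(1, 2), c(TRUE, TRUE)), "both positive and negative")
})

test_that("AUC agrees exactly with brute-force enumeration on random fixtures", {
  withr::with_seed(51, {
    for (i in 1:25) {
      n <- sample(5:60, 1)
      pos <- c(TRUE, FALSE, runif(n - 2) < 0.5)
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
      r <- roc_and_auc(scores, pos)
      expect_equal(r$auc, brute_force_auc(scores, pos))
    }
  })
})

test_that("trapezoidal area under the ROC curve equals the Mann-Whitney AUC", {
  withr::with_seed(52, {
    for (i in 1:10) {
      n <- sample(10:80, 1)
      pos <- c(TRUE, FALSE, runif(n - 2) < 0.4)
      scores <- round(runif(n), 2)
      r <- roc_and_auc(scores, pos)
      cv <- r$curve
      trap <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + cv$tpr[-1]) / 2)
      expect_equal(trap, r$auc, tolerance = 1e-9)
      expect_equal(c(cv$fpr[1], cv$tpr[1]), c(0, 0))
      expect_equal(c(cv$fpr[nrow(cv)], cv$tpr[nrow(cv)]), c(1, 1))
      expect_false(is.unsorted(cv$fpr))
      expect_false(is.unsorted(cv$tpr))
    }
  })
})

test_that("DeLong variance is non-negative and invariant to row permutation", {
  withr::with_seed(53, {
    for (i in 1:10) {
      n <- 40
      pos <- c(TRUE, FALSE, runif(n - 2) < 0.5)
      scores <- runif(n)
      r <- roc_and_auc(scores, pos)
      expect_gte(r$variance, 0)
      perm <- sample(n)
      r2 <- roc_and_auc(scores[perm], pos[perm])
      expect_identical(r2$auc, r$auc)
      expect_identical(r2$variance, r$variance)
    }
  })
})

test_that("DeLong AUC variance and CI agree with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(54, {
    pos <- runif(300) < 0.4
    scores <- rnorm(300, mean = ifelse(pos, 0.8, 0.2), sd = 0.5)
    r <- roc_and_auc(scores, pos)
    proc <- pROC::roc(response = pos, predictor = scores, quiet = TRUE,
                      direction = "<")
    expect_equal(r$auc, as.numeric(pROC::auc(proc)), tolerance = 1e-12)
    expect_equal(r$variance, pROC::var(proc, method = "delong"),
                 tolerance = 1e-12)
  })
})

test_that("independent-curve z-test matches the normal-distribution oracle", {
  a1 <- list(auc = 0.9, variance = 0.03^2)
  a2 <- list(auc = 0.8, variance = 0.04^2)
  res <- delong_test_independent(a1, a2)
  expect_equal(res$z, 2.0)
  expect_equal(res$p, 2 * pnorm(-2))
  expect_equal(res$p, 0.0455, tolerance = 1e-3)
  # identical AUCs -> z = 0, p = 1
  same <- delong_test_independent(a1, a1)
  expect_equal(c(same$z, same$p), c(0, 1))
  # swapping flips the sign of z, p unchanged
  rev <- delong_test_independent(a2, a1)
  expect_equal(rev$z, -res$z)
  expect_equal(rev$p, res$p)
  # degenerate: both variances zero with unequal AUCs
  expect_warning(
    deg <- delong_test_independent(list(auc = 0.9, variance = 0),
                                   list(auc = 0.8, variance = 0)),
    "zero pooled variance")
  expect_equal(deg$p, 0)
})

test_that("paired test is null on self-comparison and matches pROC", {
  withr::with_seed(55, {
    pos <- c(rep(TRUE, 30), rep(FALSE, 50))
    sa <- rnorm(80, ifelse(pos, 0.7, 0.3), 0.4)
    sb <- 0.6 * sa + rnorm(80, ifelse(pos, 0.2, 0.1), 0.4)
    self <- delong_test_paired(sa, sa, pos)
    expect_equal(c(self$z, self$p), c(0, 1))
    res <- delong_test_paired(sa, sb, pos)
    skip_if_not_installed("pROC")
    ra <- pROC::roc(pos, sa, quiet = TRUE, direction = "<")
    rb <- pROC::roc(pos, sb, quiet = TRUE, direction = "<")
    pt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(res$z, as.numeric(pt$statistic), tolerance = 1e-9)
    expect_equal(res$p, as.numeric(pt$p.value), tolerance = 1e-9)
  })
})

test_that("complementary scores give the complementary AUC", {
  withr::with_seed(56, {
    pos <- c(rep(TRUE, 3), rep(FALSE, 3))
    sa <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
    ra <- roc_and_auc(sa, pos)
    rb <- roc_and_auc(1 - sa, pos)
    expect_equal(rb$auc, 1 - ra$auc)
  })
})

test_that("evaluate_model assembles a coherent per-class report", {
  sess <- small_study(seed = 10)
  ds <- build_dataset(sess$recording, sess$tags)
  ds$label <- collapse_labels(ds$label, "three")
  sp <- split_dataset(ds, seed = 10)
  fit <- train_forest(sp$train, forest_params(n_trees = 200, seed = 10),
                      classes = scheme_classes("three"))
  pr <- predict(fit, sp$validation)
  rep <- evaluate_model(sp$validation$label, pr$predicted, pr$scores,
                        classes = fit$classes)
  expect_equal(nrow(rep$metrics), 3)
  expect_equal(sum(rep$metrics$n_obs), nrow(sp$validation))
  expect_equal(rep$accuracy, rep$correct / rep$total)
  expect_true(all(rep$metrics$ci_low <= rep$metrics$auc, na.rm = TRUE))
  expect_true(all(rep$metrics$auc <= rep$metrics$ci_high, na.rm = TRUE))
})

test_that("a noiseless study is perfectly classified with unit AUCs", {
  sess <- small_study(seed = 12, cfg = quiet_cfg(seed = 12))
  ds <- build_dataset(sess$recording, sess$tags)
  ds$label <- collapse_labels(ds$label, "three")
  sp <- split_dataset(ds, seed = 12, stratified = TRUE)
  fit <- train_forest(sp$train, forest_params(n_trees = 300, seed = 12),
                      classes = scheme_classes("three"))
  pr <- predict(fit, sp$validation)
  rep <- evaluate_model(sp$validation$label, pr$predicted, pr$scores,
                        classes = fit$classes)
  expect_equal(rep$accuracy, 1)
  expect_true(all(rep$metrics$auc == 1))
  # training rows classify to their own label
  pr_train <- predict(fit, sp$train)
  expect_equal(as.character(pr_train$predicted), as.character(sp$train$label))
})

test_that("collapsed-scheme metrics equal metrics on the collapsed matrix", {
  withr::with_seed(57, {
    truth <- sample(motion_labels(), 120, replace = TRUE)
    pred <- ifelse(runif(120) < 0.7, truth, sample(motion_labels(), 120, TRUE))
    t3 <- collapse_labels(truth, "three")
    p3 <- collapse_labels(pred, "three")
    cm3 <- confusion_and_accuracy(t3, p3, classes = scheme_classes("three"))
    # collapse the five-class confusion matrix directly and compare
    cm5 <- confusion_and_accuracy(truth, pred, classes = scheme_classes("five"))
    grp <- as.character(collapse_labels(scheme_classes("five"), "three"))
    coll <- rowsum(t(rowsum(cm5$counts, grp)), grp)
    for (cl in scheme_classes("three")) {
      m_direct <- class_metrics(cm3, cl)
      tp <- coll[cl, cl]; fn <- sum(coll[, cl]) - tp  # coll is transposed: [pred, truth]
      fp <- sum(coll[cl, ]) - tp; tn <- sum(coll) - tp - fn - fp
      expect_equal(m_direct$sensitivity, tp / (tp + fn))
      expect_equal(m_direct$specificity, tn / (tn + fp))
    }
  })
})
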