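# Performance surface: confusion matrices, one-vs-rest sensitivity and
# specificity, ROC curves, and DeLong's nonparametric AUC variance estimator
# (structural components), including the paired-covariance form for
# comparing two curves scored on the same rows and the independent-sample
# z-test for curves from disjoint subjects.

#' Confusion matrix and overall accuracy
#'
#' @param truth True labels (factor or character).
#' @param predicted Predicted labels, same length.
#' @param classes Ordered vocabulary; defaults to the union of factor levels.
#' @return List of class \code{net_confusion}: \code{classes}, \code{counts}
#'   (true x predicted matrix), \code{correct}, \code{total},
#'   \code{accuracy} (= trace/total).
#' @export
confusion_and_accuracy <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted))
    stop("confusion_and_accuracy: truth and predicted lengths differ", call. = FALSE)
  if (is.null(classes))
    classes <- union(levels(factor(truth)), levels(factor(predicted)))
  truth <- factor(as.character(truth), levels = classes)
  predicted <- factor(as.character(predicted), levels = classes)
  if (anyNA(truth) || anyNA(predicted))
    stop("confusion_and_accuracy: labels outside the class vocabulary", call. = FALSE)
  counts <- table(truth = truth, predicted = predicted)
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  correct <- sum(diag(counts))
  total <- sum(counts)
  structure(list(classes = classes, counts = counts, correct = correct,
                 total = total, accuracy = correct / total),
            class = "net_confusion")
}

#' @export
print.net_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (%d classes, %d observations)\n",
              length(x$classes), x$total))
  print(x$counts)
  cat(sprintf("Overall accuracy: %d/%d (%.1f%%)\n",
              x$correct, x$total, 100 * x$accuracy))
  invisible(x)
}

#' One-vs-rest sensitivity and specificity for one class
#'
#' Reduces the multiclass confusion matrix to the binary problem
#' class-vs-rest. A metric with a zero denominator (no true positives or no
#' true negatives in the data) is undefined and reported as \code{NA} with a
#' warning, never coerced to 0.
#'
#' @param cm A \code{net_confusion}.
#' @param class Class label.
#' @return List: \code{class}, \code{n_obs} (true count),
#'   \code{sensitivity} = TP/(TP+FN), \code{specificity} = TN/(TN+FP).
#' @export
class_metrics <- function(cm, class) {
  if (!class %in% cm$classes)
    stop("class_metrics: class '", class, "' not in vocabulary", call. = FALSE)
  k <- cm$counts
  tp <- k[class, class]
  fn <- sum(k[class, ]) - tp
  fp <- sum(k[, class]) - tp
  tn <- sum(k) - tp - fn - fp
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (is.na(sens))
    warning("class_metrics: sensitivity undefined for '", class,
            "' (no true instances)", call. = FALSE)
  if (is.na(spec))
    warning("class_metrics: specificity undefined for '", class,
            "' (no true negatives)", call. = FALSE)
  list(class = class, n_obs = tp + fn, sensitivity = sens, specificity = spec)
}

# DeLong structural components for one score vector. psi(X, Y) scores each
# (positive, negative) pair 1 / 0.5 / 0 as the positive's score is above /
# tied with / below the negative's; the AUC is the mean over all pairs
# (the Mann-Whitney statistic), V10 the per-positive row means, V01 the
# per-negative column means.
auc_components <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  m <- length(pos)
  n <- length(neg)
  if (m == 0 || n == 0)
    stop("roc_and_auc: need both positive and negative instances", call. = FALSE)
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi), m = m, n = n)
}

var0 <- function(x) if (length(x) < 2) 0 else var(x)

as_binary_truth <- function(truth, positive_class = NULL) {
  if (is.logical(truth)) return(truth)
  if (is.numeric(truth) && all(truth %in% c(0, 1))) return(truth == 1)
  if (is.null(positive_class))
    stop("roc_and_auc: give logical/0-1 truth, or supply positive_class",
         call. = FALSE)
  as.character(truth) == positive_class
}

#' One-vs-rest ROC curve with DeLong AUC inference
#'
#' The AUC is the Mann-Whitney statistic (ties count one half); its variance
#' is DeLong's estimator \eqn{S_{10}/m + S_{01}/n}, the sample variances of
#' the per-positive and per-negative structural components over the m
#' positives and n negatives. The 95\% CI is Wald on the AUC scale,
#' truncated to [0, 1]. The curve is built over all distinct score
#' thresholds, so its trapezoidal area equals the Mann-Whitney AUC.
#'
#' @param scores Numeric score for the positive class, one per row.
#' @param truth Logical (or 0/1) positive indicator, or labels combined with
#'   \code{positive_class}.
#' @param positive_class Label treated as positive when \code{truth} is a
#'   label vector.
#' @return Object of class \code{net_roc}: \code{curve} (data frame
#'   threshold/fpr/tpr from (0,0) to (1,1)), \code{auc}, \code{variance},
#'   \code{ci_low}, \code{ci_high}, and the structural components.
#' @export
roc_and_auc <- function(scores, truth, positive_class = NULL) {
  pos <- as_binary_truth(truth, positive_class)
  stopifnot(length(scores) == length(pos))
  comp <- auc_components(scores, pos)
  variance <- var0(comp$v10) / comp$m + var0(comp$v01) / comp$n
  half <- 1.96 * sqrt(variance)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(curve = curve, auc = comp$auc, variance = variance,
                 ci_low = max(0, comp$auc - half),
                 ci_high = min(1, comp$auc + half),
                 v10 = comp$v10, v01 = comp$v01, m = comp$m, n = comp$n),
            class = "net_roc")
}

#' @export
print.net_roc <- function(x, ...) {
  cat(sprintf("AUC %.4f (95%% CI %.4f-%.4f), DeLong variance %.3g, m=%d n=%d\n",
              x$auc, x$ci_low, x$ci_high, x$variance, x$m, x$n))
  invisible(x)
}

auc_and_var <- function(a) {
  if (inherits(a, "net_roc")) return(list(auc = a$auc, variance = a$variance))
  if (is.list(a) && all(c("auc", "variance") %in% names(a)))
    return(list(auc = a$auc, variance = a$variance))
  stop("expected a net_roc object or a list with auc and variance", call. = FALSE)
}

delong_z_p <- function(diff, vard) {
  if (vard <= 0) {
    if (diff == 0) return(list(z = 0, p = 1))
    warning("DeLong test: zero pooled variance with unequal AUCs; p = 0",
            call. = FALSE)
    return(list(z = sign(diff) * Inf, p = 0))
  }
  z <- diff / sqrt(vard)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' DeLong z-test for two independent ROC curves
#'
#' For curves estimated on disjoint samples (e.g. adults-only vs
#' children-only models) the AUC difference is normalized by the sum of the
#' two DeLong variances: z = (auc1 - auc2) / sqrt(var1 + var2), two-sided
#' normal p-value.
#'
#' @param a1,a2 \code{net_roc} objects (or lists with \code{auc} and
#'   \code{variance}).
#' @return List: \code{z}, \code{p}, \code{auc_diff}.
#' @export
delong_test_independent <- function(a1, a2) {
  e1 <- auc_and_var(a1)
  e2 <- auc_and_var(a2)
  if (e1$variance < 0 || e2$variance < 0)
    stop("delong_test_independent: negative variance", call. = FALSE)
  d <- e1$auc - e2$auc
  res <- delong_z_p(d, e1$variance + e2$variance)
  list(z = res$z, p = res$p, auc_diff = d)
}

#' DeLong test for two correlated ROC curves
#'
#' For two score sets on the same rows (paired design), the variance of the
#' AUC difference subtracts twice the covariance of the paired structural
#' components: var(d) = (S10a + S10b - 2 S10ab)/m + (S01a + S01b - 2 S01ab)/n.
#'
#' @param scores_a,scores_b Two score vectors on the same rows.
#' @param truth Positive indicator (shared), as in \code{\link{roc_and_auc}}.
#' @param positive_class As in \code{\link{roc_and_auc}}.
#' @return List: \code{z}, \code{p}, \code{auc_a}, \code{auc_b},
#'   \code{auc_diff}, \code{var_diff}.
#' @export
delong_test_paired <- function(scores_a, scores_b, truth, positive_class = NULL) {
  pos <- as_binary_truth(truth, positive_class)
  stopifnot(length(scores_a) == length(pos), length(scores_b) == length(pos))
  ca <- auc_components(scores_a, pos)
  cb <- auc_components(scores_b, pos)
  cov10 <- if (ca$m < 2) 0 else cov(ca$v10, cb$v10)
  cov01 <- if (ca$n < 2) 0 else cov(ca$v01, cb$v01)
  vard <- (var0(ca$v10) + var0(cb$v10) - 2 * cov10) / ca$m +
          (var0(ca$v01) + var0(cb$v01) - 2 * cov01) / ca$n
  vard <- max(vard, 0)  # guard against negative rounding of a ~0 variance
  d <- ca$auc - cb$auc
  res <- delong_z_p(d, vard)
  list(z = res$z, p = res$p, auc_a = ca$auc, auc_b = cb$auc,
       auc_diff = d, var_diff = vard)
}

#' Full evaluation report for one model
#'
#' Assembles the confusion matrix, overall accuracy, and per-class
#' one-vs-rest sensitivity, specificity and DeLong AUC with 95\% CI, scored
#' on the vote fractions.
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param scores Rows x classes matrix of per-class scores (vote fractions);
#'   column names must cover the vocabulary.
#' @param classes Ordered vocabulary; defaults to score column names.
#' @return Object of class \code{eval_report}: \code{confusion},
#'   \code{accuracy}, \code{correct}, \code{total}, \code{metrics} (one row
#'   per class: n_obs, sensitivity, specificity, auc, ci_low, ci_high),
#'   \code{rocs} (named list of \code{net_roc}).
#' @export
evaluate_model <- function(truth, predicted, scores, classes = NULL) {
  if (is.null(classes)) classes <- colnames(scores)
  cm <- confusion_and_accuracy(truth, predicted, classes = classes)
  truth_chr <- as.character(truth)
  rocs <- list()
  rows <- lapply(classes, function(cl) {
    met <- class_metrics(cm, cl)
    pos <- truth_chr == cl
    if (any(pos) && any(!pos)) {
      roc <- roc_and_auc(scores[, cl], pos)
      rocs[[cl]] <<- roc
      data.frame(class = cl, n_obs = met$n_obs, sensitivity = met$sensitivity,
                 specificity = met$specificity, auc = roc$auc,
                 ci_low = roc$ci_low, ci_high = roc$ci_high,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(class = cl, n_obs = met$n_obs, sensitivity = met$sensitivity,
                 specificity = met$specificity, auc = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, stringsAsFactors = FALSE)
    }
  })
  structure(list(confusion = cm, accuracy = cm$accuracy, correct = cm$correct,
                 total = cm$total, metrics = do.call(rbind, rows), rocs = rocs),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  print(x$confusion)
  cat("\nPer-class one-vs-rest metrics:\n")
  m <- x$metrics
  m$auc_ci <- ifelse(is.na(m$auc), "-",
                     sprintf(paste0("%.", digits, "f (%.", digits, "f-%.",
                                    digits, "f)"), m$auc, m$ci_low, m$ci_high))
  print(m[, c("class", "n_obs", "sensitivity", "specificity", "auc_ci")],
        row.names = FALSE, digits = digits)
  invisible(x)
}
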