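# Random-forest harness: seeded 80/20 splitting, training with the study's
# hyperparameters (1000 trees, mtry 4 ~ sqrt(10 features)), vote-fraction
# scores, and feature-importance ranking.

#' Forest hyperparameters
#'
#' @param n_trees Number of trees (default 1000).
#' @param mtry Candidate variables per split (default 4).
#' @param importance_type "gini" (mean decrease in node impurity, default) or
#'   "accuracy" (mean decrease in permutation accuracy).
#' @param seed Integer seed for tree growing.
#' @return List of class \code{forest_params}.
#' @export
forest_params <- function(n_trees = 1000, mtry = 4,
                          importance_type = c("gini", "accuracy"), seed = 1L) {
  importance_type <- match.arg(importance_type)
  if (n_trees < 1) stop("forest_params: n_trees must be >= 1", call. = FALSE)
  if (mtry < 1) stop("forest_params: mtry must be >= 1", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 importance_type = importance_type, seed = as.integer(seed)),
            class = "forest_params")
}

#' Seeded train/validation split
#'
#' Uniform sampling without replacement; the training partition takes
#' \code{floor(train_fraction * N)} rows and validation the remainder
#' (2506 rows at 0.8 split as 2004/502). With \code{stratified = TRUE} the
#' floor is applied per label class.
#'
#' @param table Observation table with a \code{label} column.
#' @param train_fraction Proportion in (0, 1).
#' @param seed Integer seed.
#' @param stratified Stratify the split by label?
#' @return List with elements \code{train} and \code{validation}.
#' @export
split_dataset <- function(table, train_fraction = 0.8, seed = 1L,
                          stratified = FALSE) {
  n <- nrow(table)
  if (n < 2) stop("split_dataset: need at least 2 rows", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("split_dataset: train_fraction must be in (0, 1)", call. = FALSE)
  idx <- with_seed(seed, {
    if (stratified) {
      unlist(lapply(split(seq_len(n), table$label, drop = TRUE), function(ix)
        sample(ix, floor(train_fraction * length(ix)))), use.names = FALSE)
    } else {
      sample(n, floor(train_fraction * n))
    }
  })
  if (length(idx) == 0 || length(idx) == n)
    stop("split_dataset: split would leave an empty partition", call. = FALSE)
  list(train = table[sort(idx), , drop = FALSE],
       validation = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

dataset_features <- function(table) {
  setdiff(names(table), c("label", "subject_class", "subject_id"))
}

#' Train the random-forest classifier
#'
#' Grows \code{n_trees} classification trees, each on a bootstrap resample
#' with \code{mtry} candidate features per split, via the randomForest
#' package. Reproducible given \code{params$seed}.
#'
#' @param train Observation table (feature columns + \code{label}).
#' @param params A \code{\link{forest_params}}.
#' @param classes Optional ordered output vocabulary; defaults to the levels
#'   of \code{train$label}.
#' @return Object of class \code{net_forest}: the fitted ensemble plus the
#'   feature names and ordered class vocabulary.
#' @export
train_forest <- function(train, params = forest_params(), classes = NULL) {
  feats <- dataset_features(train)
  if (params$mtry > length(feats))
    stop("train_forest: mtry (", params$mtry, ") exceeds feature count (",
         length(feats), ")", call. = FALSE)
  y <- train$label
  if (is.null(classes)) classes <- levels(factor(y))
  y <- factor(as.character(y), levels = classes)
  y <- droplevels(y)
  if (nlevels(y) < 2)
    stop("train_forest: training data contain a single class", call. = FALSE)
  classes <- levels(y)
  x <- train[, feats, drop = FALSE]
  fit <- with_seed(params$seed,
    randomForest::randomForest(x = x, y = y, ntree = params$n_trees,
                               mtry = params$mtry, importance = TRUE))
  structure(list(model = fit, classes = classes, feature_names = feats,
                 params = params),
            class = "net_forest")
}

#' Predict labels and vote-fraction scores
#'
#' Per-class scores are the fraction of trees voting for that class (each
#' row's scores sum to 1); the predicted label is the argmax, ties broken by
#' the fixed class order.
#'
#' @param object A \code{net_forest}.
#' @param newdata Observation table with the model's feature columns.
#' @param ... Unused.
#' @return List with \code{predicted} (factor over the model's classes) and
#'   \code{scores} (rows x classes matrix of vote fractions).
#' @export
predict.net_forest <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing))
    stop("predict.net_forest: newdata lacks feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(newdata) == 0) {
    sc <- matrix(numeric(0), ncol = length(object$classes),
                 dimnames = list(NULL, object$classes))
    return(list(predicted = factor(character(0), levels = object$classes),
                scores = sc))
  }
  votes <- predict(object$model, newdata[, object$feature_names, drop = FALSE],
                   type = "vote", norm.votes = TRUE)
  votes <- votes[, object$classes, drop = FALSE]
  votes <- votes / rowSums(votes)
  pick <- apply(votes, 1, which.max)  # which.max: first max = class-order tie-break
  list(predicted = factor(object$classes[pick], levels = object$classes),
       scores = votes)
}

#' Feature-importance ranking
#'
#' Features ordered by decreasing importance (mean decrease in Gini impurity
#' by default, or mean decrease in permutation accuracy); ties broken by
#' feature order.
#'
#' @param fit A \code{net_forest}.
#' @param type Importance measure; defaults to the one in the fit's params.
#' @return Data frame with columns \code{feature} and \code{importance},
#'   sorted descending.
#' @export
importance_ranking <- function(fit, type = NULL) {
  if (is.null(type)) type <- fit$params$importance_type
  type <- match.arg(type, c("gini", "accuracy"))
  imp <- randomForest::importance(fit$model,
                                  type = if (type == "gini") 2 else 1)
  vals <- imp[fit$feature_names, 1]
  ord <- order(-vals, seq_along(vals))
  data.frame(feature = fit$feature_names[ord], importance = unname(vals[ord]),
             stringsAsFactors = FALSE)
}
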