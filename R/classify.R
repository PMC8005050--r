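#' Random-Forest configuration
#'
#' Hyperparameters for the ensemble: number of trees (default 500),
#' predictors tried per split (default `floor(sqrt(p))`, the classification
#' default of the randomForest package) and the base seed that makes every
#' validation fold reproducible.
#'
#' @param n_trees number of trees.
#' @param mtry predictors per split, or `NULL` for `floor(sqrt(p))`.
#' @param seed integer base seed.
#' @return object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500, mtry = NULL, seed = 1) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed)),
            class = "rf_config")
}

# Split a feature table into the predictor matrix and the label factor.
feature_matrix <- function(features) {
  cols <- setdiff(names(features), c("individual", "burst_id", "label"))
  as.matrix(features[, cols, drop = FALSE])
}

#' Train a Random Forest on a feature table
#'
#' An ensemble of decision trees whose prediction is the plurality vote over
#' trees; deterministic under the configured seed. Sentinel feature values
#' (e.g. the zero-variance ICV sentinel) are ordinary numbers that trees
#' split on naturally.
#'
#' @param features feature table from [feature_table()] (columns
#'   `individual`, `burst_id`, `label` plus predictors), or a plain predictor
#'   matrix if `labels` is given.
#' @param labels optional label vector overriding `features$label`.
#' @param config an [rf_config()].
#' @return a fitted `randomForest` model.
#' @export
train_rf <- function(features, labels = NULL, config = rf_config()) {
  if (is.null(labels)) labels <- features$label
  x <- if (is.data.frame(features)) feature_matrix(features) else features
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2)
    stop("training data must contain at least 2 behavior classes")
  mtry <- if (is.null(config$mtry)) max(1, floor(sqrt(ncol(x)))) else config$mtry
  set.seed(config$seed)
  randomForest::randomForest(x = x, y = y, ntree = config$n_trees, mtry = mtry)
}

#' Leave-one-burst-out cross-validation
#'
#' N folds for N bursts: fold i trains on the other N-1 rows and predicts
#' row i, so every row is used N-1 times for training and exactly once for
#' testing. Fold i is fitted with seed `base_seed + i`, which makes the
#' prediction for a given burst independent of row order.
#'
#' @param features feature table with `label` (and `burst_id`) columns.
#' @param config an [rf_config()]; its seed is the base seed.
#' @return data frame `(individual, burst_id, true, predicted, design)` with
#'   one row per burst.
#' @export
leave_one_out <- function(features, config = rf_config()) {
  n <- nrow(features)
  if (n < 2) stop("leave-one-out needs at least 2 bursts")
  # rows are processed in burst_id order so fold seeds (and the bootstrap
  # draws inside each fold) attach to burst identity, not to row order
  features <- features[order(features$burst_id), , drop = FALSE]
  x <- feature_matrix(features)
  y <- factor(features$label)
  pred <- character(n)
  for (i in seq_len(n)) {
    cfg <- rf_config(config$n_trees, config$mtry, config$seed + i)
    fit <- train_rf(x[-i, , drop = FALSE], labels = y[-i], config = cfg)
    pred[i] <- as.character(stats::predict(fit, x[i, , drop = FALSE]))
  }
  data.frame(individual = features$individual, burst_id = features$burst_id,
             true = as.character(y), predicted = pred, design = "loo",
             stringsAsFactors = FALSE)
}

#' Leave-one-individual-out validation
#'
#' Trains one model on the pooled bursts of every individual except
#' `test_individual` and predicts all of the test individual's bursts — the
#' deployment-relevant design, mimicking classification of an unobserved
#' animal from models trained on observed ones. Test categories absent from
#' the training pool are flagged `untrainable`: the model cannot emit them,
#' so they can never be predicted correctly.
#'
#' @param features pooled feature table covering several individuals.
#' @param test_individual the withheld individual.
#' @param config an [rf_config()].
#' @return data frame `(individual, burst_id, true, predicted, design,
#'   untrainable)` for the test individual's bursts.
#' @export
cross_individual <- function(features, test_individual, config = rf_config()) {
  test <- features$individual == test_individual
  if (!any(test)) stop("no bursts for test individual ", test_individual)
  if (all(test)) stop("no training individuals distinct from ", test_individual)
  train_labels <- unique(features$label[!test])
  test_labels <- unique(features$label[test])
  if (!length(intersect(train_labels, test_labels)))
    stop("training and test label sets do not overlap")
  fit <- train_rf(features[!test, , drop = FALSE], config = config)
  pred <- stats::predict(fit, feature_matrix(features[test, , drop = FALSE]))
  data.frame(individual = test_individual,
             burst_id = features$burst_id[test],
             true = features$label[test],
             predicted = as.character(pred),
             design = "cross_individual",
             untrainable = !(features$label[test] %in% train_labels),
             stringsAsFactors = FALSE)
}
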