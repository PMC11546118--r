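#' Random-forest hyperparameters
#'
#' Capacity-limited defaults used throughout the pipeline: 50 trees, depth
#' capped at 3, and a weighted minimum of 30 samples per leaf -- a
#' deliberately small-capacity ensemble intended for biomarker ranking
#' rather than maximal predictive power, with no further hyperparameter
#' optimisation.  Rows are weighted inversely to class size, weights are
#' rescaled per tree so the total equals the number of training rows, and
#' the leaf-occupancy threshold applies to these weighted counts.
#'
#' @param n_trees number of trees.
#' @param max_depth maximum split depth.
#' @param min_samples_leaf minimum weighted occupancy of every leaf.
#' @param features_per_split `"sqrt"` (ceiling of the square root of the
#'   feature count) or an explicit integer.
#' @param bootstrap_rows bootstrap-resample rows per tree.
#' @param seed forest seed (per-tree seeds are derived from it).
#' @return An object of class `ff_forest_params`.
#' @export
forest_params <- function(n_trees = 50, max_depth = 3, min_samples_leaf = 30,
                          features_per_split = "sqrt", bootstrap_rows = TRUE,
                          seed = 1) {
  if (n_trees < 1 || max_depth < 1 || min_samples_leaf < 1) {
    stop_domain("n_trees, max_depth and min_samples_leaf must all be >= 1")
  }
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 min_samples_leaf = as.numeric(min_samples_leaf),
                 features_per_split = features_per_split,
                 bootstrap_rows = isTRUE(bootstrap_rows),
                 seed = as.numeric(seed)),
            class = "ff_forest_params")
}

resolve_mtry <- function(features_per_split, p) {
  if (identical(features_per_split, "sqrt")) {
    as.integer(ceiling(sqrt(p)))
  } else {
    m <- as.integer(features_per_split)
    if (is.na(m) || m < 1) stop_domain("features_per_split must be 'sqrt' or >= 1")
    min(m, p)
  }
}

as_class_factor <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop_domain("y must have exactly two classes")
    y
  } else {
    lev <- sort(unique(as.character(y)))
    if (length(lev) > 2) stop_domain("y must have exactly two classes")
    if (length(lev) == 1) lev <- c(lev, paste0(lev, "_other"))
    factor(as.character(y), levels = lev)
  }
}

#' Train a class-weighted random forest
#'
#' Trees split on weighted Gini impurity, are limited to `max_depth`
#' levels, and keep a weighted minimum of `min_samples_leaf` per leaf.
#' Each tree sees a bootstrap resample of the rows and `ceiling(sqrt(p))`
#' candidate features per split.  Equal-gain splits are resolved toward the
#' lowest feature index, then the lowest threshold, so training is fully
#' deterministic under the seed.
#'
#' @param X numeric matrix, rows = samples, columns = features.
#' @param y two-class labels aligned with rows.
#' @param weights per-row sample weights; defaults to
#'   [class_weights()] of `y`.
#' @param params an [forest_params()] object.
#' @return An object of class `ff_forest` with stored tree structures
#'   (node tables) and accumulated Gini importances.
#' @export
train_forest <- function(X, y, weights = NULL, params = forest_params()) {
  X <- as.matrix(X)
  y <- as_class_factor(y)
  if (nrow(X) != length(y)) stop_domain("X and y are misaligned")
  if (is.null(weights)) weights <- class_weights(y)
  if (length(weights) != length(y)) stop_domain("weights misaligned with y")
  mtry <- resolve_mtry(params$features_per_split, ncol(X))
  fit <- cpp_build_forest(X, as.integer(y) - 1L, as.numeric(weights),
                          params$n_trees, params$max_depth,
                          params$min_samples_leaf, mtry,
                          params$bootstrap_rows, derive_seed(params$seed))
  structure(list(trees = fit$trees,
                 importance = as.numeric(fit$importance),
                 classes = levels(y),
                 features = colnames(X) %||% paste0("V", seq_len(ncol(X))),
                 mtry = mtry,
                 params = params),
            class = "ff_forest")
}

#' Predict with a trained forest
#'
#' Class probability is the mean of per-tree weighted leaf class
#' frequencies; the predicted class is the probability argmax (an exact
#' 0.5 tie resolves to the first class level, deterministically).
#'
#' @param object an `ff_forest`.
#' @param newdata numeric matrix with the training feature columns.
#' @param type `"class"` or `"prob"` (probability of the second class
#'   level).
#' @param ... unused.
#' @export
predict.ff_forest <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$features)) {
    stop_domain("newdata has ", ncol(newdata), " columns; forest expects ",
                length(object$features))
  }
  prob <- cpp_predict_forest(object$trees, newdata)
  if (type == "prob") return(prob)
  factor(object$classes[ifelse(prob > 0.5, 2L, 1L)], levels = object$classes)
}

#' Mean-decrease-in-impurity feature importances
#'
#' For every split node the weighted impurity decrease
#' `W * I(parent) - W_L * I(left) - W_R * I(right)` (normalised by the root
#' weight) is credited to the split feature; per-tree sums are averaged
#' over the forest and rescaled to sum to one whenever any split exists.
#' A forest with no splits returns all-zero importances.
#'
#' @param model an `ff_forest`.
#' @return Named nonnegative numeric vector summing to 1 (or all zeros).
#' @export
mdi_importances <- function(model) {
  imp <- model$importance
  s <- sum(imp)
  if (s > 0) imp <- imp / s
  setNames(imp, model$features)
}

#' Audit stored trees against the capacity constraints
#'
#' Re-traverses every stored node table and reports, per tree, the maximum
#' split depth and the minimum weighted leaf occupancy, so tests can verify
#' post hoc that `max_depth` and `min_samples_leaf` were honoured.
#'
#' @param model an `ff_forest`.
#' @return data.frame with columns `tree`, `max_depth`, `min_leaf_weight`,
#'   `n_nodes`.
#' @export
audit_forest <- function(model) {
  rows <- lapply(seq_along(model$trees), function(t) {
    tr <- model$trees[[t]]
    leaf <- tr[, "feature"] == 0
    data.frame(tree = t,
               max_depth = max(tr[, "depth"]),
               min_leaf_weight = min(tr[leaf, "w0"] + tr[leaf, "w1"]),
               n_nodes = nrow(tr))
  })
  do.call(rbind, rows)
}

#' @export
print.ff_forest <- function(x, ...) {
  cat("ff_forest: ", length(x$trees), " trees, ", length(x$features),
      " features (mtry ", x$mtry, "), classes ",
      paste(x$classes, collapse = "/"), "\n", sep = "")
  invisible(x)
}
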