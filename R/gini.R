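#' Gini impurity of a weighted two-class distribution
#'
#' Computes `sum_class p_class * (1 - p_class)` where `p_class` is the
#' weighted relative frequency of each class in the set.  For two classes
#' the impurity lies in `[0, 0.5]`: 0 for a pure set, 0.5 at balance, and
#' it is invariant under swapping the class labels.
#'
#' @param dist named numeric vector of nonnegative per-class total weights
#'   (e.g. `c(pcos = 5, control = 5)`).
#' @return Impurity in `[0, 0.5]` for two classes.
#' @export
#' @examples
#' gini_impurity(c(pcos = 10, control = 0))  # 0
#' gini_impurity(c(pcos = 5, control = 5))   # 0.5
#' gini_impurity(c(pcos = 1, control = 3))   # 0.375
gini_impurity <- function(dist) {
  if (!is.numeric(dist) || length(dist) < 1) {
    stop_domain("dist must be a numeric vector of class weights")
  }
  if (any(dist < 0)) stop_domain("class weights must be nonnegative")
  tot <- sum(dist)
  if (tot <= 0) stop_domain("total class weight must be positive")
  p <- dist / tot
  sum(p * (1 - p))
}

#' Inverse-class-size sample weights
#'
#' Each row receives weight `1 / n_class(row)`, so both classes contribute
#' equal total weight regardless of imbalance (the total weight of each
#' class is exactly 1 before any rescaling).
#'
#' @param labels vector (character or factor) of class labels; both classes
#'   must be present.
#' @return Numeric vector of per-row weights aligned with `labels`.
#' @export
#' @examples
#' class_weights(rep(c("pcos", "control"), c(1, 4)))
class_weights <- function(labels) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) {
    stop_domain("both classes must be present to compute class weights")
  }
  unname(1 / as.numeric(tab[labels]))
}

#' Balanced accuracy
#'
#' Mean of per-class recalls; insensitive to class imbalance.  A constant
#' prediction scores 0.5 on a two-class problem.
#'
#' @param y_true,y_pred aligned label vectors; `y_true` must contain both
#'   classes.
#' @return Number in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop_domain("y_true and y_pred must have equal length")
  }
  classes <- unique(y_true)
  if (length(classes) < 2) {
    stop_domain("y_true must contain both classes")
  }
  recalls <- vapply(classes, function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1))
  mean(recalls)
}
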