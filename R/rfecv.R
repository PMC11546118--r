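# Recursive feature elimination with grouped cross-validation, and the
# persistence scores accumulated over repeated cycles.
#
# One RFECV cycle walks a single elimination path: at every round each
# training fold fits a forest on the active features, held-out balanced
# accuracy is recorded, fold-averaged MDI ranks the features, and the
# least important one(s) are dropped.  The walk continues to a single
# feature; the optimal feature count is then read off the accuracy curve
# (ties toward fewer features) and per-feature cycle scores are computed
# from the recorded elimination order: a feature's score is the number of
# elimination rounds it survives counting from the first round, so
# later-eliminated and finally-retained features score highest.  Summing
# over cycles, features that persist across independently refit cycles
# separate from the background.

#' One cycle of grouped RFECV with persistence scoring
#'
#' @param X numeric matrix (rows = measurement rows, columns = proteins).
#' @param y two-class labels aligned with rows.
#' @param records data.frame with `patient_id` and `group` columns aligned
#'   with rows; used for patient-grouped fold assignment.
#' @param params [forest_params()].
#' @param n_folds grouped CV folds (default 20).
#' @param step elimination step: an integer number of features per round,
#'   or a fraction in (0,1) interpreted as `ceiling(step * n_active)` --
#'   the documented speed knob for wide matrices.
#' @param seed cycle seed; folds, per-round and per-fold forest seeds are
#'   all derived from it.
#' @param folds optional precomputed [grouped_kfold()] assignment (used to
#'   keep folds fixed across cycles).
#' @return An `ff_rfecv` object: `optimal_feature_count`, named `score`
#'   vector (elimination rounds survived, counted from round one), the
#'   accuracy `history`, `per_fold_balanced_accuracy` at the optimum, and
#'   `n_rounds`.
#' @export
rfecv_run <- function(X, y, records, params = forest_params(), n_folds = 20,
                      step = 1, seed = params$seed, folds = NULL) {
  X <- as.matrix(X)
  y <- as_class_factor(y)
  p <- ncol(X)
  if (p < 2) stop_domain("RFECV needs at least 2 features")
  if (step <= 0) stop_domain("step must be positive")
  if (is.null(folds)) {
    folds <- grouped_kfold(records, n_folds, derive_seed(seed, 1))
  }
  rf <- row_folds(folds, records)

  active <- seq_len(p)
  elim_round <- rep(NA_integer_, p)
  hist_count <- integer(0)
  hist_acc <- numeric(0)
  fold_accs <- list()
  round <- 0L

  repeat {
    round <- round + 1L
    imp_sum <- numeric(length(active))
    accs <- rep(NA_real_, folds$n_folds)
    for (f in seq_len(folds$n_folds)) {
      tr <- rf != f
      ytr <- y[tr]
      if (length(unique(as.character(ytr))) < 2) next
      pf <- params
      pf$seed <- derive_seed(seed, 2, round, f)
      model <- train_forest(X[tr, active, drop = FALSE], ytr,
                            class_weights(ytr), pf)
      imp_sum <- imp_sum + model$importance
      te <- rf == f
      yte <- as.character(y[te])
      if (length(unique(yte)) == 2) {
        pred <- predict(model, X[te, active, drop = FALSE])
        accs[f] <- balanced_accuracy(yte, as.character(pred))
      }
    }
    hist_count[round] <- length(active)
    hist_acc[round] <- mean(accs, na.rm = TRUE)
    fold_accs[[round]] <- accs
    if (length(active) == 1L) break
    k <- if (step < 1) ceiling(step * length(active)) else step
    k <- as.integer(min(k, length(active) - 1L))
    # ascending importance; importance ties eliminate the higher feature
    # index first so lower indices persist (deterministic)
    ord <- order(imp_sum, -active)
    drop <- active[ord[seq_len(k)]]
    elim_round[drop] <- round
    active <- setdiff(active, drop)
  }

  best <- max(hist_acc)
  optimal_count <- min(hist_count[hist_acc >= best - 1e-12])
  r0 <- which(hist_count == optimal_count)[1]
  # persistence: elimination rounds survived, counting from round one
  # (the final round eliminates nothing, so survivors get round - 1)
  score <- as.integer(ifelse(is.na(elim_round), round - 1L, elim_round - 1L))
  names(score) <- colnames(X) %||% paste0("V", seq_len(p))

  structure(list(
    optimal_feature_count = as.integer(optimal_count),
    score = score,
    history = data.frame(round = seq_len(round), n_features = hist_count,
                         balanced_accuracy = hist_acc),
    per_fold_balanced_accuracy = fold_accs[[r0]][!is.na(fold_accs[[r0]])],
    n_rounds = round,
    folds = folds
  ), class = "ff_rfecv")
}

#' Accumulate persistence scores over repeated RFECV cycles
#'
#' Runs [rfecv_run()] `n_cycles` times with per-cycle derived seeds (by
#' default the fold assignment is also re-drawn each cycle) and sums the
#' per-cycle scores into the final protein score table.  Reproducible given
#' the master seed.
#'
#' @inheritParams rfecv_run
#' @param n_cycles number of cycles (the reference analysis used 30).
#' @param refold_each_cycle re-draw the grouped fold assignment each cycle
#'   (default TRUE); if FALSE one assignment derived from the master seed
#'   is reused.
#' @return An `ff_scores` data.frame: `protein_id`, `score`, `selected`
#'   (all FALSE until [select_outlier_proteins()] is applied), with the
#'   per-cycle optimal feature counts in `attr(, "optimal_counts")`.
#' @export
accumulate_scores <- function(X, y, records, params = forest_params(),
                              n_folds = 20, n_cycles = 30, step = 1,
                              seed = 1, refold_each_cycle = TRUE) {
  if (n_cycles < 1) stop_domain("n_cycles must be >= 1")
  X <- as.matrix(X)
  folds_fixed <- if (!refold_each_cycle) {
    grouped_kfold(records, n_folds, derive_seed(seed, 1))
  } else {
    NULL
  }
  total <- numeric(ncol(X))
  opt <- integer(n_cycles)
  for (cyc in seq_len(n_cycles)) {
    res <- rfecv_run(X, y, records, params, n_folds, step = step,
                     seed = derive_seed(seed, 100, cyc), folds = folds_fixed)
    total <- total + res$score
    opt[cyc] <- res$optimal_feature_count
  }
  out <- data.frame(protein_id = colnames(X) %||% paste0("V", seq_len(ncol(X))),
                    score = total, selected = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "n_cycles") <- n_cycles
  attr(out, "optimal_counts") <- opt
  class(out) <- c("ff_scores", "data.frame")
  out
}

#' Select outlier-score proteins
#'
#' Applies the heavy-tail rule used to call biomarkers from the score
#' distribution: proteins whose score exceeds
#' `median(score) + k * IQR(score)` are selected (default `k = 1.5`).
#' With all scores identical the IQR is zero and nothing exceeds the
#' threshold, so the selection is empty.
#'
#' @param table an `ff_scores` table or a named numeric score vector.
#' @param k IQR multiplier.
#' @return Character vector of selected protein IDs, with the numeric
#'   threshold in `attr(, "threshold")`.
#' @export
select_outlier_proteins <- function(table, k = 1.5) {
  if (inherits(table, "ff_scores") || is.data.frame(table)) {
    scores <- setNames(table$score, table$protein_id)
  } else {
    scores <- table
  }
  if (length(scores) < 4) stop_domain("need at least 4 scored proteins")
  thr <- median(scores) + k * (quantile(scores, 0.75, names = FALSE) -
                                 quantile(scores, 0.25, names = FALSE))
  sel <- names(scores)[scores > thr]
  attr(sel, "threshold") <- thr
  sel
}

#' Grouped-CV balanced accuracy of a forest on a protein subset
#'
#' Evaluates the final classifier: a forest restricted to the selected
#' proteins, assessed by patient-grouped cross-validation with the mean
#' balanced accuracy over folds.
#'
#' @inheritParams rfecv_run
#' @param X matrix restricted to the selected proteins.
#' @return Mean balanced accuracy in `[0, 1]`.
#' @export
evaluate_final_classifier <- function(X, y, records, params = forest_params(),
                                      n_folds = 20, seed = 1) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop_domain("the selected protein set is empty")
  y <- as_class_factor(y)
  folds <- grouped_kfold(records, n_folds, derive_seed(seed, 1))
  rf <- row_folds(folds, records)
  accs <- rep(NA_real_, folds$n_folds)
  for (f in seq_len(folds$n_folds)) {
    tr <- rf != f
    ytr <- y[tr]
    if (length(unique(as.character(ytr))) < 2) next
    pf <- params
    pf$seed <- derive_seed(seed, 2, f)
    model <- train_forest(X[tr, , drop = FALSE], ytr, class_weights(ytr), pf)
    yte <- as.character(y[rf == f])
    if (length(unique(yte)) == 2) {
      pred <- predict(model, X[rf == f, , drop = FALSE])
      accs[f] <- balanced_accuracy(yte, as.character(pred))
    }
  }
  mean(accs, na.rm = TRUE)
}

#' @export
print.ff_rfecv <- function(x, ...) {
  cat("ff_rfecv: ", x$n_rounds, " rounds, optimal feature count ",
      x$optimal_feature_count, ", CV balanced accuracy at optimum ",
      sprintf("%.3f", x$history$balanced_accuracy[
        x$history$n_features == x$optimal_feature_count][1]), "\n", sep = "")
  invisible(x)
}
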