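# Per-protein log2 fold-change estimation with bootstrap confidence
# intervals.
#
# Pseudoreplication guard: technical repeats of one follicular fluid are
# correlated, so they are first collapsed to a single fluid-level value
# (the median of the log2 intensities over repeats).  All resampling then
# treats fluids as the independent unit.  The statistic is the difference
# of group medians on the log2 scale, so the point estimate is a log2 fold
# change directly.

#' Collapse technical repeats to fluid-level log2 medians
#'
#' @param dataset an `ff_dataset`.
#' @return An `ff_fluid_matrix`: list with `values` (rows = fluids,
#'   columns = proteins; medians over repeats of `log2(intensity)`),
#'   `group` and `patient_id` (named by fluid).
#' @export
aggregate_repeats <- function(dataset) {
  validate_ff_dataset(dataset)
  m <- log2(dataset$intensities)
  s <- dataset$samples
  idx <- split(seq_len(nrow(m)), s$fluid_id)
  vals <- t(vapply(idx, function(i) {
    apply(m[i, , drop = FALSE], 2, median)
  }, numeric(ncol(m))))
  colnames(vals) <- colnames(m)
  first <- vapply(idx, `[`, integer(1), 1)
  structure(list(values = vals,
                 group = setNames(s$group[first], names(idx)),
                 patient_id = setNames(s$patient_id[first], names(idx))),
            class = "ff_fluid_matrix")
}

#' Difference of group medians
#'
#' @param values_pcos,values_control numeric vectors of fluid-level log2
#'   values, both nonempty.
#' @return `median(values_pcos) - median(values_control)`.
#' @export
group_median_diff <- function(values_pcos, values_control) {
  if (length(values_pcos) == 0 || length(values_control) == 0) {
    stop_domain("both groups must be nonempty")
  }
  median(values_pcos) - median(values_control)
}

#' Percentile bootstrap CI for a difference of group medians
#'
#' Resamples each group independently with replacement `n_boot` times and
#' takes the 2.5/97.5 percentiles (at `level = 0.95`) of the resampled
#' difference-in-medians statistic.  The significance flag is set when the
#' interval excludes zero.  Deterministic under the seed.
#'
#' @param values_pcos,values_control fluid-level log2 values, each with at
#'   least 2 observations.
#' @param n_boot number of bootstrap resamples (reference analysis:
#'   10,000).
#' @param level confidence level.
#' @param seed resampling seed.
#' @return List with `log2_fc`, `ci_low`, `ci_high`, `n_boot`, `level`,
#'   `significant`.
#' @export
bootstrap_ci <- function(values_pcos, values_control, n_boot = 10000,
                         level = 0.95, seed = 1) {
  if (length(values_pcos) < 2 || length(values_control) < 2) {
    stop_domain("each group needs at least 2 fluids for the bootstrap")
  }
  if (n_boot < 1) stop_domain("n_boot must be >= 1")
  est <- group_median_diff(values_pcos, values_control)
  stats <- cpp_boot_median_diff(as.numeric(values_pcos),
                                as.numeric(values_control),
                                as.integer(n_boot), derive_seed(seed, 3))
  alpha <- (1 - level) / 2
  ci <- quantile(stats, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(log2_fc = est, ci_low = ci[1], ci_high = ci[2],
       n_boot = as.integer(n_boot), level = level,
       significant = ci[1] > 0 || ci[2] < 0)
}

#' Estimate log2 fold changes for a set of proteins
#'
#' Aggregates repeats to fluid level (unless given an already aggregated
#' `ff_fluid_matrix`), then computes the difference-in-medians log2 fold
#' change with its percentile bootstrap CI for every requested protein.
#' Per-protein seeds are derived from the master seed and the protein's
#' column index, so estimates do not depend on which subset is requested.
#'
#' @param dataset an `ff_dataset` or `ff_fluid_matrix`.
#' @param proteins `"all"` or a character vector of protein IDs.
#' @param n_boot,level,seed see [bootstrap_ci()].
#' @return An `ff_effects` data.frame (`protein_id, log2_fc, ci_low,
#'   ci_high, n_boot, significant`), sorted by descending `|log2_fc|`.
#' @export
estimate_all <- function(dataset, proteins = "all", n_boot = 10000,
                         level = 0.95, seed = 1) {
  fl <- if (inherits(dataset, "ff_fluid_matrix")) dataset else aggregate_repeats(dataset)
  ids <- colnames(fl$values)
  if (identical(proteins, "all")) {
    proteins <- ids
  } else {
    unknown <- setdiff(proteins, ids)
    if (length(unknown) > 0) {
      stop_domain("unknown protein id(s): ", paste(unknown, collapse = ", "))
    }
  }
  is_pcos <- fl$group == "pcos"
  rows <- lapply(proteins, function(pid) {
    j <- match(pid, ids)
    v <- fl$values[, j]
    ci <- bootstrap_ci(v[is_pcos], v[!is_pcos], n_boot = n_boot,
                       level = level, seed = derive_seed(seed, 4, j))
    data.frame(protein_id = pid, log2_fc = ci$log2_fc, ci_low = ci$ci_low,
               ci_high = ci$ci_high, n_boot = ci$n_boot,
               significant = ci$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$log2_fc), out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ff_effects", "data.frame")
  out
}
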