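#' Grouped k-fold assignment by patient
#'
#' Partitions patients (not rows) into `n_folds` folds so that all
#' measurement rows of a patient share one fold and each patient appears in
#' exactly one test set.  Patients are shuffled within clinical group and
#' dealt round-robin, which keeps fold sizes within one patient of each
#' other and mixes the groups across folds.
#'
#' @param records data.frame with columns `patient_id` and `group` (one row
#'   per measurement row, repeats allowed).
#' @param n_folds number of folds (default 20).
#' @param seed deterministic shuffle seed.
#' @return An object of class `ff_folds`: list with `n_folds` and
#'   `fold_of_patient` (named integer vector).
#' @export
grouped_kfold <- function(records, n_folds = 20, seed = 1) {
  pat <- unique(records[, c("patient_id", "group")])
  if (anyDuplicated(pat$patient_id)) {
    stop_domain("a patient is mapped to more than one group")
  }
  if (nrow(pat) < n_folds) {
    stop_domain("fewer distinct patients (", nrow(pat),
                ") than folds (", n_folds, ")")
  }
  ordered <- with_seed(derive_seed(seed, 17), {
    unlist(lapply(split(pat$patient_id, pat$group),
                  function(x) x[sample.int(length(x))]),
           use.names = FALSE)
  })
  fold <- rep_len(seq_len(n_folds), length(ordered))
  structure(list(n_folds = as.integer(n_folds),
                 fold_of_patient = setNames(fold, ordered)),
            class = "ff_folds")
}

# fold index of every measurement row
row_folds <- function(folds, records) {
  unname(folds$fold_of_patient[records$patient_id])
}

#' @export
print.ff_folds <- function(x, ...) {
  cat("ff_folds: ", length(x$fold_of_patient), " patients in ",
      x$n_folds, " folds (sizes ",
      paste(range(table(x$fold_of_patient)), collapse = "-"), ")\n", sep = "")
  invisible(x)
}
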