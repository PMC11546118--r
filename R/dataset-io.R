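# Plain-text serialization of abundance datasets.
#
# Two tab-separated files: the intensity matrix (first column `row_id`,
# remaining columns protein IDs) and the sample metadata (`row_id,
# patient_id, group, fluid_id, repeat_index`).  Intensities are written
# with 15 significant digits so a round trip is an identity well past the
# 12-digit contract.

#' Write an abundance dataset to a TSV file pair
#'
#' @param dataset an `ff_dataset`.
#' @param matrix_path,metadata_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, matrix_path, metadata_path) {
  validate_ff_dataset(dataset)
  m <- dataset$intensities
  txt <- matrix(sprintf("%.15g", m), nrow(m), ncol(m), dimnames = dimnames(m))
  df <- data.frame(row_id = dataset$samples$row_id, txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$samples, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(matrix = matrix_path, metadata = metadata_path))
}

#' Read an abundance dataset from a TSV file pair
#'
#' Performs full structural validation and reports the (1-based, data) row
#' number of the first offending record on failure: non-positive or
#' non-numeric intensities, metadata rows whose fluid maps to more than one
#' patient, patients mapped to more than one group, and row_id mismatches
#' between the two files.
#'
#' @param matrix_path,metadata_path paths written by [write_dataset()].
#' @return An `ff_dataset`.
#' @export
read_dataset <- function(matrix_path, metadata_path) {
  for (p in c(matrix_path, metadata_path)) {
    if (!file.exists(p)) stop_domain("file not found: ", p)
  }
  mat <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(mat) < 2 || names(mat)[1] != "row_id") {
    stop_domain("malformed matrix header: first column must be 'row_id'")
  }
  meta <- read.delim(metadata_path, check.names = FALSE,
                     stringsAsFactors = FALSE,
                     colClasses = "character")
  need <- c("row_id", "patient_id", "group", "fluid_id", "repeat_index")
  if (!identical(sort(names(meta)), sort(need))) {
    stop_domain("malformed metadata header: need columns ",
                paste(need, collapse = ", "))
  }
  meta <- meta[, need]
  meta$repeat_index <- as.integer(meta$repeat_index)

  vals <- as.matrix(mat[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(mat[-1], is.numeric, logical(1)))[1]
    stop_domain("parse error: non-numeric intensity in column '",
                names(mat)[-1][bad], "'")
  }
  off <- which(!is.finite(vals) | vals <= 0, arr.ind = TRUE)
  if (nrow(off) > 0) {
    stop_domain("parse error at matrix row ", off[1, 1],
                ": intensity must be strictly positive and finite")
  }
  rownames(vals) <- mat$row_id

  if (!identical(meta$row_id, mat$row_id)) {
    if (!setequal(meta$row_id, mat$row_id)) {
      miss <- setdiff(mat$row_id, meta$row_id)[1]
      stop_domain("parse error: row_id '", miss %||% setdiff(meta$row_id, mat$row_id)[1],
                  "' present in only one of the two files")
    }
    meta <- meta[match(mat$row_id, meta$row_id), ]
  }
  # orphan references: a fluid spanning two patients, a patient in two groups
  fp <- tapply(meta$patient_id, meta$fluid_id, function(x) length(unique(x)))
  if (any(fp > 1)) {
    f <- names(fp)[fp > 1][1]
    stop_domain("parse error at metadata row ",
                which(meta$fluid_id == f)[2],
                ": fluid '", f, "' references more than one patient")
  }
  pg <- tapply(meta$group, meta$patient_id, function(x) length(unique(x)))
  if (any(pg > 1)) {
    pt <- names(pg)[pg > 1][1]
    stop_domain("parse error at metadata row ",
                which(meta$patient_id == pt)[2],
                ": patient '", pt, "' mapped to more than one group")
  }
  ff_dataset(vals, meta)
}
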