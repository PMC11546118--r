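#' Winsorise a numeric vector
#'
#' Replaces the `floor(gamma * n)` smallest values by the smallest retained
#' value and, symmetrically, the largest by the largest retained value.
#' `gamma = 0` is the identity; order statistics between the tails are
#' untouched.
#'
#' @param values numeric vector, nonempty.
#' @param gamma winsorisation proportion in `[0, 0.5)`.
#' @return Winsorised vector of the same length and order.
#' @export
#' @examples
#' winsorize(1:10, 0.2)  # 3 3 3 4 5 6 7 8 8 8
winsorize <- function(values, gamma) {
  if (length(values) == 0) stop_domain("values must be nonempty")
  if (gamma < 0 || gamma >= 0.5) stop_domain("gamma must lie in [0, 0.5)")
  g <- floor(gamma * length(values))
  if (g == 0) return(values)
  s <- sort(values)
  lo <- s[g + 1]
  hi <- s[length(values) - g]
  pmin(pmax(values, lo), hi)
}

#' Winsorised robust correlation matrix
#'
#' Column-wise winsorisation followed by the plain product-moment
#' correlation: the standard robust correlation estimator in which extreme
#' observations are clipped to the tails before computing Pearson's r.
#' `gamma = 0` reproduces the ordinary correlation matrix.  Pairs that are
#' degenerate (zero variance) after winsorisation are reported as `NA`
#' rather than a fabricated value; the diagonal is always 1.
#'
#' @param X numeric matrix (rows = fluids or samples, columns = proteins);
#'   at least 3 rows and 2 columns.
#' @param gamma winsorisation proportion (default 0.2, the conventional
#'   choice in the robust-statistics literature).
#' @return An `ff_wincor` object: `proteins`, symmetric matrix `r` with
#'   unit diagonal, and `gamma`.
#' @export
wincor_matrix <- function(X, gamma = 0.2) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop_domain("need at least 3 rows")
  if (ncol(X) < 2) stop_domain("need at least 2 proteins")
  W <- apply(X, 2, winsorize, gamma = gamma)
  r <- suppressWarnings(cor(W))
  diag(r) <- 1
  proteins <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  dimnames(r) <- list(proteins, proteins)
  structure(list(proteins = proteins, r = r, gamma = gamma),
            class = "ff_wincor")
}

#' @export
print.ff_wincor <- function(x, ...) {
  cat("ff_wincor: ", length(x$proteins), " proteins, gamma = ", x$gamma,
      "\n", sep = "")
  off <- x$r[upper.tri(x$r)]
  cat("  off-diagonal r: min ", sprintf("%.3f", min(off, na.rm = TRUE)),
      ", median ", sprintf("%.3f", median(off, na.rm = TRUE)),
      ", max ", sprintf("%.3f", max(off, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Basic correlation heatmap
#'
#' Minimal base-graphics rendering of a winsorised correlation matrix
#' (blue = -1, white = 0, red = +1).
#'
#' @param x an `ff_wincor`.
#' @param ... passed to [graphics::image()].
#' @export
plot.ff_wincor <- function(x, ...) {
  r <- x$r
  n <- ncol(r)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(41)
  graphics::image(seq_len(n), seq_len(n), t(r[n:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(r), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(r)), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}
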