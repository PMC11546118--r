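# Shared fixtures and independent oracles.  Everything is generated in
# code; no stored data.

# A small cohort configuration for fast tests.
tiny_cohort <- function(n_pcos = 15, n_control = 15, p = 30,
                        effects = data.frame(protein = integer(0),
                                             log2_fc = numeric(0)),
                        seed = 1, ...) {
  cohort_config(n_pcos_patients = n_pcos, n_control_patients = n_control,
                n_proteins = p, effects = effects, repeat_sd_spread = 0,
                seed = seed, ...)
}

# Perfectly separable two-class fixture: one informative feature, optional
# noise features; enough rows per class for depth-1 splits under the
# default leaf minimum.
separable_fixture <- function(n_per_class = 60, p_noise = 0, seed = 42,
                              n_patients_per_class = 20) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c("control", "pcos"), each = n_per_class)
  x <- c(rnorm(n_per_class, 0, 0.1), rnorm(n_per_class, 3, 0.1))
  X <- cbind(signal = x)
  if (p_noise > 0) {
    X <- cbind(X, matrix(rnorm(n * p_noise), n, p_noise,
                         dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  }
  pat <- paste0(y, "_pat", rep_len(seq_len(n_patients_per_class), n_per_class))
  records <- data.frame(patient_id = pat,
                        group = y, stringsAsFactors = FALSE)
  list(X = X, y = y, records = records)
}

# Independent MDI oracle: brute-force re-accumulation of weighted impurity
# decreases from the stored node tables, recomputing every impurity from
# the per-node class-weight totals (ignores the stored impurity column).
oracle_mdi <- function(model) {
  p <- length(model$features)
  g <- function(w0, w1) {
    tot <- w0 + w1
    if (tot <= 0) return(0)
    pr <- c(w0, w1) / tot
    sum(pr * (1 - pr))
  }
  imp <- numeric(p)
  for (tr in model$trees) {
    w_root <- tr[1, "w0"] + tr[1, "w1"]
    for (i in seq_len(nrow(tr))) {
      f <- tr[i, "feature"]
      if (f > 0) {
        l <- tr[i, "left"]; r <- tr[i, "right"]
        dec <- (tr[i, "w0"] + tr[i, "w1"]) * g(tr[i, "w0"], tr[i, "w1"]) -
          (tr[l, "w0"] + tr[l, "w1"]) * g(tr[l, "w0"], tr[l, "w1"]) -
          (tr[r, "w0"] + tr[r, "w1"]) * g(tr[r, "w0"], tr[r, "w1"])
        imp[f] <- imp[f] + dec / w_root
      }
    }
  }
  imp / length(model$trees)
}

# Independent product-moment correlation (manual sums, no stats::cor).
oracle_pearson <- function(X) {
  n <- nrow(X)
  ctr <- sweep(X, 2, colMeans(X))
  cv <- crossprod(ctr) / (n - 1)
  sd <- sqrt(diag(cv))
  cv / tcrossprod(sd)
}

# log2 fold change actually realised in a dataset: difference of group
# medians of the fluid-level log2 medians (the package's estimator, but
# computed here from first principles).
oracle_log2fc <- function(dataset, protein) {
  s <- dataset$samples
  v <- log2(dataset$intensities[, protein])
  fl <- tapply(v, s$fluid_id, median)
  grp <- tapply(s$group, s$fluid_id, `[`, 1)
  median(fl[grp == "pcos"]) - median(fl[grp == "control"])
}
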