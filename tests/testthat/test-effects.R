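test_that("repeat aggregation takes fluid medians of log2 intensities", {
  d <- simulate_cohort(tiny_cohort(n_pcos = 2, n_control = 2, p = 4, seed = 4))
  # overwrite one fluid's repeats with known values
  s <- d$samples
  f1 <- s$fluid_id[1]
  d$intensities[s$fluid_id == f1, 1] <- c(2, 4, 512)
  d$intensities[s$fluid_id == f1, 2] <- 7
  fl <- aggregate_repeats(d)
  expect_equal(unname(fl$values[f1, 1]), 2)       # median of log2 {1,2,9}
  expect_equal(unname(fl$values[f1, 2]), log2(7)) # median of equal repeats
  expect_equal(nrow(fl$values), length(unique(s$fluid_id)))

  # the reference geometry: 213 fluids in, 213 rows out
  d2 <- simulate_cohort(tiny_cohort(n_pcos = 34, n_control = 37, p = 3,
                                    fluids_per_patient_range = c(3, 3)))
  expect_equal(nrow(aggregate_repeats(d2)$values), 213)
})

test_that("group median difference follows the definition", {
  expect_equal(group_median_diff(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(group_median_diff(c(1, 2, 3), c(0, 0, 10)), 2)
  x <- rnorm(31)
  expect_equal(group_median_diff(x - 0.61, x), -0.61)
  expect_error(group_median_diff(numeric(0), 1:3), "nonempty")
})

test_that("degenerate bootstrap gives a point interval", {
  ci <- bootstrap_ci(rep(2.5, 5), rep(1.5, 6), n_boot = 200, seed = 3)
  expect_equal(ci$log2_fc, 1)
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)
  expect_true(ci$significant)
  ci0 <- bootstrap_ci(rep(2, 5), rep(2, 6), n_boot = 200, seed = 3)
  expect_false(ci0$significant)
  expect_error(bootstrap_ci(1, 1:5), "at least 2")
})

test_that("estimates are location and scale equivariant", {
  set.seed(7)
  a <- rnorm(30); b <- rnorm(25)
  base <- bootstrap_ci(a, b, n_boot = 500, seed = 11)
  shift <- bootstrap_ci(a + 0.75, b, n_boot = 500, seed = 11)
  expect_equal(shift$log2_fc, base$log2_fc + 0.75)
  expect_equal(shift$ci_low, base$ci_low + 0.75)
  expect_equal(shift$ci_high, base$ci_high + 0.75)

  # multiplying raw intensities by 2^c shifts the log2 fold change by c
  d <- simulate_cohort(tiny_cohort(n_pcos = 6, n_control = 6, p = 3, seed = 5))
  e1 <- estimate_all(d, n_boot = 300, seed = 9)
  d2 <- d
  pc <- d2$samples$group == "pcos"
  d2$intensities[pc, ] <- d2$intensities[pc, ] * 2^0.5
  e2 <- estimate_all(d2, n_boot = 300, seed = 9)
  m1 <- setNames(e1$log2_fc, e1$protein_id)
  m2 <- setNames(e2$log2_fc, e2$protein_id)
  expect_equal(m2[names(m1)], m1 + 0.5)
})

test_that("duplicating repeat rows changes nothing (pseudoreplication guard)", {
  d <- simulate_cohort(tiny_cohort(n_pcos = 5, n_control = 5, p = 6, seed = 12))
  dup <- d
  extra <- d$samples
  extra$repeat_index <- extra$repeat_index + max(extra$repeat_index)
  extra$row_id <- paste0(extra$row_id, "b")
  m2 <- d$intensities
  rownames(m2) <- extra$row_id
  dup$intensities <- rbind(d$intensities, m2)
  dup$samples <- rbind(d$samples, extra)
  e1 <- estimate_all(d, n_boot = 400, seed = 2)
  e2 <- estimate_all(dup, n_boot = 400, seed = 2)
  expect_identical(e1, e2)
})

test_that("CI width shrinks with group size on average", {
  width <- function(n, seeds = 1:20) {
    mean(vapply(seeds, function(s) {
      set.seed(1000 * n + s)
      ci <- bootstrap_ci(rnorm(n, 0.3, 0.4), rnorm(n, 0, 0.4),
                         n_boot = 500, seed = s)
      ci$ci_high - ci$ci_low
    }, numeric(1)))
  }
  w <- c(width(10), width(20), width(50))
  expect_true(all(diff(w) <= 0))
})

test_that("estimate_all handles subsets, ordering and unknown ids", {
  eff <- data.frame(protein = c(2, 5), log2_fc = c(-0.61, 0.2))
  d <- simulate_cohort(tiny_cohort(n_pcos = 34, n_control = 40, p = 8,
                                   effects = eff, seed = 42))
  e <- estimate_all(d, n_boot = 2000, seed = 5)
  expect_equal(nrow(e), 8)
  expect_true(all(diff(abs(e$log2_fc)) <= 1e-12))
  # the strongly downregulated protein lands in its reference-style band
  est <- e$log2_fc[e$protein_id == "prot_0002"]
  expect_true(est > -0.90 && est < -0.34)
  expect_true(e$significant[e$protein_id == "prot_0002"])

  one <- estimate_all(d, proteins = "prot_0005", n_boot = 500, seed = 5)
  expect_equal(nrow(one), 1)
  # per-protein seeds are derived from the column, not the subset
  expect_equal(one$log2_fc,
               e$log2_fc[e$protein_id == "prot_0005"])
  expect_error(estimate_all(d, proteins = "nope"), "unknown protein")
})
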