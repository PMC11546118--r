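# RFECV behaviour is checked on deliberately small cohorts (fewer folds,
# 25-tree forests) to keep the default test run fast; the full-width
# configuration is exercised in test-acceptance.R.

fast_params <- function(seed = 1) forest_params(n_trees = 25, seed = seed)

test_that("strong informative features are retained in the optimal set", {
  eff <- data.frame(protein = 1:3, log2_fc = c(1.2, -1.0, 1.0))
  hits <- vapply(1:5, function(s) {
    d <- simulate_cohort(tiny_cohort(n_pcos = 20, n_control = 20, p = 25,
                                     effects = eff, seed = 200 + s))
    res <- rfecv_run(log2(d$intensities), d$samples$group, d$samples,
                     fast_params(), n_folds = 5, seed = s)
    top <- names(sort(res$score, decreasing = TRUE))[1:5]
    sum(sprintf("prot_%04d", 1:3) %in% top)
  }, numeric(1))
  expect_gte(mean(hits == 3), 0.8)
})

test_that("all-noise features give chance-level accuracy", {
  accs <- vapply(1:5, function(s) {
    d <- simulate_cohort(tiny_cohort(n_pcos = 20, n_control = 20, p = 15,
                                     seed = 300 + s))
    res <- rfecv_run(log2(d$intensities), d$samples$group, d$samples,
                     fast_params(), n_folds = 5, seed = s)
    max(res$history$balanced_accuracy)
  }, numeric(1))
  # even the max over the elimination path stays near 0.5 on pure noise
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.7)
})

test_that("a constant feature is eliminated first", {
  fx <- separable_fixture(n_per_class = 60, n_patients_per_class = 30)
  X <- cbind(fx$X, flat = rep(1, nrow(fx$X)))
  res <- rfecv_run(X, fx$y, fx$records, fast_params(), n_folds = 5, seed = 2)
  expect_equal(res$n_rounds, 2)
  expect_gt(res$score["signal"], res$score["flat"])
  expect_equal(res$optimal_feature_count, 1)
})

test_that("score accumulation is additive and seed-deterministic", {
  d <- simulate_cohort(tiny_cohort(n_pcos = 12, n_control = 12, p = 10,
                                   effects = data.frame(protein = 4,
                                                        log2_fc = 1.5),
                                   seed = 9))
  X <- log2(d$intensities)
  one <- accumulate_scores(X, d$samples$group, d$samples, fast_params(),
                           n_folds = 4, n_cycles = 1, seed = 77)
  direct <- rfecv_run(X, d$samples$group, d$samples, fast_params(),
                      n_folds = 4, seed = ffproteo:::derive_seed(77, 100, 1))
  expect_equal(setNames(one$score, one$protein_id), direct$score)

  again <- accumulate_scores(X, d$samples$group, d$samples, fast_params(),
                             n_folds = 4, n_cycles = 1, seed = 77)
  expect_identical(one, again)

  three <- accumulate_scores(X, d$samples$group, d$samples, fast_params(),
                             n_folds = 4, n_cycles = 3, seed = 77)
  expect_true(all(three$score >= one$score - 1e-9))
  expect_equal(length(attr(three, "optimal_counts")), 3)
})

test_that("outlier selection applies the median + k*IQR rule", {
  expect_equal(length(select_outlier_proteins(
    setNames(rep(6, 10), paste0("p", 1:10)))), 0)

  sc <- setNames(c(rep(6, 480), rep(330, 4)), paste0("p", 1:484))
  expect_equal(sort(select_outlier_proteins(sc)),
               sort(paste0("p", 481:484)))

  # reference-like profile: heavy background at median 6 / IQR 4.75 plus
  # the 20 outlying biomarker scores
  bg <- rep(c(1, 4, 8, 11), 116)
  out <- c(330, 330, 330, 330, 324, 301, 210, 178, 146, 128,
           93, 83, 59, 55, 51, 49, 48, 46, 44, 44)
  sc <- setNames(c(bg, out), paste0("p", seq_len(484)))
  sel <- select_outlier_proteins(sc)
  expect_true(length(sel) >= 15 && length(sel) <= 25)
  expect_true(all(paste0("p", 465:484) %in% sel))

  expect_error(select_outlier_proteins(setNames(1:3, c("a", "b", "c"))),
               "at least 4")
})

test_that("final-classifier evaluation responds to signal", {
  fx <- separable_fixture(n_per_class = 90, n_patients_per_class = 30)
  acc <- evaluate_final_classifier(fx$X, fx$y, fx$records, fast_params(),
                                   n_folds = 5, seed = 4)
  expect_gte(acc, 0.95)

  # label permutation destroys the signal
  set.seed(10)
  perm_pat <- unique(fx$records$patient_id)
  new_grp <- setNames(sample(rep(c("control", "pcos"), length.out =
                                   length(perm_pat))), perm_pat)
  yp <- unname(new_grp[fx$records$patient_id])
  recp <- fx$records
  recp$group <- yp
  accp <- mean(vapply(1:5, function(s) {
    evaluate_final_classifier(fx$X, yp, recp, fast_params(seed = s),
                              n_folds = 5, seed = s)
  }, numeric(1)))
  expect_gt(accp, 0.35)
  expect_lt(accp, 0.65)
})
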