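test_that("a perfectly separating feature yields in-sample balanced accuracy 1", {
  fx <- separable_fixture(n_per_class = 60)
  m <- train_forest(fx$X, fx$y, params = forest_params(seed = 9))
  pred <- predict(m, fx$X)
  expect_equal(balanced_accuracy(fx$y, as.character(pred)), 1)
  prob <- predict(m, fx$X, type = "prob")
  expect_true(all(prob >= 0 & prob <= 1))
})

test_that("capacity constraints hold on every stored tree", {
  d <- simulate_cohort(tiny_cohort(n_pcos = 20, n_control = 20, p = 15,
                                   seed = 6))
  m <- train_forest(log2(d$intensities), d$samples$group,
                    params = forest_params(seed = 2))
  a <- audit_forest(m)
  expect_true(all(a$max_depth <= 3))
  # weighted occupancy; allow rounding slack at the constraint boundary
  expect_true(all(a$min_leaf_weight >= 30 - 1e-8))
})

test_that("too few rows for a split gives single-leaf majority trees", {
  set.seed(1)
  n <- 20 # < 2 * min_samples_leaf
  X <- matrix(rnorm(2 * n), n, 2)
  y <- rep(c("control", "pcos"), c(8, 12))
  m <- train_forest(X, y, weights = rep(1, n), params = forest_params(seed = 3))
  a <- audit_forest(m)
  expect_true(all(a$n_nodes == 1))
  expect_true(all(mdi_importances(m) == 0))
  # weighted-majority prediction everywhere (unweighted here: majority class)
  expect_true(all(predict(m, X) == "pcos"))
})

test_that("constant-label training predicts that class everywhere", {
  set.seed(2)
  X <- matrix(rnorm(200), 100, 2)
  m <- train_forest(X, rep("pcos", 100), weights = rep(1, 100),
                    params = forest_params(seed = 1))
  expect_true(all(predict(m, X) == "pcos"))
})

test_that("importance concentrates on the only splittable feature", {
  fx <- separable_fixture(n_per_class = 60)
  X <- cbind(fx$X, flat = rep(1, nrow(fx$X)))
  m <- train_forest(X, fx$y, params = forest_params(seed = 7,
                                                    features_per_split = 2))
  imp <- mdi_importances(m)
  expect_equal(unname(imp["signal"]), 1)
  expect_equal(unname(imp["flat"]), 0)
})

test_that("reported MDI matches the brute-force oracle", {
  set.seed(31)
  X <- matrix(rnorm(200 * 6), 200, 6)
  y <- ifelse(X[, 2] + 0.5 * X[, 5] + rnorm(200, 0, 0.5) > 0, "pcos", "control")
  m <- train_forest(X, y, params = forest_params(seed = 13))
  expect_lt(max(abs(m$importance - oracle_mdi(m))), 1e-10)
  # and the exported normalisation sums to one
  expect_equal(sum(mdi_importances(m)), 1)
})

test_that("forests are deterministic under the seed", {
  fx <- separable_fixture(n_per_class = 40, p_noise = 3)
  m1 <- train_forest(fx$X, fx$y, params = forest_params(seed = 5))
  m2 <- train_forest(fx$X, fx$y, params = forest_params(seed = 5))
  expect_identical(m1$trees, m2$trees)
  m3 <- train_forest(fx$X, fx$y, params = forest_params(seed = 6))
  expect_false(identical(m1$trees, m3$trees))
})

test_that("misaligned inputs are rejected", {
  fx <- separable_fixture(n_per_class = 40)
  expect_error(train_forest(fx$X, fx$y[-1]), "misaligned")
  m <- train_forest(fx$X, fx$y)
  expect_error(predict(m, cbind(fx$X, fx$X)), "expects")
})
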