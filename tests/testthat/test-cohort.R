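test_that("default effect table matches the reference profile", {
  eff <- table2_default_effects()
  expect_equal(nrow(eff), 20)
  expect_false(anyDuplicated(eff$protein) > 0)
  expect_true(all(eff$protein >= 1 & eff$protein <= 484))
  expect_equal(eff$log2_fc[eff$label == "MYL6"], -0.61)
  expect_equal(eff$log2_fc[eff$label == "AGT"], 0.41)
  expect_equal(eff$log2_fc[eff$label == "APOA1"], 0.18)
  # one large downregulation; the remaining negatives are the two small
  # non-significant -0.07 entries of the reference profile
  expect_equal(sort(eff$log2_fc[eff$log2_fc < 0]), c(-0.61, -0.07, -0.07))
  expect_true(all(abs(eff$log2_fc[eff$log2_fc > 0] - 0.295) <= 0.115))
})

test_that("simulated cohorts have the configured nested geometry", {
  d <- simulate_cohort(cohort_config(seed = 5))
  s <- d$samples
  expect_equal(length(unique(s$patient_id)), 74)
  expect_equal(length(unique(s$patient_id[s$group == "pcos"])), 34)
  expect_equal(ncol(d$intensities), 484)
  # every fluid has exactly repeats_per_fluid rows
  expect_true(all(table(s$fluid_id) == 3))
  fl_per_pat <- tapply(s$fluid_id, s$patient_id,
                       function(x) length(unique(x)))
  expect_true(all(fl_per_pat %in% 2:3))
  expect_true(all(is.finite(d$intensities)) && all(d$intensities > 0))

  # forcing 71 patients x 3 fluids gives the reference 213 fluids, 639 rows
  d2 <- simulate_cohort(tiny_cohort(n_pcos = 34, n_control = 37, p = 5,
                                    fluids_per_patient_range = c(3, 3)))
  expect_equal(length(unique(d2$samples$fluid_id)), 213)
  expect_equal(nrow(d2$intensities), 639)
})

test_that("identical configs give bit-identical datasets, new seeds differ", {
  cfg <- tiny_cohort(seed = 11)
  d1 <- simulate_cohort(cfg)
  d2 <- simulate_cohort(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_cohort(tiny_cohort(seed = 12))
  expect_false(identical(d1$intensities, d3$intensities))
})

test_that("null cohorts show no systematic group differences", {
  # scaled-down Monte-Carlo: effect-free cohorts must have near-zero mean
  # log2 group differences for almost all proteins
  diffs <- unlist(lapply(1:20, function(s) {
    d <- simulate_cohort(tiny_cohort(n_pcos = 200, n_control = 200, p = 25,
                                     patient_sd = 0.1, fluid_sd = 0.1,
                                     repeat_sd = 0.1, seed = s))
    m <- log2(d$intensities)
    pc <- d$samples$group == "pcos"
    colMeans(m[pc, ]) - colMeans(m[!pc, ])
  }))
  expect_gte(mean(abs(diffs) < 0.05), 0.95)
})

test_that("injected log2 fold changes are recovered at fluid level", {
  eff <- data.frame(protein = c(3, 8, 14, 19, 23, 27),
                    log2_fc = c(-0.61, 0.18, 0.41, 0.26, -0.07, 0.33))
  err <- unlist(lapply(1:20, function(s) {
    d <- simulate_cohort(tiny_cohort(n_pcos = 50, n_control = 50, p = 30,
                                     effects = eff, patient_sd = 0.1,
                                     fluid_sd = 0.1, repeat_sd = 0.1,
                                     seed = 100 + s))
    vapply(seq_len(nrow(eff)), function(i) {
      oracle_log2fc(d, eff$protein[i]) - eff$log2_fc[i]
    }, numeric(1))
  }))
  expect_gte(mean(abs(err) < 0.1), 0.9)
})

test_that("block proteins correlate and the anti protein anti-correlates", {
  cfg <- tiny_cohort(n_pcos = 40, n_control = 40, p = 20,
                     effects = data.frame(protein = 1, log2_fc = 0),
                     block_proteins = 2:9, anti_protein = 15,
                     block_rho = 0.6, seed = 21)
  d <- simulate_cohort(cfg)
  fl <- aggregate_repeats(d)
  r <- cor(fl$values[, 2:9])
  expect_gte(min(r[upper.tri(r)]), 0.6 - 0.15)
  block_mean <- rowMeans(fl$values[, 2:9])
  expect_lte(cor(block_mean, fl$values[, 15]), 0)
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(cohort_config(n_pcos_patients = 0), "n_pcos_patients")
  expect_error(cohort_config(block_rho = 1.2), "block_rho")
  expect_error(cohort_config(patient_sd = -1), "patient_sd")
  expect_error(tiny_cohort(p = 10,
                           effects = data.frame(protein = c(2, 2),
                                                log2_fc = c(1, 1))),
               "effects")
  expect_error(tiny_cohort(p = 10,
                           effects = data.frame(protein = 3, log2_fc = 1),
                           block_proteins = c(4, 5), anti_protein = 4),
               "anti_protein")
  expect_error(cohort_config(fluids_per_patient_range = c(3, 2)),
               "fluids_per_patient_range")
})

test_that("a minority of proteins reach technical CV below 20%", {
  d <- simulate_cohort(cohort_config(seed = 8))
  lm <- log(d$intensities)
  s <- d$samples
  wsd <- vapply(seq_len(ncol(lm)), function(j) {
    sqrt(mean(tapply(lm[, j], s$fluid_id, stats::sd)^2))
  }, numeric(1))
  cv <- sqrt(exp(wsd^2) - 1)
  frac <- mean(cv < 0.2)
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.4)
})
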