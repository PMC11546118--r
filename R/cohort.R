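#' Default differential-abundance effect table
#'
#' The 20 reference log2 fold changes used as the simulator's default
#' injected effects.  They are the point estimates reported for the 20
#' outlier-score proteins in the follicular-fluid PCOS-vs-donor contrast
#' this package emulates: one large negative effect (a myosin light chain,
#' MYL6-like, -0.61), two small non-significant negative effects (-0.07),
#' and seventeen positive effects between 0.18 and 0.41.  Each effect is
#' assigned to a fixed, evenly spaced protein index so the injected columns
#' are scattered across the matrix.
#'
#' @param n_proteins number of proteins in the target matrix; indices are
#'   spread over `1:n_proteins` (default 484).
#' @return A data.frame with columns `protein` (integer column index),
#'   `log2_fc` (numeric) and `label` (gene-style tag of the emulated
#'   protein).
#' @export
#' @examples
#' eff <- table2_default_effects()
#' nrow(eff)                       # 20
#' eff$log2_fc[eff$label == "MYL6"]  # -0.61
table2_default_effects <- function(n_proteins = 484) {
  labels <- c("MYL6", "AFM", "SERPINA1", "A2M", "AGT", "CFB", "CP", "APOA1",
              "ITIH1", "SERPING1", "KNG1", "GC", "C9", "A1BG", "SERPINA6",
              "SERPINC1", "SERPINF1", "SELENBP1", "PDIA6", "ITIH2")
  fc <- c(-0.61, 0.21, 0.23, 0.26, 0.41, 0.36, 0.35, 0.18,
          0.19, -0.07, 0.24, 0.28, 0.18, 0.18, 0.29,
          -0.07, 0.29, 0.33, 0.34, 0.23)
  if (n_proteins < 20) {
    stop_domain("n_proteins must be >= 20 to place the 20 default effects")
  }
  idx <- floor(seq(1, n_proteins, length.out = 22))[2:21]
  data.frame(protein = as.integer(idx), log2_fc = fc, label = labels,
             stringsAsFactors = FALSE)
}

#' Configuration of a synthetic follicular-fluid cohort
#'
#' Describes the nested repeated-measures design to simulate: patients in
#' two clinical groups (pcos / control), 2--3 follicular fluids per patient,
#' a fixed number of technical repeats per fluid, and a lognormal intensity
#' model with a three-level random-intercept variance decomposition
#' (patient / fluid / repeat) on the natural-log scale.
#'
#' Defaults reproduce the geometry of the emulated study: 34 PCOS + 40
#' control patients, 2--3 fluids each, 3 repeats per fluid, 484 proteins,
#' and the [table2_default_effects()] log2 fold changes injected into the
#' PCOS group.  `repeat_sd` is the median technical standard deviation on
#' the natural-log scale; with the default per-protein spread
#' (`repeat_sd_spread = 0.3`, lognormal multiplier) roughly a fifth of
#' proteins end up with technical CV below 20%, matching the reported
#' quantification precision (98 of 484 proteins with CV < 20%).
#'
#' Correlated block: proteins in `block_proteins` share a latent factor with
#' loading `sqrt(block_rho)` at every variance level, giving pairwise
#' correlation `block_rho`; `anti_protein` loads with `-sqrt(block_rho)`
#' and is therefore anti-correlated with the whole block (the MYL6-like
#' signature).  By default the block is the positive-effect proteins and
#' the anti-correlated protein is the most downregulated one.
#'
#' @param n_pcos_patients,n_control_patients patients per group.
#' @param fluids_per_patient_range inclusive integer range of fluids drawn
#'   uniformly per patient.
#' @param repeats_per_fluid technical repeats per fluid.
#' @param n_proteins number of quantified proteins.
#' @param effects data.frame with columns `protein` (index) and `log2_fc`;
#'   injected as group effects in PCOS rows.  Use a 0-row data.frame for a
#'   null cohort.
#' @param block_proteins integer indices of the positively correlated block
#'   (default: the positive-effect proteins).
#' @param anti_protein optional index anti-correlated with the block
#'   (default: the most negative effect protein, if any).
#' @param block_rho target pairwise correlation inside the block, in (0,1).
#' @param patient_sd,fluid_sd,repeat_sd standard deviations of the three
#'   random-intercept levels, natural-log scale.
#' @param repeat_sd_spread sdlog of the per-protein lognormal multiplier on
#'   `repeat_sd`; 0 gives every protein the same technical sd.
#' @param baseline_log_mean_range range of per-protein baseline natural-log
#'   intensities (uniform).
#' @param seed integer master seed; identical configurations give
#'   bit-identical datasets.
#' @return An object of class `ff_cohort_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_pcos_patients = 34,
                          n_control_patients = 40,
                          fluids_per_patient_range = c(2L, 3L),
                          repeats_per_fluid = 3,
                          n_proteins = 484,
                          effects = table2_default_effects(n_proteins),
                          block_proteins = NULL,
                          anti_protein = NULL,
                          block_rho = 0.5,
                          patient_sd = 0.15,
                          fluid_sd = 0.15,
                          repeat_sd = 0.25,
                          repeat_sd_spread = 0.3,
                          baseline_log_mean_range = c(3, 12),
                          seed = 1) {
  if (is.null(effects) || nrow(effects) == 0) {
    effects <- data.frame(protein = integer(0), log2_fc = numeric(0))
  }
  if (is.null(block_proteins)) {
    block_proteins <- effects$protein[effects$log2_fc > 0]
  }
  if (is.null(anti_protein) && nrow(effects) > 0 && any(effects$log2_fc < 0)) {
    anti_protein <- effects$protein[which.min(effects$log2_fc)]
  }
  cfg <- structure(list(
    n_pcos_patients = as.integer(n_pcos_patients),
    n_control_patients = as.integer(n_control_patients),
    fluids_per_patient_range = as.integer(fluids_per_patient_range),
    repeats_per_fluid = as.integer(repeats_per_fluid),
    n_proteins = as.integer(n_proteins),
    effects = effects,
    block_proteins = as.integer(block_proteins),
    anti_protein = if (is.null(anti_protein)) NULL else as.integer(anti_protein),
    block_rho = block_rho,
    patient_sd = patient_sd,
    fluid_sd = fluid_sd,
    repeat_sd = repeat_sd,
    repeat_sd_spread = repeat_sd_spread,
    baseline_log_mean_range = as.numeric(baseline_log_mean_range),
    seed = as.numeric(seed)
  ), class = "ff_cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, why) {
    stop_domain("invalid cohort configuration: field '", field, "' ", why)
  }
  for (f in c("n_pcos_patients", "n_control_patients", "repeats_per_fluid",
              "n_proteins")) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v < 1) bad(f, "must be a count >= 1")
  }
  r <- cfg$fluids_per_patient_range
  if (length(r) != 2 || any(is.na(r)) || r[1] < 1 || r[2] < r[1]) {
    bad("fluids_per_patient_range", "must be an inclusive integer range >= 1")
  }
  eff <- cfg$effects
  if (!is.data.frame(eff) || !all(c("protein", "log2_fc") %in% names(eff))) {
    bad("effects", "must be a data.frame with columns protein, log2_fc")
  }
  if (anyDuplicated(eff$protein)) bad("effects", "protein indices must be distinct")
  if (nrow(eff) > 0 && (any(eff$protein < 1) || any(eff$protein > cfg$n_proteins))) {
    bad("effects", "protein indices must lie in 1..n_proteins")
  }
  if (length(cfg$block_proteins) > 0 &&
      (any(cfg$block_proteins < 1) || any(cfg$block_proteins > cfg$n_proteins))) {
    bad("block_proteins", "indices must lie in 1..n_proteins")
  }
  if (!is.null(cfg$anti_protein)) {
    if (cfg$anti_protein %in% cfg$block_proteins) {
      bad("anti_protein", "must not be a member of block_proteins")
    }
    if (cfg$anti_protein < 1 || cfg$anti_protein > cfg$n_proteins) {
      bad("anti_protein", "must lie in 1..n_proteins")
    }
  }
  if (!(cfg$block_rho > 0 && cfg$block_rho < 1)) {
    bad("block_rho", "must lie strictly in (0, 1)")
  }
  for (f in c("patient_sd", "fluid_sd", "repeat_sd", "repeat_sd_spread")) {
    if (cfg[[f]] < 0) bad(f, "must be >= 0")
  }
  b <- cfg$baseline_log_mean_range
  if (length(b) != 2 || b[2] < b[1]) {
    bad("baseline_log_mean_range", "must be a non-empty interval")
  }
  invisible(cfg)
}

#' Simulate a synthetic follicular-fluid proteome cohort
#'
#' Draws a complete abundance dataset from a [cohort_config()]: natural-log
#' intensities are the sum of a per-protein baseline, patient, fluid and
#' repeat random intercepts, a shared latent factor for the correlated
#' block, and a `ln(2) * log2_fc` group shift for effect proteins in PCOS
#' rows; the matrix is then exponentiated, so intensities are strictly
#' positive and lognormal.  Identical configurations (including the seed)
#' give bit-identical datasets.
#'
#' @param config an `ff_cohort_config`.
#' @return An `ff_dataset`: list with `intensities` (rows = measurement
#'   repeats, columns = proteins) and `samples` (data.frame `row_id,
#'   patient_id, group, fluid_id, repeat_index`).
#' @export
#' @examples
#' d <- simulate_cohort(cohort_config(n_pcos_patients = 3,
#'                                    n_control_patients = 3,
#'                                    n_proteins = 25, seed = 7))
#' dim(d$intensities)
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    n_pat <- config$n_pcos_patients + config$n_control_patients
    patient_id <- sprintf("P%03d", seq_len(n_pat))
    group <- rep(c("pcos", "control"),
                 c(config$n_pcos_patients, config$n_control_patients))
    r <- config$fluids_per_patient_range
    n_fluids_per <- if (r[1] == r[2]) {
      rep(r[1], n_pat)
    } else {
      sample(seq(r[1], r[2]), n_pat, replace = TRUE)
    }
    n_fluids <- sum(n_fluids_per)
    fluid_patient <- rep(seq_len(n_pat), n_fluids_per)
    fluid_id <- sprintf("F%04d", seq_len(n_fluids))
    k <- config$repeats_per_fluid
    row_fluid <- rep(seq_len(n_fluids), each = k)
    n <- n_fluids * k
    samples <- data.frame(
      row_id = sprintf("R%05d", seq_len(n)),
      patient_id = patient_id[fluid_patient[row_fluid]],
      group = group[fluid_patient[row_fluid]],
      fluid_id = fluid_id[row_fluid],
      repeat_index = rep(seq_len(k), n_fluids),
      stringsAsFactors = FALSE
    )

    p <- config$n_proteins
    baseline <- runif(p, config$baseline_log_mean_range[1],
                      config$baseline_log_mean_range[2])
    # per-protein technical sd: lognormal spread around repeat_sd
    tech_sd <- config$repeat_sd *
      exp(rnorm(p, 0, config$repeat_sd_spread))

    # latent-factor loadings for the correlated block
    lambda <- numeric(p)
    lambda[config$block_proteins] <- sqrt(config$block_rho)
    if (!is.null(config$anti_protein)) {
      lambda[config$anti_protein] <- -sqrt(config$block_rho)
    }
    own <- sqrt(1 - lambda^2)

    level_effect <- function(n_units, sd_vec) {
      z_latent <- rnorm(n_units)
      z_own <- matrix(rnorm(n_units * p), n_units, p)
      eff <- z_own * rep(own, each = n_units) +
        outer(z_latent, lambda)
      eff * rep(sd_vec, each = n_units)
    }
    pat_eff <- level_effect(n_pat, rep(config$patient_sd, p))
    flu_eff <- level_effect(n_fluids, rep(config$fluid_sd, p))
    rep_eff <- level_effect(n, tech_sd)

    beta <- numeric(p)
    beta[config$effects$protein] <- config$effects$log2_fc
    is_pcos <- samples$group == "pcos"

    lnX <- rep(baseline, each = n) +
      pat_eff[fluid_patient[row_fluid], , drop = FALSE] +
      flu_eff[row_fluid, , drop = FALSE] +
      rep_eff +
      outer(as.numeric(is_pcos), beta * log(2))
    intensities <- exp(lnX)
    dimnames(intensities) <- list(samples$row_id, sprintf("prot_%04d", seq_len(p)))
    ff_dataset(intensities, samples)
  })
}

#' Construct and validate an abundance dataset
#'
#' @param intensities strictly positive numeric matrix, rows = measurement
#'   repeats, columns = proteins (unique column names).
#' @param samples data.frame with columns `row_id, patient_id, group,
#'   fluid_id, repeat_index`, aligned with the matrix rows.
#' @return An object of class `ff_dataset`.
#' @export
ff_dataset <- function(intensities, samples) {
  d <- structure(list(intensities = intensities, samples = samples),
                 class = "ff_dataset")
  validate_ff_dataset(d)
  d
}

validate_ff_dataset <- function(d) {
  m <- d$intensities
  s <- d$samples
  need <- c("row_id", "patient_id", "group", "fluid_id", "repeat_index")
  if (!all(need %in% names(s))) {
    stop_domain("sample metadata must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(m) != nrow(s)) {
    stop_domain("intensity matrix has ", nrow(m), " rows but metadata has ",
                nrow(s))
  }
  if (!all(is.finite(m)) || any(m <= 0)) {
    stop_domain("intensities must be finite and strictly positive")
  }
  if (anyDuplicated(colnames(m)) || is.null(colnames(m))) {
    stop_domain("protein identifiers must be present and unique")
  }
  if (!all(s$group %in% c("pcos", "control"))) {
    stop_domain("group labels must be 'pcos' or 'control'")
  }
  if (any(s$repeat_index < 1)) stop_domain("repeat_index must be >= 1")
  if (anyDuplicated(paste(s$fluid_id, s$repeat_index))) {
    stop_domain("(fluid_id, repeat_index) pairs must be unique")
  }
  if (any(tapply(s$patient_id, s$fluid_id, function(x) length(unique(x))) > 1)) {
    stop_domain("every fluid must belong to exactly one patient")
  }
  if (any(tapply(s$group, s$patient_id, function(x) length(unique(x))) > 1)) {
    stop_domain("every patient must belong to exactly one group")
  }
  invisible(d)
}

#' @export
print.ff_dataset <- function(x, ...) {
  s <- x$samples
  cat("ff_dataset: ", nrow(x$intensities), " measurement rows, ",
      ncol(x$intensities), " proteins\n", sep = "")
  cat("  patients: ", length(unique(s$patient_id)),
      " (pcos ", length(unique(s$patient_id[s$group == "pcos"])),
      " / control ", length(unique(s$patient_id[s$group == "control"])),
      "), fluids: ", length(unique(s$fluid_id)), "\n", sep = "")
  invisible(x)
}
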