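# End-to-end orchestration: simulate (or load) -> score -> select ->
# effects -> correlate -> report, with a JSON run manifest for
# reproducibility.  Every stage failure is re-raised with the stage name
# so a broken input is attributable.

#' Pipeline run configuration
#'
#' @param cohort an [cohort_config()] for simulate mode, or `NULL` to read
#'   an existing dataset from `matrix_path`/`metadata_path`.
#' @param matrix_path,metadata_path TSV inputs (ignored in simulate mode).
#' @param forest [forest_params()] for all forests.
#' @param n_folds grouped-CV folds.
#' @param n_cycles RFECV cycles for score accumulation.
#' @param step RFECV elimination step (see [rfecv_run()]).
#' @param outlier_k IQR multiplier of [select_outlier_proteins()].
#' @param n_boot,level bootstrap settings for [estimate_all()].
#' @param gamma winsorisation proportion for [wincor_matrix()].
#' @param effects_scope `"selected"` (default) to estimate effects for the
#'   selected proteins only, `"all"` for every protein.
#' @param seed master seed; all stage seeds are derived from it.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return An object of class `ff_run_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            matrix_path = NULL, metadata_path = NULL,
                            forest = forest_params(),
                            n_folds = 20, n_cycles = 30, step = 1,
                            outlier_k = 1.5, n_boot = 10000, level = 0.95,
                            gamma = 0.2,
                            effects_scope = c("selected", "all"),
                            seed = 1, out_dir = tempfile("ffproteo_run_"),
                            quiet = FALSE) {
  effects_scope <- match.arg(effects_scope)
  if (is.null(cohort)) {
    if (is.null(matrix_path) || is.null(metadata_path)) {
      stop_domain("non-simulate mode needs matrix_path and metadata_path")
    }
  }
  structure(list(cohort = cohort, matrix_path = matrix_path,
                 metadata_path = metadata_path, forest = forest,
                 n_folds = as.integer(n_folds),
                 n_cycles = as.integer(n_cycles), step = step,
                 outlier_k = outlier_k, n_boot = as.integer(n_boot),
                 level = level, gamma = gamma,
                 effects_scope = effects_scope, seed = as.numeric(seed),
                 out_dir = out_dir, quiet = isTRUE(quiet)),
            class = "ff_run_config")
}

run_stage <- function(name, quiet, expr) {
  if (!quiet) message("[ffproteo] stage '", name, "' ...")
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

write_tsv_ <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "n_boot" &
    !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.15g", df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes simulate/load, persistence scoring, outlier selection, effect
#' estimation, winsorised correlation and report assembly, writing
#' `scores.tsv`, `effects.tsv`, `corr.tsv`, `report.tsv` (and in simulate
#' mode `matrix.tsv`/`metadata.tsv`) plus `manifest.json` to
#' `config$out_dir`.  Identical config + seed produces byte-identical TSV
#' outputs.
#'
#' @param config an [pipeline_config()].
#' @return Invisibly, a list with the report table, all stage results and
#'   the artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ff_run_config"))
  quiet <- config$quiet
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  artifacts <- character(0)

  dataset <- if (!is.null(config$cohort)) {
    run_stage("simulate", quiet, {
      d <- simulate_cohort(config$cohort)
      paths <- write_dataset(d, file.path(config$out_dir, "matrix.tsv"),
                             file.path(config$out_dir, "metadata.tsv"))
      artifacts <- c(artifacts, paths)
      d
    })
  } else {
    run_stage("metadata", quiet, {
      if (!file.exists(config$metadata_path)) {
        stop("metadata file not found: ", config$metadata_path)
      }
      NULL
    })
    run_stage("matrix", quiet, {
      if (!file.exists(config$matrix_path)) {
        stop("matrix file not found: ", config$matrix_path)
      }
      read_dataset(config$matrix_path, config$metadata_path)
    })
  }

  X <- log2(dataset$intensities)
  y <- factor(dataset$samples$group, levels = c("control", "pcos"))
  records <- dataset$samples

  scores <- run_stage("score", quiet, {
    accumulate_scores(X, y, records, config$forest,
                      n_folds = config$n_folds, n_cycles = config$n_cycles,
                      step = config$step, seed = derive_seed(config$seed, 11))
  })
  selected <- run_stage("select", quiet, {
    select_outlier_proteins(scores, k = config$outlier_k)
  })
  scores$selected <- scores$protein_id %in% selected

  fl <- run_stage("aggregate", quiet, aggregate_repeats(dataset))
  effects <- run_stage("effects", quiet, {
    wanted <- if (config$effects_scope == "all") "all" else selected
    if (!identical(wanted, "all") && length(wanted) == 0) {
      stop("no proteins selected; nothing to estimate")
    }
    estimate_all(fl, proteins = wanted, n_boot = config$n_boot,
                 level = config$level, seed = derive_seed(config$seed, 12))
  })
  correlation <- run_stage("correlate", quiet, {
    if (length(selected) >= 2) {
      wincor_matrix(fl$values[, selected, drop = FALSE], gamma = config$gamma)
    } else {
      NULL
    }
  })
  final_bacc <- run_stage("evaluate", quiet, {
    if (length(selected) >= 1) {
      evaluate_final_classifier(X[, selected, drop = FALSE], y, records,
                                config$forest, n_folds = config$n_folds,
                                seed = derive_seed(config$seed, 13))
    } else {
      NA_real_
    }
  })

  report <- run_stage("report", quiet, {
    eff_sel <- effects[effects$protein_id %in% selected, , drop = FALSE]
    rep <- merge(scores[scores$selected,
                        c("protein_id", "score"), drop = FALSE],
                 eff_sel[, c("protein_id", "log2_fc", "ci_low", "ci_high",
                             "significant")],
                 by = "protein_id")
    rep <- rep[order(-rep$score, -abs(rep$log2_fc), rep$protein_id), ,
               drop = FALSE]
    rownames(rep) <- NULL
    rep
  })

  out <- config$out_dir
  artifacts <- c(artifacts,
                 write_tsv_(scores, file.path(out, "scores.tsv")),
                 write_tsv_(effects, file.path(out, "effects.tsv")))
  if (!is.null(correlation)) {
    cm <- data.frame(protein_id = correlation$proteins,
                     correlation$r, check.names = FALSE,
                     stringsAsFactors = FALSE)
    artifacts <- c(artifacts, write_tsv_(cm, file.path(out, "corr.tsv")))
  }
  artifacts <- c(artifacts, write_tsv_(report, file.path(out, "report.tsv")))

  wall <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest_path <- make_manifest(
    config,
    stage_seeds = list(score = derive_seed(config$seed, 11),
                       effects = derive_seed(config$seed, 12),
                       evaluate = derive_seed(config$seed, 13)),
    artifacts = artifacts,
    path = file.path(out, "manifest.json"),
    extra = list(final_balanced_accuracy = final_bacc,
                 n_selected = length(selected),
                 wall_clock_sec = wall)
  )
  if (!quiet) {
    message("[ffproteo] ", length(selected), " proteins selected; ",
            "final grouped-CV balanced accuracy ",
            sprintf("%.3f", final_bacc))
  }
  invisible(list(report = report, scores = scores, selected = selected,
                 effects = effects, correlation = correlation,
                 final_balanced_accuracy = final_bacc,
                 artifacts = artifacts, manifest = manifest_path,
                 dataset = dataset))
}

config_to_list <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$cohort)) {
    ch <- unclass(cfg$cohort)
    ch$effects <- as.list(ch$effects)
    cfg$cohort <- ch
  }
  cfg$forest <- unclass(cfg$forest)
  cfg
}

config_from_list <- function(lst) {
  cohort <- if (!is.null(lst$cohort)) {
    ch <- lst$cohort
    eff <- as.data.frame(ch$effects, stringsAsFactors = FALSE)
    cohort_config(
      n_pcos_patients = ch$n_pcos_patients,
      n_control_patients = ch$n_control_patients,
      fluids_per_patient_range = unlist(ch$fluids_per_patient_range),
      repeats_per_fluid = ch$repeats_per_fluid,
      n_proteins = ch$n_proteins,
      effects = eff,
      block_proteins = unlist(ch$block_proteins),
      anti_protein = ch$anti_protein,
      block_rho = ch$block_rho,
      patient_sd = ch$patient_sd, fluid_sd = ch$fluid_sd,
      repeat_sd = ch$repeat_sd, repeat_sd_spread = ch$repeat_sd_spread,
      baseline_log_mean_range = unlist(ch$baseline_log_mean_range),
      seed = ch$seed)
  } else {
    NULL
  }
  fp <- lst$forest
  pipeline_config(
    cohort = cohort,
    matrix_path = lst$matrix_path, metadata_path = lst$metadata_path,
    forest = forest_params(fp$n_trees, fp$max_depth, fp$min_samples_leaf,
                           fp$features_per_split, fp$bootstrap_rows, fp$seed),
    n_folds = lst$n_folds, n_cycles = lst$n_cycles, step = lst$step,
    outlier_k = lst$outlier_k, n_boot = lst$n_boot, level = lst$level,
    gamma = lst$gamma, effects_scope = lst$effects_scope, seed = lst$seed,
    out_dir = lst$out_dir, quiet = lst$quiet)
}

#' Write a run manifest
#'
#' Records the full configuration, stage seeds, package and R versions and
#' the md5 checksum of every artifact, so a completed run can be replayed
#' and verified byte-for-byte with [replay_run()].
#'
#' @param config the `ff_run_config` of the completed run.
#' @param stage_seeds named list of derived stage seeds.
#' @param artifacts character vector of artifact paths (nonempty).
#' @param path manifest output path.
#' @param extra optional named list of run summary values.
#' @return The manifest path, invisibly.
#' @export
make_manifest <- function(config, stage_seeds, artifacts, path,
                          extra = list()) {
  if (length(artifacts) == 0) stop_domain("artifact list must be nonempty")
  sums <- tools::md5sum(artifacts)
  manifest <- c(list(
    package = "ffproteo",
    version = as.character(utils::packageVersion("ffproteo")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    stage_seeds = stage_seeds,
    config = config_to_list(config),
    artifacts = lapply(seq_along(artifacts), function(i) {
      list(file = basename(artifacts[i]), md5 = unname(sums[i]))
    })
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Replay a run from its manifest and verify checksums
#'
#' Re-runs the pipeline with the configuration and seed stored in a
#' manifest, into a fresh directory, and compares the md5 checksum of
#' every TSV artifact with the recorded one.  Any mismatch raises a
#' reproducibility error.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir scratch directory for the replay.
#' @return TRUE invisibly on success.
#' @export
replay_run <- function(manifest_path, out_dir = tempfile("ffproteo_replay_")) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  cfg_lst <- man$config
  cfg_lst$out_dir <- out_dir
  cfg_lst$quiet <- TRUE
  config <- config_from_list(cfg_lst)
  run_pipeline(config)
  arts <- man$artifacts
  for (i in seq_len(nrow(arts))) {
    f <- file.path(out_dir, arts$file[i])
    if (!file.exists(f)) {
      stop_domain("reproducibility error: artifact '", arts$file[i],
                  "' missing on replay")
    }
    new_md5 <- unname(tools::md5sum(f))
    if (!identical(new_md5, arts$md5[i])) {
      stop_domain("reproducibility error: checksum mismatch for '",
                  arts$file[i], "'")
    }
  }
  invisible(TRUE)
}
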