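# End-to-end orchestration: simulate -> extract -> differential -> predict,
# driven by a config, with deterministic seeding and a run manifest.

#' Pipeline configuration
#'
#' Collects every stage option with its default, so a run manifest records the
#' fully resolved configuration. One global seed fans out to per-stage seeds
#' by fixed offsets, giving stage-level reproducibility without cross-stage
#' coupling.
#'
#' @param out_dir Output directory (created if missing).
#' @param cohort A [cohort_config()] (defaults to the emulated study
#'   conditions).
#' @param wpm_mode,sc_window Linguistic feature options.
#' @param voicing_threshold,intensity_gate_db Acoustic feature options.
#' @param fdr_mode FDR family mode for [differential_analysis()].
#' @param C_grid,inner_folds,bootstrap_B,ci_level Prediction options.
#' @param n_hisoc_items Items included in the `HiSoC_all` feature set.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("uhrspeech_run_"),
                            cohort = NULL,
                            wpm_mode = "x0.75", sc_window = 5,
                            voicing_threshold = 0.45, intensity_gate_db = 10,
                            fdr_mode = "within_contrast",
                            C_grid = 10^(-3:2), inner_folds = 5,
                            bootstrap_B = 1000, ci_level = 0.95,
                            n_hisoc_items = 15,
                            seed = 1L) {
  if (is.null(cohort)) cohort <- cohort_config(seed = seed)
  structure(list(out_dir = out_dir, cohort = cohort, wpm_mode = wpm_mode,
                 sc_window = sc_window, voicing_threshold = voicing_threshold,
                 intensity_gate_db = intensity_gate_db, fdr_mode = fdr_mode,
                 C_grid = C_grid, inner_folds = inner_folds,
                 bootstrap_B = bootstrap_B, ci_level = ci_level,
                 n_hisoc_items = n_hisoc_items, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `cohort` block
#' mirrors [cohort_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort <- NULL
  if (!is.null(raw$cohort)) {
    ca <- raw$cohort
    if (!is.null(ca$group_sizes)) ca$group_sizes <- unlist(ca$group_sizes)
    cohort <- do.call(cohort_config, ca)
  }
  raw$cohort <- cohort
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

write_manifest <- function(config, stage, dir) {
  manifest <- list(stage = stage, seed = config$seed,
                   package_version = as.character(utils::packageVersion("uhrspeech")),
                   options = config[setdiff(names(config), "cohort")],
                   cohort = unclass(config$cohort))
  jsonlite::write_json(manifest, file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Simulate a cohort and write its artifacts to disk
#'
#' Writes one WAV + TextGrid pair per participant, a cohort CSV (covariates,
#' outcome, and the 32 rating columns), the toy embedding table, and a
#' manifest.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$out_dir
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    message("created output directory ", dir)
  }
  sim <- simulate_cohort(config$cohort, audio = TRUE)
  for (id in sim$participants$id) {
    write_wav(sim$recordings[[id]], file.path(dir, paste0(id, ".wav")))
    write_textgrid(sim$transcripts[[id]], file.path(dir, paste0(id, ".TextGrid")))
  }
  utils::write.csv(sim$participants, file.path(dir, "cohort.csv"), row.names = FALSE)
  write_embeddings(sim$embeddings, file.path(dir, "embeddings.txt"))
  write_manifest(config, "simulate", dir)
  message("simulated ", nrow(sim$participants), " participants -> ", dir)
  invisible(dir)
}

#' Extract the feature table from on-disk artifacts
#'
#' Reads each participant's WAV and TextGrid, computes the 4 linguistic and 5
#' acoustic features, joins covariates and rater-averaged item scores, and
#' writes `features.csv`. A participant whose extraction fails is flagged
#' (`extract_ok = FALSE`, feature columns `NA`) and the run continues.
#'
#' @param config A [pipeline_config()].
#' @return The feature table data frame, invisibly.
#' @export
run_extract <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$out_dir
  cohort <- utils::read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  embeddings <- read_embeddings(file.path(dir, "embeddings.txt"))
  feat_names <- c("WPM", "AR", "Dysfluency", "SC",
                  "F0_m", "F0_sd", "Int_m", "Int_sd", "HF500")
  feats <- as.data.frame(matrix(NA_real_, nrow(cohort), length(feat_names),
                                dimnames = list(NULL, feat_names)))
  ok <- logical(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$id[i]
    row <- tryCatch({
      tg <- read_textgrid(file.path(dir, paste0(id, ".TextGrid")))
      tx <- transcript_from_intervals(tg$intervals, tg$total_duration_s)
      rec <- read_wav(file.path(dir, paste0(id, ".wav")), speaker_sex = cohort$sex[i])
      cbind(extract_linguistic(tx, embeddings, wpm_mode = config$wpm_mode,
                               sc_window = config$sc_window),
            extract_acoustic(rec, voicing_threshold = config$voicing_threshold,
                             intensity_gate_db = config$intensity_gate_db))
    }, error = function(e) {
      warning("extraction failed for ", id, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(row)) { feats[i, ] <- row; ok[i] <- TRUE }
  }
  out <- cbind(cohort, feats, extract_ok = ok)
  out <- aggregate_ratings(out)
  utils::write.csv(out, file.path(dir, "features.csv"), row.names = FALSE)
  write_manifest(config, "extract", dir)
  message("extracted features for ", sum(ok), "/", nrow(out), " participants")
  invisible(out)
}

#' Run the differential analysis stage
#'
#' Fits the covariate-adjusted model per feature (both families), writes the
#' contrast table (`contrasts.csv`) and the cohort covariate test table
#' (`cohort_tests.csv`).
#'
#' @param config A [pipeline_config()].
#' @param feature_table Optional feature table; read from `features.csv` in
#'   the output directory when omitted.
#' @return List with `contrasts` and `cohort_tests`, invisibly.
#' @export
run_differential <- function(config, feature_table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$out_dir
  if (is.null(feature_table)) {
    feature_table <- utils::read.csv(file.path(dir, "features.csv"),
                                     stringsAsFactors = FALSE)
  }
  ft <- feature_table[!is.na(feature_table$WPM), , drop = FALSE]
  contrasts <- rbind(
    differential_analysis(ft, c("WPM", "AR", "Dysfluency", "SC"),
                          family = "linguistic", fdr_mode = config$fdr_mode),
    differential_analysis(ft, c("F0_m", "F0_sd", "Int_m", "Int_sd", "HF500"),
                          family = "acoustic", fdr_mode = config$fdr_mode)
  )
  tests <- cohort_covariate_tests(ft)
  utils::write.csv(contrasts, file.path(dir, "contrasts.csv"), row.names = FALSE)
  utils::write.csv(tests, file.path(dir, "cohort_tests.csv"), row.names = FALSE)
  write_manifest(config, "differential", dir)
  invisible(list(contrasts = contrasts, cohort_tests = tests))
}

#' Run the outcome prediction stage
#'
#' Evaluates the five feature sets on the converted-vs-all and remitted-vs-all
#' tasks and writes the 5 x 2 evaluation grid as CSV and JSON plus per-fold
#' details.
#'
#' @param config A [pipeline_config()].
#' @param feature_table Optional feature table; read from `features.csv` when
#'   omitted.
#' @return The [evaluate_feature_sets()] result, invisibly.
#' @export
run_predict <- function(config, feature_table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$out_dir
  if (is.null(feature_table)) {
    feature_table <- utils::read.csv(file.path(dir, "features.csv"),
                                     stringsAsFactors = FALSE)
  }
  ft <- feature_table[!is.na(feature_table$WPM), , drop = FALSE]
  tasks <- list(converted = make_task(ft, "converted"),
                remitted = make_task(ft, "remitted"))
  res <- evaluate_feature_sets(ft, tasks,
                               feature_sets = default_feature_sets(config$n_hisoc_items),
                               C_grid = config$C_grid,
                               inner_folds = config$inner_folds,
                               B = config$bootstrap_B, level = config$ci_level,
                               seed = config$seed + 100L)
  utils::write.csv(res$summary, file.path(dir, "evaluation.csv"), row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  chosen <- lapply(res$details, function(d) d$chosen_C)
  jsonlite::write_json(chosen, file.path(dir, "chosen_C.json"), digits = NA)
  write_manifest(config, "predict", dir)
  invisible(res)
}

#' Run the full pipeline end to end
#'
#' @param config A [pipeline_config()].
#' @return List with the `features` table, `differential` results, and
#'   `prediction` results, invisibly.
#' @export
run_pipeline <- function(config) {
  run_simulate(config)
  features <- run_extract(config)
  differential <- run_differential(config, features)
  prediction <- run_predict(config, features)
  invisible(list(features = features, differential = differential,
                 prediction = prediction))
}
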