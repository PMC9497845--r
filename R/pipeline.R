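#' End-to-end run configuration
#'
#' One master seed deterministically derives every stage seed (cohort,
#' SMOTE, CV folds, permutation draws), so a full run is regenerable from
#' config + seed alone.
#'
#' @param cohort a [cohort_spec()] (its seed is overridden by the derived
#'   stage seed).
#' @param effect an [effect_spec()].
#' @param features a [feature_config()].
#' @param balance a [balance_spec()] for the cancer/no-cancer exercise.
#' @param cv a [cv_config()].
#' @param lsdl list of threshold-search parameters (`n_iterations`,
#'   `levels_per_iteration`, `min_samples`).
#' @param grade_target per-class SMOTE target of the grade exercise
#'   (default 20, the documented reproduction value: 9 -> 20, 13 -> 20).
#' @param leakage_safe re-run SMOTE inside each training fold instead of
#'   the (leakage-prone, protocol-faithful) whole-dataset default.
#' @param output_dir where pipeline commands write.
#' @param seed master integer seed.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(cohort = cohort_spec(), effect = effect_spec(),
                       features = feature_config(), balance = balance_spec(),
                       cv = cv_config(), lsdl = list(n_iterations = 4L,
                                                     levels_per_iteration = 16L,
                                                     min_samples = 8L),
                       grade_target = 20L, leakage_safe = FALSE,
                       output_dir = "lsdl_run", seed = 1L) {
  structure(list(cohort = cohort, effect = effect, features = features,
                 balance = balance, cv = cv, lsdl = lsdl,
                 grade_target = as.integer(grade_target),
                 leakage_safe = isTRUE(leakage_safe),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

# Stage seeds derived from the master seed; kept below 2^31.
derive_seed <- function(master, stage) {
  (as.integer(master) %% 1000003L) * 1009L + as.integer(stage)
}

#' Simulate the on-disk cohort (pipeline stage)
#'
#' Writes the cancer/no-cancer datasets 1 and 2, their concatenation
#' (dataset 3), the grade-cohort pair, and a YAML manifest into
#' `config$output_dir`.
#'
#' @param config a [run_config()].
#' @return named list of written file paths, invisibly.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- config$cohort
  cohort$seed <- derive_seed(config$seed, 1L)
  pair <- generate_cohort(cohort, config$effect)
  ds3 <- concatenate_datasets(pair$dataset1, pair$dataset2, "dataset3")
  gpair <- generate_grade_cohort(cohort, config$effect, config$effect,
                                 replicates = 3L, mode = "pair")
  gds3 <- concatenate_datasets(gpair$dataset1, gpair$dataset2,
                               "grade_dataset3")
  paths <- list()
  all_ds <- list(dataset1 = pair$dataset1, dataset2 = pair$dataset2,
                 dataset3 = ds3, grade_dataset1 = gpair$dataset1,
                 grade_dataset2 = gpair$dataset2, grade_dataset3 = gds3)
  for (nm in names(all_ds)) {
    p <- file.path(config$output_dir, paste0(nm, ".csv"))
    write_spectra_csv(all_ds[[nm]], p)
    paths[[nm]] <- p
  }
  manifest <- lapply(names(all_ds), function(nm)
    list(path = basename(paths[[nm]]), name = nm,
         n = length(all_ds[[nm]]$spectra),
         acquisition_mode = all_ds[[nm]]$spectra[[1]]$acquisition_mode))
  names(manifest) <- names(all_ds)
  mp <- file.path(config$output_dir, "manifest.yaml")
  write_manifest(manifest, mp)
  paths$manifest <- mp
  message(sprintf("simulated %s", paste(sprintf("%s(n=%d)", names(all_ds),
          vapply(all_ds, function(d) length(d$spectra), integer(1))),
          collapse = ", ")))
  invisible(paths)
}

# Feature table of a dataset, excluding signals flagged by lsdl_apply.
subsignal_features <- function(model, dataset, config) {
  subs <- suppressWarnings(lsdl_apply(model, dataset))
  flagged <- attr(subs, "flagged")
  if (any(flagged))
    message(sprintf("excluding %d flagged signal(s)", sum(flagged)))
  cfg <- config; cfg$reduced_after_lsdl <- TRUE
  extract_feature_matrix(subs[!flagged], cfg,
                         labels = dataset_labels(dataset)[!flagged])
}

#' Full reproduction run (pipeline stage)
#'
#' Simulates the cohorts, learns one decomposition per acquisition
#' protocol (datasets 1 and 2; dataset 3 is decomposed per origin subset
#' with its own learned parameters), benchmarks the nine models on the
#' raw-spectrum and decomposed representations for the cancer/no-cancer
#' exercise and on the decomposed representation for the grade exercise,
#' and writes all result tables, both threshold-search tables, PCA
#' projections and a provenance report under `config$output_dir`.
#'
#' @param config a [run_config()].
#' @return list with `tables` (9 metrics tables), `lsdl_models`,
#'   `pca` (raw + lsdl projections) and `report`, invisibly.
#' @export
cmd_reproduce <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  cohort <- config$cohort
  cohort$seed <- derive_seed(config$seed, 1L)
  pair <- generate_cohort(cohort, config$effect)
  gpair <- generate_grade_cohort(cohort, config$effect, config$effect,
                                 replicates = 3L, mode = "pair")

  bal <- config$balance
  bal$seed <- derive_seed(config$seed, 2L)
  cv <- config$cv
  cv$seed <- derive_seed(config$seed, 3L)
  fold_balance <- if (config$leakage_safe) bal else NULL
  balance_now <- function(fm, spec) {
    if (config$leakage_safe) fm else smote_balance(fm, spec)
  }

  message(if (config$leakage_safe)
    "balancing mode: leakage-safe (SMOTE inside each training fold)"
    else "balancing mode: protocol-faithful (SMOTE before cross-validation)")

  # raw representation -------------------------------------------------
  raw_cfg <- config$features; raw_cfg$reduced_after_lsdl <- FALSE
  raw1 <- extract_feature_matrix(pair$dataset1, raw_cfg)
  raw2 <- extract_feature_matrix(pair$dataset2, raw_cfg)
  raw1b <- balance_now(raw1, bal)
  raw2b <- balance_now(raw2, bal)
  raw3b <- rbind(raw1b, raw2b)

  # decomposed representation ------------------------------------------
  search <- function(ds) lsdl_threshold_search(
    ds, config$features,
    n_iterations = config$lsdl$n_iterations,
    levels_per_iteration = config$lsdl$levels_per_iteration,
    min_samples = config$lsdl$min_samples, keep_features = FALSE)
  m1 <- search(pair$dataset1)
  m2 <- search(pair$dataset2)
  lsdl1 <- subsignal_features(m1, pair$dataset1, config$features)
  lsdl2 <- subsignal_features(m2, pair$dataset2, config$features)
  lsdl1b <- balance_now(lsdl1, bal)
  lsdl2b <- balance_now(lsdl2, bal)
  lsdl3b <- rbind(lsdl1b, lsdl2b)

  # grade exercise (decomposed representation only) --------------------
  gbal <- balance_spec(k_neighbors = min(bal$k_neighbors, 5L),
                       target_per_class = config$grade_target,
                       seed = derive_seed(config$seed, 4L))
  g1 <- subsignal_features(m1, gpair$dataset1, config$features)
  g2 <- subsignal_features(m2, gpair$dataset2, config$features)
  g1b <- balance_now(g1, gbal)
  g2b <- balance_now(g2, gbal)
  g3b <- rbind(g1b, g2b)

  tabs <- run_grid(list(raw_dataset1 = raw1b, raw_dataset2 = raw2b,
                        raw_dataset3 = raw3b,
                        lsdl_dataset1 = lsdl1b, lsdl_dataset2 = lsdl2b,
                        lsdl_dataset3 = lsdl3b,
                        grade_lsdl_dataset1 = g1b, grade_lsdl_dataset2 = g2b,
                        grade_lsdl_dataset3 = g3b),
                   cv = cv, balance = fold_balance)

  for (nm in names(tabs))
    write_metrics_csv(tabs[[nm]], file.path(out, paste0(nm, "_metrics.csv")))
  write_search_table(m1, file.path(out, "lsdl_search_dataset1.csv"))
  write_search_table(m2, file.path(out, "lsdl_search_dataset2.csv"))
  write_lsdl_model(m1, file.path(out, "lsdl_model_dataset1.json"))
  write_lsdl_model(m2, file.path(out, "lsdl_model_dataset2.json"))

  pca_raw <- pca_projection(raw1b)
  pca_lsdl <- pca_projection(lsdl1b)
  plot_pca_projection(pca_raw, file.path(out, "pca_raw_dataset1.png"),
                      main = "Raw spectra features")
  plot_pca_projection(pca_lsdl, file.path(out, "pca_lsdl_dataset1.png"),
                      main = "Decomposed features")

  report <- list(
    seed = config$seed,
    stage_seeds = list(cohort = cohort$seed, smote = bal$seed,
                       cv = cv$seed, grade_smote = gbal$seed),
    leakage_safe = config$leakage_safe,
    counts = list(
      dataset1 = nrow(raw1b), dataset2 = nrow(raw2b), dataset3 = nrow(raw3b),
      cancer_cumulative = nrow(raw1b) + nrow(raw2b) + nrow(raw3b),
      grade_dataset1 = nrow(g1b), grade_dataset2 = nrow(g2b),
      grade_dataset3 = nrow(g3b),
      grade_cumulative = nrow(g1b) + nrow(g2b) + nrow(g3b)),
    lsdl = list(
      dataset1 = list(direction = m1$scheme$direction,
                      level = m1$scheme$level,
                      iteration = m1$scheme$iteration),
      dataset2 = list(direction = m2$scheme$direction,
                      level = m2$scheme$level,
                      iteration = m2$scheme$iteration)),
    n_tables = length(tabs),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("lsdlspectra")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(tables = tabs, lsdl_models = list(m1, m2),
                 pca = list(raw = pca_raw, lsdl = pca_lsdl),
                 report = report))
}
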