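#' Run configuration with study-scale defaults
#'
#' All tunable parameters of the workflow with defaults equal to the study's
#' stated design wherever it states one (cohort sizes, thresholds, sweep
#' bounds); the remaining values are the package's documented choices. The
#' configuration serializes losslessly to JSON via [write_run_config()].
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # synthetic truth
    effect_log2_magnitude = 1,
    null_simulation = FALSE,
    noise = simulation_truth(),
    # discovery phase
    n_cases_discovery = 10L, discovery_control_ratio = 1L,
    hormone_fraction_discovery = 0.5,
    age_range_discovery = c(15L, 19L),
    n_mirnas = 754L,
    max_discordance = 1.0, ct_max = 34, max_missing_fraction = 0.5,
    outlier_flagging = TRUE, outlier_alpha = 0.05,
    n_references = 5L, p_strong = 0.005, p_both = 0.05,
    # replication phase
    n_cases = 54L, control_ratio = 2L, hormone_fraction = 0.78,
    age_range = c(13L, 25L),
    pathology_unconfirmed_rate = 14 / 36,
    n_literature = 8L, n_positive_controls = 3L, n_negative_controls = 3L,
    blank_wells = 3L, qc_fraction = 0.05,
    shift_value = 0.001, background_subtract = FALSE,
    p_gate = 0.15, cfs_folds = 10L, cfs_majority = 0.5,
    train_fraction = 2 / 3, split_strata = c("group", "hormone_use"),
    # model construction
    n_networks = 15000L, top_k = 50L, max_iter = 200L, l2 = 1e-4,
    # evaluation
    threshold = 0.5, ci_level = 0.95,
    sensitivity_analysis = FALSE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: the
#'   restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$noise <- unclass(x$noise)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  eff <- x$noise$effects
  x$noise$effects <- effect_spec(as.character(eff$mirna_id),
                                 as.character(eff$stratum),
                                 as.numeric(eff$log2_effect))
  x$noise <- structure(x$noise, class = "simulation_truth")
  for (f in c("seed", "n_cases_discovery", "discovery_control_ratio",
              "n_mirnas", "n_references", "n_cases", "control_ratio",
              "n_literature", "n_positive_controls", "n_negative_controls",
              "blank_wells", "cfs_folds", "n_networks", "top_k", "max_iter")) {
    x[[f]] <- as.integer(x[[f]])
  }
  structure(x, class = "run_config")
}

# deterministic fan-out of named sub-seeds from the master seed
fan_out_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(2^31 - 2, 8),
                  c("discovery_cohort", "ct", "replication_cohort", "mfi",
                    "split", "cfs", "ensemble", "sensitivity"))
}

# discovery phase over a simulated qPCR cohort; returns the candidate list
run_discovery <- function(config, truth, seeds) {
  cohort <- simulate_cohort(config$n_cases_discovery,
                            config$discovery_control_ratio,
                            config$hormone_fraction_discovery,
                            config$age_range_discovery,
                            seed = seeds[["discovery_cohort"]],
                            phase = "discovery")
  ct <- simulate_ct_matrix(cohort, truth, config$n_mirnas, seed = seeds[["ct"]])
  collapsed <- collapse_duplicates(ct, config$max_discordance)
  if (config$outlier_flagging) {
    groups <- cohort$group[match(colnames(collapsed$values), cohort$sample_id)]
    collapsed <- flag_outliers(collapsed, groups, config$outlier_alpha)
  }
  qc <- qc_filter(collapsed, config$ct_max, config$max_missing_fraction)
  imputed <- impute_missing(qc$ct, cohort)
  expr <- global_normalize(imputed)
  groups <- cohort$group[match(colnames(expr$values), cohort$sample_id)]
  ranking <- normfinder_stability(expr, groups)
  expr$reference_set <- select_references(ranking, config$n_references)
  tests <- stratified_ttests(expr, cohort)
  rule <- discovery_selection_rule(tests$p_hormone, tests$p_nonhormone,
                                   config$p_strong, config$p_both)
  tests <- cbind(tests, rule)
  list(cohort = cohort, qc_report = qc$report, expr = expr,
       stability = ranking, reference_set = expr$reference_set,
       selection = tests,
       selected = tests$mirna_id[tests$included])
}

# replication feature selection + model construction + evaluation on one
# feature table (shared by the main analysis and the sensitivity rerun)
run_model_stage <- function(features, config, seeds, panel) {
  candidates_all <- panel$probe_id[panel$category %in% c("discovery", "literature")]
  uni <- univariate_tests(features, training_only = TRUE,
                          probes = attr(features, "probes"))
  gate <- uni$probe_id[uni$probe_id %in% candidates_all &
                         !is.na(uni$p_raw) & uni$p_raw <= config$p_gate]
  pca <- pca_separation(features, training_only = TRUE)
  fs <- cfs_select(features, gate, forced = "hormone_use",
                   folds = config$cfs_folds, seed = seeds[["cfs"]],
                   majority = config$cfs_majority)
  df <- as.data.frame(features)
  model_cols <- c(fs$selected, fs$forced)
  x_all <- as.matrix(df[, model_cols, drop = FALSE])
  storage.mode(x_all) <- "double"
  y_all <- as.integer(df$group == "case")
  tr <- df$split == "train"
  ens <- ensemble_search(x_all[tr, , drop = FALSE], y_all[tr],
                         n_networks = config$n_networks, top_k = config$top_k,
                         seed = seeds[["ensemble"]],
                         max_iter = config$max_iter, l2 = config$l2)
  final <- select_final(ens, x_all[!tr, , drop = FALSE], y_all[!tr])
  prob_train <- predict_proba(final$model, x_all[tr, , drop = FALSE])
  prob_test <- predict_proba(final$model, x_all[!tr, , drop = FALSE])
  list(univariate = uni, pca = pca, feature_set = fs,
       ensemble_manifest = ens$manifest, final = final,
       confusion_train = confusion_at_threshold(prob_train, y_all[tr],
                                                config$threshold, config$ci_level),
       confusion_test = confusion_at_threshold(prob_test, y_all[!tr],
                                               config$threshold, config$ci_level),
       roc_test = final$roc)
}

#' Run the whole two-phase workflow on a simulated study
#'
#' Simulates a discovery cohort and qPCR matrix, runs the discovery
#' statistics and candidate selection, assembles the replication panel
#' (candidates + literature additions + control probes), simulates the
#' replication cohort and bead-array matrix, performs the 2:1 stratified
#' split, replication feature selection (univariate gate, CFS with forced
#' hormone covariate), the MLP ensemble sweep with test-set final selection,
#' and the ROC/confusion evaluation. When `sensitivity_analysis` is set, the
#' model stage is re-run on the identical split and panel with
#' non-pathology-confirmed cases removed.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_report` with per-stage results, the
#'   recovery summary against the simulation truth, and the seeds used.
#' @export
run_pipeline <- function(config = run_config()) {
  seeds <- fan_out_seeds(config$seed)
  truth <- config$noise
  if (config$null_simulation) {
    truth$effects <- truth$effects[0, , drop = FALSE]
  } else if (nrow(truth$effects) > 0) {
    truth$effects$log2_effect <- sign(truth$effects$log2_effect) *
      config$effect_log2_magnitude
  }
  discovery <- run_discovery(config, truth, seeds)

  panel <- assemble_panel(
    discovery$selected,
    literature_additions = if (config$n_literature > 0)
      sprintf("miR-lit-%02d", seq_len(config$n_literature)) else character(0),
    positive_controls = if (config$n_positive_controls > 0)
      sprintf("posctrl-%02d", seq_len(config$n_positive_controls)) else character(0),
    negative_controls = if (config$n_negative_controls > 0)
      sprintf("negctrl-%02d", seq_len(config$n_negative_controls)) else character(0))

  cohort <- simulate_cohort(config$n_cases, config$control_ratio,
                            config$hormone_fraction, config$age_range,
                            seed = seeds[["replication_cohort"]],
                            phase = "replication",
                            pathology_unconfirmed_rate =
                              if (config$sensitivity_analysis)
                                config$pathology_unconfirmed_rate else 0)
  cohort <- stratified_split(cohort, config$train_fraction,
                             config$split_strata, seed = seeds[["split"]])
  mfi <- simulate_mfi_matrix(cohort, truth, panel$probe_id,
                             blank_wells = config$blank_wells,
                             qc_fraction = config$qc_fraction,
                             background_probes =
                               panel$probe_id[panel$category == "negative_control"],
                             seed = seeds[["mfi"]])
  features <- preprocess_mfi(mfi, cohort, config$shift_value,
                             config$background_subtract)
  main <- run_model_stage(features, config, seeds, panel)

  sensitivity <- NULL
  if (config$sensitivity_analysis) {
    keep <- cohort$group == "control" | cohort$pathology_confirmed %in% TRUE
    reduced <- features[features$sample_id %in% cohort$sample_id[keep], ,
                        drop = FALSE]
    attr(reduced, "probes") <- attr(features, "probes")
    class(reduced) <- class(features)
    sensitivity <- run_model_stage(reduced, config, seeds, panel)
  }

  structure(list(config = config, seeds = seeds, truth = truth,
                 discovery = discovery, panel = panel, cohort = cohort,
                 replication = main, sensitivity = sensitivity,
                 recovery = list(
                   discovery = recovery_report(discovery$selected, truth),
                   cfs = recovery_report(main$feature_set$selected, truth))),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Two-phase plasma-miRNA workflow report\n")
  cat(sprintf("  discovery: %d candidates of %d miRNAs (planted recall %.2f)\n",
              length(x$discovery$selected), x$config$n_mirnas,
              x$recovery$discovery$recall))
  cat(sprintf("  panel: %d probes\n", nrow(x$panel)))
  cat(sprintf("  CFS: %d probes + forced %s\n",
              length(x$replication$feature_set$selected),
              paste(x$replication$feature_set$forced, collapse = ",")))
  cat("  testing-set ")
  print(x$replication$roc_test)
  invisible(x)
}

#' Write the pipeline report artifacts to a directory
#'
#' Writes the candidate table, panel, univariate results, ensemble manifest,
#' ROC points, confusion summaries, recovery summary, seeds and config as
#' TSV/JSON files.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  tsv(report$discovery$selection, "discovery_selection.tsv")
  tsv(report$panel, "panel.tsv")
  tsv(report$replication$univariate, "replication_univariate.tsv")
  tsv(report$replication$ensemble_manifest, "ensemble_manifest.tsv")
  tsv(report$replication$roc_test$points, "roc_points_test.tsv")
  summary <- list(
    seeds = as.list(report$seeds),
    discovery_selected = report$discovery$selected,
    reference_set = report$discovery$reference_set,
    panel_size = nrow(report$panel),
    cfs_selected = report$replication$feature_set$selected,
    test_auc = report$replication$roc_test$auc,
    test_auc_p = report$replication$roc_test$p_two_sided,
    confusion_train = unclass(report$replication$confusion_train),
    confusion_test = unclass(report$replication$confusion_test),
    recovery = report$recovery)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  write_run_config(report$config, file.path(dir, "config.json"))
  invisible(dir)
}
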