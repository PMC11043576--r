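#' Planted differential-expression effects
#'
#' An effect specification plants a case-vs-control log2 fold change on one
#' miRNA, restricted to a hormone-use stratum ("hormone", "non_hormone") or
#' present in both ("both"). Positive `log2_effect` means up-regulation in
#' cases (lower Ct, higher fluorescence).
#'
#' @param mirna_id character ids (unique).
#' @param stratum one of "hormone", "non_hormone", "both" per effect.
#' @param log2_effect signed log2 fold changes (nonzero).
#' @return data.frame of class `effect_spec`.
#' @export
effect_spec <- function(mirna_id, stratum, log2_effect) {
  stopifnot(length(mirna_id) == length(stratum),
            length(mirna_id) == length(log2_effect))
  if (anyDuplicated(mirna_id)) stop("duplicate mirna_id in effect spec", call. = FALSE)
  if (!all(stratum %in% c("hormone", "non_hormone", "both"))) {
    stop("stratum must be 'hormone', 'non_hormone' or 'both'", call. = FALSE)
  }
  if (any(log2_effect == 0)) stop("planted log2_effect must be nonzero", call. = FALSE)
  structure(data.frame(mirna_id = as.character(mirna_id),
                       stratum = as.character(stratum),
                       log2_effect = as.numeric(log2_effect),
                       stringsAsFactors = FALSE),
            class = c("effect_spec", "data.frame"))
}

#' Default planted-effect pattern
#'
#' Five planted probes mirroring the three empirical categories of
#' hormone-modified dysregulation: two effects confined to hormone users, two
#' to non-users, and one present in both strata, with mixed directions.
#'
#' @param log2_magnitude absolute planted log2 fold change (default 1).
#' @return an [effect_spec()].
#' @export
default_effects <- function(log2_magnitude = 1) {
  effect_spec(
    mirna_id    = paste0("miR-sim-", sprintf("%04d", 1:5)),
    stratum     = c("hormone", "hormone", "non_hormone", "non_hormone", "both"),
    log2_effect = log2_magnitude * c(1, -1, 1, -1, -1)
  )
}

#' Ground truth for a simulated study
#'
#' Bundles the planted effects with the generator's noise model. Defaults are
#' the package's standing study conditions: Ct measurement noise of 0.20
#' cycles and technical-duplicate scatter of 0.20 cycles (duplicates then
#' agree within ~0.5 cycles, ordinary qPCR quality), 2% missing wells, a
#' per-sample global loading shift of 0.5 cycles that global normalization
#' must remove, and log10-MFI noise of 0.15 (~40% CV on raw fluorescence).
#'
#' @param effects an [effect_spec()] (may have zero rows for a null study).
#' @param reference_mirnas ids simulated with minimal variance (stable
#'   normalization candidates); must be disjoint from the effect ids.
#' @param noise_sd_ct per-measurement Ct noise sd, cycles.
#' @param duplicate_sd sd of the difference between technical duplicates,
#'   cycles.
#' @param missing_rate probability a Ct measurement is missing.
#' @param global_shift_sd sd of the per-sample loading shift, cycles.
#' @param reference_sd residual sd of the reference miRNAs, cycles.
#' @param noise_sd_log10mfi per-measurement log10-MFI noise sd.
#' @param negative_rate probability an arbitrary study-well MFI value is
#'   recorded as a (background-overcorrected) negative number. Default 0:
#'   negatives arise physically at background-level signal, so the generator
#'   produces them through its `background_probes` (see
#'   [simulate_mfi_matrix()]) rather than by corrupting expressed probes.
#' @return list of class `simulation_truth`.
#' @export
simulation_truth <- function(effects = default_effects(),
                             reference_mirnas = paste0("miR-simref-", sprintf("%02d", 1:5)),
                             noise_sd_ct = 0.20,
                             duplicate_sd = 0.20,
                             missing_rate = 0.02,
                             global_shift_sd = 0.5,
                             reference_sd = 0.02,
                             noise_sd_log10mfi = 0.15,
                             negative_rate = 0) {
  if (length(intersect(effects$mirna_id, reference_mirnas))) {
    stop("reference_mirnas must be disjoint from effect miRNAs", call. = FALSE)
  }
  structure(list(effects = effects,
                 reference_mirnas = as.character(reference_mirnas),
                 noise_sd_ct = noise_sd_ct,
                 duplicate_sd = duplicate_sd,
                 missing_rate = missing_rate,
                 global_shift_sd = global_shift_sd,
                 reference_sd = reference_sd,
                 noise_sd_log10mfi = noise_sd_log10mfi,
                 negative_rate = negative_rate),
            class = "simulation_truth")
}

#' Null (no-effect) truth with optional zero noise
#'
#' @param noise if `FALSE`, every noise source is switched off, so downstream
#'   statistics are exactly null.
#' @return a [simulation_truth()].
#' @export
null_truth <- function(noise = TRUE) {
  eff <- effect_spec(character(0), character(0), numeric(0))
  if (noise) {
    simulation_truth(effects = eff)
  } else {
    simulation_truth(effects = eff, noise_sd_ct = 0, duplicate_sd = 0,
                     missing_rate = 0, global_shift_sd = 0, reference_sd = 0,
                     noise_sd_log10mfi = 0, negative_rate = 0)
  }
}

#' Simulate a frequency-matched case-control cohort
#'
#' Cases and `control_ratio` times as many controls; hormone use is drawn
#' Bernoulli(`hormone_fraction`) identically in both groups, so the cohort is
#' frequency-matched on hormone use by construction. Ages are uniform over
#' `age_range`. A fraction of cases can be flagged as lacking pathology
#' confirmation, for the sensitivity re-analysis.
#'
#' @param n_cases number of cases (default 54).
#' @param control_ratio controls per case (default 2).
#' @param hormone_fraction probability of hormone use at blood draw
#'   (default 0.78, the replication-phase rate; the discovery phase used 0.5).
#' @param age_range integer years, default 13-25.
#' @param seed integer seed.
#' @param phase phase label.
#' @param pathology_unconfirmed_rate fraction of cases flagged not
#'   pathology-confirmed (default 0).
#' @return a [cohort_table()].
#' @export
simulate_cohort <- function(n_cases = 54L, control_ratio = 2L,
                            hormone_fraction = 0.78,
                            age_range = c(13L, 25L), seed = 1L,
                            phase = c("replication", "discovery"),
                            pathology_unconfirmed_rate = 0) {
  stopifnot(n_cases >= 1, control_ratio >= 1)
  phase <- match.arg(phase)
  set.seed(seed)
  n_controls <- control_ratio * n_cases
  n <- n_cases + n_controls
  df <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("case", "control"), c(n_cases, n_controls)),
    hormone_use = stats::runif(n) < hormone_fraction,
    age = sample(seq(age_range[1], age_range[2]), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  df$pathology_confirmed <- NA
  df$pathology_confirmed[df$group == "case"] <-
    stats::runif(n_cases) >= pathology_unconfirmed_rate
  cohort_table(df, phase = phase)
}

#' Construct a Ct matrix container
#'
#' @param values miRNA x column numeric matrix of Ct cycles (NA = missing).
#' @param pairs optional data.frame (`sample_id`, `col_a`, `col_b`) pairing
#'   technical-duplicate columns; `NULL` for already-collapsed matrices.
#' @return list of class `ct_matrix`.
#' @export
ct_matrix <- function(values, pairs = NULL) {
  stopifnot(is.matrix(values))
  bad <- !is.na(values) & (values < 0 | values > 40)
  if (any(bad)) stop("Ct values must lie in [0, 40] or be missing", call. = FALSE)
  if (!is.null(pairs)) {
    stopifnot(all(c("sample_id", "col_a", "col_b") %in% names(pairs)))
    missing_cols <- setdiff(c(pairs$col_a, pairs$col_b), colnames(values))
    if (length(missing_cols)) {
      stop("replicate column(s) not in matrix: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(values = values, pairs = pairs), class = "ct_matrix")
}

# expression-scale effect per (miRNA, sample): +log2_effect means
# up-regulated in cases within the stratum
effect_matrix <- function(effects, mirnas, cohort) {
  eff <- matrix(0, nrow = length(mirnas), ncol = nrow(cohort),
                dimnames = list(mirnas, cohort$sample_id))
  if (nrow(effects) == 0) return(eff)
  is_case <- cohort$group == "case"
  for (k in seq_len(nrow(effects))) {
    g <- match(effects$mirna_id[k], mirnas)
    if (is.na(g)) stop("effect miRNA not in panel: ", effects$mirna_id[k],
                       call. = FALSE)
    in_stratum <- switch(effects$stratum[k],
                         hormone = cohort$hormone_use,
                         non_hormone = !cohort$hormone_use,
                         both = rep(TRUE, nrow(cohort)))
    eff[g, is_case & in_stratum] <- effects$log2_effect[k]
  }
  eff
}

#' Simulate a discovery-phase Ct matrix with technical duplicates
#'
#' Baseline Ct per miRNA ~ Uniform(18, 33); a per-sample global loading shift
#' ~ Normal(0, `global_shift_sd`) is added to every miRNA (the artifact that
#' global normalization removes); planted effects lower case Ct by
#' `log2_effect` cycles within their stratum; each technical duplicate adds
#' independent Normal(0, `duplicate_sd`/sqrt(2)) scatter so the A-B difference
#' has sd `duplicate_sd`; measurements go missing with `missing_rate`.
#' Values above 34 are left in place for the QC filter to act on.
#'
#' @param cohort a [cohort_table()].
#' @param truth a [simulation_truth()].
#' @param n_mirnas panel size (default 754); the planted-effect and reference
#'   ids occupy the first rows, the rest are null probes named
#'   `miR-sim-bg-*`.
#' @param seed integer seed.
#' @return a [ct_matrix()] with duplicate columns `<sample>_A`, `<sample>_B`.
#' @export
simulate_ct_matrix <- function(cohort, truth, n_mirnas = 754L, seed = 1L) {
  planted <- unique(c(truth$effects$mirna_id, truth$reference_mirnas))
  if (n_mirnas < length(planted)) {
    stop("n_mirnas must be >= planted effects + references", call. = FALSE)
  }
  set.seed(seed)
  n_bg <- n_mirnas - length(planted)
  mirnas <- c(planted, if (n_bg > 0) paste0("miR-sim-bg-", sprintf("%04d", seq_len(n_bg))))
  n <- nrow(cohort)
  baseline <- stats::runif(n_mirnas, 18, 33)
  shift <- stats::rnorm(n, 0, truth$global_shift_sd)
  eff <- effect_matrix(truth$effects, mirnas, cohort)
  is_ref <- mirnas %in% truth$reference_mirnas
  sd_vec <- ifelse(is_ref, truth$reference_sd, truth$noise_sd_ct)
  # biological/measurement value shared by the two technical duplicates
  mu <- baseline + matrix(shift, n_mirnas, n, byrow = TRUE) - eff +
    matrix(stats::rnorm(n_mirnas * n, 0, 1), n_mirnas, n) * sd_vec
  dup_sd <- truth$duplicate_sd / sqrt(2)
  rep_a <- mu + matrix(stats::rnorm(n_mirnas * n, 0, dup_sd), n_mirnas, n)
  rep_b <- mu + matrix(stats::rnorm(n_mirnas * n, 0, dup_sd), n_mirnas, n)
  values <- matrix(NA_real_, n_mirnas, 2 * n)
  values[, seq(1, 2 * n, by = 2)] <- rep_a
  values[, seq(2, 2 * n, by = 2)] <- rep_b
  cols <- as.vector(rbind(paste0(cohort$sample_id, "_A"),
                          paste0(cohort$sample_id, "_B")))
  dimnames(values) <- list(mirnas, cols)
  if (truth$missing_rate > 0) {
    values[stats::runif(length(values)) < truth$missing_rate] <- NA_real_
  }
  values[] <- pmin(pmax(values, 0), 40)
  pairs <- data.frame(sample_id = cohort$sample_id,
                      col_a = paste0(cohort$sample_id, "_A"),
                      col_b = paste0(cohort$sample_id, "_B"),
                      stringsAsFactors = FALSE)
  ct_matrix(values, pairs)
}

#' Construct an MFI matrix container
#'
#' @param values probe x well numeric matrix of mean fluorescence intensity
#'   (negative values allowed: background over-correction).
#' @param well_role named character vector over the wells: "study", "blank",
#'   or "qc_pool".
#' @return list of class `mfi_matrix`.
#' @export
mfi_matrix <- function(values, well_role) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (!setequal(names(well_role), colnames(values))) {
    stop("well_role must name every well of the matrix", call. = FALSE)
  }
  if (!all(well_role %in% c("study", "blank", "qc_pool"))) {
    stop("well roles must be study/blank/qc_pool", call. = FALSE)
  }
  structure(list(values = values, well_role = well_role[colnames(values)]),
            class = "mfi_matrix")
}

#' Simulate a replication-phase MFI matrix
#'
#' Study wells: log10 MFI ~ Normal(baseline_p, `noise_sd_log10mfi`) plus the
#' stratum-specific planted effect on the log10 scale
#' (`log2_effect * log10(2)`). Blank wells carry low background fluorescence;
#' QC wells replicate one pooled-plasma profile. Probes listed in
#' `background_probes` (e.g. non-human negative-control probes) have no
#' template, so their background-corrected readout scatters around zero and
#' is frequently negative -- these exercise the pre-log shift rule the way
#' the assay produces negatives.
#'
#' @param cohort a [cohort_table()]; one study well per sample.
#' @param truth a [simulation_truth()].
#' @param panel character vector of probe ids (must contain every effect id).
#' @param blank_wells number of water-control wells (default 3).
#' @param qc_fraction pooled-QC wells as a fraction of study wells
#'   (default 0.05).
#' @param background_probes subset of `panel` simulated at background level.
#' @param seed integer seed.
#' @return an [mfi_matrix()].
#' @export
simulate_mfi_matrix <- function(cohort, truth, panel, blank_wells = 3L,
                                qc_fraction = 0.05,
                                background_probes = character(0), seed = 1L) {
  stopifnot(length(panel) > 0)
  set.seed(seed)
  p <- length(panel)
  n <- nrow(cohort)
  n_qc <- round(qc_fraction * n)
  baseline <- stats::runif(p, 2.0, 3.5)  # log10 MFI units
  eff <- effect_matrix(truth$effects[truth$effects$mirna_id %in% panel, , drop = FALSE],
                       panel, cohort) * log10(2)
  log_study <- baseline + eff +
    matrix(stats::rnorm(p * n, 0, truth$noise_sd_log10mfi), p, n)
  study <- 10^log_study
  bg <- panel %in% background_probes
  if (any(bg)) {
    # no template: background-corrected readout scatters around zero
    study[bg, ] <- stats::rnorm(sum(bg) * n, 5, 10)
  }
  if (truth$negative_rate > 0) {
    neg <- stats::runif(length(study)) < truth$negative_rate
    study[neg] <- -stats::runif(sum(neg), 0.1, 5)
  }
  qc <- if (n_qc > 0) {
    qcv <- 10^(baseline + matrix(stats::rnorm(p * n_qc, 0, 0.05), p, n_qc))
    if (any(bg)) qcv[bg, ] <- stats::rnorm(sum(bg) * n_qc, 5, 10)
    qcv
  }
  blank <- if (blank_wells > 0) {
    matrix(stats::rnorm(p * blank_wells, 30, 5), p, blank_wells)
  }
  values <- cbind(study, qc, blank)
  wells <- c(cohort$sample_id,
             if (n_qc > 0) sprintf("QC%02d", seq_len(n_qc)),
             if (blank_wells > 0) sprintf("BLANK%02d", seq_len(blank_wells)))
  dimnames(values) <- list(panel, wells)
  role <- stats::setNames(rep(c("study", "qc_pool", "blank"),
                              c(n, n_qc, blank_wells)), wells)
  mfi_matrix(values, role)
}

#' Planted-effect recovery summary
#'
#' @param selected character vector of selected miRNA ids.
#' @param truth a [simulation_truth()] (or an [effect_spec()]).
#' @return list with `recall` (selected fraction of planted effects),
#'   `n_false` (selections outside the planted set), and the id sets.
#' @export
recovery_report <- function(selected, truth) {
  planted <- if (inherits(truth, "simulation_truth")) truth$effects$mirna_id
             else truth$mirna_id
  hit <- intersect(selected, planted)
  list(recall = if (length(planted)) length(hit) / length(planted) else NA_real_,
       n_false = length(setdiff(selected, planted)),
       recovered = hit,
       missed = setdiff(planted, hit))
}

#' Write / read expression matrices as TSV
#'
#' Probes as rows, wells as columns, first column `probe_id`. For an
#' [mfi_matrix()] the well roles go to a `<path>.roles.tsv` sidecar.
#'
#' @param x a `ct_matrix` or `mfi_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expr_tsv <- function(x, path) {
  values <- x$values
  df <- data.frame(probe_id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (inherits(x, "mfi_matrix")) {
    utils::write.table(
      data.frame(well = names(x$well_role), role = unname(x$well_role)),
      paste0(path, ".roles.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_expr_tsv
#' @param type "ct" or "mfi".
#' @export
read_expr_tsv <- function(path, type = c("ct", "mfi")) {
  type <- match.arg(type)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$probe_id
  if (type == "ct") {
    cols <- colnames(values)
    a <- grepl("_A$", cols)
    pairs <- NULL
    if (any(a)) {
      ids <- sub("_A$", "", cols[a])
      pairs <- data.frame(sample_id = ids, col_a = paste0(ids, "_A"),
                          col_b = paste0(ids, "_B"), stringsAsFactors = FALSE)
    }
    ct_matrix(values, pairs)
  } else {
    roles <- utils::read.table(paste0(path, ".roles.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
    mfi_matrix(values, stats::setNames(roles$role, roles$well))
  }
}
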