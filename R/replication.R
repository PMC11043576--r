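#' Preprocess bead-array fluorescence into a modelling feature table
#'
#' Study-well MFI values are optionally background-corrected (mean blank MFI
#' per probe; off by default), any value at or below zero is shifted to
#' `shift_value` (default 0.001), and values are log10-transformed. Pooled-QC
#' wells are excluded from the study table but summarized as a per-probe CV;
#' blank wells are summarized as mean background.
#'
#' @param mfi an [mfi_matrix()].
#' @param cohort a [cohort_table()] covering the study wells (supplies group,
#'   hormone use and the train/test split).
#' @param shift_value replacement for non-positive values before log10.
#' @param background_subtract subtract mean blank fluorescence per probe
#'   before the shift (default `FALSE`).
#' @return data.frame of class `feature_table`: `sample_id`, `group`,
#'   `hormone_use`, `split`, then one log10-MFI column per probe. QC and
#'   blank summaries are attached as attributes `qc_cv` and
#'   `blank_background`.
#' @export
preprocess_mfi <- function(mfi, cohort, shift_value = 0.001,
                           background_subtract = FALSE) {
  v <- mfi$values
  role <- mfi$well_role
  study_wells <- names(role)[role == "study"]
  if (length(study_wells) == 0) stop("no study wells", call. = FALSE)
  if (any(rowSums(is.finite(v)) == 0)) {
    stop("probe with no finite values", call. = FALSE)
  }
  blanks <- v[, role == "blank", drop = FALSE]
  background <- if (ncol(blanks)) rowMeans(blanks) else rep(0, nrow(v))
  study <- v[, study_wells, drop = FALSE]
  if (background_subtract) study <- study - background
  study[study <= 0] <- shift_value
  logv <- log10(study)
  qc <- v[, role == "qc_pool", drop = FALSE]
  qc_cv <- if (ncol(qc) >= 2) {
    apply(qc, 1, function(x) stats::sd(x) / mean(x))
  } else rep(NA_real_, nrow(v))
  idx <- match(study_wells, cohort$sample_id)
  if (anyNA(idx)) stop("study well(s) missing from cohort", call. = FALSE)
  out <- data.frame(sample_id = study_wells,
                    group = cohort$group[idx],
                    hormone_use = cohort$hormone_use[idx],
                    split = if (!is.null(cohort$split)) cohort$split[idx]
                            else NA_character_,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(t(logv), check.names = FALSE))
  rownames(out) <- NULL
  structure(out, probes = rownames(v), qc_cv = qc_cv,
            blank_background = background,
            class = c("feature_table", "data.frame"))
}

# probe-value matrix (samples x probes) from a feature table
feature_values <- function(features, probes = NULL) {
  if (is.null(probes)) probes <- attr(features, "probes")
  as.matrix(as.data.frame(features)[, probes, drop = FALSE])
}

#' Univariate case-vs-control tests per probe
#'
#' Two-sided pooled-variance t-tests on log10 MFI, by default on the training
#' split only (the testing set never informs selection). The fold change is
#' `10^(mean_case - mean_control)` in the signed convention; Holm-Sidak
#' adjusted p-values are attached.
#'
#' @param features a [preprocess_mfi()] table.
#' @param training_only restrict to `split == "train"` (default `TRUE`).
#' @param probes probe subset (default: all probes in the table).
#' @param var_equal pooled variance (default) or Welch.
#' @return data.frame: `probe_id`, `mean_diff` (log10 units), `fold_change`,
#'   `p_raw`, `p_adj`.
#' @export
univariate_tests <- function(features, training_only = TRUE, probes = NULL,
                             var_equal = TRUE) {
  df <- as.data.frame(features)
  if (training_only) {
    if (all(is.na(df$split))) stop("no split assigned", call. = FALSE)
    df <- df[df$split == "train", , drop = FALSE]
  }
  if (sum(df$group == "case") < 2 || sum(df$group == "control") < 2) {
    stop("need >= 2 cases and >= 2 controls", call. = FALSE)
  }
  if (is.null(probes)) probes <- attr(features, "probes")
  x <- t(as.matrix(df[, probes, drop = FALSE]))
  res <- row_ttests(x, which(df$group == "case"), which(df$group == "control"),
                    var_equal = var_equal)
  data.frame(probe_id = rownames(x),
             mean_diff = res$mean_diff,
             fold_change = signed_fc(10^res$mean_diff),
             p_raw = res$p,
             p_adj = holm_sidak_adjust(res$p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Holm-Sidak step-down multiple-testing adjustment
#'
#' Sort the m raw p-values ascending; the i-th smallest becomes
#' `1 - (1 - p_(i))^(m - i + 1)`; a running maximum enforces monotonicity,
#' values are capped at 1 and returned in the input order. Missing p-values
#' are ignored (they do not count toward m) and stay missing.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
holm_sidak_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  ord <- order(p[ok])
  ps <- p[ok][ord]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out[ok[ord]] <- adj
  out
}

#' PCA separation check
#'
#' Principal components of the standardized probe columns, with two
#' label-free separation summaries: the AUC of PC1 scores against the group
#' labels (folded to be at least 0.5, since the sign of a principal axis is
#' arbitrary) and the agreement of a 2-means clustering with case/control
#' status (also folded over the label matching).
#'
#' @param features a [preprocess_mfi()] table.
#' @param training_only restrict to the training split (default `TRUE`).
#' @return list: `scores` (sample x PC matrix), `var_explained`, `pc1_auc`,
#'   `cluster_agreement`, `dropped` (constant columns removed).
#' @export
pca_separation <- function(features, training_only = TRUE) {
  df <- as.data.frame(features)
  if (training_only && !all(is.na(df$split))) {
    df <- df[df$split == "train", , drop = FALSE]
  }
  if (nrow(df) < 3) stop("need >= 3 samples for PCA", call. = FALSE)
  x <- as.matrix(df[, attr(features, "probes"), drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant probe column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  is_case <- df$group == "case"
  a <- auc_rank(pc$x[is_case, 1], pc$x[!is_case, 1])
  km <- stats::kmeans(scale(x), centers = 2, nstart = 10)
  agree <- mean((km$cluster == 1) == is_case)
  list(scores = pc$x, var_explained = var_explained,
       pc1_auc = max(a, 1 - a),
       cluster_agreement = max(agree, 1 - agree),
       dropped = dropped)
}
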