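#' Collapse technical duplicates
#'
#' Each duplicate pair is replaced by its mean when the two measurements agree
#' within `max_discordance` cycles, and set missing otherwise. If only one of
#' the pair was measured, the single value passes through; columns without a
#' pairing pass through unchanged.
#'
#' @param ct a [ct_matrix()] with `pairs` defined.
#' @param max_discordance maximum tolerated |A - B| in cycles (default 1).
#' @return a [ct_matrix()] with one column per sample and no pairing.
#' @export
collapse_duplicates <- function(ct, max_discordance = 1.0) {
  if (is.null(ct$pairs)) stop("ct matrix has no duplicate pairing", call. = FALSE)
  pairs <- ct$pairs
  a <- ct$values[, pairs$col_a, drop = FALSE]
  b <- ct$values[, pairs$col_b, drop = FALSE]
  m <- (a + b) / 2
  m[!is.na(a) & !is.na(b) & abs(a - b) > max_discordance] <- NA_real_
  only_a <- !is.na(a) & is.na(b)
  only_b <- is.na(a) & !is.na(b)
  m[only_a] <- a[only_a]
  m[only_b] <- b[only_b]
  colnames(m) <- pairs$sample_id
  extra <- setdiff(colnames(ct$values), c(pairs$col_a, pairs$col_b))
  if (length(extra)) m <- cbind(m, ct$values[, extra, drop = FALSE])
  ct_matrix(m, pairs = NULL)
}

#' Ct quality-control filter
#'
#' Measurements with Ct above `ct_max` are unreliable near the amplification
#' limit and are set missing; miRNAs whose missing fraction then exceeds
#' `max_missing_fraction` are dropped entirely. The rule is strictly "greater
#' than": a value exactly at `ct_max` is retained.
#'
#' @param ct a collapsed [ct_matrix()].
#' @param ct_max exclusion threshold in cycles (default 34).
#' @param max_missing_fraction per-miRNA missingness cutoff (default 0.5).
#' @return list with `ct` (filtered matrix) and `report` (dropped ids,
#'   per-sample and per-miRNA missingness).
#' @export
qc_filter <- function(ct, ct_max = 34, max_missing_fraction = 0.5) {
  stopifnot(ct_max > 0)
  v <- ct$values
  v[!is.na(v) & v > ct_max] <- NA_real_
  miss_frac <- rowMeans(is.na(v))
  drop <- miss_frac > max_missing_fraction
  if (all(drop)) stop("every miRNA failed QC; nothing to analyze", call. = FALSE)
  report <- list(dropped = rownames(v)[drop],
                 mirna_missing_fraction = miss_frac,
                 sample_missing_fraction = colMeans(is.na(v)),
                 ct_max = ct_max)
  list(ct = ct_matrix(v[!drop, , drop = FALSE], pairs = ct$pairs),
       report = report)
}

#' Flag within-group outlier measurements (Grubbs test)
#'
#' Reproducible stand-in for interactive outlier screening: per miRNA and
#' group, a single Grubbs test at level `alpha` flags at most one extreme
#' measurement per pass, which is set missing; passes repeat until no flag.
#'
#' @param ct a collapsed [ct_matrix()].
#' @param groups character/factor group label per sample column.
#' @param alpha test level (default 0.05).
#' @return a [ct_matrix()] with flagged values set missing.
#' @export
flag_outliers <- function(ct, groups, alpha = 0.05) {
  v <- ct$values
  stopifnot(length(groups) == ncol(v))
  grubbs_crit <- function(n, alpha) {
    t2 <- stats::qt(1 - alpha / (2 * n), n - 2)^2
    ((n - 1) / sqrt(n)) * sqrt(t2 / (n - 2 + t2))
  }
  for (g in unique(groups)) {
    cols <- which(groups == g)
    for (i in seq_len(nrow(v))) {
      repeat {
        x <- v[i, cols]
        obs <- which(!is.na(x))
        n <- length(obs)
        if (n < 3) break
        s <- stats::sd(x[obs])
        if (s == 0) break
        dev <- abs(x[obs] - mean(x[obs])) / s
        j <- which.max(dev)
        if (dev[j] > grubbs_crit(n, alpha)) {
          v[i, cols[obs[j]]] <- NA_real_
        } else break
      }
    }
  }
  ct_matrix(v, pairs = ct$pairs)
}

#' Impute missing Ct values
#'
#' Default strategy replaces a missing value with the mean of its miRNA within
#' the same (group, hormone-use) cell; an empty cell falls back to the miRNA
#' grand mean with a warning. Observed values are never altered.
#'
#' @param ct a collapsed [ct_matrix()].
#' @param cohort a [cohort_table()] covering the matrix columns.
#' @param strategy "cell_mean" (group x hormone cell) or "grand_mean".
#' @return a [ct_matrix()] without missing values.
#' @export
impute_missing <- function(ct, cohort, strategy = c("cell_mean", "grand_mean")) {
  strategy <- match.arg(strategy)
  v <- ct$values
  idx <- match(colnames(v), cohort$sample_id)
  if (anyNA(idx)) stop("matrix columns missing from cohort", call. = FALSE)
  all_missing <- rowSums(!is.na(v)) == 0
  if (any(all_missing)) {
    stop("miRNA(s) with no observed values: ",
         paste(rownames(v)[all_missing], collapse = ", "), call. = FALSE)
  }
  if (!anyNA(v)) return(ct)
  grand <- rowMeans(v, na.rm = TRUE)
  if (strategy == "grand_mean") {
    for (i in seq_len(nrow(v))) v[i, is.na(v[i, ])] <- grand[i]
  } else {
    cell <- paste(cohort$group[idx], cohort$hormone_use[idx])
    fell_back <- FALSE
    for (cl in unique(cell)) {
      cols <- which(cell == cl)
      sub <- v[, cols, drop = FALSE]
      cm <- rowMeans(sub, na.rm = TRUE)
      empty <- !is.finite(cm)
      if (any(empty)) { cm[empty] <- grand[empty]; fell_back <- TRUE }
      for (i in seq_len(nrow(v))) {
        miss <- is.na(sub[i, ])
        if (any(miss)) v[i, cols[miss]] <- cm[i]
      }
    }
    if (fell_back) warning("empty imputation cell; grand-mean fallback used",
                           call. = FALSE)
  }
  ct_matrix(v, pairs = ct$pairs)
}

#' Normalized expression container
#'
#' @param values miRNA x sample matrix of delta-Ct (cycles).
#' @param reference_set character ids of the reference miRNAs (may be empty
#'   before reference selection).
#' @return list of class `normalized_expr`.
#' @export
normalized_expr <- function(values, reference_set = character(0)) {
  structure(list(values = values, reference_set = as.character(reference_set)),
            class = "normalized_expr")
}

#' Global (per-sample mean) normalization
#'
#' Subtracts each sample's mean Ct over the common detected miRNA set, so
#' per-sample loading differences cancel: the delta-Ct column means are
#' exactly zero and adding a constant to a whole sample column leaves its
#' normalized values unchanged.
#'
#' @param ct an imputed [ct_matrix()] (no missing values).
#' @return a [normalized_expr()].
#' @export
global_normalize <- function(ct) {
  v <- ct$values
  if (anyNA(v)) stop("global normalization requires an imputed matrix", call. = FALSE)
  delta <- sweep(v, 2, colMeans(v))
  normalized_expr(delta)
}

# per-sample delta-Ct relative to the reference-set mean; identity when no
# reference set has been chosen yet
ref_adjust <- function(expr) {
  if (length(expr$reference_set) == 0) return(expr$values)
  refs <- intersect(expr$reference_set, rownames(expr$values))
  if (length(refs) == 0) stop("reference set not present in matrix", call. = FALSE)
  sweep(expr$values, 2, colMeans(expr$values[refs, , drop = FALSE]))
}

# ratio -> signed display convention: ratios below 1 become negative
# reciprocals, so |FC| >= 1 always
signed_fc <- function(ratio) {
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Relative quantification by 2^-ddCt
#'
#' ddCt is the case-minus-control difference of reference-adjusted delta-Ct
#' means; the expression ratio is `2^-ddCt` (lower Ct = more template), shown
#' in the signed convention (ratio 0.25 is reported as -4).
#'
#' @param expr a [normalized_expr()] with its `reference_set` filled.
#' @param case_ids,control_ids sample ids of the two groups.
#' @return list with `ddct`, `ratio`, and `fold_change` (signed), each a
#'   named vector over miRNAs.
#' @export
ddct_fold_change <- function(expr, case_ids, control_ids) {
  stopifnot(length(case_ids) > 0, length(control_ids) > 0)
  adj <- ref_adjust(expr)
  ddct <- rowMeans(adj[, case_ids, drop = FALSE]) -
    rowMeans(adj[, control_ids, drop = FALSE])
  ratio <- 2^(-ddct)
  list(ddct = ddct, ratio = ratio, fold_change = signed_fc(ratio))
}

# pooled-variance two-sample t-test p-value and case-minus-control mean
# difference per matrix row; degenerate rows (zero variance in both groups)
# get p = 1 when the means agree, NA otherwise
row_ttests <- function(adj, case_cols, control_cols, var_equal = TRUE) {
  p <- apply(adj, 1, function(x) {
    xc <- x[case_cols]; xk <- x[control_cols]
    if (stats::sd(xc) == 0 && stats::sd(xk) == 0) {
      return(if (mean(xc) == mean(xk)) 1 else NA_real_)
    }
    stats::t.test(xc, xk, var.equal = var_equal)$p.value
  })
  mean_diff <- rowMeans(adj[, case_cols, drop = FALSE]) -
    rowMeans(adj[, control_cols, drop = FALSE])
  list(p = p, mean_diff = mean_diff)
}

#' Hormone-stratified discovery t-tests
#'
#' Within each hormone-use stratum independently, a two-sided pooled-variance
#' (Student's) t-test of cases vs. controls on reference-adjusted delta-Ct,
#' with the 2^-ddCt signed fold change computed on the same values. A stratum
#' with fewer than two cases or two controls yields missing results.
#'
#' @param expr a [normalized_expr()] (reference set applied if present).
#' @param cohort a [cohort_table()] covering the expression columns.
#' @param var_equal pooled variance (default, Student's) or Welch.
#' @return data.frame: `mirna_id`, `fc_hormone`, `p_hormone`,
#'   `fc_nonhormone`, `p_nonhormone`.
#' @export
stratified_ttests <- function(expr, cohort, var_equal = TRUE) {
  adj <- ref_adjust(expr)
  idx <- match(colnames(adj), cohort$sample_id)
  if (anyNA(idx)) stop("expression columns missing from cohort", call. = FALSE)
  grp <- cohort$group[idx]
  horm <- cohort$hormone_use[idx]
  out <- data.frame(mirna_id = rownames(adj), stringsAsFactors = FALSE)
  for (stratum in c(TRUE, FALSE)) {
    cc <- which(horm == stratum & grp == "case")
    kk <- which(horm == stratum & grp == "control")
    lab <- if (stratum) "hormone" else "nonhormone"
    if (length(cc) < 2 || length(kk) < 2) {
      warning("degenerate ", lab, " stratum; results flagged missing",
              call. = FALSE)
      out[[paste0("fc_", lab)]] <- NA_real_
      out[[paste0("p_", lab)]] <- NA_real_
      next
    }
    res <- row_ttests(adj, cc, kk, var_equal = var_equal)
    out[[paste0("fc_", lab)]] <- signed_fc(2^(-res$mean_diff))
    out[[paste0("p_", lab)]] <- res$p
  }
  out
}

#' Dual-threshold candidate inclusion rule
#'
#' A miRNA enters the replication panel if it reaches p < 0.005 in either
#' hormone stratum, or p <= 0.05 in both strata simultaneously. The strong
#' single-stratum clause takes precedence in the recorded reason.
#'
#' @param p_hormone,p_nonhormone p-value vectors (may contain NA).
#' @param p_strong single-stratum threshold (default 0.005).
#' @param p_both both-strata threshold (default 0.05).
#' @return data.frame: `included` (logical) and `inclusion_reason`
#'   ("either_stratum_p005", "both_strata_p05", "none").
#' @export
discovery_selection_rule <- function(p_hormone, p_nonhormone,
                                     p_strong = 0.005, p_both = 0.05) {
  stopifnot(length(p_hormone) == length(p_nonhormone))
  chk <- c(p_hormone, p_nonhormone)
  if (any(!is.na(chk) & (chk < 0 | chk > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  strong <- (!is.na(p_hormone) & p_hormone < p_strong) |
    (!is.na(p_nonhormone) & p_nonhormone < p_strong)
  both <- !is.na(p_hormone) & !is.na(p_nonhormone) &
    p_hormone <= p_both & p_nonhormone <= p_both
  reason <- ifelse(strong, "either_stratum_p005",
                   ifelse(both, "both_strata_p05", "none"))
  data.frame(included = reason != "none", inclusion_reason = reason,
             stringsAsFactors = FALSE)
}

#' Assemble the replication probe panel
#'
#' Concatenates the discovery candidates with literature additions and
#' positive/negative control probes, preserving category labels. Categories
#' must be disjoint.
#'
#' @param selected discovery-selected miRNA ids.
#' @param literature_additions ids added from prior reports.
#' @param positive_controls,negative_controls assay control probe ids.
#' @return data.frame: `probe_id`, `category`.
#' @export
assemble_panel <- function(selected, literature_additions = character(0),
                           positive_controls = character(0),
                           negative_controls = character(0)) {
  cats <- list(discovery = selected, literature = literature_additions,
               positive_control = positive_controls,
               negative_control = negative_controls)
  all_ids <- unlist(cats, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    dup <- unique(all_ids[duplicated(all_ids)])
    stop("probe(s) in more than one category: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  data.frame(probe_id = all_ids,
             category = rep(names(cats), lengths(cats)),
             stringsAsFactors = FALSE)
}
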