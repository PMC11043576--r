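#' Correlation-based feature selection merit
#'
#' The CFS heuristic scores a feature subset by
#' `merit = k * rcf / sqrt(k + k * (k - 1) * rff)`,
#' where `k` is the subset size, `rcf` the mean absolute feature-class
#' correlation and `rff` the mean absolute pairwise inter-correlation over
#' the subset: good subsets are class-correlated but mutually uncorrelated.
#'
#' @param class_corr vector of |correlation with class| per feature.
#' @param feature_corr |correlation| matrix between features.
#' @param subset integer or character indices of the evaluated subset.
#' @return the merit score (a single number).
#' @export
cfs_merit <- function(class_corr, feature_corr, subset) {
  if (length(subset) == 0) stop("subset must be nonempty", call. = FALSE)
  if (is.character(subset)) subset <- match(subset, names(class_corr))
  k <- length(subset)
  rcf <- mean(class_corr[subset])
  rff <- if (k > 1) {
    sub <- feature_corr[subset, subset, drop = FALSE]
    (sum(sub) - k) / (k * (k - 1))  # off-diagonal mean (diagonal is 1)
  } else 0
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

# absolute Pearson correlations of features with a binary class
# (point-biserial) and with each other; zero-variance columns get 0
abs_correlations <- function(x, y) {
  sds <- apply(x, 2, stats::sd)
  cc <- rep(0, ncol(x))
  ok <- sds > 0
  if (any(ok)) cc[ok] <- abs(stats::cor(x[, ok, drop = FALSE], as.numeric(y)))
  names(cc) <- colnames(x)
  fc <- matrix(0, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
  if (sum(ok) > 1) fc[ok, ok] <- abs(stats::cor(x[, ok, drop = FALSE]))
  diag(fc) <- 1
  list(class_corr = cc, feature_corr = fc)
}

# subset search maximizing CFS merit over the candidate features, with the
# forced features present in every evaluated subset. Exhaustive when few
# candidates; otherwise best-first forward search with a stall limit.
cfs_search <- function(class_corr, feature_corr, candidates, forced,
                       stall_limit = 5L, exhaustive_limit = 15L) {
  nc <- length(candidates)
  cand_idx <- match(candidates, names(class_corr))
  forced_idx <- match(forced, names(class_corr))
  merit_of <- function(mask) {
    cfs_merit(class_corr, feature_corr, c(forced_idx, cand_idx[mask]))
  }
  if (nc == 0) {
    return(list(selected = character(0),
                merit = if (length(forced)) merit_of(logical(0)) else NA_real_))
  }
  best_mask <- rep(FALSE, nc)
  best_merit <- if (length(forced)) merit_of(best_mask) else -Inf
  if (nc <= exhaustive_limit) {
    for (code in seq_len(2^nc - 1)) {
      mask <- as.logical(bitwAnd(code, 2^(seq_len(nc) - 1)))
      m <- merit_of(mask)
      if (m > best_merit + 1e-12) { best_merit <- m; best_mask <- mask }
    }
  } else {
    key <- function(mask) paste0("s", paste(which(mask), collapse = ","))
    open <- list(list(mask = best_mask, merit = best_merit))
    seen <- new.env(parent = emptyenv())
    assign(key(best_mask), TRUE, envir = seen)
    stalls <- 0L
    while (length(open) > 0 && stalls < stall_limit) {
      i <- which.max(vapply(open, `[[`, numeric(1), "merit"))
      cur <- open[[i]]
      open[[i]] <- NULL
      improved <- FALSE
      for (j in which(!cur$mask)) {
        mask <- cur$mask
        mask[j] <- TRUE
        k <- key(mask)
        if (exists(k, envir = seen)) next
        assign(k, TRUE, envir = seen)
        m <- merit_of(mask)
        open[[length(open) + 1L]] <- list(mask = mask, merit = m)
        if (m > best_merit + 1e-12) {
          best_merit <- m
          best_mask <- mask
          improved <- TRUE
        }
      }
      stalls <- if (improved) 0L else stalls + 1L
    }
  }
  list(selected = candidates[best_mask], merit = best_merit)
}

#' CFS with cross-validated fold aggregation and a forced covariate
#'
#' Candidates (typically the probes passing the univariate `p <= 0.15` gate
#' on the training set) are searched per cross-validation fold: within each
#' of `folds` group-stratified folds the held-in portion supplies the
#' correlations, a merit-maximizing subset is found (exhaustively for up to
#' `exhaustive_limit` candidates, best-first with a stall limit of 5
#' otherwise), and the final feature set is the features picked in at least
#' half of the folds, plus the forced covariates, which take part in every
#' evaluated subset regardless of merit.
#'
#' @param features a [preprocess_mfi()] table.
#' @param candidates candidate probe ids.
#' @param forced forced covariate column names (default `"hormone_use"`).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param training_only restrict to the training split (default `TRUE`).
#' @param majority fraction of folds required to keep a feature (default 0.5).
#' @param exhaustive_limit exhaustive-search cutoff (default 15 candidates).
#' @return list of class `feature_set`: `selected` (probes), `forced`,
#'   `per_fold` (list of per-fold picks), `fold_frequency`, `merits`.
#' @export
cfs_select <- function(features, candidates, forced = "hormone_use",
                       folds = 10L, seed = 1L, training_only = TRUE,
                       majority = 0.5, exhaustive_limit = 15L) {
  df <- as.data.frame(features)
  if (training_only && !all(is.na(df$split))) {
    df <- df[df$split == "train", , drop = FALSE]
  }
  candidates <- as.character(candidates)
  if (length(candidates) == 0) {
    warning("no candidates passed the gate; feature set is the forced covariates",
            call. = FALSE)
    return(structure(list(selected = character(0), forced = forced,
                          per_fold = list(), fold_frequency = numeric(0),
                          merits = numeric(0)),
                     class = "feature_set"))
  }
  cols <- c(candidates, forced)
  x <- as.matrix(as.data.frame(df)[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  y <- as.integer(df$group == "case")
  set.seed(seed)
  fold_id <- integer(nrow(df))
  for (g in unique(df$group)) {
    members <- which(df$group == g)
    fold_id[members] <- sample(rep_len(seq_len(folds), length(members)))
  }
  per_fold <- vector("list", folds)
  merits <- numeric(folds)
  for (f in seq_len(folds)) {
    keep <- fold_id != f
    corr <- abs_correlations(x[keep, , drop = FALSE], y[keep])
    res <- cfs_search(corr$class_corr, corr$feature_corr,
                      candidates, forced, exhaustive_limit = exhaustive_limit)
    per_fold[[f]] <- res$selected
    merits[f] <- res$merit
  }
  freq <- table(factor(unlist(per_fold), levels = candidates)) / folds
  selected <- candidates[freq >= majority]
  structure(list(selected = selected, forced = forced, per_fold = per_fold,
                 fold_frequency = as.numeric(freq), merits = merits),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set: %d selected probe(s) + forced {%s}>\n",
              length(x$selected), paste(x$forced, collapse = ", ")))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
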