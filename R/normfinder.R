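#' Normfinder reference-gene stability
#'
#' Model-based stability estimate for choosing normalization references.
#' For gene i in group g with group mean `a_ig`, within-group variance
#' `v_ig` and group size `n_g`, the group-bias term is the two-way
#' interaction residual
#' `d_ig = a_ig - mean_g(a_ig) - mean_i(a_ig) + mean_ig(a_ig)`,
#' and the stability value is
#' `rho_i = (1/G) * sum_g ( |d_ig| + sqrt(v_ig / n_g) )`.
#' Lower rho means more stable: small systematic case/control bias and small
#' within-group scatter. This is the unshrunk estimator; the components are
#' returned so shrinkage variants can be layered on.
#'
#' With a single group the bias term vanishes and the ranking reduces to the
#' per-gene standard error `sqrt(v / n)`.
#'
#' @param expr a [normalized_expr()] (globally normalized delta-Ct).
#' @param groups character/factor group label per sample column.
#' @return data.frame of class `stability_ranking`: `mirna_id`, `rho`, plus
#'   one `bias_<g>` and `se_<g>` column per group, sorted by ascending rho
#'   with ties broken lexicographically by id.
#' @export
normfinder_stability <- function(expr, groups) {
  v <- expr$values
  stopifnot(length(groups) == ncol(v))
  groups <- as.character(groups)
  glev <- unique(groups)
  n_g <- table(groups)[glev]
  if (any(n_g < 2)) stop("every group needs >= 2 samples", call. = FALSE)
  a <- sapply(glev, function(g) rowMeans(v[, groups == g, drop = FALSE]))
  a <- matrix(a, nrow = nrow(v), dimnames = list(rownames(v), glev))
  vv <- sapply(glev, function(g) apply(v[, groups == g, drop = FALSE], 1, stats::var))
  vv <- matrix(vv, nrow = nrow(v), dimnames = list(rownames(v), glev))
  gene_mean <- rowMeans(a)
  group_mean <- colMeans(a)
  grand <- mean(a)
  d <- a - gene_mean - matrix(group_mean, nrow(a), ncol(a), byrow = TRUE) + grand
  se <- sweep(sqrt(vv), 2, sqrt(as.numeric(n_g)), "/")
  rho <- rowMeans(abs(d) + se)
  out <- data.frame(mirna_id = rownames(v), rho = rho,
                    stringsAsFactors = FALSE)
  for (g in glev) {
    out[[paste0("bias_", g)]] <- d[, g]
    out[[paste0("se_", g)]] <- se[, g]
  }
  out <- out[order(out$rho, out$mirna_id), ]
  rownames(out) <- NULL
  structure(out, class = c("stability_ranking", "data.frame"))
}

#' Select the most stable reference miRNAs
#'
#' @param ranking a [normfinder_stability()] result.
#' @param k number of references (default 5).
#' @return character vector of the k smallest-rho ids (ties lexicographic).
#' @export
select_references <- function(ranking, k = 5L) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > nrow(ranking)) stop("k exceeds number of ranked miRNAs", call. = FALSE)
  ord <- order(ranking$rho, ranking$mirna_id)
  ranking$mirna_id[ord][seq_len(k)]
}
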