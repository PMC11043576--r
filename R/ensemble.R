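#' Random-architecture MLP ensemble sweep
#'
#' Samples `n_networks` architectures over the hidden-size and activation
#' ranges, trains each on the training rows only, ranks them by training-set
#' AUC (descending; failed networks rank last) and retains the `top_k` best
#' with full per-network seeds for reproducibility.
#'
#' @param X training feature matrix.
#' @param y binary training labels (1 = case).
#' @param n_networks networks to construct (study-scale default 15000; use a
#'   few hundred for quick runs).
#' @param top_k networks to retain (default 50).
#' @param seed master seed; per-network seeds are fanned out from it.
#' @param max_iter,l2 training controls passed to [train_bfgs()].
#' @return list of class `ensemble_result`: `manifest` (network id, seed,
#'   hidden size, activation, training AUC, failed flag, ranked), `models`
#'   (the `top_k` trained networks, in rank order), `n_failed`.
#' @export
ensemble_search <- function(X, y, n_networks = 15000L, top_k = 50L,
                            seed = 1L, max_iter = 200L, l2 = 1e-4) {
  stopifnot(n_networks >= top_k, top_k >= 1)
  X <- as.matrix(X)
  y <- as.numeric(y)
  set.seed(seed)
  net_seeds <- sample.int(2^31 - 2, n_networks)
  models <- vector("list", n_networks)
  manifest <- data.frame(network = seq_len(n_networks), seed = net_seeds,
                         n_hidden = NA_integer_, activation = NA_character_,
                         train_auc = NA_real_, failed = FALSE,
                         stringsAsFactors = FALSE)
  for (i in seq_len(n_networks)) {
    arch <- sample_architecture(ncol(X), net_seeds[i])
    model <- train_bfgs(arch, X, y, max_iter = max_iter, l2 = l2)
    manifest$n_hidden[i] <- arch$n_hidden
    manifest$activation[i] <- arch$hidden_activation
    manifest$failed[i] <- model$failed
    if (!model$failed) {
      prob <- predict_proba(model, X)
      manifest$train_auc[i] <- auc_rank(prob[y == 1], prob[y == 0])
    }
    models[[i]] <- model
  }
  n_failed <- sum(manifest$failed)
  if (n_failed > n_networks / 2) {
    stop("more than half of the networks failed training", call. = FALSE)
  }
  ord <- order(-ifelse(is.na(manifest$train_auc), -Inf, manifest$train_auc),
               manifest$network)
  manifest <- manifest[ord, ]
  manifest$rank <- seq_len(n_networks)
  rownames(manifest) <- NULL
  structure(list(manifest = manifest,
                 models = models[manifest$network[seq_len(top_k)]],
                 top_k = as.integer(top_k), n_failed = n_failed),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result: %d networks trained (%d failed), top %d retained>\n",
              nrow(x$manifest), x$n_failed, x$top_k))
  print(utils::head(x$manifest, 5))
  invisible(x)
}

#' Final model selection on the testing set
#'
#' Scores every retained network on the held-out testing rows and returns the
#' one with the highest testing AUC (ties broken by higher training AUC, then
#' lower network index). Selecting on the testing set follows the published
#' procedure and is optimistically biased; see the package vignette.
#'
#' @param result an [ensemble_search()] result.
#' @param X_test,y_test testing feature matrix and binary labels.
#' @return list of class `final_model`: `model`, `network` (id in the sweep),
#'   `test_auc`, `train_auc`, `roc` (a [roc_report()] on the testing set),
#'   `candidates` (testing AUC per retained network).
#' @export
select_final <- function(result, X_test, y_test) {
  stopifnot(length(result$models) >= 1)
  y_test <- as.numeric(y_test)
  if (length(y_test) == 0) stop("empty testing split", call. = FALSE)
  top <- utils::head(result$manifest, result$top_k)
  test_auc <- vapply(seq_along(result$models), function(i) {
    m <- result$models[[i]]
    if (m$failed) return(NA_real_)
    prob <- predict_proba(m, X_test)
    auc_rank(prob[y_test == 1], prob[y_test == 0])
  }, numeric(1))
  ord <- order(-ifelse(is.na(test_auc), -Inf, test_auc),
               -ifelse(is.na(top$train_auc), -Inf, top$train_auc),
               top$network)
  best <- ord[1]
  model <- result$models[[best]]
  prob <- predict_proba(model, X_test)
  roc <- roc_report(prob[y_test == 1], prob[y_test == 0])
  structure(list(model = model, network = top$network[best],
                 test_auc = test_auc[best], train_auc = top$train_auc[best],
                 roc = roc,
                 candidates = data.frame(network = top$network,
                                         train_auc = top$train_auc,
                                         test_auc = test_auc)),
            class = "final_model")
}
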