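#' Sample a random single-hidden-layer architecture
#'
#' Hidden size is uniform over the integer range from `ceiling(n_inputs/3)`
#' to `floor(1.5 * n_inputs)` (forced non-empty for tiny input counts) and
#' the hidden activation is uniform over the four admissible families:
#' linear, logistic, hyperbolic tangent, exponential. The output unit is
#' always logistic, so the network output is a probability.
#'
#' @param n_inputs number of input features.
#' @param rng_seed integer seed; the draw is deterministic given the seed.
#' @return list of class `architecture_spec`.
#' @export
sample_architecture <- function(n_inputs, rng_seed = 1L) {
  stopifnot(n_inputs >= 1)
  set.seed(rng_seed)
  lower <- max(1L, as.integer(ceiling(n_inputs / 3)))
  upper <- max(lower, as.integer(floor(1.5 * n_inputs)))
  n_hidden <- if (lower == upper) lower else sample(lower:upper, 1L)
  act <- sample(c("linear", "logistic", "tanh", "exponential"), 1L)
  structure(list(n_inputs = as.integer(n_inputs), n_hidden = n_hidden,
                 hidden_activation = act, output_activation = "logistic",
                 init_seed = as.integer(rng_seed)),
            class = "architecture_spec")
}

hidden_act <- function(u, kind) {
  switch(kind,
         linear = u,
         logistic = 1 / (1 + exp(-u)),
         tanh = tanh(u),
         exponential = exp(pmin(pmax(u, -30), 30)),
         stop("unknown activation: ", kind, call. = FALSE))
}

hidden_act_grad <- function(u, a, kind) {
  switch(kind,
         linear = matrix(1, nrow(u), ncol(u)),
         logistic = a * (1 - a),
         tanh = 1 - a^2,
         exponential = a * (u > -30 & u < 30),
         stop("unknown activation: ", kind, call. = FALSE))
}

sigmoid <- function(u) 1 / (1 + exp(-pmin(pmax(u, -30), 30)))

# pack/unpack the parameter vector: W1 (h x p), b1 (h), w2 (h), b2
unpack_theta <- function(theta, p, h) {
  list(W1 = matrix(theta[seq_len(h * p)], h, p),
       b1 = theta[h * p + seq_len(h)],
       w2 = theta[h * p + h + seq_len(h)],
       b2 = theta[h * p + 2 * h + 1])
}

mlp_forward <- function(par, X, act) {
  U <- X %*% t(par$W1)
  U <- sweep(U, 2, par$b1, "+")
  A <- hidden_act(U, act)
  prob <- sigmoid(drop(A %*% par$w2) + par$b2)
  list(U = U, A = A, prob = pmin(pmax(prob, 1e-12), 1 - 1e-12))
}

# penalized binomial cross-entropy and its analytic gradient
mlp_loss <- function(theta, X, y, h, act, l2) {
  par <- unpack_theta(theta, ncol(X), h)
  fw <- mlp_forward(par, X, act)
  -mean(y * log(fw$prob) + (1 - y) * log(1 - fw$prob)) +
    l2 * (sum(par$W1^2) + sum(par$w2^2))
}

mlp_grad <- function(theta, X, y, h, act, l2) {
  n <- nrow(X)
  par <- unpack_theta(theta, ncol(X), h)
  fw <- mlp_forward(par, X, act)
  dout <- (fw$prob - y) / n
  gw2 <- drop(crossprod(fw$A, dout)) + 2 * l2 * par$w2
  gb2 <- sum(dout)
  dA <- outer(dout, par$w2)
  dU <- dA * hidden_act_grad(fw$U, fw$A, act)
  gW1 <- crossprod(dU, X) + 2 * l2 * par$W1
  gb1 <- colSums(dU)
  c(as.vector(gW1), gb1, gw2, gb2)
}

# standardization derived from training data; binary 0/1 columns pass
# through untouched
fit_standardizer <- function(X) {
  is_binary <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  center <- ifelse(is_binary, 0, colMeans(X))
  s <- apply(X, 2, stats::sd)
  scale <- ifelse(is_binary | s == 0, 1, s)
  list(center = center, scale = scale)
}

apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2, std$center), 2, std$scale, "/")
}

#' Train a multilayer perceptron by BFGS
#'
#' Minimizes the L2-penalized binomial cross-entropy of a single-hidden-layer
#' perceptron with the architecture's activation family, using the
#' Broyden-Fletcher-Goldfarb-Shanno quasi-Newton optimizer from seeded
#' small-uniform initial weights (half-width `0.5/sqrt(fan-in)`). Inputs are
#' standardized to training mean/sd (binary 0/1 covariates pass through);
#' the standardization is stored in the model. A non-finite loss triggers one
#' automatic restart with a five-fold smaller initialization; a second
#' failure marks the network as failed.
#'
#' @param arch an [sample_architecture()] spec (its `init_seed` seeds the
#'   weight initialization).
#' @param X numeric feature matrix (training rows only).
#' @param y binary labels (1 = case).
#' @param max_iter BFGS iteration cap (default 200).
#' @param l2 weight penalty (default 1e-4).
#' @return list of class `mlp_model` with weights, standardization and
#'   diagnostics (`final_loss`, `converged`, `failed`, `counts`).
#' @export
train_bfgs <- function(arch, X, y, max_iter = 200L, l2 = 1e-4) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(is.finite(X)), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("need both classes in training data", call. = FALSE)
  if (ncol(X) != arch$n_inputs) stop("feature count does not match architecture",
                                     call. = FALSE)
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)
  p <- ncol(Xs)
  h <- arch$n_hidden
  n_par <- h * p + 2 * h + 1
  set.seed(arch$init_seed)
  attempt <- function(scale_div) {
    r1 <- 0.5 / sqrt(p) / scale_div
    r2 <- 0.5 / sqrt(h) / scale_div
    theta0 <- c(stats::runif(h * p, -r1, r1), rep(0, h),
                stats::runif(h, -r2, r2), 0)
    tryCatch(
      stats::optim(theta0, mlp_loss, mlp_grad, X = Xs, y = y, h = h,
                   act = arch$hidden_activation, l2 = l2, method = "BFGS",
                   control = list(maxit = max_iter, reltol = 1e-10)),
      error = function(e) NULL)
  }
  fit <- attempt(1)
  if (is.null(fit) || !is.finite(fit$value)) fit <- attempt(5)
  failed <- is.null(fit) || !is.finite(fit$value)
  par <- if (!failed) unpack_theta(fit$par, p, h) else
    unpack_theta(rep(0, n_par), p, h)
  structure(list(architecture = arch,
                 W1 = par$W1, b1 = par$b1, w2 = par$w2, b2 = par$b2,
                 center = std$center, scale = std$scale,
                 feature_names = colnames(X),
                 final_loss = if (failed) NA_real_ else fit$value,
                 converged = !failed && fit$convergence == 0,
                 failed = failed,
                 counts = if (failed) c(0, 0) else fit$counts),
            class = "mlp_model")
}

#' Predict endometriosis probabilities from a trained network
#'
#' Applies the model's stored training-set standardization and runs the
#' forward pass; outputs lie in (0, 1) and represent the probability of case
#' status for the sample's expression pattern plus hormone use.
#'
#' @param model an [train_bfgs()] model.
#' @param X feature matrix with the model's feature count (and names, if the
#'   model has them).
#' @return numeric vector of probabilities.
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$architecture$n_inputs) {
    stop("feature count does not match model", call. = FALSE)
  }
  if (!is.null(model$feature_names) && !is.null(colnames(X))) {
    if (!setequal(colnames(X), model$feature_names)) {
      stop("feature names do not match model", call. = FALSE)
    }
    X <- X[, model$feature_names, drop = FALSE]
  }
  Xs <- apply_standardizer(list(center = model$center, scale = model$scale), X)
  mlp_forward(list(W1 = model$W1, b1 = model$b1, w2 = model$w2, b2 = model$b2),
              Xs, model$architecture$hidden_activation)$prob
}

#' Serialize / restore a trained network as JSON
#'
#' Numbers are written at full precision so that a save/load round trip is
#' bit-exact.
#'
#' @param model an `mlp_model`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `mlp_to_json`: the path (invisibly) or the JSON string;
#'   `mlp_from_json`: the restored `mlp_model`.
#' @export
mlp_to_json <- function(model, path = NULL) {
  payload <- list(
    architecture = unclass(model$architecture),
    W1 = model$W1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
    center = model$center, scale = model$scale,
    feature_names = model$feature_names,
    final_loss = model$final_loss, converged = model$converged,
    failed = model$failed)
  # 17 significant digits guarantee an exact double round trip
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           matrix = "rowmajor", null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' @rdname mlp_to_json
#' @param json JSON string or file path produced by [mlp_to_json()].
#' @export
mlp_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  arch <- structure(x$architecture, class = "architecture_spec")
  arch$n_inputs <- as.integer(arch$n_inputs)
  arch$n_hidden <- as.integer(arch$n_hidden)
  arch$init_seed <- as.integer(arch$init_seed)
  W1 <- matrix(as.numeric(x$W1), arch$n_hidden, arch$n_inputs)
  structure(list(architecture = arch, W1 = W1,
                 b1 = as.numeric(x$b1), w2 = as.numeric(x$w2),
                 b2 = as.numeric(x$b2),
                 center = stats::setNames(as.numeric(x$center), x$feature_names),
                 scale = stats::setNames(as.numeric(x$scale), x$feature_names),
                 feature_names = x$feature_names,
                 final_loss = x$final_loss, converged = x$converged,
                 failed = x$failed, counts = NULL),
            class = "mlp_model")
}
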