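test_that("architecture sampling respects the hidden-size sweep bounds", {
  draws <- t(sapply(1:400, function(s) {
    a <- sample_architecture(6L, s)
    c(h = a$n_hidden, act = match(a$hidden_activation,
                                  c("linear", "logistic", "tanh", "exponential")))
  }))
  expect_true(all(draws[, "h"] >= 2 & draws[, "h"] <= 9))  # ceil(6/3)..floor(9)
  expect_setequal(unique(draws[, "h"]), 2:9)
  expect_setequal(unique(draws[, "act"]), 1:4)
  # approximate uniformity over the 8 hidden sizes
  chi <- suppressWarnings(stats::chisq.test(table(draws[, "h"])))
  expect_gt(chi$p.value, 0.001)
  expect_equal(sample_architecture(1L, 3L)$n_hidden, 1L)  # degenerate range
  expect_identical(sample_architecture(6L, 99L), sample_architecture(6L, 99L))
})

test_that("the forward pass matches hand-computed arithmetic", {
  # 2-2-1 network with fixed weights, logistic hidden
  arch <- structure(list(n_inputs = 2L, n_hidden = 2L,
                         hidden_activation = "logistic",
                         output_activation = "logistic", init_seed = 1L),
                    class = "architecture_spec")
  model <- structure(list(
    architecture = arch,
    W1 = matrix(c(1, -1, 0.5, 2), 2, 2),  # rows = hidden units
    b1 = c(0.1, -0.2), w2 = c(1.5, -0.7), b2 = 0.3,
    center = c(0, 0), scale = c(1, 1), feature_names = NULL,
    failed = FALSE), class = "mlp_model")
  x <- c(0.4, -1.2)
  u <- model$W1 %*% x + model$b1
  a <- 1 / (1 + exp(-u))
  p_hand <- 1 / (1 + exp(-(sum(a * model$w2) + model$b2)))
  expect_equal(unname(predict_proba(model, matrix(x, 1, 2))), unname(p_hand))
  # zero weights -> probability exactly 0.5 for any input
  zero <- model
  zero$W1[] <- 0; zero$b1[] <- 0; zero$w2[] <- 0; zero$b2 <- 0
  expect_equal(unname(predict_proba(zero, matrix(rnorm(10), 5, 2))),
               rep(0.5, 5))
  # batch output equals concatenated single-sample calls
  xb <- matrix(rnorm(8), 4, 2)
  batch <- predict_proba(model, xb)
  singles <- sapply(1:4, function(i) predict_proba(model, xb[i, , drop = FALSE]))
  expect_equal(unname(batch), unname(singles))
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(51)
  for (act in c("linear", "logistic", "tanh", "exponential")) {
    X <- matrix(rnorm(30), 10, 3)
    y <- rep(c(0, 1), 5)
    h <- 2L
    theta <- runif(h * 3 + 2 * h + 1, -0.5, 0.5)
    g_an <- endomiR:::mlp_grad(theta, X, y, h, act, l2 = 1e-3)
    eps <- 1e-6
    g_num <- vapply(seq_along(theta), function(j) {
      tp <- theta; tm <- theta
      tp[j] <- tp[j] + eps; tm[j] <- tm[j] - eps
      (endomiR:::mlp_loss(tp, X, y, h, act, 1e-3) -
         endomiR:::mlp_loss(tm, X, y, h, act, 1e-3)) / (2 * eps)
    }, numeric(1))
    expect_equal(g_an, g_num, tolerance = 1e-5)
  }
})

test_that("BFGS training solves separable data and the XOR pattern", {
  set.seed(52)
  n <- 40
  X <- cbind(rnorm(n) + rep(c(2, -2), each = n / 2), rnorm(n))
  y <- rep(c(1, 0), each = n / 2)
  arch <- sample_architecture(2L, 7L)
  model <- train_bfgs(arch, X, y)
  expect_false(model$failed)
  prob <- predict_proba(model, X)
  expect_equal(endomiR:::auc_rank(prob[y == 1], prob[y == 0]), 1)

  # XOR is learnable with 2 hidden units for some restart
  Xx <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  yx <- c(0, 1, 1, 0)
  archx <- structure(list(n_inputs = 2L, n_hidden = 2L,
                          hidden_activation = "tanh",
                          output_activation = "logistic", init_seed = 1L),
                     class = "architecture_spec")
  solved <- FALSE
  for (s in 1:10) {
    archx$init_seed <- s
    m <- train_bfgs(archx, Xx, yx, max_iter = 500L, l2 = 1e-6)
    if (!m$failed && all((predict_proba(m, Xx) > 0.5) == (yx == 1))) {
      solved <- TRUE
      break
    }
  }
  expect_true(solved)

  expect_error(train_bfgs(arch, X, rep(1, n)), "both classes")
})

test_that("binary covariates bypass standardization", {
  set.seed(53)
  X <- cbind(rnorm(20, 10, 5), rep(c(0, 1), 10))
  std <- endomiR:::fit_standardizer(X)
  expect_equal(std$center[2], 0)
  expect_equal(std$scale[2], 1)
  expect_equal(std$center[1], mean(X[, 1]))
})

test_that("model JSON serialization round-trips bit-exactly", {
  set.seed(54)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- rep(c(0, 1), 10)
  model <- train_bfgs(sample_architecture(3L, 5L), X, y)
  json <- mlp_to_json(model)
  back <- mlp_from_json(json)
  expect_identical(back$W1, model$W1)
  expect_identical(back$b1, model$b1)
  expect_identical(back$w2, model$w2)
  expect_identical(back$b2, model$b2)
  expect_identical(back$center, model$center)
  expect_identical(back$scale, model$scale)
  expect_identical(predict_proba(back, X), predict_proba(model, X))
  # through a file too
  path <- tempfile(fileext = ".json")
  mlp_to_json(model, path)
  expect_identical(predict_proba(mlp_from_json(path), X),
                   predict_proba(model, X))
})
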