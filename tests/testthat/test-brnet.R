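# Network forward/Jacobian correctness and the Bayesian-regularization
# Levenberg-Marquardt trainer against closed-form oracles.

test_that("initialization is seeded, bounded, and has 1219 parameters", {
  arch <- mlp_architecture()
  w1 <- init_weights(arch, 42)
  w2 <- init_weights(arch, 42)
  expect_identical(w1, w2)
  w3 <- init_weights(arch, 43)
  expect_false(identical(w1, w3))
  expect_equal(n_params(arch), 19 * 20 + 20 + 20 * 20 + 20 + 20 * 19 + 19)
  expect_equal(n_params(arch), 1219L)
  for (l in seq_along(w1$layers)) {
    lim <- 1 / sqrt(arch$sizes[l])
    expect_true(all(abs(w1$layers[[l]]$W) <= lim))
    expect_true(all(abs(w1$layers[[l]]$b) <= lim))
  }
})

test_that("forward pass matches hand computation", {
  arch <- mlp_architecture()
  w <- init_weights(arch, 1)
  for (l in 1:3) {
    w$layers[[l]]$W[] <- 0
    w$layers[[l]]$b[] <- 0
  }
  Y <- mlp_forward(w, matrix(rnorm(19), 1, 19))
  expect_equal(as.vector(Y), rep(0, 19)) # logistic(0)=0.5 into zero W3

  # single-unit chain: tanh(0)=0 -> logistic(0)=0.5 -> 0.5 * w3
  chain <- mlp_architecture(c(1, 1, 1, 1))
  wc <- init_weights(chain, 1)
  for (l in 1:3) { wc$layers[[l]]$W[] <- 1; wc$layers[[l]]$b[] <- 0 }
  wc$layers[[3]]$W[] <- 0.8
  expect_equal(as.vector(mlp_forward(wc, matrix(0, 1, 1))), 0.5 * 0.8)

  expect_error(mlp_forward(w, matrix(0, 1, 5)), "expects 19")
})

test_that("analytic Jacobian matches central finite differences", {
  arch <- mlp_architecture(c(3, 4, 4, 2))
  w <- init_weights(arch, 7)
  X <- matrix(rnorm(15), 5, 3)
  J <- mlp_jacobian(w, X)
  Jfd <- fd_jacobian(w, X)
  expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-5)

  # zero input row: first-layer weight derivatives vanish for that row
  X0 <- rbind(0, X[-1, ])
  J0 <- mlp_jacobian(w, X0)
  w1_cols <- 1:(3 * 4)
  rows_of_sample1 <- seq(1, nrow(J0), by = nrow(X0)) # sample 1, each output
  expect_true(all(J0[rows_of_sample1, w1_cols] == 0))
})

test_that("Jacobian of a bias-free linear single layer is the input pattern", {
  arch <- mlp_architecture(c(4, 1), "linear", use_bias = FALSE)
  w <- init_weights(arch, 2)
  X <- matrix(rnorm(24), 6, 4)
  expect_equal(mlp_jacobian(w, X), X, ignore_attr = TRUE)
})

test_that("compiled Gauss-Newton terms equal crossprod of the reference Jacobian", {
  arch <- mlp_architecture(c(3, 5, 4, 2))
  w <- init_weights(arch, 12)
  X <- matrix(rnorm(21), 7, 3)
  Tt <- matrix(rnorm(14), 7, 2)
  J <- mlp_jacobian(w, X)
  E <- mlp_forward(w, X) - Tt
  gt <- balanceAD:::gn_terms(w$layers, c(0L, 1L, 2L), X, Tt, TRUE)
  expect_equal(gt$JtJ, crossprod(J), tolerance = 1e-12)
  expect_equal(drop(gt$Jte), drop(crossprod(J, as.vector(E))), tolerance = 1e-12)
  expect_equal(gt$E_D, sum(E^2))
})

test_that("frozen-hyperparameter LM on a linear model equals closed-form ridge", {
  set.seed(3)
  arch <- mlp_architecture(c(4, 1), "linear", use_bias = FALSE)
  X <- matrix(rnorm(80), 20, 4)
  tt <- matrix(rnorm(20), 20, 1)
  alpha <- 0.5; beta <- 2
  m <- train_bayes_reg(X, tt,
                       train_config(max_epochs = 200, fixed_alpha = alpha,
                                    fixed_beta = beta, grad_tol = 1e-12,
                                    seed = 5),
                       arch = arch)
  w_hat <- as.vector(m$final_weights$layers[[1]]$W)
  w_ridge <- solve(crossprod(X) + (alpha / beta) * diag(4), crossprod(X, tt))
  expect_lt(max(abs(w_hat - as.vector(w_ridge))), 1e-6)
})

test_that("with alpha frozen at 0 the trainer solves unregularized least squares", {
  set.seed(6)
  arch <- mlp_architecture(c(3, 1), "linear", use_bias = FALSE)
  X <- matrix(rnorm(60), 20, 3)
  tt <- matrix(X %*% c(1, -2, 0.5) + rnorm(20, sd = 0.1), 20, 1)
  m <- train_bayes_reg(X, tt,
                       train_config(max_epochs = 100, fixed_alpha = 0,
                                    fixed_beta = 1, grad_tol = 1e-13, seed = 2),
                       arch = arch)
  w_ols <- as.vector(qr.solve(X, tt))
  expect_lt(max(abs(as.vector(m$final_weights$layers[[1]]$W) - w_ols)), 1e-6)
})

test_that("larger alpha/beta shrinks the weight norm on the linear toy", {
  set.seed(9)
  arch <- mlp_architecture(c(4, 1), "linear", use_bias = FALSE)
  X <- matrix(rnorm(120), 30, 4)
  tt <- matrix(X %*% c(2, -1, 1, 0.5), 30, 1)
  ew <- vapply(c(0.1, 1, 10, 100), function(a) {
    m <- train_bayes_reg(X, tt,
                         train_config(max_epochs = 200, fixed_alpha = a,
                                      fixed_beta = 1, grad_tol = 1e-13,
                                      seed = 4),
                         arch = arch)
    sum(balanceAD:::flatten_weights(m$final_weights)^2)
  }, numeric(1))
  expect_true(all(diff(ew) < 0))
})

test_that("noiseless linearly realizable targets are fit exactly with gamma near the true rank", {
  set.seed(10)
  arch <- mlp_architecture(c(4, 2), "linear", use_bias = FALSE)
  X <- matrix(rnorm(160), 40, 4)
  W_true <- matrix(c(1, -1, 0.5, 2, 0.3, 0, 1, -0.5), 4, 2)
  Tt <- X %*% W_true
  m <- train_bayes_reg(X, Tt, train_config(max_epochs = 300, seed = 3,
                                           grad_tol = 0),
                       arch = arch)
  expect_lt(m$best_mse, 1e-8)
  expect_equal(m$gamma, n_params(arch), tolerance = 0.05) # 8 informative directions
})

test_that("gamma stays within [0, N_w] and the checkpoint MSE is the history minimum", {
  set.seed(20)
  X <- matrix(runif(30 * 6, -1, 1), 30, 6)
  Tt <- X[sample(30), ]
  arch <- mlp_architecture(c(6, 8, 8, 6))
  m <- train_bayes_reg(X, Tt, train_config(max_epochs = 60, seed = 8),
                       arch = arch)
  g <- m$history$gamma[!is.na(m$history$gamma)]
  expect_true(all(g >= 0 & g <= n_params(arch)))
  expect_true(all(m$history$alpha >= 0))
  expect_true(all(m$history$beta > 0))
  expect_equal(m$best_mse, min(m$history$mse))
  expect_equal(m$history$mse[m$best_epoch], m$best_mse)
})

test_that("evaluation returns exact MSE and shift-invariant R-squared", {
  arch <- mlp_architecture(c(2, 2), "linear", use_bias = FALSE)
  m <- structure(list(weights = {
    w <- init_weights(arch, 1)
    w$layers[[1]]$W <- diag(2)
    w
  }, arch = arch), class = "br_model")
  X <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2)
  ev <- evaluate_model(m, X, X)
  expect_equal(ev$r_squared, 1)
  expect_equal(ev$mse, 0)
  ev2 <- evaluate_model(m, X, X + 3)
  expect_equal(ev2$r_squared, 1)
  expect_equal(ev2$mse, 9)
  # 4-element case against the direct Pearson formula
  Tt <- matrix(c(1, 2, 4, 3, 5, 7, 6, 9), 4, 2)
  ev3 <- evaluate_model(m, X, Tt)
  r <- cor(as.vector(X), as.vector(Tt))
  expect_equal(ev3$r_squared, r^2)
  expect_warning(evaluate_model(m, X, matrix(1, 4, 2)), "constant")
})

test_that("row splits are disjoint, exhaustive, seeded", {
  sp <- split_rows(100, 0.85, seed = 4)
  expect_equal(length(sp$train), 85L)
  expect_equal(length(sp$test), 15L)
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_rows(100, 0.85, seed = 4))
  expect_error(split_rows(3, 0.99), "empty")
  expect_error(split_rows(1, 0.5), "at least 2")
})

test_that("full-architecture training runs with monotone checkpoint on a 150-row cohort-like matrix", {
  X <- toy_features(150, seed = 33)
  sc <- fit_scaler(X); Xs <- apply_scaler(X, sc)
  pt <- permute_targets(Xs, 17)
  m <- train_bayes_reg(Xs, pt$targets,
                       train_config(max_epochs = 200, seed = 21))
  expect_s3_class(m, "br_model")
  expect_equal(m$best_mse, min(m$history$mse))
  best_so_far <- cummin(m$history$mse)
  expect_true(all(diff(best_so_far) <= 0))
  g <- m$history$gamma[!is.na(m$history$gamma)]
  expect_true(all(g >= 0 & g <= 1219))
})

test_that("model serialization reproduces predictions and metadata", {
  X <- toy_features(30, seed = 5)
  sc <- fit_scaler(X); Xs <- apply_scaler(X, sc)
  pt <- permute_targets(Xs, 3)
  m <- train_bayes_reg(Xs, pt$targets, train_config(max_epochs = 10, seed = 2))
  m$scaler <- sc; m$permutation <- pt$permutation
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(mlp_forward(m2$weights, Xs), mlp_forward(m$weights, Xs),
               tolerance = 1e-12)
  expect_identical(m2$permutation, pt$permutation)
  expect_equal(m2$scaler$min, sc$min)
  expect_equal(m2$best_epoch, m$best_epoch)
})
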