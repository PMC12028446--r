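# Dense feed-forward network (default 19-20-20-19, tanh -> logistic ->
# linear) and a from-scratch Bayesian-regularization Levenberg-Marquardt
# trainer in the evidence-framework (Gauss-Newton Hessian) formulation:
# minimize F = beta * E_D + alpha * E_W, with alpha, beta re-estimated from
# the data after every accepted step and gamma the effective number of
# well-determined parameters.

.activations <- list(
  tanh = list(f = tanh, df = function(a) 1 - a^2),
  logistic = list(f = function(z) 1 / (1 + exp(-z)),
                  df = function(a) a * (1 - a)),
  linear = list(f = identity, df = function(a) rep(1, length(a)))
)

#' Describe a feed-forward architecture
#'
#' @param sizes integer vector of layer widths, input first. The default is
#'   the balance-assessment network: 19 inputs, two hidden layers of 20
#'   units, 19 outputs.
#' @param activations one activation name (`"tanh"`, `"logistic"`,
#'   `"linear"`) per non-input layer. The output layer is linear: targets
#'   live in `[-1, 1]`, so a linear read-out is safe and invertible.
#' @param use_bias logical; include bias vectors (default TRUE).
#' @return an object of class `mlp_arch`.
#' @export
mlp_architecture <- function(sizes = c(19, 20, 20, 19),
                             activations = c("tanh", "logistic", "linear"),
                             use_bias = TRUE) {
  if (length(sizes) < 2) stopf("need at least input and output layers")
  if (length(activations) != length(sizes) - 1) {
    stopf("need one activation per non-input layer")
  }
  bad <- setdiff(activations, names(.activations))
  if (length(bad)) stopf("unknown activation: %s", bad[1])
  structure(list(sizes = as.integer(sizes), activations = activations,
                 use_bias = isTRUE(use_bias)),
            class = "mlp_arch")
}

#' Total parameter count of an architecture
#'
#' For the default 19-20-20-19 network with biases this is
#' 19*20+20 + 20*20+20 + 20*19+19 = 1219.
#'
#' @param arch an [mlp_architecture()] (or `mlp_weights`).
#' @export
n_params <- function(arch) {
  if (inherits(arch, "mlp_weights")) arch <- arch$arch
  s <- arch$sizes
  L <- length(s) - 1
  sum(s[-length(s)] * s[-1]) + if (arch$use_bias) sum(s[-1]) else 0L
}

#' Initialize network weights
#'
#' Default scheme: every weight and bias of layer `l` drawn uniformly in
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`; fully seeded.
#'
#' @param arch an [mlp_architecture()].
#' @param seed integer seed.
#' @param scheme initialization scheme; only `"uniform_fanin"` currently.
#' @return an object of class `mlp_weights`: list of per-layer `W`
#'   (fan_in x fan_out) and `b`.
#' @export
init_weights <- function(arch, seed, scheme = c("uniform_fanin")) {
  scheme <- match.arg(scheme)
  s <- arch$sizes
  layers <- with_seed(seed, lapply(seq_len(length(s) - 1), function(l) {
    fan_in <- s[l]
    lim <- 1 / sqrt(fan_in)
    W <- matrix(stats::runif(fan_in * s[l + 1], -lim, lim), fan_in, s[l + 1])
    b <- if (arch$use_bias) stats::runif(s[l + 1], -lim, lim) else
      numeric(s[l + 1])
    list(W = W, b = b)
  }))
  structure(list(layers = layers, arch = arch), class = "mlp_weights")
}

flatten_weights <- function(weights) {
  unlist(lapply(weights$layers, function(l) {
    if (weights$arch$use_bias) c(as.vector(l$W), l$b) else as.vector(l$W)
  }), use.names = FALSE)
}

unflatten_weights <- function(w, arch) {
  s <- arch$sizes
  layers <- vector("list", length(s) - 1)
  pos <- 0L
  for (l in seq_along(layers)) {
    nw <- s[l] * s[l + 1]
    W <- matrix(w[pos + seq_len(nw)], s[l], s[l + 1])
    pos <- pos + nw
    if (arch$use_bias) {
      b <- w[pos + seq_len(s[l + 1])]
      pos <- pos + s[l + 1]
    } else b <- numeric(s[l + 1])
    layers[[l]] <- list(W = W, b = b)
  }
  structure(list(layers = layers, arch = arch), class = "mlp_weights")
}

# Forward pass keeping activations and activation derivatives per layer.
forward_pass <- function(weights, X) {
  arch <- weights$arch
  L <- length(weights$layers)
  A <- vector("list", L + 1)
  D <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    act <- .activations[[arch$activations[l]]]
    Z <- A[[l]] %*% weights$layers[[l]]$W
    if (arch$use_bias) Z <- sweep(Z, 2, weights$layers[[l]]$b, "+")
    Al <- act$f(Z)
    A[[l + 1]] <- Al
    D[[l]] <- matrix(act$df(Al), nrow(Al), ncol(Al))
  }
  list(A = A, D = D)
}

#' Network forward pass
#'
#' @param weights an `mlp_weights` object.
#' @param X matrix with one row per sample and `sizes[1]` columns.
#' @return prediction matrix, one row per sample.
#' @export
mlp_forward <- function(weights, X) {
  stopifnot(inherits(weights, "mlp_weights"))
  X <- as.matrix(X)
  if (ncol(X) != weights$arch$sizes[1]) {
    stopf("X has %d columns; the network expects %d",
          ncol(X), weights$arch$sizes[1])
  }
  fp <- forward_pass(weights, X)
  fp$A[[length(fp$A)]]
}

# Row-wise Khatri-Rao product: column (j-1)*p + m is A[, m] * B[, j].
.krp <- function(A, B) {
  p <- ncol(A); q <- ncol(B)
  A[, rep(seq_len(p), times = q), drop = FALSE] *
    B[, rep(seq_len(q), each = p), drop = FALSE]
}

# Per-layer column offsets in the flattened parameter vector.
.param_offsets <- function(arch) {
  s <- arch$sizes
  L <- length(s) - 1
  offs <- vector("list", L)
  pos <- 0L
  for (l in seq_len(L)) {
    nw <- s[l] * s[l + 1]
    offs[[l]] <- list(W = pos, b = pos + nw)
    pos <- pos + nw + if (arch$use_bias) s[l + 1] else 0L
  }
  offs
}

#' Jacobian of the network outputs with respect to all parameters
#'
#' Rows are ordered output-block first: rows `(k-1)*n + i` hold
#' `d y[i, k] / d w`. This matches `as.vector(Y - T)` (column-major) as the
#' error vector for Levenberg-Marquardt.
#'
#' @param weights an `mlp_weights` object.
#' @param X input matrix.
#' @return `(n * n_out) x n_params(arch)` matrix.
#' @export
mlp_jacobian <- function(weights, X) {
  stopifnot(inherits(weights, "mlp_weights"))
  X <- as.matrix(X)
  arch <- weights$arch
  fp <- forward_pass(weights, X)
  n <- nrow(X)
  L <- length(weights$layers)
  K <- arch$sizes[length(arch$sizes)]
  offs <- .param_offsets(arch)
  Np <- n_params(arch)
  J <- matrix(0, n * K, Np)
  for (k in seq_len(K)) {
    rows <- (k - 1L) * n + seq_len(n)
    # output layer: d y_k / d W_L[, j] is nonzero only for j = k
    dL <- fp$D[[L]][, k]
    wcol <- offs[[L]]$W + (k - 1L) * arch$sizes[L] + seq_len(arch$sizes[L])
    J[rows, wcol] <- fp$A[[L]] * dL
    if (arch$use_bias) J[rows, offs[[L]]$b + k] <- dL
    if (L > 1) {
      # delta starts as sensitivity wrt layer L-1 activations
      delta <- matrix(dL, n, arch$sizes[L]) *
        matrix(weights$layers[[L]]$W[, k], n, arch$sizes[L], byrow = TRUE)
      for (l in seq(L - 1, 1)) {
        delta <- delta * fp$D[[l]] # now sensitivity wrt Z_l
        J[rows, offs[[l]]$W + seq_len(arch$sizes[l] * arch$sizes[l + 1])] <-
          .krp(fp$A[[l]], delta)
        if (arch$use_bias) {
          J[rows, offs[[l]]$b + seq_len(arch$sizes[l + 1])] <- delta
        }
        if (l > 1) delta <- delta %*% t(weights$layers[[l]]$W)
      }
    }
  }
  J
}

#' Training configuration for the Bayesian-regularization trainer
#'
#' @param max_epochs maximum outer Levenberg-Marquardt iterations
#'   (default 10000).
#' @param mu_init initial damping (default 0.005).
#' @param mu_increase,mu_decrease damping schedule factors (x10 on a
#'   rejected step, /10 on an accepted one).
#' @param mu_max training stops once damping exceeds this (default 1e10).
#' @param grad_tol stop when the gradient norm of the regularized objective
#'   falls below this (default 1e-7).
#' @param seed master seed; weight initialization uses a seed derived from
#'   it.
#' @param train_fraction fraction of rows used for training when the caller
#'   lets the trainer split (default 0.85).
#' @param fixed_alpha,fixed_beta freeze the regularization hyperparameters
#'   at the given values instead of evidence re-estimation (used for
#'   plain-LM and ridge-equivalence checks; `NULL` = adapt).
#' @return an object of class `train_config`.
#' @export
train_config <- function(max_epochs = 10000, mu_init = 0.005,
                         mu_increase = 10, mu_decrease = 10,
                         mu_max = 1e10, grad_tol = 1e-7, seed = 1,
                         train_fraction = 0.85,
                         fixed_alpha = NULL, fixed_beta = NULL) {
  if (max_epochs < 1) stopf("max_epochs must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must be in (0, 1)")
  }
  structure(list(max_epochs = as.integer(max_epochs), mu_init = mu_init,
                 mu_increase = mu_increase, mu_decrease = mu_decrease,
                 mu_max = mu_max, grad_tol = grad_tol, seed = seed,
                 train_fraction = train_fraction,
                 fixed_alpha = fixed_alpha, fixed_beta = fixed_beta),
            class = "train_config")
}

#' Split row indices into train and test sets
#'
#' Disjoint, exhaustive and seeded.
#'
#' @param n number of rows.
#' @param train_fraction fraction assigned to training (default 0.85).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`.
#' @export
split_rows <- function(n, train_fraction = 0.85, seed = 1) {
  if (n < 2) stopf("need at least 2 rows to split")
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n) {
    stopf("train_fraction %g yields an empty train or test set for n = %d",
          train_fraction, n)
  }
  train <- sort(with_seed(seed, sample.int(n, n_train)))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Train a network with Bayesian-regularization Levenberg-Marquardt
#'
#' Minimizes `F = beta * E_D + alpha * E_W` (`E_D` the sum of squared
#' errors over training rows, `E_W` the sum of squared weights) by damped
#' Gauss-Newton steps
#' `dw = -(2 beta J'J + (2 alpha + mu) I)^{-1} (2 beta J'e + 2 alpha w)`.
#' After each accepted step the evidence framework re-estimates the
#' hyperparameters: with `H ~ 2 beta J'J + 2 alpha I`,
#' `gamma = N_w - 2 alpha tr(H^-1)`, `alpha = gamma / (2 E_W)`,
#' `beta = (N - gamma) / (2 E_D)` (`N` = number of training error terms).
#' Initial `alpha = 0`, `beta = 1`. Training stops at `max_epochs`, when
#' `mu` exceeds `mu_max`, or when the gradient norm drops below
#' `grad_tol`; the epoch and weights with minimum training MSE are
#' retained as the model checkpoint.
#'
#' @param X scaled input matrix.
#' @param T_target scaled (permuted) target matrix, same shape as the
#'   network output.
#' @param config a [train_config()].
#' @param rows integer indices of the training rows (default: all).
#' @param arch an [mlp_architecture()]; default the 19-20-20-19 balance
#'   network.
#' @param weights optional initial `mlp_weights` (default: seeded
#'   [init_weights()]).
#' @param keep_history logical; record the per-epoch trace (default TRUE).
#' @return an object of class `br_model`; see Details.
#' @details The returned model contains the best-checkpoint `weights`, the
#'   final hyperparameters `alpha`, `beta` and effective parameter count
#'   `gamma`, `best_epoch` and `best_mse`, a `history` data frame
#'   (epoch, mse, alpha, beta, gamma, mu), the training `rows`, the
#'   `config`, and the stopping `reason`. Slots `scaler` and `permutation`
#'   are filled by [run_anomaly_pipeline()].
#' @export
train_bayes_reg <- function(X, T_target, config = train_config(),
                            rows = NULL, arch = NULL, weights = NULL,
                            keep_history = TRUE) {
  X <- as.matrix(X); T_target <- as.matrix(T_target)
  if (nrow(X) != nrow(T_target)) {
    stopf("X and T_target must have the same number of rows")
  }
  if (is.null(arch)) {
    arch <- mlp_architecture(sizes = c(ncol(X), 20, 20, ncol(T_target)))
  }
  if (is.null(rows)) rows <- seq_len(nrow(X))
  if (length(rows) < 2) stopf("need at least 2 training rows")
  Xtr <- X[rows, , drop = FALSE]
  Ttr <- T_target[rows, , drop = FALSE]
  if (is.null(weights)) {
    weights <- init_weights(arch, derive_seed(config$seed, 37L))
  }
  Np <- n_params(arch)
  N <- length(Ttr)
  w <- flatten_weights(weights)

  adapt <- is.null(config$fixed_alpha) && is.null(config$fixed_beta)
  alpha <- config$fixed_alpha %||% 0
  beta <- config$fixed_beta %||% 1
  mu <- config$mu_init

  obj <- function(wvec) {
    wt <- unflatten_weights(wvec, arch)
    E <- mlp_forward(wt, Xtr) - Ttr
    sum(E * E)
  }
  E_D <- obj(w)
  E_W <- sum(w * w)
  F_cur <- beta * E_D + alpha * E_W

  gamma <- NA_real_
  best_mse <- E_D / N
  best_w <- w
  best_epoch <- 0L
  hist <- if (keep_history) {
    data.frame(epoch = integer(), mse = numeric(), alpha = numeric(),
               beta = numeric(), gamma = numeric(), mu = numeric())
  } else NULL
  reason <- "max_epochs"

  act_codes <- match(arch$activations, c("tanh", "logistic", "linear")) - 1L

  for (epoch in seq_len(config$max_epochs)) {
    wt <- unflatten_weights(w, arch)
    # Gauss-Newton terms J'J and J'e from the compiled block-structured
    # accumulation (equals crossprod on the full mlp_jacobian)
    gt <- gn_terms(wt$layers, act_codes, Xtr, Ttr, arch$use_bias)
    E_D <- gt$E_D
    E_W <- sum(w * w)
    F_cur <- beta * E_D + alpha * E_W
    g <- 2 * beta * drop(gt$Jte) + 2 * alpha * w
    if (!all(is.finite(g))) stopf("non-finite gradient at epoch %d", epoch)
    if (sqrt(sum(g * g)) < config$grad_tol) {
      reason <- "grad_tol"
      break
    }
    JtJ <- gt$JtJ

    accepted <- FALSE
    while (mu <= config$mu_max) {
      A <- 2 * beta * JtJ
      diag(A) <- diag(A) + 2 * alpha + mu
      ch <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(ch)) {
        mu <- mu * config$mu_increase
        next
      }
      dw <- -backsolve(ch, backsolve(ch, g, transpose = TRUE))
      w_new <- w + dw
      E_D_new <- obj(w_new)
      F_new <- beta * E_D_new + alpha * sum(w_new * w_new)
      if (is.finite(F_new) && F_new < F_cur) {
        w <- w_new
        E_D <- E_D_new
        E_W <- sum(w * w)
        mu <- max(mu / config$mu_decrease, 1e-20)
        accepted <- TRUE
        break
      }
      mu <- mu * config$mu_increase
    }
    if (!accepted) {
      reason <- "mu_max"
      break
    }
    if (!is.finite(E_D)) stopf("non-finite loss at epoch %d", epoch)

    if (adapt) {
      # Evidence update (Gauss-Newton Hessian at the pre-step Jacobian).
      if (alpha == 0) {
        gamma <- min(Np, N)
      } else {
        H <- 2 * beta * JtJ
        diag(H) <- diag(H) + 2 * alpha
        tr_inv <- tryCatch(sum(diag(chol2inv(chol(H)))),
                           error = function(e) NA_real_)
        gamma <- if (is.na(tr_inv)) gamma else Np - 2 * alpha * tr_inv
      }
      gamma <- min(max(gamma, 0), Np)
      alpha <- gamma / max(2 * E_W, .Machine$double.eps)
      beta <- max(N - gamma, .Machine$double.eps) /
        max(2 * E_D, .Machine$double.eps)
      beta <- min(beta, 1e12)
      alpha <- min(alpha, 1e12)
    }
    F_cur <- beta * E_D + alpha * E_W

    mse <- E_D / N
    if (keep_history) {
      hist[nrow(hist) + 1L, ] <- list(epoch, mse, alpha, beta,
                                      if (is.na(gamma)) NA_real_ else gamma,
                                      mu)
    }
    if (mse < best_mse) {
      best_mse <- mse
      best_w <- w
      best_epoch <- epoch
    }
  }

  structure(list(
    weights = unflatten_weights(best_w, arch),
    final_weights = unflatten_weights(w, arch),
    arch = arch, alpha = alpha, beta = beta, gamma = gamma,
    best_epoch = best_epoch, best_mse = best_mse,
    history = hist, rows = rows, config = config, reason = reason,
    scaler = NULL, permutation = NULL, test_rows = NULL
  ), class = "br_model")
}

#' @export
print.br_model <- function(x, ...) {
  cat(sprintf(
    "<br_model> %s net, best MSE %.5g at epoch %d (stop: %s)\n  alpha = %.4g, beta = %.4g, gamma = %.1f of %d parameters\n",
    paste(x$arch$sizes, collapse = "-"), x$best_mse, x$best_epoch,
    x$reason, x$alpha, x$beta, x$gamma, n_params(x$arch)))
  invisible(x)
}

#' Evaluate a trained model on a row subset
#'
#' @param model a `br_model`.
#' @param X,T_target scaled inputs and targets.
#' @param rows integer indices of the rows to evaluate (default: all).
#' @return list with `mse` (mean squared error over all output elements)
#'   and `r_squared` (squared Pearson correlation between flattened
#'   predictions and targets; `NA` with a warning if either side is
#'   constant).
#' @export
evaluate_model <- function(model, X, T_target, rows = NULL) {
  stopifnot(inherits(model, "br_model"))
  if (is.null(rows)) rows <- seq_len(nrow(X))
  if (!length(rows)) stopf("rows must be nonempty")
  P <- mlp_forward(model$weights, as.matrix(X)[rows, , drop = FALSE])
  Tm <- as.matrix(T_target)[rows, , drop = FALSE]
  mse <- mean((P - Tm)^2)
  p <- as.vector(P); t <- as.vector(Tm)
  if (stats::sd(p) == 0 || stats::sd(t) == 0) {
    warnf("constant predictions or targets; r_squared undefined")
    r2 <- NA_real_
  } else {
    r2 <- stats::cor(p, t)^2
  }
  list(mse = mse, r_squared = r2)
}
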