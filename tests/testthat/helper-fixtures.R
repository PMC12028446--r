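# Shared fixtures: tiny trials, analytic CoP paths, and small synthetic
# feature tables that avoid the full signal pipeline where it is not the
# thing under test.

make_trial <- function(n = 100, fz = 600, my = -30, mx = 12, fs = 100, ...) {
  force_plate_trial(fx = numeric(n), fy = numeric(n), fz = rep(fz, n),
                    mx = rep(mx, n), my = rep(my, n), mz = numeric(n),
                    sample_rate = fs, ...)
}

sine_cop <- function(freq, fs = 100, dur = 20, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  cop_series(amp * sin(2 * pi * freq * t), amp * sin(2 * pi * freq * t), fs)
}

# small correlated feature table mimicking a cohort without signal work:
# an age-like latent drives the 12 sway columns
toy_features <- function(n = 40, seed = 1, p = 19) {
  set.seed(seed)
  age <- runif(n, 18, 85)
  X <- matrix(rnorm(n * p, sd = 0.1), n, p)
  X[, 1] <- age
  for (j in 8:p) X[, j] <- 0.5 + 0.01 * age + rnorm(n, sd = 0.05)
  X[, 2] <- rbinom(n, 1, 0.3)
  X[, 3] <- rnorm(n, 62, 8); X[, 4] <- rnorm(n, 162, 9)
  X[, 5] <- X[, 3] / (X[, 4] / 100)^2
  X[, 6] <- 0.152 * X[, 4] + rnorm(n, 0, 0.5)
  X[, 7] <- pmax(2, 16 - 0.1 * (age - 18) + rnorm(n, 0, 2))
  colnames(X) <- feature_columns()
  rownames(X) <- sprintf("S%03d", seq_len(n))
  X
}

# brute-force percentile by linear interpolation of order statistics,
# independent of stats::quantile
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- p * (length(s) - 1)
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

fd_jacobian <- function(weights, X, h = 1e-6) {
  arch <- weights$arch
  wv <- balanceAD:::flatten_weights(weights)
  K <- arch$sizes[length(arch$sizes)]
  out <- matrix(0, nrow(X) * K, length(wv))
  for (p in seq_along(wv)) {
    wp <- wv; wp[p] <- wp[p] + h
    wm <- wv; wm[p] <- wm[p] - h
    Yp <- mlp_forward(balanceAD:::unflatten_weights(wp, arch), X)
    Ym <- mlp_forward(balanceAD:::unflatten_weights(wm, arch), X)
    out[, p] <- as.vector((Yp - Ym) / (2 * h))
  }
  out
}
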