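# The anomaly score: simulate each participant through the trained
# network, regress the real 19-vector on the predicted one, min-max
# normalize the R-squared values, and split at the 25th/75th percentiles.

.group_levels <- c("below_25", "mid_25_75", "above_75")

#' Per-participant agreement score
#'
#' Predicts the participant's 19 output variables from their (scaled)
#' feature vector and fits a single ordinary least-squares regression of
#' the real values on the predictions across the 19 variable pairs. The
#' returned R-squared equals the squared Pearson correlation of the two
#' vectors, so the regression direction is immaterial. The comparison is
#' done in the model's scaled space.
#'
#' @param model a trained `br_model`.
#' @param x_scaled the participant's scaled 19-element feature vector.
#' @return R-squared in `[0, 1]`; 0 with attribute `degenerate = TRUE` if
#'   either vector has zero variance.
#' @export
participant_score <- function(model, x_scaled) {
  stopifnot(inherits(model, "br_model"))
  x <- as.numeric(x_scaled)
  pred <- as.numeric(mlp_forward(model$weights, matrix(x, nrow = 1)))
  if (stats::sd(pred) == 0 || stats::sd(x) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(pred, x)^2
}

#' Score every row of a scaled feature matrix
#'
#' @param model a trained `br_model`.
#' @param Xs scaled feature matrix (all participants, training and test
#'   rows alike).
#' @return numeric vector of per-row R-squared values, named by row names.
#' @export
score_participants <- function(model, Xs) {
  Xs <- as.matrix(Xs)
  P <- mlp_forward(model$weights, Xs)
  out <- vapply(seq_len(nrow(Xs)), function(i) {
    p <- P[i, ]; x <- Xs[i, ]
    if (stats::sd(p) == 0 || stats::sd(x) == 0) 0 else stats::cor(p, x)^2
  }, numeric(1))
  names(out) <- rownames(Xs)
  out
}

#' Min-max normalize anomaly scores
#'
#' `s' = (s - min) / (max - min)`: the lowest score maps to 0, the highest
#' to 1, and the ordering of participants is preserved.
#'
#' @param scores numeric vector of per-participant R-squared values.
#' @return normalized scores in `[0, 1]`.
#' @export
normalize_scores <- function(scores) {
  if (length(scores) < 2) stopf("need at least 2 participants to normalize")
  lo <- min(scores); hi <- max(scores)
  if (hi == lo) stopf("all scores identical; normalization (and grouping) undefined")
  (scores - lo) / (hi - lo)
}

#' Assign percentile subgroups
#'
#' The 25th and 75th percentiles are computed by linear interpolation of
#' order statistics (index `h = p * (n - 1)`; `quantile` type 7). Scores
#' strictly below P25 form `below_25`, strictly above P75 form `above_75`,
#' and everything else (boundaries included) forms `mid_25_75`.
#'
#' @param norm_scores normalized scores from [normalize_scores()].
#' @return factor with levels `below_25`, `mid_25_75`, `above_75`.
#' @export
assign_groups <- function(norm_scores) {
  if (length(norm_scores) < 4) stopf("need at least 4 participants to form groups")
  qs <- stats::quantile(norm_scores, c(0.25, 0.75), type = 7, names = FALSE)
  g <- ifelse(norm_scores < qs[1], "below_25",
              ifelse(norm_scores > qs[2], "above_75", "mid_25_75"))
  factor(g, levels = .group_levels)
}

#' Run the full anomaly-detection pipeline on a feature matrix
#'
#' Scale (min-max to `[-1, 1]`, fitted on the training rows), permute the
#' participant order to form targets, train the Bayesian-regularization
#' network, score all participants (training and test rows alike),
#' normalize, and group at the 25th/75th percentiles. All randomness
#' (split, initialization, permutation) fans out from one master seed.
#'
#' @param features a participants x 19 matrix from [assemble_features()].
#' @param config a [train_config()]; its `seed` is the master seed.
#' @param arch optional [mlp_architecture()] override.
#' @return list of class `anomaly_run` with `results` (data frame:
#'   `participant_id`, `r_squared`, `norm_score`, `group`), the trained
#'   `model` (with scaler and permutation attached), and `evaluation`
#'   (train/test/all MSE and R-squared).
#' @export
run_anomaly_pipeline <- function(features, config = train_config(),
                                 arch = NULL) {
  X <- as.matrix(features)
  n <- nrow(X)
  split <- split_rows(n, config$train_fraction,
                      seed = stage_seed(config$seed, "split"))
  scaler <- fit_scaler(X, rows = split$train)
  Xs <- apply_scaler(X, scaler)
  pt <- permute_targets(Xs, seed = stage_seed(config$seed, "permute"))
  model <- train_bayes_reg(Xs, pt$targets, config = config,
                           rows = split$train, arch = arch)
  model$scaler <- scaler
  model$permutation <- pt$permutation
  model$test_rows <- split$test
  evaluation <- list(
    train = evaluate_model(model, Xs, pt$targets, split$train),
    test = evaluate_model(model, Xs, pt$targets, split$test),
    all = evaluate_model(model, Xs, pt$targets)
  )
  r2 <- score_participants(model, Xs)
  ns <- normalize_scores(r2)
  grp <- assign_groups(ns)
  results <- data.frame(
    participant_id = rownames(X) %||% as.character(seq_len(n)),
    r_squared = unname(r2), norm_score = unname(ns), group = grp,
    stringsAsFactors = FALSE)
  structure(list(results = results, model = model, evaluation = evaluation),
            class = "anomaly_run")
}

#' @export
print.anomaly_run <- function(x, ...) {
  tab <- table(x$results$group)
  cat(sprintf(
    "<anomaly_run> %d participants: %d below_25 / %d mid / %d above_75\n  train R2 = %.5f, test R2 = %.5f, all R2 = %.5f; best MSE %.4f (epoch %d)\n",
    nrow(x$results), tab["below_25"], tab["mid_25_75"], tab["above_75"],
    x$evaluation$train$r_squared, x$evaluation$test$r_squared,
    x$evaluation$all$r_squared, x$model$best_mse, x$model$best_epoch))
  invisible(x)
}
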