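# The 19-variable participant feature matrix: 7 socio-anthropometric
# columns followed by 4 conditions x 3 sway metrics, plus min-max scaling
# and the permuted training targets.

.conditions <- data.frame(
  label = c("firm_eo", "firm_ec", "foam_eo", "foam_ec"),
  surface = c("firm", "firm", "foam", "foam"),
  vision = c("open", "closed", "open", "closed"),
  stringsAsFactors = FALSE)

.metrics <- c("area", "mean_velocity", "median_frequency")

#' Canonical feature column names
#'
#' The fixed, documented order of the 19 modeling variables: age, gender
#' (F = 0, M = 1), body mass (kg), height (cm), BMI (kg/m^2), foot length
#' (cm), years of education, then for each condition (firm eyes-open, firm
#' eyes-closed, foam eyes-open, foam eyes-closed) the ellipse area (cm^2),
#' mean velocity (cm/s) and median frequency (Hz).
#'
#' @return character vector of length 19.
#' @export
feature_columns <- function() {
  c("age", "gender", "mass", "height", "bmi", "foot_length",
    "education_years",
    as.vector(t(outer(.conditions$label, .metrics, paste, sep = "_"))))
}

#' Assemble the participants x 19 feature matrix
#'
#' Joins demographics with per-condition sway features. Participants
#' missing any of the four condition cells are excluded from the matrix and
#' listed in the `excluded` attribute with the reason, never silently
#' dropped.
#'
#' @param demographics data frame with columns `participant_id`, `age`,
#'   `gender` (`"F"`/`"M"`), `mass`, `height`, `bmi`, `foot_length`,
#'   `education_years`.
#' @param sway long data frame as returned by [cohort_sway_features()].
#' @param include optional character vector of participant ids to model
#'   (an explicit inclusion list); default all.
#' @return numeric matrix (class `feature_matrix`) with participant ids as
#'   row names, the 19 canonical columns, and attribute `excluded`
#'   (data frame `participant_id`, `reason`).
#' @export
assemble_features <- function(demographics, sway, include = NULL) {
  if (inherits(demographics, "cohort_recordings")) {
    demographics <- demographics$demographics
  }
  ids <- as.character(demographics$participant_id)
  if (!is.null(include)) ids <- intersect(ids, as.character(include))
  cols <- feature_columns()
  excluded <- list()
  rows <- list()
  for (id in ids) {
    d <- demographics[demographics$participant_id == id, , drop = FALSE]
    v <- numeric(19)
    names(v) <- cols
    v["age"] <- d$age
    v["gender"] <- if (toupper(d$gender) == "M") 1 else 0
    v["mass"] <- d$mass
    v["height"] <- d$height
    v["bmi"] <- d$bmi
    v["foot_length"] <- d$foot_length
    v["education_years"] <- d$education_years
    ok <- TRUE
    for (ci in seq_len(nrow(.conditions))) {
      s <- sway[sway$participant_id == id &
                  sway$surface == .conditions$surface[ci] &
                  sway$vision == .conditions$vision[ci], , drop = FALSE]
      if (nrow(s) != 1L) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          participant_id = id,
          reason = sprintf("missing condition %s", .conditions$label[ci]),
          stringsAsFactors = FALSE)
        ok <- FALSE
        break
      }
      for (m in .metrics) {
        v[paste(.conditions$label[ci], m, sep = "_")] <- s[[m]]
      }
    }
    if (ok && anyNA(v)) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        participant_id = id, reason = "missing value",
        stringsAsFactors = FALSE)
      ok <- FALSE
    }
    if (ok) rows[[id]] <- v
  }
  if (!length(rows)) stopf("no participant has complete features")
  X <- do.call(rbind, rows)
  colnames(X) <- cols
  attr(X, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(participant_id = character(), reason = character())
  class(X) <- c("feature_matrix", class(X))
  X
}

#' Fit a per-column min-max scaler
#'
#' Minima and maxima are taken over the training rows only, so test rows
#' may legitimately scale outside `[-1, 1]`. Constant columns are flagged
#' and mapped to 0.
#'
#' @param X numeric matrix.
#' @param rows integer indices of the training rows (default: all rows).
#' @return an object of class `minmax_scaler`.
#' @export
fit_scaler <- function(X, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(X))
  if (length(rows) < 2) stopf("need at least 2 training rows to fit a scaler")
  sub <- X[rows, , drop = FALSE]
  mins <- apply(sub, 2, min)
  maxs <- apply(sub, 2, max)
  structure(list(min = mins, max = maxs, constant = maxs == mins),
            class = "minmax_scaler")
}

#' Scale a matrix to `[-1, 1]` with a fitted scaler
#'
#' `x' = 2 (x - min) / (max - min) - 1` per column; constant columns map
#' to 0. Values outside the training range extrapolate beyond `[-1, 1]`.
#'
#' @param X numeric matrix with the scaler's column count.
#' @param scaler a [fit_scaler()] result.
#' @export
apply_scaler <- function(X, scaler) {
  stopifnot(inherits(scaler, "minmax_scaler"), ncol(X) == length(scaler$min))
  rng <- scaler$max - scaler$min
  rng[scaler$constant] <- 1 # avoid 0/0; numerator is 0 there anyway
  out <- sweep(sweep(X, 2, scaler$min), 2, rng, "/") * 2 - 1
  out[, scaler$constant] <- 0
  out
}

#' Invert [apply_scaler()] exactly
#'
#' Constant columns are restored to their (constant) training value.
#'
#' @param Xs scaled matrix.
#' @param scaler a [fit_scaler()] result.
#' @export
inverse_scaler <- function(Xs, scaler) {
  stopifnot(inherits(scaler, "minmax_scaler"), ncol(Xs) == length(scaler$min))
  rng <- scaler$max - scaler$min
  out <- sweep(sweep((Xs + 1) / 2, 2, rng, "*"), 2, scaler$min, "+")
  for (j in which(scaler$constant)) out[, j] <- scaler$min[j]
  out
}

#' Build the permuted training targets
#'
#' The network's output layer carries the same 19 variables as the input,
#' but with the order of participants randomized: the target for row `i` is
#' the (scaled) feature vector of participant `perm[i]`. The permutation is
#' drawn uniformly (identity and fixed points permitted) and returned so a
#' trained model is fully reproducible.
#'
#' @param Xs scaled feature matrix.
#' @param seed integer seed for the permutation draw.
#' @return list with `targets` (row-permuted copy of `Xs`) and
#'   `permutation` (integer vector; `targets[i, ] == Xs[permutation[i], ]`).
#' @export
permute_targets <- function(Xs, seed) {
  n <- nrow(Xs)
  if (n < 2) stopf("need at least 2 rows to permute")
  perm <- with_seed(seed, sample.int(n))
  list(targets = Xs[perm, , drop = FALSE], permutation = perm)
}
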