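# Synthetic cohort simulator: demographics with realistic covariance,
# condition- and age-dependent AR(1) sway, the exact force-platform inverse
# model, and planted demographics-sway-mismatch anomalies. Gives every
# other module a no-download test surface.

#' Specification of a synthetic cohort
#'
#' Defaults describe a plausible adult convenience sample spanning 18-85
#' years: sway magnitude grows ~10% per decade of age, closing the eyes
#' multiplies sway by 1.5 and standing on foam by 2.0 (multiplicative
#' across factors), and CoP dynamics follow a slow AR(1) (coefficient
#' 0.995 at 100 Hz).
#'
#' @param n_participants cohort size.
#' @param seed master seed; the whole cohort (demographics, every trial,
#'   anomaly flags) is reproducible from it.
#' @param age_range years, default `c(18, 85)`.
#' @param female_fraction proportion of women (default 0.72).
#' @param height_mean,height_sd named by gender (`F`, `M`), cm.
#' @param mass_mean,mass_sd named by gender, kg.
#' @param mass_height_cor within-gender mass-height correlation.
#' @param height_bounds,mass_bounds truncation bounds (plausibility).
#' @param education_mean mean years of study at age 18.
#' @param education_age_slope change in expected years of study per year
#'   of age (negative: older cohorts report less schooling).
#' @param education_sd residual SD of years of study.
#' @param baseline_sd stationary CoP SD (cm) per axis for an 18-year-old
#'   on firm ground, eyes open.
#' @param age_slope fractional sway increase per decade of age.
#' @param ec_mult,foam_mult condition multipliers (eyes closed, foam);
#'   both must be >= 1.
#' @param ar_coef AR(1) coefficient of the sway dynamics.
#' @param sample_rate Hz; `duration` s per trial.
#' @param n_trials trials per condition.
#' @param anomaly_fraction fraction of participants planted as anomalous
#'   (demographics-sway mismatch), in `[0, 0.5)`.
#' @param anomaly_mechanism how a planted participant's sway is made
#'   inconsistent with their demographics: `"both"` (default) draws the
#'   sway-generating age from a distant donor *and* inverts the condition
#'   multipliers (their sway shrinks when the eyes close or the surface
#'   softens — the signature of a disordered sensory response);
#'   `"age_mismatch"` only re-draws the age; `"invert_conditions"` only
#'   inverts the multipliers.
#' @param anomaly_age_gap minimum |age difference| (years) between a
#'   planted participant's true age and the donor age generating their
#'   sway.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 150, seed = 1,
                        age_range = c(18, 85), female_fraction = 0.72,
                        height_mean = c(F = 158, M = 172),
                        height_sd = c(F = 6, M = 6.5),
                        mass_mean = c(F = 59, M = 69),
                        mass_sd = c(F = 7, M = 8),
                        mass_height_cor = 0.5,
                        height_bounds = c(140, 189.8),
                        mass_bounds = c(44, 75.9),
                        education_mean = 16, education_age_slope = -0.1,
                        education_sd = 2.5,
                        baseline_sd = 0.3, age_slope = 0.10,
                        ec_mult = 1.5, foam_mult = 2.0, ar_coef = 0.995,
                        sample_rate = 100, duration = 60, n_trials = 3,
                        anomaly_fraction = 0,
                        anomaly_mechanism = c("both", "age_mismatch",
                                              "invert_conditions"),
                        anomaly_age_gap = 25) {
  anomaly_mechanism <- match.arg(anomaly_mechanism)
  if (n_participants < 2) stopf("n_participants must be >= 2")
  if (age_range[1] < 18 || age_range[2] > 85 || age_range[1] >= age_range[2]) {
    stopf("age_range must be increasing and within [18, 85]")
  }
  if (ec_mult < 1 || foam_mult < 1) stopf("condition multipliers must be >= 1")
  if (anomaly_fraction < 0 || anomaly_fraction >= 0.5) {
    stopf("anomaly_fraction must be in [0, 0.5)")
  }
  if (abs(ar_coef) >= 1) stopf("ar_coef must be inside (-1, 1)")
  if (baseline_sd < 0) stopf("baseline_sd must be >= 0")
  structure(as.list(environment()), class = "cohort_spec")
}

.trunc_norm <- function(n, mean, sd, lo, hi) {
  # rejection sampling; bounds are wide relative to sd so this converges fast
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

#' Generate a synthetic demographics table
#'
#' Seeded draws: age uniform over the range; height and mass jointly
#' normal within gender (truncated to the plausibility bounds); BMI
#' computed from mass and height; foot length proportional to height with
#' noise; years of study decline with age.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with columns `participant_id`, `age`, `gender`,
#'   `mass`, `height`, `bmi`, `foot_length`, `education_years`.
#' @export
generate_participants <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  with_seed(derive_seed(spec$seed, 1L), {
    gender <- ifelse(stats::runif(n) < spec$female_fraction, "F", "M")
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    height <- numeric(n); mass <- numeric(n)
    for (g in c("F", "M")) {
      idx <- which(gender == g)
      if (!length(idx)) next
      h <- .trunc_norm(length(idx), spec$height_mean[[g]], spec$height_sd[[g]],
                       spec$height_bounds[1], spec$height_bounds[2])
      z <- (h - spec$height_mean[[g]]) / spec$height_sd[[g]]
      r <- spec$mass_height_cor
      m <- spec$mass_mean[[g]] + spec$mass_sd[[g]] *
        (r * z + sqrt(1 - r^2) * stats::rnorm(length(idx)))
      m <- pmin(pmax(m, spec$mass_bounds[1]), spec$mass_bounds[2])
      height[idx] <- h; mass[idx] <- m
    }
    edu <- spec$education_mean +
      spec$education_age_slope * (age - spec$age_range[1]) +
      stats::rnorm(n, 0, spec$education_sd)
    edu <- pmin(pmax(round(edu), 2), 22)
    data.frame(
      participant_id = sprintf("S%03d", seq_len(n)),
      age = round(age, 1), gender = gender,
      mass = round(mass, 1), height = round(height, 1),
      bmi = round(mass, 1) / (round(height, 1) / 100)^2,
      foot_length = round(0.152 * height + stats::rnorm(n, 0, 0.5), 1),
      education_years = edu,
      stringsAsFactors = FALSE)
  })
}

#' Stationary sway SD implied by the sway model
#'
#' `baseline_sd * (1 + age_slope * (age - age_min) / 10) * ec_mult^closed *
#' foam_mult^foam` (cm).
#'
#' @param spec a [cohort_spec()].
#' @param age years.
#' @param surface `"firm"` or `"foam"`; `vision` `"open"` or `"closed"`.
#' @param vision see `surface`.
#' @param invert logical; invert the condition multipliers (divide instead
#'   of multiply), the planted signature of a disordered condition
#'   response.
#' @export
sway_sd <- function(spec, age, surface, vision, invert = FALSE) {
  s <- spec$baseline_sd *
    (1 + spec$age_slope * (age - spec$age_range[1]) / 10)
  ec <- if (invert) 1 / spec$ec_mult else spec$ec_mult
  fo <- if (invert) 1 / spec$foam_mult else spec$foam_mult
  if (vision == "closed") s <- s * ec
  if (surface == "foam") s <- s * fo
  s
}

#' Generate one synthetic CoP trial
#'
#' Two independent AR(1) processes (anterior-posterior and
#' medial-lateral), each with the stationary SD given by [sway_sd()],
#' initialized from the stationary distribution.
#'
#' @param spec a [cohort_spec()].
#' @param age sway-generating age (years) — for planted anomalies this is
#'   the donor age, not the participant's true age.
#' @param surface,vision condition.
#' @param seed trial seed.
#' @param invert passed to [sway_sd()].
#' @return a [cop_series()] of `duration * sample_rate` samples.
#' @export
generate_cop_trial <- function(spec, age, surface, vision, seed,
                               invert = FALSE) {
  n <- round(spec$duration * spec$sample_rate)
  sigma <- sway_sd(spec, age, surface, vision, invert)
  if (sigma == 0) {
    return(cop_series(numeric(n), numeric(n), spec$sample_rate))
  }
  a <- spec$ar_coef
  innov_sd <- sigma * sqrt(1 - a^2)
  with_seed(seed, {
    gen <- function() {
      x0 <- stats::rnorm(1, 0, sigma)
      as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), a,
                               method = "recursive", init = x0))
    }
    cop_series(gen(), gen(), spec$sample_rate)
  })
}

#' Convert a CoP series to an equivalent force-platform trial
#'
#' Exact inverse of [compute_cop()] with zero sensor-plane offset:
#' `Fz = mass * 9.81` (constant quiet-stance load, optional noise),
#' `My = -cop_x[m] * Fz`, `Mx = cop_y[m] * Fz`, and `Fx = Fy = Mz = 0`.
#'
#' @param cop a [cop_series()] (cm).
#' @param mass body mass in kg (> 0).
#' @param noise_sd optional white noise SD added to Fz (N).
#' @param ... metadata passed to [force_plate_trial()].
#' @return a [force_plate_trial()].
#' @export
cop_to_forces <- function(cop, mass, noise_sd = 0, ...) {
  stopifnot(inherits(cop, "cop_series"))
  if (mass <= 0) stopf("mass must be > 0")
  n <- length(cop$cop_x)
  fz <- rep(mass * 9.81, n)
  if (noise_sd > 0) fz <- fz + stats::rnorm(n, 0, noise_sd)
  force_plate_trial(fx = numeric(n), fy = numeric(n), fz = fz,
                    mx = cop$cop_y / 100 * fz, my = -cop$cop_x / 100 * fz,
                    mz = numeric(n), sample_rate = cop$sample_rate, ...)
}

# Anomaly plan: which participants are planted and which donor age
# generates their sway. Seeded independently of trial noise so flipping
# anomaly_fraction does not perturb non-flagged participants.
anomaly_plan <- function(spec, demographics) {
  n <- nrow(demographics)
  n_anom <- round(spec$anomaly_fraction * n)
  plan <- data.frame(participant_id = demographics$participant_id,
                     flagged = FALSE,
                     sway_age = demographics$age,
                     invert = FALSE,
                     stringsAsFactors = FALSE)
  if (n_anom == 0) return(plan)
  mech <- spec$anomaly_mechanism %||% "both"
  with_seed(derive_seed(spec$seed, 2L), {
    flagged <- sample.int(n, n_anom)
    if (mech %in% c("both", "age_mismatch")) {
      for (i in flagged) {
        true_age <- demographics$age[i]
        donors <- demographics$age[abs(demographics$age - true_age) >=
                                     spec$anomaly_age_gap]
        plan$sway_age[i] <- if (length(donors)) {
          donors[sample.int(length(donors), 1)]
        } else {
          # degenerate narrow cohort: take the farthest age available
          demographics$age[which.max(abs(demographics$age - true_age))]
        }
      }
    }
    if (mech %in% c("both", "invert_conditions")) plan$invert[flagged] <- TRUE
    plan$flagged[flagged] <- TRUE
  })
  plan
}

.condition_grid <- function() {
  data.frame(surface = c("firm", "firm", "foam", "foam"),
             vision = c("open", "closed", "open", "closed"),
             stringsAsFactors = FALSE)
}

trial_seed <- function(spec, i_participant, i_condition, i_trial) {
  derive_seed(spec$seed, 3L, i_participant, i_condition, i_trial)
}

#' Simulate a cohort and extract its sway features in one pass
#'
#' For every participant, condition and trial: draw the AR(1) CoP series
#' (using the donor age for planted anomalies), convert it to a raw
#' force-platform trial, recover the CoP through the standard filtering
#' pipeline, and average the three sway metrics per condition — i.e. each
#' trial traverses the same signal path as a laboratory recording, without
#' materializing the whole cohort in memory.
#'
#' @param spec a [cohort_spec()].
#' @param ... passed to [compute_cop()] (e.g. `filter = FALSE`).
#' @return list of class `synthetic_cohort` with `demographics`, `sway`
#'   (long feature data frame as from [cohort_sway_features()]), `anomaly`
#'   (the ground-truth plan, kept separate from model inputs) and `spec`.
#' @export
simulate_cohort_features <- function(spec, ...) {
  stopifnot(inherits(spec, "cohort_spec"))
  dem <- generate_participants(spec)
  plan <- anomaly_plan(spec, dem)
  grid <- .condition_grid()
  rows <- vector("list", nrow(dem) * nrow(grid))
  k <- 0L
  for (i in seq_len(nrow(dem))) {
    for (ci in seq_len(nrow(grid))) {
      cops <- lapply(seq_len(spec$n_trials), function(tr) {
        cop <- generate_cop_trial(spec, plan$sway_age[i],
                                  grid$surface[ci], grid$vision[ci],
                                  seed = trial_seed(spec, i, ci, tr),
                                  invert = plan$invert[i])
        trial <- cop_to_forces(cop, dem$mass[i],
                               participant_id = dem$participant_id[i],
                               surface = grid$surface[ci],
                               vision = grid$vision[ci], trial_index = tr)
        compute_cop(trial, ...)
      })
      fe <- condition_features(cops, n_expected = spec$n_trials)
      k <- k + 1L
      rows[[k]] <- data.frame(
        participant_id = dem$participant_id[i],
        surface = grid$surface[ci], vision = grid$vision[ci],
        area = fe$area, mean_velocity = fe$mean_velocity,
        median_frequency = fe$median_frequency, stringsAsFactors = FALSE)
    }
  }
  structure(list(demographics = dem, sway = do.call(rbind, rows),
                 anomaly = plan, spec = spec),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk in the manifest layout
#'
#' Generates the same trials as [simulate_cohort_features()] (identical
#' seeds) but writes raw force-platform text files plus `manifest.csv`,
#' `demographics.csv` and `anomaly_truth.csv`, consumable by
#' [load_cohort()]. Intended for modest cohort sizes; a 60 s trial file is
#' ~0.5 MB of text.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_synthetic_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dem <- generate_participants(spec)
  plan <- anomaly_plan(spec, dem)
  grid <- .condition_grid()
  man <- list()
  for (i in seq_len(nrow(dem))) {
    for (ci in seq_len(nrow(grid))) {
      for (tr in seq_len(spec$n_trials)) {
        cop <- generate_cop_trial(spec, plan$sway_age[i],
                                  grid$surface[ci], grid$vision[ci],
                                  seed = trial_seed(spec, i, ci, tr),
                                  invert = plan$invert[i])
        trial <- cop_to_forces(cop, dem$mass[i],
                               participant_id = dem$participant_id[i],
                               surface = grid$surface[ci],
                               vision = grid$vision[ci], trial_index = tr)
        fname <- sprintf("%s_%s_%s_%d.csv", dem$participant_id[i],
                         grid$surface[ci], grid$vision[ci], tr)
        write_trial(trial, file.path(dir, fname))
        man[[length(man) + 1L]] <- data.frame(
          participant_id = dem$participant_id[i],
          surface = grid$surface[ci], vision = grid$vision[ci],
          trial = tr, file = fname, stringsAsFactors = FALSE)
      }
    }
  }
  utils::write.table(dem, file.path(dir, "demographics.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(do.call(rbind, man), file.path(dir, "manifest.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(plan, file.path(dir, "anomaly_truth.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants (%d planted anomalies), seed %d\n",
              nrow(x$demographics), sum(x$anomaly$flagged), x$spec$seed))
  invisible(x)
}
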