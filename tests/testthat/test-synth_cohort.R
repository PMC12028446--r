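# Synthetic-cohort generator: determinism, demographic plausibility, AR(1)
# sway calibration, the force-plate inverse model, and anomaly planting.

test_that("demographics are seeded, bounded, and internally consistent", {
  spec <- cohort_spec(n_participants = 40, seed = 3)
  d1 <- generate_participants(spec)
  d2 <- generate_participants(spec)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 40L)
  expect_true(all(d1$age >= 18 & d1$age <= 85))
  expect_true(all(d1$height >= 140 & d1$height <= 189.8))
  expect_true(all(d1$mass >= 44 & d1$mass <= 75.9))
  expect_equal(d1$bmi, d1$mass / (d1$height / 100)^2)
  expect_true(all(d1$gender %in% c("F", "M")))
  # education declines with age by construction
  expect_lt(cor(d1$age, d1$education_years), 0)
  # foot length tracks height
  expect_gt(cor(d1$height, d1$foot_length), 0.8)
})

test_that("spec validation rejects infeasible parameters", {
  expect_error(cohort_spec(age_range = c(10, 85)), "age_range")
  expect_error(cohort_spec(ec_mult = 0.8), "multipliers")
  expect_error(cohort_spec(anomaly_fraction = 0.6), "anomaly_fraction")
  expect_error(cohort_spec(ar_coef = 1), "ar_coef")
})

test_that("AR(1) sway reproduces its stationary SD and the condition ordering", {
  spec <- cohort_spec(n_participants = 2, seed = 1)
  for (cond in list(c("firm", "open"), c("foam", "closed"))) {
    cop <- generate_cop_trial(spec, 40, cond[1], cond[2], seed = 99)
    target <- sway_sd(spec, 40, cond[1], cond[2])
    expect_equal(sd(cop$cop_x), target, tolerance = 0.1)
    expect_equal(sd(cop$cop_y), target, tolerance = 0.1)
    expect_equal(length(cop$cop_x), 6000L)
  }
  # eyes-closed exceeds eyes-open for the same participant in >= 95% of seeds
  hits <- vapply(1:40, function(s) {
    eo <- generate_cop_trial(spec, 50, "firm", "open", seed = derive_seed(s, 1))
    ec <- generate_cop_trial(spec, 50, "firm", "closed", seed = derive_seed(s, 2))
    sd(ec$cop_x) > sd(eo$cop_x)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # sway grows with age and is multiplicative across conditions
  expect_equal(sway_sd(spec, 28, "firm", "open") / sway_sd(spec, 18, "firm", "open"),
               1.1)
  expect_equal(sway_sd(spec, 30, "foam", "closed"),
               sway_sd(spec, 30, "firm", "open") * 1.5 * 2.0)
  # zero baseline -> identically zero series
  spec0 <- cohort_spec(n_participants = 2, seed = 1, baseline_sd = 0)
  cop0 <- generate_cop_trial(spec0, 40, "firm", "open", seed = 5)
  expect_true(all(cop0$cop_x == 0) && all(cop0$cop_y == 0))
})

test_that("cop_to_forces is the exact algebraic inverse of compute_cop", {
  set.seed(21)
  cop <- cop_series(rnorm(300, sd = 0.4), rnorm(300, sd = 0.4), 100)
  tr <- cop_to_forces(cop, mass = 60)
  expect_equal(tr$fz, rep(588.6, 300))
  back <- compute_cop(tr, filter = FALSE)
  expect_lt(max(abs(back$cop_x - cop$cop_x)), 1e-9)
  expect_lt(max(abs(back$cop_y - cop$cop_y)), 1e-9)

  zero <- cop_series(numeric(10), numeric(10), 100)
  trz <- cop_to_forces(zero, mass = 70)
  expect_true(all(trz$mx == 0) && all(trz$my == 0))
  expect_error(cop_to_forces(cop, mass = 0), "mass")
})

test_that("planted anomalies are counted, isolated, and outside the clean envelope", {
  n <- 30
  clean <- simulate_cohort_features(
    cohort_spec(n_participants = n, seed = 77, duration = 10))
  planted <- simulate_cohort_features(
    cohort_spec(n_participants = n, seed = 77, duration = 10,
                anomaly_fraction = 0.2))
  expect_equal(sum(planted$anomaly$flagged), round(0.2 * n))
  expect_false(any(clean$anomaly$flagged))

  # non-flagged participants' features identical to the clean run
  ok <- !planted$anomaly$flagged
  ids_ok <- planted$anomaly$participant_id[ok]
  sw_c <- clean$sway[clean$sway$participant_id %in% ids_ok, ]
  sw_p <- planted$sway[planted$sway$participant_id %in% ids_ok, ]
  expect_equal(sw_p, sw_c)
  expect_identical(planted$demographics, clean$demographics)

  # flagged participants fall outside the 95% envelope of the clean
  # age-sway relationship (foam eyes-closed area, log scale)
  get_fec <- function(coh) {
    s <- coh$sway[coh$sway$surface == "foam" & coh$sway$vision == "closed", ]
    s[match(coh$demographics$participant_id, s$participant_id), "area"]
  }
  fit <- lm(log(get_fec(clean)) ~ clean$demographics$age)
  resid_clean <- resid(fit)
  env <- quantile(resid_clean, c(0.025, 0.975), type = 7)
  pred_planted <- cbind(1, planted$demographics$age) %*% coef(fit)
  resid_planted <- log(get_fec(planted)) - pred_planted
  flagged_out <- resid_planted[planted$anomaly$flagged] < env[1] |
    resid_planted[planted$anomaly$flagged] > env[2]
  expect_true(all(flagged_out))
})

test_that("anomaly mechanisms shape the planted sway as documented", {
  spec <- cohort_spec(n_participants = 10, seed = 5, anomaly_fraction = 0.2,
                      anomaly_mechanism = "age_mismatch")
  dem <- generate_participants(spec)
  plan <- balanceAD:::anomaly_plan(spec, dem)
  fl <- plan$flagged
  expect_true(all(plan$sway_age[fl] != dem$age[fl]))
  expect_true(all(plan$sway_age[fl] %in% dem$age)) # donor is a real cohort age
  expect_true(all(plan$sway_age[!fl] == dem$age[!fl]))
  expect_false(any(plan$invert))

  spec2 <- cohort_spec(n_participants = 10, seed = 5, anomaly_fraction = 0.2,
                       anomaly_mechanism = "invert_conditions")
  plan2 <- balanceAD:::anomaly_plan(spec2, generate_participants(spec2))
  expect_true(all(plan2$invert[plan2$flagged]))
  expect_equal(plan2$sway_age, generate_participants(spec2)$age)
  # inverted multipliers shrink eyes-closed sway below eyes-open
  expect_lt(sway_sd(spec2, 40, "firm", "closed", invert = TRUE),
            sway_sd(spec2, 40, "firm", "open", invert = TRUE))
})

test_that("one master seed reproduces the full cohort feature set", {
  spec <- cohort_spec(n_participants = 5, seed = 13, duration = 8,
                      anomaly_fraction = 0.2)
  a <- simulate_cohort_features(spec)
  b <- simulate_cohort_features(spec)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$sway, b$sway)
  expect_identical(a$anomaly, b$anomaly)
})

test_that("written synthetic cohorts reload to the same features", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_participants = 3, seed = 8, duration = 6)
  write_synthetic_cohort(spec, dir)
  coh <- load_cohort(file.path(dir, "manifest.csv"),
                     file.path(dir, "demographics.csv"))
  sway_disk <- cohort_sway_features(coh)
  mem <- simulate_cohort_features(spec)
  key <- function(d) d[order(d$participant_id, d$surface, d$vision), ]
  sd_ <- key(sway_disk); sm <- key(mem$sway)
  expect_equal(sd_$area, sm$area, tolerance = 1e-6)
  expect_equal(sd_$mean_velocity, sm$mean_velocity, tolerance = 1e-6)
  truth <- read.csv(file.path(dir, "anomaly_truth.csv"))
  expect_equal(nrow(truth), 3L)
})
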