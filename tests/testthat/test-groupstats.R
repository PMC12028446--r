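# ANOVA/Bonferroni/assumption tests against direct-formula oracles, and
# the multiplication-factor summary.

anova_oracle <- function(values, labels) {
  labels <- factor(labels)
  k <- nlevels(labels); n <- length(values)
  grand <- mean(values)
  ss_b <- sum(tapply(values, labels, function(v) length(v) * (mean(v) - grand)^2))
  ss_w <- sum(tapply(values, labels, function(v) sum((v - mean(v))^2)))
  F <- (ss_b / (k - 1)) / (ss_w / (n - k))
  list(F = F, p = pf(F, k - 1, n - k, lower.tail = FALSE))
}

test_that("one-way ANOVA matches the brute-force sum-of-squares formula", {
  vals <- c(3.1, 2.9, 3.0, 4.2, 4.0, 4.4, 5.1, 5.3, 4.9) # fixed 9-value toy
  labs <- rep(c("a", "b", "c"), each = 3)
  got <- one_way_anova(vals, labs)
  want <- anova_oracle(vals, labs)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)

  # equal group means with positive within-group variance -> F ~ 0
  v0 <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)
  got0 <- one_way_anova(v0, labs)
  expect_equal(got0$F, 0)
  expect_equal(got0$p, 1)

  expect_error(one_way_anova(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(5)
  v <- c(rnorm(12), rnorm(15, 0.7))
  g <- rep(c("x", "y"), c(12, 15))
  F_got <- one_way_anova(v, g)$F
  t_got <- t.test(v ~ g, var.equal = TRUE)$statistic
  expect_equal(F_got, unname(t_got)^2, tolerance = 1e-10)
})

test_that("Bonferroni adjustment triples and caps the Welch p-values", {
  set.seed(6)
  v <- c(rnorm(10), rnorm(10, 1), rnorm(10, 2))
  g <- rep(c("a", "b", "c"), each = 10)
  pw <- pairwise_bonferroni(v, g)
  expect_equal(nrow(pw), 3L)
  for (i in 1:3) {
    raw <- t.test(v[g == pw$group1[i]], v[g == pw$group2[i]])$p.value
    expect_equal(pw$p_raw[i], raw)
    expect_equal(pw$p_adj[i], min(1, 3 * raw))
  }
  expect_identical(order(pw$p_adj), order(pw$p_raw)) # monotone map
  # capping at 1
  v2 <- c(rnorm(20), rnorm(20), rnorm(20))
  pw2 <- pairwise_bonferroni(v2, rep(c("a", "b", "c"), each = 20))
  expect_true(all(pw2$p_adj <= 1))
  expect_true(all(pw2$p_adj >= pw2$p_raw))
})

test_that("assumption tests report and flag rather than act", {
  # groups with identical absolute deviations -> classical Levene F = 0, p = 1
  base <- c(-2, -1, 0, 1, 2, -1.5, 1.5, 0.5, -0.5, 0)
  v <- c(base, base + 10, base - 3)
  g <- rep(c("a", "b", "c"), each = length(base))
  at <- assumption_tests(v, g)
  expect_equal(at$levene$F, 0, tolerance = 1e-12)
  expect_equal(at$levene$p, 1, tolerance = 1e-12)
  expect_equal(at$shapiro$p, rep(shapiro.test(base)$p.value, 3))

  # undersized group is skipped with a flag
  at2 <- assumption_tests(c(1, 2, rnorm(10), rnorm(10)),
                          rep(c("a", "b", "c"), c(2, 10, 10)))
  expect_true(at2$shapiro$skipped[at2$shapiro$group == "a"])
  expect_false(any(at2$shapiro$skipped[-1]))
})

test_that("Shapiro-Wilk detects heavy skew in nearly all seeds", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    shapiro.test(rexp(50))$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("multiplication factors reconstruct raw units and average to 1", {
  X <- cbind(v1 = c(1, 2, 3), v2 = c(10, 10, 10))
  mf <- multiplication_factor(X, c("g1", "g1", "g2"))
  t1 <- mf$table[mf$table$variable == "v1", ]
  expect_equal(t1$mf_mean[t1$group == "g1"], mean(c(0.5, 1.0)))
  expect_equal(t1$mf_mean[t1$group == "g2"], 1.5)
  expect_equal(mf$grand_mean[["v1"]], 2)
  # population-weighted mean of MF is exactly 1 per variable
  mfs <- c(0.5, 1.0, 1.5)
  expect_equal(mean(mfs), 1)
  expect_equal(sd(mfs[1:2]), t1$mf_sd[t1$group == "g1"])

  # identical participants: MF = 1, SD = 0
  X2 <- matrix(5, 4, 2, dimnames = list(NULL, c("a", "b")))
  mf2 <- multiplication_factor(X2, rep(c("g1", "g2"), 2))
  expect_true(all(mf2$table$mf_mean == 1))
  expect_true(all(mf2$table$mf_sd == 0))

  # zero grand mean -> variable omitted, flagged
  X3 <- cbind(ok = c(1, 2, 3), zero = c(-1, 0, 1))
  mf3 <- multiplication_factor(X3, c("a", "a", "b"))
  expect_equal(mf3$omitted, "zero")
  expect_false("zero" %in% mf3$table$variable)
})

test_that("population MF mean is 1 for every feature on a simulated matrix", {
  X <- toy_features(60, seed = 12)
  mf <- multiplication_factor(X, assign_groups(normalize_scores(rowSums(X))))
  MF <- sweep(X, 2, mf$grand_mean, "/")
  expect_equal(unname(colMeans(MF)), rep(1, 19))
})

test_that("ANOVA detects a large injected group effect in nearly all seeds", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    g <- rep(c("a", "b", "c"), each = 50)
    v <- rnorm(150) + c(a = -0.75, b = 0, c = 0.75)[g] # Cohen's f ~ 0.6
    one_way_anova(v, g)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the report marks significance per the ANOVA and regenerates byte-identically", {
  set.seed(30)
  X <- toy_features(45, seed = 30)
  labels <- assign_groups(normalize_scores(runif(45)))
  comp <- group_comparisons(X[, 1:5], labels)
  expect_equal(nrow(comp), 5L)
  expect_equal(anyDuplicated(comp$variable), 0L)
  expect_equal(comp$significant, comp$p < 0.05)
  expect_true(all(comp$levene_p >= 0 & comp$levene_p <= 1))

  results <- data.frame(participant_id = rownames(X),
                        r_squared = runif(45), norm_score = runif(45),
                        group = labels)
  mf <- multiplication_factor(X[, 1:5], labels)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  rep1 <- balance_report(comp, results, mf, dir = d1, meta = c(seed = "1"))
  balance_report(comp, results, mf, dir = d2, meta = c(seed = "1"))
  expect_true(all(grepl("\\*", rep1$stats$marker) == rep1$stats$significant))
  for (f in c("stats.csv", "mf_table.csv", "scores.csv", "summary.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
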