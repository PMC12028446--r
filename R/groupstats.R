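# Subgroup statistics: one-way ANOVA with Bonferroni-adjusted pairwise
# comparisons, assumption tests (Shapiro-Wilk, Levene), and the
# multiplication-factor (MF) summary used for radar-chart comparison.

#' One-way fixed-effects ANOVA
#'
#' @param values numeric response.
#' @param labels group labels (factor or character).
#' @return list with `F`, `p`, and degrees of freedom `df1`, `df2`.
#' @export
one_way_anova <- function(values, labels) {
  labels <- factor(labels)
  sizes <- table(labels)
  if (length(sizes) < 2) stopf("need at least 2 groups")
  if (any(sizes < 2)) {
    stopf("group '%s' has fewer than 2 members", names(sizes)[sizes < 2][1])
  }
  ft <- tryCatch(stats::oneway.test(values ~ labels, var.equal = TRUE),
                 error = function(e) NULL)
  if (is.null(ft) || !is.finite(ft$statistic)) {
    # degenerate response (e.g. constant within every group)
    return(list(F = NA_real_, p = NA_real_,
                df1 = length(levels(droplevels(labels))) - 1,
                df2 = length(values) - length(levels(droplevels(labels)))))
  }
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]))
}

#' Pairwise t-tests with Bonferroni adjustment
#'
#' Welch (unequal-variance) two-sample t-test for each of the three group
#' pairs; `p_adj = min(1, 3 p)`. Set `pool_sd = TRUE` for the classical
#' pooled-variance t-test.
#'
#' @param values numeric response.
#' @param labels group labels with exactly 3 levels present.
#' @param pool_sd logical (default FALSE = Welch).
#' @return data frame with `group1`, `group2`, `p_raw`, `p_adj`.
#' @export
pairwise_bonferroni <- function(values, labels, pool_sd = FALSE) {
  labels <- factor(labels)
  lev <- levels(droplevels(labels))
  if (length(lev) != 3) stopf("expected exactly 3 groups, got %d", length(lev))
  pairs <- utils::combn(lev, 2)
  p_raw <- apply(pairs, 2, function(pr) {
    tryCatch(stats::t.test(values[labels == pr[1]], values[labels == pr[2]],
                           var.equal = pool_sd)$p.value,
             error = function(e) NA_real_) # essentially constant data
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             p_raw = p_raw, p_adj = pmin(1, 3 * p_raw),
             stringsAsFactors = FALSE)
}

#' Normality and homogeneity-of-variance checks
#'
#' Shapiro-Wilk per group and Levene's test (classical, mean-centered)
#' across groups. Outcomes are reported, never used to switch tests.
#'
#' @param values numeric response.
#' @param labels group labels.
#' @return list with `shapiro` (data frame `group`, `W`, `p`, `skipped` —
#'   groups of fewer than 3 members are skipped with a flag) and `levene`
#'   (list `F`, `p`).
#' @export
assumption_tests <- function(values, labels) {
  labels <- factor(labels)
  lev <- levels(droplevels(labels))
  sw <- do.call(rbind, lapply(lev, function(g) {
    v <- values[labels == g]
    if (length(v) < 3 || length(unique(v)) == 1) {
      data.frame(group = g, W = NA_real_, p = NA_real_, skipped = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      st <- stats::shapiro.test(v)
      data.frame(group = g, W = unname(st$statistic),
                 p = unname(st$p.value), skipped = FALSE,
                 stringsAsFactors = FALSE)
    }
  }))
  lv <- tryCatch(
    suppressWarnings(car::leveneTest(values, droplevels(labels),
                                     center = "mean")),
    error = function(e) NULL)
  if (is.null(lv)) {
    levene <- list(F = NA_real_, p = NA_real_)
  } else {
    levene <- list(F = lv[1, "F value"], p = lv[1, "Pr(>F)"])
  }
  list(shapiro = sw, levene = levene)
}

#' Multiplication-factor (MF) table
#'
#' Each variable is expressed as a multiple of its grand mean over all
#' participants: `MF = value / grand_mean`, so `MF x grand_mean`
#' reconstructs the raw units and the participant-weighted mean of MF is 1
#' exactly. Reported per group as mean +/- SD, the radar-chart scale used
#' to compare percentile subgroups.
#'
#' @param features raw-unit participants x variables matrix.
#' @param labels group label per participant.
#' @return list with `table` (data frame `variable`, `group`, `n`,
#'   `mf_mean`, `mf_sd`), `grand_mean` (named vector), and `omitted`
#'   (variables with zero grand mean, for which MF is undefined).
#' @export
multiplication_factor <- function(features, labels) {
  X <- as.matrix(features)
  labels <- factor(labels)
  if (nrow(X) != length(labels)) stopf("labels length must match rows")
  gm <- colMeans(X)
  omit <- colnames(X)[gm == 0]
  keep <- gm != 0
  MF <- sweep(X[, keep, drop = FALSE], 2, gm[keep], "/")
  rows <- list()
  for (v in colnames(MF)) {
    for (g in levels(labels)) {
      vals <- MF[labels == g, v]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = g, n = length(vals),
        mf_mean = mean(vals), mf_sd = stats::sd(vals),
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), grand_mean = gm, omitted = omit)
}

#' Compare subgroups on every feature
#'
#' For each variable: group sizes and MF mean +/- SD, one-way ANOVA,
#' Bonferroni-adjusted pairwise p-values, Shapiro-Wilk per group, Levene
#' across groups, and a significance flag at `alpha`.
#'
#' @param features raw-unit participants x variables matrix.
#' @param labels 3-level group factor (e.g. from [assign_groups()]).
#' @param alpha significance level (default 0.05).
#' @param pool_sd passed to [pairwise_bonferroni()].
#' @return data frame of class `group_comparisons`, one row per variable.
#' @export
group_comparisons <- function(features, labels, alpha = 0.05,
                              pool_sd = FALSE) {
  X <- as.matrix(features)
  labels <- droplevels(factor(labels))
  lev <- levels(labels)
  if (length(lev) != 3) stopf("expected 3 groups, got %d", length(lev))
  rows <- lapply(colnames(X), function(v) {
    vals <- X[, v]
    an <- one_way_anova(vals, labels)
    pw <- pairwise_bonferroni(vals, labels, pool_sd = pool_sd)
    at <- assumption_tests(vals, labels)
    out <- data.frame(variable = v, F = an$F, p = an$p,
                      significant = !is.na(an$p) && an$p < alpha,
                      stringsAsFactors = FALSE)
    for (i in 1:3) {
      out[[sprintf("p_adj_%s_vs_%s", pw$group1[i], pw$group2[i])]] <- pw$p_adj[i]
    }
    for (i in seq_along(lev)) {
      out[[sprintf("shapiro_p_%s", lev[i])]] <- at$shapiro$p[i]
    }
    out$levene_p <- at$levene$p
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("group_comparisons", class(out))
  out
}

#' Assemble and optionally write the full group-statistics report
#'
#' Combines the per-variable comparisons, the per-participant anomaly
#' results and the MF table into one machine-readable structure mirroring
#' the radar-chart convention: a variable carries a significance marker
#' (`*`) iff its ANOVA p-value is below alpha.
#'
#' @param comparisons a [group_comparisons()] data frame.
#' @param results the `results` data frame of an [run_anomaly_pipeline()]
#'   run.
#' @param mf a [multiplication_factor()] result.
#' @param dir optional output directory; if given, writes `stats.csv`,
#'   `mf_table.csv` and `scores.csv` (deterministic byte-for-byte given
#'   identical inputs and `meta`).
#' @param meta named character vector stamped as `# key: value` header
#'   lines on every file.
#' @return list of class `balance_report` with elements `stats`, `mf`,
#'   `scores` and `summary_lines` (human-readable).
#' @export
balance_report <- function(comparisons, results, mf, dir = NULL,
                           meta = NULL) {
  alpha <- attr(comparisons, "alpha") %||% 0.05
  stats_df <- as.data.frame(comparisons)
  stats_df$marker <- ifelse(stats_df$significant, "*", "")
  lines <- c(
    sprintf("MF = value / grand mean (grand mean over all %d participants); value = MF x grand mean",
            nrow(results)),
    sprintf("'*' marks ANOVA p < %g", alpha),
    sprintf("%-28s F = %8.3f  p = %.4f %s", stats_df$variable,
            stats_df$F, stats_df$p, stats_df$marker))
  out <- structure(list(stats = stats_df, mf = mf$table, scores = results,
                        summary_lines = lines),
                   class = "balance_report")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_csv_meta(stats_df, file.path(dir, "stats.csv"), meta)
    write_csv_meta(mf$table, file.path(dir, "mf_table.csv"), meta)
    write_csv_meta(results, file.path(dir, "scores.csv"), meta)
    writeLines(lines, file.path(dir, "summary.txt"))
  }
  out
}

#' @export
print.balance_report <- function(x, ...) {
  writeLines(x$summary_lines)
  invisible(x)
}
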