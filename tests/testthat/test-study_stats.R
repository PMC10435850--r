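test_that("group comparisons use the appropriate test", {
  x <- c(1, 2, 3, 4, 5)
  same <- compare_groups(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(91)
  a <- rnorm(200); b <- rnorm(200) + 10
  expect_lt(compare_groups(a, b)$p_value, 1e-6)

  g1 <- rep(c("yes", "no"), c(50, 0))
  g2 <- rep(c("yes", "no"), c(0, 50))
  expect_lt(compare_groups(g1, g2, kind = "categorical")$p_value, 1e-6)

  expect_error(compare_groups(1, 2), ">= 2 observations")
  expect_error(compare_groups(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("the univariate screen selects p < 0.05 factors plus age", {
  d <- synth_cohort(cohort_spec(n_patients = 60, seed = 92))
  d$self <- d$index  # factor equal to the index
  # a factor equal to the index fits perfectly; the F-test warning is expected
  scr <- suppressWarnings(univariate_screen(d, c("self", "bmi", "age")))
  expect_lt(scr$p_values[["self"]], 1e-12)
  expect_true("self" %in% scr$selected)
  expect_true("age" %in% scr$selected)  # carried regardless of its p

  d$flat <- 1
  expect_error(univariate_screen(d, "flat"), "constant factor")
  expect_error(univariate_screen(d, "ghost"), "unknown factor")

  # type-I control under the null: a zero-slope factor stays unselected
  # in about 95% of replicates
  hits <- vapply(1:200, function(r) {
    dd <- synth_cohort(cohort_spec(n_patients = 24, seed = 3000 + r))
    univariate_screen(dd, "bmi")$p_values[["bmi"]] < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("age-adjusted models recover planted coefficients", {
  d <- synth_cohort(cohort_spec(n_patients = 500, beta = c(alsfrs_r_total = 0.006),
                                sigma = 0.04, seed = 93))
  m <- adjusted_model(d, "alsfrs_r_total")
  expect_true(m$ci_low <= m$coefficient && m$coefficient <= m$ci_high)
  expect_lt(abs(m$coefficient - 0.006), 0.002)
  expect_lt(m$adjusted_p, 0.001)

  # a factor independent of the index has a CI covering 0
  m0 <- adjusted_model(d, "bmi")
  expect_true(m0$ci_low <= 0 && 0 <= m0$ci_high)

  d$age2 <- d$age
  expect_error(adjusted_model(d, "age2"), "collinear")
  expect_error(adjusted_model(d, "age"), "age")

  # logistic variant runs and reports the factor row
  ml <- adjusted_model(d, "alsfrs_r_total", logistic = TRUE,
                       cutoff = median(d$index))
  expect_equal(ml$model, "logistic")
  expect_true(is.finite(ml$coefficient))
})

test_that("the factor table mirrors the two-step analysis", {
  d <- synth_cohort(cohort_spec(n_patients = 120, seed = 94))
  tab <- factor_analysis_table(d, c("age", "alsfrs_r_total", "bmi"))
  expect_equal(tab$factor, c("age", "alsfrs_r_total", "bmi"))
  r <- tab[tab$factor == "alsfrs_r_total", ]
  expect_true(r$selected)
  expect_true(r$ci_low <= r$coefficient & r$coefficient <= r$ci_high)
})

test_that("ROC analysis matches oracles and respects invariants", {
  # perfect separation (impaired have the lower index)
  idx <- c(seq(0.05, 0.15, length.out = 8), seq(0.3, 0.5, length.out = 8))
  out <- rep(c(1L, 0L), each = 8)
  r <- roc_cutoff(idx, out)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$direction, "low")
  expect_true(r$cutoff >= min(idx) && r$cutoff <= max(idx))

  # null: outcome independent of index
  set.seed(95)
  r0 <- roc_cutoff(runif(4000), rep(0:1, 2000))
  expect_lt(abs(r0$auc - 0.5), 0.05)

  # all-pairs concordance oracle, 12 vs 12
  set.seed(96)
  idx2 <- c(rnorm(12, 0.2, 0.09), rnorm(12, 0.37, 0.11))
  out2 <- rep(c(1L, 0L), each = 12)
  r2 <- roc_cutoff(idx2, out2)
  conc <- 0
  for (i in which(out2 == 1L)) for (j in which(out2 == 0L))
    conc <- conc + (idx2[i] < idx2[j]) + 0.5 * (idx2[i] == idx2[j])
  expect_equal(r2$auc, conc / 144)

  # invariance under a strictly monotone transform
  r3 <- roc_cutoff(exp(3 * idx2), out2)
  expect_equal(r3$auc, r2$auc)

  expect_error(roc_cutoff(idx2, rep(1L, 24)), "both outcome classes")
})

test_that("ROC results agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(97)
  idx <- c(rnorm(30, 0.2, 0.09), rnorm(40, 0.37, 0.11))
  out <- rep(c(1L, 0L), c(30, 40))
  r <- roc_cutoff(idx, out)
  pr <- pROC::roc(out, idx, quiet = TRUE, direction = ">")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  best <- pROC::coords(pr, "best", best.method = "youden", transpose = FALSE)
  expect_equal(r$sensitivity + r$specificity,
               best$sensitivity[1] + best$specificity[1])
})

test_that("the t-test sample size reproduces the planning computation", {
  res <- sample_size(0.08, 0.06, alpha = 0.05, power = 0.80)
  expect_equal(res$n_total, 20L)
  expect_gte(res$achieved_power, 0.80)

  # doubling the difference shrinks the requirement strictly
  expect_lt(sample_size(0.16, 0.06)$n_total, res$n_total)

  # Monte-Carlo power oracle at the returned n
  set.seed(98)
  nper <- res$n_per_group
  reps <- 10000
  a <- matrix(rnorm(nper * reps, 0, 0.06), nper)
  b <- matrix(rnorm(nper * reps, 0.08, 0.06), nper)
  va <- apply(a, 2, var); vb <- apply(b, 2, var)
  tstat <- (colMeans(b) - colMeans(a)) / sqrt((va + vb) / nper)
  df <- (va + vb)^2 / (va^2 + vb^2) * (nper - 1)
  mc_power <- mean(abs(tstat) > qt(0.975, df))
  expect_gte(mc_power, 0.80 - 3 * sqrt(0.8 * 0.2 / reps))

  expect_error(sample_size(0, 0.06), "nonzero")
})
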