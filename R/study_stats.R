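# Study statistics: group comparison, two-step covariate screening with
# age-adjusted models, ROC cutoff selection and the t-test sample-size
# computation. Model fits go through stats::lm / t.test / chisq.test;
# the ROC quantities are computed rank-based here (Mann-Whitney AUC,
# Youden cutoff) so the tie and direction rules are explicit.

#' Compare two groups
#'
#' Two-sided Welch t-test for continuous measures (Student's by
#' `var_equal = TRUE`), chi-square test for categorical ones.
#'
#' @param values_a,values_b observations per group: numeric for
#'   `kind = "continuous"`, category labels for `"categorical"`.
#' @param kind `"continuous"` or `"categorical"`.
#' @param var_equal use the pooled-variance t-test (default `FALSE`).
#' @return list with `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(values_a, values_b,
                           kind = c("continuous", "categorical"),
                           var_equal = FALSE) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    if (length(values_a) < 2L || length(values_b) < 2L)
      stop("need >= 2 observations per group")
    if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
        mean(values_a) == mean(values_b))
      stop("zero variance in both groups")
    ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  } else {
    if (length(values_a) == 0L || length(values_b) == 0L)
      stop("empty group")
    g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
    ht <- stats::chisq.test(table(g, c(values_a, values_b)))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}

# p-value of a single factor in a linear model of index on that factor
factor_p <- function(cohort, factor) {
  f <- stats::as.formula(paste("index ~", factor))
  fit <- stats::lm(f, data = cohort)
  an <- stats::anova(fit)
  an[["Pr(>F)"]][1]
}

#' Univariate screen of cohort factors
#'
#' Regresses the swallowing sound index on each factor separately and
#' reports the factor p-values. The selected set for adjusted modeling
#' is every factor with p < `alpha`, plus age, which is always carried
#' forward.
#'
#' @param cohort a cohort `data.frame` with an `index` column.
#' @param factors character vector of factor (column) names.
#' @param alpha selection level (default 0.05).
#' @return list with `p_values` (named) and `selected` (character).
#' @export
univariate_screen <- function(cohort, factors, alpha = 0.05) {
  stopifnot(is.data.frame(cohort), "index" %in% names(cohort))
  if (nrow(cohort) < 3L) stop("need >= 3 complete rows")
  for (f in factors) {
    if (!f %in% names(cohort)) stop("unknown factor: ", f)
    v <- cohort[[f]]
    if ((is.numeric(v) && stats::var(v) == 0) ||
        (!is.numeric(v) && length(unique(v)) < 2L))
      stop("constant factor: ", f)
  }
  p <- vapply(factors, factor_p, numeric(1), cohort = cohort)
  selected <- union(names(p)[p < alpha], intersect("age", names(cohort)))
  list(p_values = p, selected = selected)
}

#' Age-adjusted model for one factor
#'
#' Linear regression of the index on the factor plus age (one adjusted
#' model per factor, mirroring a per-row multivariate table). A logistic
#' variant — outcome = index below `cutoff` — is available with
#' `logistic = TRUE`.
#'
#' @param cohort cohort `data.frame` with `index` and `age`.
#' @param factor factor column name.
#' @param logistic fit `glm(index < cutoff ~ factor + age, binomial)`
#'   instead of the linear model.
#' @param cutoff index cutoff defining the impaired outcome when
#'   `logistic = TRUE`.
#' @return An object of class `factor_model_result`: `factor`,
#'   `univariate_p`, `coefficient`, `ci_low`, `ci_high`, `adjusted_p`.
#' @export
adjusted_model <- function(cohort, factor, logistic = FALSE, cutoff = NULL) {
  stopifnot(is.data.frame(cohort), "age" %in% names(cohort))
  if (!factor %in% names(cohort)) stop("unknown factor: ", factor)
  if (identical(factor, "age")) stop("factor duplicates the age adjustment")
  v <- cohort[[factor]]
  if (is.numeric(v) && abs(stats::cor(v, cohort$age)) > 0.999)
    stop("collinearity: ", factor, " is (near-)identical to age")
  if (logistic) {
    if (is.null(cutoff)) stop("logistic = TRUE requires a cutoff")
    cohort$.outcome <- as.integer(cohort$index < cutoff)
    fit <- stats::glm(stats::as.formula(paste(".outcome ~", factor, "+ age")),
                      family = stats::binomial(), data = cohort)
  } else {
    fit <- stats::lm(stats::as.formula(paste("index ~", factor, "+ age")),
                     data = cohort)
  }
  if (fit$qr$rank < length(stats::coef(fit)) || anyNA(stats::coef(fit)))
    stop("collinearity: rank-deficient design for factor ", factor)
  cf <- summary(fit)$coefficients
  row <- grep(paste0("^", factor), rownames(cf))[1]
  ci <- suppressMessages(stats::confint(fit, level = 0.95))
  structure(
    list(factor = factor,
         univariate_p = factor_p(cohort, factor),
         coefficient = cf[row, 1],
         ci_low = ci[row, 1], ci_high = ci[row, 2],
         adjusted_p = cf[row, 4],
         model = if (logistic) "logistic" else "linear"),
    class = "factor_model_result"
  )
}

#' @export
print.factor_model_result <- function(x, ...) {
  cat(sprintf("%s: coef %.4g (95%% CI %.4g to %.4g), p = %.3g (univariate p = %.3g)\n",
              x$factor, x$coefficient, x$ci_low, x$ci_high,
              x$adjusted_p, x$univariate_p))
  invisible(x)
}

#' Two-step factor analysis table
#'
#' Runs [univariate_screen()] over `factors` and fits the age-adjusted
#' model for each selected factor (age itself is the adjustment, not a
#' row), returning a table with one row per factor.
#'
#' @inheritParams univariate_screen
#' @return `data.frame` with columns `factor`, `univariate_p`,
#'   `selected`, `coefficient`, `ci_low`, `ci_high`, `adjusted_p`.
#' @export
factor_analysis_table <- function(cohort, factors, alpha = 0.05) {
  scr <- univariate_screen(cohort, factors, alpha)
  rows <- lapply(factors, function(f) {
    sel <- f %in% scr$selected
    if (sel && f != "age") {
      m <- adjusted_model(cohort, f)
      data.frame(factor = f, univariate_p = scr$p_values[[f]], selected = TRUE,
                 coefficient = m$coefficient, ci_low = m$ci_low,
                 ci_high = m$ci_high, adjusted_p = m$adjusted_p)
    } else {
      data.frame(factor = f, univariate_p = scr$p_values[[f]], selected = sel,
                 coefficient = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, adjusted_p = NA_real_)
    }
  })
  do.call(rbind, rows)
}

#' ROC analysis with Youden cutoff
#'
#' Empirical (Mann-Whitney) AUC and the index cutoff maximizing Youden's
#' J = sensitivity + specificity - 1. The direction is auto-detected: if
#' the impaired class (`outcome == 1`) has the lower mean index, a LOW
#' index predicts impairment (`index <= cutoff` calls impaired);
#' otherwise the rule is reversed. Cutoff candidates are the observed
#' index values; ties on J are broken toward the lower cutoff.
#'
#' @param index numeric swallowing sound indices.
#' @param outcome 0/1 vector, 1 = impaired.
#' @return An object of class `roc_result`: `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `direction` (`"low"` or `"high"`).
#' @export
roc_cutoff <- function(index, outcome) {
  outcome <- as.integer(outcome > 0)
  if (length(index) != length(outcome)) stop("length mismatch")
  n1 <- sum(outcome == 1L); n0 <- sum(outcome == 0L)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes required")

  low_dir <- mean(index[outcome == 1L]) <= mean(index[outcome == 0L])
  pred <- if (low_dir) -index else index      # larger predictor => impaired
  r <- rank(pred)
  auc <- (sum(r[outcome == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  cand <- sort(unique(index))
  stats_at <- vapply(cand, function(cth) {
    called <- if (low_dir) index <= cth else index >= cth
    c(sens = sum(called & outcome == 1L) / n1,
      spec = sum(!called & outcome == 0L) / n0)
  }, numeric(2))
  j <- stats_at["sens", ] + stats_at["spec", ] - 1
  pick <- which(j >= max(j) - 1e-12)[1]       # ties -> lower cutoff
  structure(
    list(auc = auc, cutoff = cand[pick],
         sensitivity = unname(stats_at["sens", pick]),
         specificity = unname(stats_at["spec", pick]),
         direction = if (low_dir) "low" else "high"),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f, cutoff %.4g (%s index => impaired), sens %.1f%%, spec %.1f%%\n",
              x$auc, x$cutoff, x$direction,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Two-sample t-test sample size
#'
#' Smallest total n (two equal groups) for which a two-sided two-sample
#' t-test at level `alpha` has power >= `power` against a difference of
#' `min_difference` at standard deviation `sd`. The power at each
#' candidate per-group n is evaluated with [stats::power.t.test()]
#' (noncentral t); the search takes the smallest integer that reaches
#' the target.
#'
#' @param min_difference smallest difference worth detecting (index
#'   units).
#' @param sd common standard deviation (index units).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @return list with `n_per_group`, `n_total`, `achieved_power`.
#' @export
sample_size <- function(min_difference, sd, alpha = 0.05, power = 0.80) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, sd > 0)
  if (min_difference == 0) stop("min_difference must be nonzero")
  for (n in 2:100000) {
    pw <- stats::power.t.test(n = n, delta = abs(min_difference), sd = sd,
                              sig.level = alpha)$power
    if (pw >= power)
      return(list(n_per_group = n, n_total = 2L * n, achieved_power = pw))
  }
  stop("no feasible n below 100000 per group")
}
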