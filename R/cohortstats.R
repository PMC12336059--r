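#' Percent change from pre to post
#'
#' `(pre - post) / pre * 100`: positive values are reductions, matching the
#' reporting convention for caffeine-induced decreases.
#'
#' @param pre,post Numeric vectors (recycled pairwise).
#' @return Percent change, positive = reduction.
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) stop("pre value of 0: percent change undefined", call. = FALSE)
  (pre - post) / pre * 100
}

test_result <- function(statistic, p_value, df = NA_real_, estimate = NA_real_,
                        ci = c(NA_real_, NA_real_), method = "") {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 df = unname(df), estimate = unname(estimate),
                 ci_low = ci[1], ci_high = ci[2], method = method),
            class = "cvr_test")
}

#' @export
print.cvr_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  if (is.finite(x$estimate))
    cat(sprintf("  estimate %.4g [%.4g, %.4g]\n", x$estimate, x$ci_low, x$ci_high))
  invisible(x)
}

#' Paired t-test on pre/post measurements
#'
#' Two-sided paired t-test on `pre - post`.  The degenerate case of
#' identical vectors (all differences zero) returns, by documented
#' convention, statistic 0 and p = 1; a constant non-zero difference has
#' zero within-pair variance and returns a signed infinite statistic with
#' p = 0, with a warning.
#'
#' @param pre,post Numeric vectors of equal length >= 2.
#' @return A test result with statistic, df, p, mean difference and 95% CI.
#' @export
paired_test <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must have equal length", call. = FALSE)
  if (length(pre) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- pre - post
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(test_result(0, 1, df = length(d) - 1, estimate = 0,
                         method = "paired t-test (degenerate: identical)"))
    warning("constant non-zero difference: zero variance", call. = FALSE)
    return(test_result(sign(mean(d)) * Inf, 0, df = length(d) - 1,
                       estimate = mean(d),
                       method = "paired t-test (degenerate: constant diff)"))
  }
  tt <- stats::t.test(pre, post, paired = TRUE)
  test_result(tt$statistic, tt$p.value, df = tt$parameter,
              estimate = tt$estimate, ci = tt$conf.int, method = "paired t-test")
}

#' Shapiro-Wilk normality check
#'
#' @param x Numeric vector, 3 <= n <= 5000 (typically pre-post differences).
#' @return A test result with W and p.
#' @export
normality_check <- function(x) {
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  sw <- stats::shapiro.test(x)
  test_result(sw$statistic, sw$p.value, method = "Shapiro-Wilk")
}

#' Independent two-sample t-test
#'
#' Two-sided two-sample t-test, Welch-corrected by default (set
#' `var_equal = TRUE` for the pooled-variance test).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return A test result.
#' @export
independent_test <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0)
    stop("both groups have zero variance: test undefined", call. = FALSE)
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  test_result(tt$statistic, tt$p.value, df = tt$parameter,
              estimate = diff(rev(tt$estimate)), ci = tt$conf.int,
              method = if (var_equal) "pooled t-test" else "Welch t-test")
}

#' Linear mixed-effects model for the pre/post crossover design
#'
#' Fits `outcome ~ caffeine * group + covariates + (1 | subject)` by REML,
#' with caffeine coded pre = 0 / post = 1 and the caffeine-naive group as
#' reference level.  P-values use the Satterthwaite degrees-of-freedom
#' approximation; confidence intervals are Wald by default (configurable).
#' Singular fits (zero random-intercept variance) are flagged, not
#' errors -- the fixed-effect estimates then coincide with OLS.
#'
#' @param records Long-format data.frame with columns `subject`, `state`
#'   (`"pre"`/`"post"`), `group` (`"naive"`/`"habituated"`), the outcome
#'   column, and any covariate columns.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate column names (default
#'   `c("sex", "age")`; use `character(0)` for none).
#' @param ci_method `"Wald"` (default) or `"profile"`.
#' @return An `lme_result`: data.frame of fixed effects (estimate, 95% CI,
#'   Satterthwaite df and p), random-intercept and residual variances, and
#'   a singularity flag.
#' @export
fit_lme <- function(records, outcome, covariates = c("sex", "age"),
                    ci_method = c("Wald", "profile")) {
  ci_method <- match.arg(ci_method)
  need <- c("subject", "state", "group", outcome, covariates)
  if (!all(need %in% names(records)))
    stop("records must contain: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(table(records$subject) < 2))
    stop("each subject needs observations in both states", call. = FALSE)
  df <- records
  df$caffeine <- as.numeric(df$state == "post")
  df$group <- stats::relevel(factor(df$group), ref = "naive")
  rhs <- paste(c("caffeine * group", covariates, "(1 | subject)"),
               collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- lmerTest::lmer(form, data = df, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular fit: random-intercept variance estimated at zero",
            call. = FALSE)
  co <- stats::coef(summary(fit))
  ci <- stats::confint(fit, parm = "beta_", method = ci_method, quiet = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  fixed <- data.frame(
    term = rownames(co),
    estimate = co[, "Estimate"],
    ci_low = ci[rownames(co), 1],
    ci_high = ci[rownames(co), 2],
    df = co[, "df"],
    p_value = co[, "Pr(>|t|)"],
    row.names = NULL
  )
  structure(
    list(fixed = fixed,
         random_intercept_var = vc$vcov[vc$grp == "subject"],
         residual_var = vc$vcov[vc$grp == "Residual"],
         singular = singular, model = fit),
    class = "lme_result"
  )
}

#' @export
print.lme_result <- function(x, ...) {
  cat("Linear mixed-effects fit (REML",
      if (x$singular) ", singular" else "", "):\n", sep = "")
  print(x$fixed, digits = 4)
  cat(sprintf("random-intercept var %.4g, residual var %.4g\n",
              x$random_intercept_var, x$residual_var))
  invisible(x)
}
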