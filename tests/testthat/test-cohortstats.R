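# Builds a long-format records table from a ground-truth cohort draw.
cohort_to_records <- function(coh, quantity = "cbf") {
  do.call(rbind, lapply(c("pre", "post"), function(st) {
    data.frame(subject = coh$subject_id, state = st, group = coh$group,
               sex = coh$sex, age = coh$age,
               y = coh[[paste0(quantity, "_", st)]])
  }))
}

test_that("percent change uses the reduction-positive convention", {
  expect_equal(percent_change(4.5, 3.0), 100 / 3)  # prints as 33.3
  expect_equal(percent_change(7, 7), 0)
  expect_equal(percent_change(50, 60), -20)
  expect_error(percent_change(0, 1), "undefined")
})

test_that("paired t-test matches the closed form and handles degeneracy", {
  # differences {2,3,1,2}: t = dbar / (s_d / sqrt(n)) = 4.899
  post <- c(10, 11, 12, 13)
  pre <- post + c(2, 3, 1, 2)
  r <- paired_test(pre, post)
  expect_equal(r$statistic, 2 / (sd(c(2, 3, 1, 2)) / 2), tolerance = 1e-12)
  expect_equal(r$statistic, 4.899, tolerance = 1e-3)
  expect_equal(r$df, 3)

  # identical vectors: statistic 0, p 1 by convention
  same <- paired_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # antisymmetry under argument exchange
  r2 <- paired_test(post, pre)
  expect_equal(r2$statistic, -r$statistic)

  expect_error(paired_test(1:3, 1:4), "equal length")
})

test_that("paired t-test has nominal type-I error and detects the study effect", {
  # null: 2000 simulated n = 8 cohorts, rejection rate within [0.03, 0.07]
  set.seed(42)
  rej <- mean(vapply(1:2000, function(i) {
    x <- rnorm(8); y <- rnorm(8)
    paired_test(x, y)$p_value < 0.05
  }, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)

  # power: the naive-group CBF-CVR effect size at n = 8 rejects > 90%
  set.seed(43)
  spec <- cohort_spec()
  power <- mean(vapply(1:500, function(i) {
    coh <- generate_cohort(spec, seed = 1000 + i)
    naive <- coh[coh$group == "naive", ]
    paired_test(naive$cbf_cvr_pre, naive$cbf_cvr_post)$p_value < 0.05
  }, logical(1)))
  expect_gt(power, 0.9)
})

test_that("Shapiro-Wilk wrapper is calibrated and powered", {
  # null p-values are uniform: KS check over 200 seeds
  set.seed(7)
  ps <- vapply(1:200, function(i) normality_check(rnorm(8))$p_value,
               numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # a heavily skewed sample is rejected almost always
  set.seed(8)
  rej <- mean(vapply(1:200, function(i)
    normality_check(rexp(100))$p_value < 0.05, logical(1)))
  expect_gt(rej, 0.9)

  expect_error(normality_check(c(1, 2)), "3 <= n")
})

test_that("independent t-test matches hand arithmetic and detects the
           group contrast in percent CBF reduction", {
  r <- independent_test(c(1, 2, 3), c(4, 5, 6), var_equal = TRUE)
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)

  same <- independent_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_error(independent_test(c(1, 1), c(2, 2)), "zero variance")

  # 31.2 +/- 14.1 vs 16.7 +/- 5.0 at n = 8/8 rejects more than half the time
  set.seed(9)
  rej <- mean(vapply(1:500, function(i) {
    a <- rnorm(8, 31.2, 14.1); b <- rnorm(8, 16.7, 5.0)
    independent_test(a, b)$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.5)
})

test_that("mixed model recovers cell contrasts and matches OLS when the
           random intercept vanishes", {
  # balanced 2x2 with a saturated fixed part: coefficients equal cell
  # contrasts regardless of noise
  set.seed(10)
  coh <- generate_cohort(cohort_spec(), seed = 3)
  rec <- cohort_to_records(coh, "cbf")
  fit <- suppressWarnings(fit_lme(rec, "y", covariates = character(0)))
  cells <- tapply(rec$y, list(rec$group, rec$state), mean)
  expect_equal(fit$fixed$estimate[fit$fixed$term == "caffeine"],
               cells["naive", "post"] - cells["naive", "pre"],
               tolerance = 1e-6)
  expect_equal(fit$fixed$estimate[fit$fixed$term == "caffeine:grouphabituated"],
               (cells["habituated", "post"] - cells["habituated", "pre"]) -
                 (cells["naive", "post"] - cells["naive", "pre"]),
               tolerance = 1e-6)

  # no true subject effect: coefficients coincide with plain OLS
  set.seed(11)
  rec$y <- rnorm(nrow(rec), 50, 5)
  fit0 <- suppressWarnings(fit_lme(rec, "y", covariates = character(0)))
  ols <- lm(y ~ I(state == "post") * relevel(factor(group), "naive"),
            data = rec)
  expect_equal(unname(fit0$fixed$estimate), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("mixed-model interaction reflects the group-differential caffeine
           effect on basal CBF", {
  set.seed(12)
  signs <- vapply(1:25, function(i) {
    coh <- generate_cohort(cohort_spec(), seed = 400 + i)
    fit <- suppressWarnings(
      fit_lme(cohort_to_records(coh, "cbf"), "y"))
    fit$fixed$estimate[fit$fixed$term == "caffeine:grouphabituated"]
  }, numeric(1))
  # habituated subjects drop less, so the interaction is positive
  expect_gt(mean(signs > 0), 0.9)
  expect_gt(mean(signs), 0)
})

test_that("mixed-model caffeine CI covers zero at the nominal rate under
           the null", {
  set.seed(13)
  covered <- vapply(1:400, function(i) {
    n <- 8
    subj_eff <- rnorm(2 * n, 0, 3)
    rec <- do.call(rbind, lapply(c("pre", "post"), function(st)
      data.frame(subject = sprintf("s%02d", 1:(2 * n)), state = st,
                 group = rep(c("naive", "habituated"), each = n),
                 y = 50 + subj_eff + rnorm(2 * n, 0, 2))))
    fit <- suppressWarnings(fit_lme(rec, "y", covariates = character(0)))
    row <- fit$fixed[fit$fixed$term == "caffeine", ]
    row$ci_low <= 0 && row$ci_high >= 0
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})
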