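#!/usr/bin/env Rscript

# Step 5: group statistics on the pipeline outputs.
#
# Reproduces the study's statistical battery on the estimated quantities:
# percent pre-to-post changes, Shapiro-Wilk normality of the paired
# differences, paired t-tests within groups, Welch t-tests between groups
# on baseline values and percent changes, and the linear mixed-effects
# model with the caffeine x group interaction, sex and age covariates and
# subject random intercepts.

library(cvrquant)

cohort <- read.csv("results/ground_truth.csv")
cbf_cvr <- read.csv("results/cbf_cvr_estimates.csv")
bold_cvr <- read.csv("results/bold_cvr_estimates.csv")
yv <- read.csv("results/yv_estimates.csv")

wide <- function(df, col) {
  merge(df[df$state == "pre", c("subject_id", "group", col)],
        df[df$state == "post", c("subject_id", col)],
        by = "subject_id", suffixes = c("_pre", "_post"))
}

stats_rows <- list()
for (nm in c("cbf_cvr", "bold_cvr", "yv")) {
  df <- get(nm)
  col <- if (nm == "yv") "yv" else nm
  w <- wide(df, col)
  for (g in c("naive", "habituated")) {
    sub <- w[w$group == g, ]
    pre <- sub[[paste0(col, "_pre")]]
    post <- sub[[paste0(col, "_post")]]
    pc <- percent_change(pre, post)
    sw <- normality_check(pre - post)
    tt <- paired_test(pre, post)
    stats_rows[[paste(nm, g)]] <- data.frame(
      outcome = nm, group = g,
      mean_pre = mean(pre), mean_post = mean(post),
      pct_change = mean(pc), pct_change_sd = sd(pc),
      shapiro_p = sw$p_value, paired_t = tt$statistic, paired_p = tt$p_value)
  }
  # between-group contrast of the percent change
  wn <- w[w$group == "naive", ]; wh <- w[w$group == "habituated", ]
  bt <- independent_test(
    percent_change(wn[[paste0(col, "_pre")]], wn[[paste0(col, "_post")]]),
    percent_change(wh[[paste0(col, "_pre")]], wh[[paste0(col, "_post")]]))
  message(sprintf("%s: between-group percent-change Welch t = %.2f, p = %.3f",
                  nm, bt$statistic, bt$p_value))
}
summary_df <- do.call(rbind, stats_rows)
write.csv(summary_df, "results/group_stats.csv", row.names = FALSE)
print(summary_df, digits = 3)

# Mixed-effects model on each outcome
meta <- cohort[, c("subject_id", "sex", "age")]
for (nm in c("cbf_cvr", "bold_cvr", "yv")) {
  df <- merge(get(nm), meta, by = "subject_id")
  col <- if (nm == "yv") "yv" else nm
  rec <- data.frame(subject = df$subject_id, state = df$state,
                    group = df$group, sex = df$sex, age = df$age,
                    y = df[[col]])
  fit <- fit_lme(rec, "y")
  message("\nMixed-effects model for ", nm, ":")
  print(fit)
  write.csv(fit$fixed, sprintf("results/lme_%s.csv", nm), row.names = FALSE)
}
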