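# Shared fixtures built in code at test time.

# One subject row with round-number ground truth, convenient for chain tests.
fixture_subject <- function(sex = "F") {
  data.frame(
    subject_id = "fix_01", group = "naive", sex = sex, age = 29, bvol = 1200,
    etco2_ra = 38, delta_etco2 = 8,
    cbf_pre = 60, cbf_post = 42,
    yv_pre = 60, yv_post = 47,
    cbf_cvr_pre = 4.5, cbf_cvr_post = 3.0,
    bold_cvr_pre = 0.17, bold_cvr_post = 0.15
  )
}

# Degenerate cohort spec: SD 0 everywhere, all subjects carry the group means.
fixture_spec_sd0 <- function(n_per_group = 2) {
  g <- default_group_params()
  for (nm in names(g)) {
    for (q in c("cbf", "yv", "cbf_cvr", "bold_cvr")) {
      g[[nm]][[q]]$pre[2] <- 0
      g[[nm]][[q]]$post[2] <- 0
    }
    g[[nm]]$age[2] <- 0
    g[[nm]]$etco2_ra[2] <- 0
    g[[nm]]$delta_etco2[2] <- 0
  }
  cohort_spec(n_per_group = n_per_group, groups = g)
}

# Brute-force per-breath maximum oracle: splits a trace into consecutive
# breath_period windows and reports the maximum sample of each.
per_breath_max <- function(trace, breath_period) {
  as.vector(tapply(trace$pco2, floor(trace$time / breath_period), max))
}
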