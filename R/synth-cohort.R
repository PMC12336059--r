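#' Two-group pre/post cohort specification
#'
#' Defines the ground-truth distributions of a two-group (caffeine-naive /
#' caffeine-habituated), two-state (pre / post caffeine) crossover cohort.
#' Defaults reproduce the study conditions: per-group/state means and SDs
#' of basal CBF variability, venous oxygenation, CBF-CVR and whole-brain
#' BOLD-CVR; group sex compositions (3M/5F naive, 5M/3F habituated) and
#' ages; baseline EtCO2 38.1 mmHg with group-specific spread; an 8 mmHg
#' hypercapnic EtCO2 step.  Basal CBF group means and the EtCO2 step are
#' not study-reported quantities and carry typical young-adult defaults
#' (see the methods vignette); all other means/SDs are the reported group
#' values.
#'
#' @param n_per_group Subjects per group.
#' @param correlation Within-subject pre/post correlation of each
#'   ground-truth quantity.
#' @param groups Named list (`naive`, `habituated`) of per-group parameter
#'   lists; see the default for the expected structure (`c(mean, sd)`
#'   pairs per state).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = 8, correlation = 0.7,
                        groups = default_group_params()) {
  stopifnot(n_per_group >= 2, abs(correlation) <= 1)
  for (g in groups) {
    for (q in c("cbf", "yv", "cbf_cvr", "bold_cvr")) {
      if (any(c(g[[q]]$pre[2], g[[q]]$post[2]) < 0))
        stop("SDs must be non-negative", call. = FALSE)
    }
  }
  structure(list(n_per_group = n_per_group, correlation = correlation,
                 groups = groups),
            class = "cohort_spec")
}

#' Default per-group ground-truth parameters
#'
#' @return Named list of per-group parameter lists used by [cohort_spec()].
#' @export
default_group_params <- function() {
  list(
    naive = list(
      sex = c("M", "M", "M", "F", "F", "F", "F", "F"),
      age = c(28.6, 5.2),
      cbf = list(pre = c(60, 15.4), post = c(41.3, 10.6)),
      yv = list(pre = c(60.8, 9.2), post = c(46.9, 3.7)),       # percent
      cbf_cvr = list(pre = c(4.5, 0.9), post = c(3.0, 0.9)),    # %/mmHg
      bold_cvr = list(pre = c(0.17, 0.04), post = c(0.15, 0.05)),
      etco2_ra = c(38.1, 4.5),
      delta_etco2 = c(8, 1)
    ),
    habituated = list(
      sex = c("M", "M", "M", "M", "M", "F", "F", "F"),
      age = c(29.1, 2.7),
      cbf = list(pre = c(55, 5.9), post = c(45.8, 4.9)),
      yv = list(pre = c(53.6, 3.9), post = c(49.6, 6.6)),
      cbf_cvr = list(pre = c(5.1, 1.5), post = c(3.7, 1.3)),
      bold_cvr = list(pre = c(0.17, 0.04), post = c(0.15, 0.05)),
      etco2_ra = c(38.1, 3.2),
      delta_etco2 = c(8, 1)
    )
  )
}

# Correlated pre/post bivariate-normal draws.
draw_prepost <- function(n, pre_ms, post_ms, rho) {
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  pre <- pre_ms[1] + pre_ms[2] * z1
  post <- post_ms[1] + post_ms[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
  cbind(pre = pre, post = post)
}

#' Draw a cohort's per-subject ground truth
#'
#' Draws per-subject (pre, post) true values of basal CBF, venous
#' oxygenation, CBF-CVR and BOLD-CVR from bivariate normals with the
#' configured means, SDs and within-subject correlation, plus per-subject
#' baseline EtCO2, hypercapnic EtCO2 step, brain volume, sex and age.
#' Deterministic under a fixed seed.  Raw inputs for any subject/state are
#' rendered on demand with [render_pc_inputs()], [render_bold_inputs()]
#' and [render_trust_inputs()].
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Data.frame of per-subject ground truth, one row per subject.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    n <- spec$n_per_group
    sex <- rep_len(g$sex, n)
    age <- round(stats::rnorm(n, g$age[1], g$age[2]), 1)
    cbf <- draw_prepost(n, g$cbf$pre, g$cbf$post, spec$correlation)
    yv <- draw_prepost(n, g$yv$pre, g$yv$post, spec$correlation)
    ccvr <- draw_prepost(n, g$cbf_cvr$pre, g$cbf_cvr$post, spec$correlation)
    bcvr <- draw_prepost(n, g$bold_cvr$pre, g$bold_cvr$post, spec$correlation)
    rows[[gname]] <- data.frame(
      subject_id = sprintf("%s_%02d", substr(gname, 1, 3), seq_len(n)),
      group = gname, sex = sex, age = age,
      bvol = stats::rnorm(n, 1200, 100),
      etco2_ra = stats::rnorm(n, g$etco2_ra[1], g$etco2_ra[2]),
      delta_etco2 = pmax(4, stats::rnorm(n, g$delta_etco2[1], g$delta_etco2[2])),
      cbf_pre = cbf[, "pre"], cbf_post = cbf[, "post"],
      yv_pre = yv[, "pre"], yv_post = yv[, "post"],
      cbf_cvr_pre = ccvr[, "pre"], cbf_cvr_post = ccvr[, "post"],
      bold_cvr_pre = bcvr[, "pre"], bold_cvr_post = bcvr[, "post"]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analytic end-tidal envelope of a simulated protocol
#'
#' The ground-truth breath-wise envelope that [generate_capno_trace()]
#' realizes: one peak per breath, at the condition level holding at the
#' peak time.
#'
#' @inheritParams generate_capno_trace
#' @return An [etco2_curve()].
#' @export
true_envelope <- function(protocol, etco2_ra, etco2_hc = etco2_ra,
                          breath_period = 4) {
  total <- protocol_duration(protocol)
  n_breaths <- floor(total / breath_period)
  peaks_t <- ((seq_len(n_breaths) - 1) + 0.5) * breath_period
  cond <- protocol_condition_at(protocol, peaks_t)
  etco2_curve(peaks_t, ifelse(cond == "hypercapnia", etco2_hc, etco2_ra))
}

subject_state <- function(subject, what, state) {
  subject[[paste0(what, "_", state)]]
}

#' Render raw phase-contrast inputs for one subject and state
#'
#' Converts the subject's true CBF and CBF-CVR into room-air/hypercapnic
#' sinus fluxes (via the unit-mass CBF relation and the subject's brain
#' volume), then renders the capnograph trace of the three-scan PC session
#' and the two velocity/magnitude image pairs.
#'
#' @param subject One row of a [generate_cohort()] table.
#' @param state `"pre"` or `"post"`.
#' @param noise_sd Velocity noise, cm/s.
#' @param seed Integer seed.
#' @return List with `trace` (capnograph), `pair` (see
#'   [generate_pc_pair()]), `protocol`, and the derived `truth`.
#' @export
render_pc_inputs <- function(subject, state = c("pre", "post"),
                             noise_sd = 0.5, seed = 1L) {
  state <- match.arg(state)
  prot <- pc_protocol()
  cbf <- subject_state(subject, "cbf", state)
  cvr <- subject_state(subject, "cbf_cvr", state)
  flux_ra <- cbf * 0.46 * subject$bvol * 1.06 / 100
  flux_hc <- flux_ra * (1 + cvr * subject$delta_etco2 / 100)
  trace <- generate_capno_trace(prot, etco2_ra = subject$etco2_ra,
                                etco2_hc = subject$etco2_ra + subject$delta_etco2,
                                seed = seed)
  pair <- generate_pc_pair(flux_ra, flux_hc, noise_sd = noise_sd,
                           windows = attr(prot, "scan_windows")[c(1, 3)],
                           seed = seed + 1L)
  list(trace = trace, pair = pair, protocol = prot,
       truth = list(flux_ra = flux_ra, flux_hc = flux_hc, cbf_ra = cbf,
                    cvr = cvr))
}

#' Render raw BOLD-CVR inputs for one subject and state
#'
#' @param subject One row of a [generate_cohort()] table.
#' @param state `"pre"` or `"post"`.
#' @param grid BOLD volume grid (default 16 x 16 x 8).
#' @param noise_sd,drift_slope,bold_delay Forward-model parameters
#'   (see [generate_bold_series()]).
#' @param seed Integer seed.
#' @return List with `trace`, `study`, `protocol` and `truth`.
#' @export
render_bold_inputs <- function(subject, state = c("pre", "post"),
                               grid = c(16, 16, 8), noise_sd = 10,
                               drift_slope = 0.02, bold_delay = 6,
                               seed = 1L) {
  state <- match.arg(state)
  prot <- bold_protocol()
  cvr <- subject_state(subject, "bold_cvr", state)
  etco2_hc <- subject$etco2_ra + subject$delta_etco2
  trace <- generate_capno_trace(prot, etco2_ra = subject$etco2_ra,
                                etco2_hc = etco2_hc, seed = seed)
  env <- true_envelope(prot, subject$etco2_ra, etco2_hc)
  study <- generate_bold_series(prot, cvr_map = array(cvr, grid), etco2 = env,
                                etco2_ref = subject$etco2_ra,
                                noise_sd = noise_sd, drift_slope = drift_slope,
                                bold_delay = bold_delay, seed = seed + 1L)
  list(trace = trace, study = study, protocol = prot,
       truth = list(cvr = cvr, bold_delay = bold_delay))
}

#' Render raw TRUST inputs for one subject and state
#'
#' @param subject One row of a [generate_cohort()] table.
#' @param state `"pre"` or `"post"`.
#' @param calib A [trust_calibration()].
#' @param noise_sd Image noise SD.
#' @param seed Integer seed.
#' @return List with `series` and `truth` (the series carries its own
#'   truth record too).
#' @export
render_trust_inputs <- function(subject, state = c("pre", "post"),
                                calib = trust_calibration(), noise_sd = 2,
                                seed = 1L) {
  state <- match.arg(state)
  yv <- subject_state(subject, "yv", state) / 100
  hct <- hct_from_sex(subject$sex)
  series <- generate_trust_series(yv_true = yv, hct = hct, calib = calib,
                                  noise_sd = noise_sd, seed = seed)
  list(series = series, truth = series$truth)
}
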