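#' Across-replicate recovery of configured group means
#'
#' The pipeline-level unbiasedness check: simulates many independent
#' cohorts whose ground truth is drawn from the configured group
#' distributions, renders the raw inputs for each subject, runs the full
#' estimation chain (`pc` = capnograph + phase-contrast to CBF-CVR;
#' `bold` = capnograph + 4D BOLD to whole-brain BOLD-CVR; `trust` = TRUST
#' series to venous oxygenation), and compares the across-replicate grand
#' mean of the estimates with the configured mean.  The Monte-Carlo
#' standard error is the SD of the per-replicate cohort means divided by
#' `sqrt(n_replicates)`.
#'
#' @param quantity `"cbf_cvr"`, `"bold_cvr"` or `"yv"`.
#' @param group `"naive"`, `"habituated"`, or `"pooled"` (both groups).
#' @param states Character subset of `c("pre", "post")`.
#' @param n_replicates Number of replicate cohorts.
#' @param spec A [cohort_spec()] (defaults to the study configuration).
#' @param seed Integer base seed; replicate r uses `seed + r` for cohort
#'   draws and rendering.
#' @return Data.frame with one row per state: `grand_mean`, `mc_se`,
#'   `configured` (the generator mean), `n_subjects` per replicate, and
#'   `n_replicates`.
#' @export
recovery_grand_mean <- function(quantity = c("cbf_cvr", "bold_cvr", "yv"),
                                group = c("naive", "habituated", "pooled"),
                                states = c("pre", "post"),
                                n_replicates = 200,
                                spec = cohort_spec(), seed = 1L) {
  quantity <- match.arg(quantity)
  group <- match.arg(group)
  states <- match.arg(states, c("pre", "post"), several.ok = TRUE)
  modality <- switch(quantity, cbf_cvr = "pc", bold_cvr = "bold", yv = "trust")
  est_col <- switch(quantity, cbf_cvr = "cbf_cvr_est", bold_cvr = "bold_cvr_est",
                    yv = "yv_est")
  calib <- trust_calibration()

  per_rep <- array(NA_real_, c(n_replicates, length(states)),
                   dimnames = list(NULL, states))
  n_subj <- NA_integer_
  for (r in seq_len(n_replicates)) {
    coh <- generate_cohort(spec, seed = seed + r)
    if (group != "pooled") coh <- coh[coh$group == group, ]
    n_subj <- nrow(coh)
    res <- run_cohort_pipeline(coh, states = states, modalities = modality,
                               calib = calib, seed = seed + r)
    for (st in states)
      per_rep[r, st] <- mean(res[res$state == st, est_col])
  }
  configured <- vapply(states, function(st) {
    gs <- if (group == "pooled") names(spec$groups) else group
    mean(vapply(gs, function(g) spec$groups[[g]][[quantity]][[st]][1],
                numeric(1)))
  }, numeric(1))
  data.frame(
    quantity = quantity, group = group, state = states,
    grand_mean = colMeans(per_rep),
    mc_se = apply(per_rep, 2, stats::sd) / sqrt(n_replicates),
    configured = configured,
    n_subjects = n_subj, n_replicates = n_replicates,
    row.names = NULL
  )
}
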