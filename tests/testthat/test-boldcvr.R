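make_study <- function(cvr = 0.2, noise_sd = 0, drift_slope = 0,
                       bold_delay = 0, grid = c(6, 6, 4), seed = 1) {
  p <- bold_protocol()
  env <- true_envelope(p, 38, 46)
  list(study = generate_bold_series(p, array(cvr, grid), env, etco2_ref = 38,
                                    noise_sd = noise_sd,
                                    drift_slope = drift_slope,
                                    bold_delay = bold_delay, seed = seed),
       env = env, protocol = p)
}

test_that("preprocessing smooths conservatively and masks by intensity", {
  s <- make_study()$study
  # fwhm 0 leaves the data untouched
  expect_identical(preprocess_bold(s, fwhm = 0)$data, s$data)

  # a spatially uniform volume is a fixed point of smoothing
  u <- bold_study(array(500, c(8, 8, 4, 12)), tr = 1.5)
  expect_equal(preprocess_bold(u, fwhm = 8)$data, u$data, tolerance = 1e-12)

  # an interior impulse (kernel support inside the volume) keeps its mass
  v <- array(0, c(16, 16, 16))
  v[8, 8, 8] <- 1000
  sm <- cvrquant:::gaussian_smooth_3d(v, c(1, 1, 1))
  expect_equal(sum(sm), 1000, tolerance = 1e-6)

  # voxels far below the robust maximum are masked out
  d <- array(1000, c(6, 6, 4, 12)); d[1, 1, 1, ] <- 1
  pp <- preprocess_bold(bold_study(d, tr = 1.5))
  expect_false(pp$mask[1, 1, 1])
  expect_equal(sum(pp$mask), 6 * 6 * 4 - 1)
})

test_that("EtCO2/BOLD alignment recovers the imposed hemodynamic delay", {
  # noiseless delay of 6 s found within one grid step
  m <- make_study(bold_delay = 6)
  al <- align_etco2(m$study, m$env, search = c(-15, 15), step = 0.5)
  expect_equal(al$shift_s, 6)

  # zero imposed delay
  m0 <- make_study(bold_delay = 0)
  expect_equal(align_etco2(m0$study, m0$env, search = c(-15, 15),
                           step = 0.5)$shift_s, 0)

  # constant global signal is undefined
  flat <- bold_study(array(100, c(4, 4, 2, 20)), tr = 1.5)
  expect_error(align_etco2(flat, m$env), "constant")

  # pure-noise series: error, or shift 0 with warning under on_fail = "zero"
  set.seed(11)
  noise <- bold_study(array(rnorm(4 * 4 * 2 * 200, 1000, 10), c(4, 4, 2, 200)),
                      tr = 1.5)
  expect_error(align_etco2(noise, m$env, search = c(-15, 15), step = 0.5),
               "below floor")
  expect_warning(
    al0 <- align_etco2(noise, m$env, search = c(-15, 15), step = 0.5,
                       on_fail = "zero"),
    "below floor")
  expect_equal(al0$shift_s, 0)
})

test_that("voxelwise GLM matches construction and a least-squares oracle", {
  p <- bold_protocol()
  nt <- p$n_dynamics
  env <- true_envelope(p, 38, 46)
  times <- (seq_len(nt) - 1) * p$tr
  e <- resample_etco2(env, times)$resampled_etco2
  l <- seq_len(nt) - (nt + 1) / 2

  # exact interpolation of a noiseless constructed series
  y <- 100 + 2 * (e - mean(e)) + 0.01 * l
  st <- bold_study(array(rep(y, each = 8), c(2, 2, 2, nt)), tr = p$tr)
  fit <- fit_glm(st, resample_etco2(env, times))
  expect_equal(max(abs(fit$beta0 - 100)), 0, tolerance = 1e-8)
  expect_equal(max(abs(fit$beta1 - 2)), 0, tolerance = 1e-10)
  expect_equal(max(abs(fit$beta2 - 0.01)), 0, tolerance = 1e-10)

  # random voxels agree with the brute-force normal-equations oracle
  m <- make_study(noise_sd = 10, drift_slope = 0.02, seed = 3)
  al <- resample_etco2(m$env, times)
  fit2 <- fit_glm(m$study, al)
  X <- cbind(1, al$resampled_etco2 - mean(al$resampled_etco2), l)
  set.seed(4)
  for (i in sample(prod(dim(m$study$data)[1:3]), 5)) {
    yv <- matrix(m$study$data, ncol = nt)[i, ]
    beta <- solve(t(X) %*% X) %*% t(X) %*% yv
    expect_equal(c(fit2$beta0[i], fit2$beta1[i], fit2$beta2[i]),
                 as.vector(beta), tolerance = 1e-8)
  }

  # constant regressor is rank deficient
  expect_error(fit_glm(st, resample_etco2(true_envelope(p, 40, 40), times)),
               "rank deficient")
})

test_that("the EtCO2 coefficient is unbiased at zero CVR", {
  p <- bold_protocol()
  env <- true_envelope(p, 38, 46)
  times <- (seq_len(p$n_dynamics) - 1) * p$tr
  al <- resample_etco2(env, times)
  b1 <- vapply(1:100, function(s) {
    st <- generate_bold_series(p, array(0, c(2, 2, 1)), env, etco2_ref = 38,
                               noise_sd = 10, drift_slope = 0, seed = s)
    mean(fit_glm(st, al)$beta1)
  }, numeric(1))
  expect_lt(abs(mean(b1)), 2 * sd(b1) / sqrt(100))
})

test_that("the CVR map references percent change to the room-air state", {
  fit <- list(beta0 = array(1000, c(1, 1, 1)), beta1 = array(2, c(1, 1, 1)),
              mask = array(TRUE, c(1, 1, 1)))
  s <- list(mean_etco2 = 43, baseline_etco2 = 38)
  expect_equal(compute_cvr_map(fit, s)$cvr[1], 2 / 990 * 100, tolerance = 1e-12)
  expect_equal(compute_cvr_map(fit, s)$cvr[1], 0.20202, tolerance = 1e-4)

  # mean equal to baseline: plain beta1/beta0 scaling
  s0 <- list(mean_etco2 = 38, baseline_etco2 = 38)
  expect_equal(compute_cvr_map(fit, s0)$cvr[1], 0.2)

  # beta1 = 0 maps to 0
  fit0 <- fit; fit0$beta1 <- array(0, c(1, 1, 1))
  expect_equal(compute_cvr_map(fit0, s)$cvr[1], 0)

  # non-positive denominator: flagged invalid and excluded, not clipped
  bad <- fit; bad$beta1 <- array(300, c(1, 1, 1))
  expect_warning(mp <- compute_cvr_map(bad, s), "excluded")
  expect_true(is.na(mp$cvr[1]))
})

test_that("CVR adjustment is multiplicative in both EtCO2 terms", {
  expect_equal(adjust_cvr(0.17, b_etco2 = 38.1, d_etco2 = 8), 0.17)
  expect_equal(adjust_cvr(0.17, b_etco2 = 39.1, d_etco2 = 8), 0.1734)
  # monotone increasing in baseline EtCO2 for positive CVR
  v <- adjust_cvr(0.17, b_etco2 = c(36, 38, 40, 42), d_etco2 = 8)
  expect_true(all(diff(v) > 0))
  expect_error(adjust_cvr(0.17, b_etco2 = 38.1, d_etco2 = -20), "non-positive")
})

test_that("ROI summaries average valid voxels and respect partitions", {
  cvr <- array(0.1, c(4, 4, 2)); cvr[3:4, , ] <- 0.3
  map <- list(cvr = cvr, valid = array(TRUE, dim(cvr)))
  m1 <- array(FALSE, dim(cvr)); m1[1:2, , ] <- TRUE
  m2 <- !m1
  out <- roi_summary(map, list(a = m1, b = m2))
  expect_equal(unname(out), c(0.1, 0.3))

  # uniform map: every ROI reports the same value
  mapu <- list(cvr = array(0.17, c(4, 4, 2)), valid = array(TRUE, c(4, 4, 2)))
  expect_equal(unname(roi_summary(mapu, list(a = m1, b = m2))), c(0.17, 0.17))

  # whole-brain mean equals the voxel-weighted mean of a partition
  whole <- array(TRUE, dim(cvr))
  wb <- roi_summary(map, list(wb = whole))
  parts <- roi_summary(map, list(a = m1, b = m2))
  w <- c(sum(m1), sum(m2)) / sum(whole)
  expect_equal(unname(wb), sum(w * parts))

  # an ROI with no valid voxels is omitted with a warning
  map$valid[1:2, , ] <- FALSE
  expect_warning(out2 <- roi_summary(map, list(a = m1, b = m2)), "omitted")
  expect_named(out2, "b")
})

test_that("end-to-end BOLD-CVR recovery and rescaling invariance", {
  subj <- fixture_subject()
  # noiseless synthetic study: voxelwise recovery well below 0.5% relative
  inp <- render_bold_inputs(subj, "pre", noise_sd = 0, drift_slope = 0,
                            seed = 1)
  est <- estimate_bold_cvr(inp$study, inp$trace, search = c(-15, 15),
                           step = 0.5)
  expect_lt(max(abs(est$map$cvr / inp$truth$cvr - 1)), 5e-3)
  expect_equal(est$whole_brain, inp$truth$cvr, tolerance = 1e-10)

  # multiplicative rescaling of the raw series leaves the CVR map unchanged
  scaled <- inp$study; scaled$data <- scaled$data * 3.7
  est2 <- estimate_bold_cvr(scaled, inp$trace, search = c(-15, 15), step = 0.5)
  expect_equal(est2$map$cvr, est$map$cvr, tolerance = 1e-10)
})
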