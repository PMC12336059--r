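test_that("capnograph generator: breath maxima follow the block schedule", {
  # constant room air: every per-breath maximum is the room-air level
  p_ra <- protocol(data.frame(condition = "room_air", duration = 120),
                   tr = 1, n_dynamics = 100)
  tr_ra <- generate_capno_trace(p_ra, etco2_ra = 40, seed = 1)
  expect_equal(per_breath_max(tr_ra, 4), rep(40, 30))

  # study protocol: envelope equals the 38/46 block function, checked
  # against the brute-force per-breath maximum oracle
  p <- bold_protocol()
  tr <- generate_capno_trace(p, etco2_ra = 38, etco2_hc = 46, seed = 2)
  maxima <- per_breath_max(tr, 4)
  peaks_t <- (seq_along(maxima) - 0.5) * 4
  expected <- ifelse(protocol_condition_at(p, peaks_t) == "hypercapnia", 46, 38)
  expect_equal(maxima, expected)

  # trough near the configured floor, never negative
  expect_gte(min(tr$pco2), 0)
  expect_lt(min(tr$pco2), 3)
})

test_that("capnograph generator rejects degenerate parameters", {
  p <- protocol(data.frame(condition = "room_air", duration = 30),
                tr = 1, n_dynamics = 30)
  expect_error(generate_capno_trace(p, 40, breath_period = 60),
               "single breath")
  expect_error(generate_capno_trace(p, 40, breath_period = 0.05),
               "two capnograph samples")
  expect_error(protocol(data.frame(condition = "room_air", duration = -5),
                        tr = 1, n_dynamics = 1), "positive")
})

test_that("BOLD generator realizes the linear forward model", {
  p <- bold_protocol()
  env <- true_envelope(p, 38, 46)

  # null response: cvr 0, no drift, no noise -> constant at beta0
  s0 <- generate_bold_series(p, array(0, c(4, 4, 2)), env, etco2_ref = 38,
                             drift_slope = 0, noise_sd = 0, seed = 1)
  expect_equal(range(s0$data), c(1000, 1000))

  # plateau/baseline signal ratio for cvr 0.2 %/mmHg and an 8 mmHg step
  s1 <- generate_bold_series(p, array(0.2, c(4, 4, 2)), env, etco2_ref = 38,
                             drift_slope = 0, noise_sd = 0, bold_delay = 0,
                             seed = 1)
  ts <- s1$data[1, 1, 1, ]
  t_grid <- bold_times(s1)
  plateau <- mean(ts[t_grid > 30 & t_grid < 60])   # mid hypercapnic block
  baseline <- ts[1]
  expect_equal(plateau / baseline, 1.016, tolerance = 1e-6)

  # mismatched regressor length is a shape error
  expect_error(generate_bold_series(p, array(0.2, c(2, 2, 2)), rep(40, 10)),
               "length")

  # determinism
  a <- generate_bold_series(p, array(0.2, c(4, 4, 2)), env, seed = 7)
  b <- generate_bold_series(p, array(0.2, c(4, 4, 2)), env, seed = 7)
  expect_identical(a$data, b$data)
})

test_that("PC generator conserves flux and wraps velocities by 2*venc", {
  # noiseless ROI-integrated flux equals configuration exactly
  pair <- generate_pc_pair(500, 650, noise_sd = 0, seed = 1)
  bf <- sum(pair$ra$velocity[pair$roi]) * pair$ra$voxel_area * 0.01 * 60
  expect_equal(bf, 500, tolerance = 1e-12)

  # wrap rule: a true 50 cm/s voxel at venc 40 is stored at -30
  expect_equal(cvrquant:::wrap_velocity(50, 40), -30)
  expect_equal(cvrquant:::wrap_velocity(c(-50, 35), 40), c(30, 35))

  # zero flux gives an identically zero velocity map
  z <- generate_pc_pair(0, 0, noise_sd = 0, seed = 1)
  expect_true(all(z$ra$velocity == 0))

  # irrecoverable aliasing (mean velocity beyond 2*venc) is refused
  expect_error(generate_pc_pair(500, 650, venc_ra = 5, noise_sd = 0),
               "irrecoverable")

  # determinism with noise
  a <- generate_pc_pair(500, 650, seed = 3)
  b <- generate_pc_pair(500, 650, seed = 3)
  expect_identical(a$ra$velocity, b$ra$velocity)
})

test_that("TRUST generator renders mono-exponential venous decay", {
  calib <- trust_calibration()
  yv60 <- calib_yv(calib, 60, 0.40)   # oxygenation giving T2 = 60 ms
  ser <- generate_trust_series(yv60, 0.40, calib = calib, noise_sd = 0,
                               seed = 1)
  d <- subtract_pairs(ser)
  sig <- vapply(d, function(x) mean(x[ser$sinus]), numeric(1))
  expect_equal(unname(sig / sig[1]), exp(-c(0, 40, 80, 160) / 60),
               tolerance = 1e-9)
  expect_equal(unname(sig[1]), 100, tolerance = 1e-9)   # eTE 0 equals S0

  # static tissue cancels exactly outside the sinus
  outside <- !ser$roi
  expect_true(all(abs(d[[2]][outside]) == 0))

  # oxygenation outside the calibration domain is refused
  expect_error(generate_trust_series(0.995, 0.40, calib = calib),
               "domain")
})

test_that("cohort generator draws reproduce the configured group statistics", {
  # SD 0: every subject carries exactly the group means
  coh0 <- generate_cohort(fixture_spec_sd0(), seed = 1)
  naive <- coh0[coh0$group == "naive", ]
  expect_true(all(naive$cbf_cvr_pre == 4.5))
  expect_true(all(naive$cbf_cvr_post == 3.0))
  expect_true(all(coh0[coh0$group == "habituated", "yv_pre"] == 53.6))

  # law of large numbers: naive pre CBF-CVR mean -> 4.5 as n grows
  big <- generate_cohort(cohort_spec(n_per_group = 4000), seed = 2)
  m <- mean(big[big$group == "naive", "cbf_cvr_pre"])
  expect_lt(abs(m - 4.5), 3 * 0.9 / sqrt(4000))

  # configured within-subject correlation is realized
  r <- cor(big[big$group == "naive", "cbf_cvr_pre"],
           big[big$group == "naive", "cbf_cvr_post"])
  expect_lt(abs(r - 0.7), 0.05)

  # determinism
  expect_identical(generate_cohort(cohort_spec(), seed = 5),
                   generate_cohort(cohort_spec(), seed = 5))

  # invalid spec parameters
  expect_error(cohort_spec(n_per_group = 1), "n_per_group")
  expect_error(cohort_spec(correlation = 1.2), "correlation")
})

test_that("generators are bitwise reproducible under a fixed seed", {
  p <- bold_protocol()
  expect_identical(generate_capno_trace(p, 38, 46, noise_sd = 0.3, seed = 9),
                   generate_capno_trace(p, 38, 46, noise_sd = 0.3, seed = 9))
  s1 <- generate_trust_series(0.6, 0.40, seed = 9)
  s2 <- generate_trust_series(0.6, 0.40, seed = 9)
  expect_identical(s1$volumes, s2$volumes)
})
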