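test_that("velocity unwrapping corrects opposite-sign near-venc voxels", {
  v <- matrix(35, 5, 5)
  v[3, 3] <- -30                       # a 50 cm/s voxel wrapped at venc 40
  scan <- pc_scan(v, NULL, venc = 40, voxel_area = 0.16)
  roi <- matrix(TRUE, 5, 5)
  un <- unwrap_velocity(scan, roi)
  expect_equal(un$velocity[3, 3], 50)
  expect_equal(un$velocity[1, 1], 35)

  # idempotence: second pass changes nothing; no-op without wraps
  expect_equal(unwrap_velocity(un, roi)$velocity, un$velocity)
  low <- pc_scan(matrix(10, 5, 5), NULL, venc = 40, voxel_area = 0.16)
  expect_equal(unwrap_velocity(low, roi)$velocity, low$velocity)

  # every correction moves a voxel by exactly 2*venc
  pair <- generate_pc_pair(500, 650, venc_ra = 25, venc_hc = 35,
                           noise_sd = 0, seed = 1)
  for (s in pair[c("ra", "hc")]) {
    un <- unwrap_velocity(s, pair$roi)
    d <- un$velocity - s$velocity
    expect_true(all(d == 0 | abs(abs(d) - 2 * s$venc) < 1e-12))
    expect_gt(sum(d != 0), 0)          # aliasing was actually exercised
  }
})

test_that("flux integration implements sum(v) * area * 0.01 * 60", {
  v <- matrix(0, 20, 20)
  v[1:10, 1:10] <- 10                  # 100 voxels at 10 cm/s
  roi <- v > 0
  scan <- pc_scan(v, NULL, venc = 40, voxel_area = 0.16)
  expect_equal(integrate_flux(scan, roi), 96)
  zero <- pc_scan(matrix(0, 20, 20), NULL, venc = 40, voxel_area = 0.16)
  expect_equal(integrate_flux(zero, roi), 0)
  expect_error(integrate_flux(scan, matrix(FALSE, 20, 20)), "empty ROI")
})

test_that("unwrap + integrate recovers the configured flux", {
  # no aliasing: exact conservation
  pair <- generate_pc_pair(500, 650, noise_sd = 0, seed = 1)
  expect_equal(integrate_flux(pair$ra, pair$roi), 500, tolerance = 1e-10)
  expect_equal(integrate_flux(pair$hc, pair$roi), 650, tolerance = 1e-10)

  # with injected aliasing: recovery only after unwrapping
  pa <- generate_pc_pair(500, 650, venc_ra = 25, venc_hc = 35,
                         noise_sd = 0, seed = 1)
  expect_equal(integrate_flux(unwrap_velocity(pa$ra, pa$roi), pa$roi), 500,
               tolerance = 1e-10)
  expect_equal(integrate_flux(unwrap_velocity(pa$hc, pa$roi), pa$roi), 650,
               tolerance = 1e-10)
  expect_false(abs(integrate_flux(pa$ra, pa$roi) - 500) < 1)
})

test_that("unit-mass CBF conversion follows the sinus-fraction relation", {
  expect_equal(compute_cbf(500, 1200), 500 * 100 / (0.46 * 1200 * 1.06))
  expect_equal(compute_cbf(500, 1200), 85.4526, tolerance = 1e-4)
  expect_equal(compute_cbf(0, 1200), 0)
  expect_equal(compute_cbf(500, 2400), compute_cbf(500, 1200) / 2)
  expect_error(compute_cbf(500, 0), "positive")
})

test_that("CBF-CVR is the percent flow change per mmHg EtCO2", {
  r <- compute_cbf_cvr(50, 60, 38, 46)
  expect_equal(r$cvr, 2.5)
  expect_equal(compute_cbf_cvr(50, 50, 38, 46)$cvr, 0)
  # scale invariance: CVR is a ratio, so any common CBF scaling cancels
  for (k in c(0.2, 3, 17)) {
    expect_equal(compute_cbf_cvr(50 * k, 60 * k, 38, 46)$cvr, 2.5)
  }
  expect_error(compute_cbf_cvr(50, 60, 40, 40), "equal")
  expect_error(compute_cbf_cvr(0, 60, 38, 46), "positive")
})

test_that("brain-volume factor cancels between flux- and CBF-based CVR", {
  bf_ra <- 480; bf_hc <- 590; bvol <- 1234
  a <- compute_cbf_cvr(bf_ra, bf_hc, 38, 46)$cvr
  b <- compute_cbf_cvr(compute_cbf(bf_ra, bvol), compute_cbf(bf_hc, bvol),
                       38, 46)$cvr
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("full PC chain recovers per-subject CBF-CVR", {
  subj <- fixture_subject()
  # noiseless: recovery to < 0.1% relative
  inp <- render_pc_inputs(subj, "pre", noise_sd = 0, seed = 1)
  est <- estimate_cbf_cvr(inp$trace, inp$pair$ra, inp$pair$hc, inp$pair$roi,
                          subj$bvol)
  expect_equal(est$cvr, inp$truth$cvr, tolerance = 1e-3)
  expect_equal(est$cbf_ra, subj$cbf_pre, tolerance = 1e-6)

  # generator noise defaults: small-sample mean bias under 2%
  errs <- vapply(1:40, function(s) {
    inp <- render_pc_inputs(subj, "pre", seed = s)
    estimate_cbf_cvr(inp$trace, inp$pair$ra, inp$pair$hc, inp$pair$roi,
                     subj$bvol)$cvr
  }, numeric(1))
  expect_lt(abs(mean(errs) / inp$truth$cvr - 1), 0.02)
})

test_that("threshold helper segments the bright synthetic sinus", {
  pair <- generate_pc_pair(500, 650, noise_sd = 0.5, seed = 2)
  roi <- threshold_sinus_roi(pair$ra$cd_magnitude, percentile = 0.93)
  # recovered mask overlaps the true sinus almost completely
  expect_gt(sum(roi & pair$roi) / sum(pair$roi), 0.9)
})
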