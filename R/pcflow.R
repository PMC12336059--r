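#' Phase-contrast scan container
#'
#' @param velocity 2D numeric matrix of through-plane velocities, cm/s, as
#'   stored by the scanner (possibly phase-wrapped into `(-venc, venc]`).
#' @param cd_magnitude 2D matrix of complex-difference magnitudes (arbitrary
#'   units), bright over flowing blood.
#' @param venc Velocity-encoding limit, cm/s.
#' @param voxel_area In-plane voxel area, mm^2.
#' @param window Acquisition window `(start, end)` in seconds relative to
#'   the gas protocol (used to pair the scan with its EtCO2 value).
#' @return A `pc_scan` object.
#' @export
pc_scan <- function(velocity, cd_magnitude, venc, voxel_area,
                    window = c(NA_real_, NA_real_)) {
  stopifnot(is.matrix(velocity), venc > 0, voxel_area > 0)
  if (!is.null(cd_magnitude))
    stopifnot(all(dim(cd_magnitude) == dim(velocity)))
  if (any(abs(velocity) > venc + 1e-9))
    stop("stored velocities must lie within [-venc, venc]", call. = FALSE)
  structure(
    list(velocity = velocity, cd_magnitude = cd_magnitude, venc = venc,
         voxel_area = voxel_area, window = window),
    class = "pc_scan"
  )
}

#' Elliptical mask on a 2D grid
#'
#' @param dim Grid dimensions `(nx, ny)`.
#' @param center Ellipse center in voxel coordinates (defaults to grid center).
#' @param semi_axes Semi-axes in voxels `(a, b)`.
#' @return Logical matrix.
#' @export
elliptical_mask <- function(dim, center = (dim + 1) / 2, semi_axes) {
  x <- matrix(seq_len(dim[1]), dim[1], dim[2])
  y <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  ((x - center[1]) / semi_axes[1])^2 + ((y - center[2]) / semi_axes[2])^2 <= 1
}

#' Simulate a room-air / hypercapnia phase-contrast scan pair
#'
#' Builds a smooth (truncated-parabolic) through-plane velocity profile over
#' an elliptical superior-sagittal-sinus region, scaled so that the
#' ROI-integrated flux equals `flux_ra` (room air) and `flux_hc`
#' (hypercapnia) exactly before noise.  Velocities beyond the venc are
#' stored phase-wrapped into `(-venc, venc]` (offset by multiples of
#' 2*venc), exercising the unwrapping stage.  The complex-difference
#' magnitude image is bright over the sinus.
#'
#' @param flux_ra,flux_hc True blood flux in ml/min for the two states.
#' @param venc_ra,venc_hc Velocity-encoding limits, cm/s (defaults 40 / 60).
#' @param grid Image dimensions (default 64 x 64).
#' @param voxel_area Voxel area in mm^2 (default 0.16, i.e. 0.4 x 0.4 mm).
#' @param semi_axes Sinus ellipse semi-axes in voxels.
#' @param noise_sd Gaussian velocity noise, cm/s.
#' @param windows List of two `(start, end)` acquisition windows in seconds
#'   (defaults to PC scans 1 and 3 of [pc_protocol()]).
#' @param seed Integer seed.
#' @return List with elements `ra`, `hc` (both [pc_scan()]), `roi` (the true
#'   sinus mask) and `truth` (the configured fluxes).
#' @export
generate_pc_pair <- function(flux_ra, flux_hc, venc_ra = 40, venc_hc = 60,
                             grid = c(64, 64), voxel_area = 0.16,
                             semi_axes = c(8, 12), noise_sd = 0.5,
                             windows = list(c(0, 60), c(120, 180)),
                             seed = 1L) {
  if (venc_ra <= 0 || venc_hc <= 0) stop("venc must be positive", call. = FALSE)
  if (flux_ra < 0 || flux_hc < 0) stop("flux must be non-negative", call. = FALSE)
  set.seed(seed)
  roi <- elliptical_mask(grid, semi_axes = semi_axes)
  # unit profile: parabolic, peaked at the ellipse center
  x <- matrix(seq_len(grid[1]), grid[1], grid[2])
  y <- matrix(seq_len(grid[2]), grid[1], grid[2], byrow = TRUE)
  c0 <- (grid + 1) / 2
  r2 <- ((x - c0[1]) / semi_axes[1])^2 + ((y - c0[2]) / semi_axes[2])^2
  prof <- pmax(0, 1 - r2) * roi

  one <- function(flux, venc, window) {
    # flux [ml/min] = sum(v [cm/s]) * voxel_area [mm^2] * 0.01 * 60
    scale <- if (flux > 0) flux / (sum(prof) * voxel_area * 0.01 * 60) else 0
    v <- prof * scale
    if (max(v) > 2 * venc)
      stop("configured flux implies velocity beyond 2*venc: irrecoverable aliasing",
           call. = FALSE)
    if (noise_sd > 0) v <- v + matrix(stats::rnorm(length(v), 0, noise_sd), nrow(v))
    stored <- wrap_velocity(v, venc)
    cd <- 10 + 90 * prof +
      if (noise_sd > 0) matrix(stats::rnorm(length(v), 0, 1), nrow(v)) else 0
    pc_scan(stored, cd, venc = venc, voxel_area = voxel_area, window = window)
  }
  list(ra = one(flux_ra, venc_ra, windows[[1]]),
       hc = one(flux_hc, venc_hc, windows[[2]]),
       roi = roi,
       truth = list(flux_ra = flux_ra, flux_hc = flux_hc))
}

# Phase wrap: map velocities into (-venc, venc] by multiples of 2*venc.
wrap_velocity <- function(v, venc) {
  w <- ((v + venc) %% (2 * venc)) - venc
  w[w == -venc] <- venc   # boundary convention: (-venc, venc]
  w
}

#' Unwrap phase-aliased velocities inside a vessel ROI
#'
#' A voxel is treated as wrapped when its sign opposes the ROI-median flow
#' direction and its value lies within `0.5 * venc` of the opposite venc
#' rail; such voxels are corrected by `2 * venc` toward the median
#' direction.  Idempotent on already-unwrapped data and a no-op when no
#' wrap is detected.
#'
#' @param scan A [pc_scan()].
#' @param roi Logical mask of the vessel.
#' @return The scan with corrected velocities.
#' @export
unwrap_velocity <- function(scan, roi) {
  stopifnot(all(dim(roi) == dim(scan$velocity)))
  v <- scan$velocity
  s <- sign(stats::median(v[roi]))
  if (s == 0) return(scan)
  wrapped <- roi & (sign(v) == -s) & (abs(v - (-s * scan$venc)) < 0.5 * scan$venc)
  v[wrapped] <- v[wrapped] + s * 2 * scan$venc
  scan$velocity <- v
  scan
}

#' Integrate blood flux over a vessel ROI
#'
#' `BF = sum(v) * voxel_area * 0.01 * 60` in ml/min (cm/s times mm^2,
#' rescaled to cm^2 and per minute).  Flow along the ROI-median direction
#' is reported positive.
#'
#' @param scan A [pc_scan()] (unwrap first if aliasing is suspected).
#' @param roi Logical vessel mask.
#' @return Blood flux in ml/min.
#' @export
integrate_flux <- function(scan, roi) {
  stopifnot(all(dim(roi) == dim(scan$velocity)))
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  v <- scan$velocity[roi]
  s <- sign(stats::median(v))
  if (s == 0) s <- 1
  s * sum(v) * scan$voxel_area * 0.01 * 60
}

#' Unit-mass cerebral blood flow from sinus flux
#'
#' `CBF = BF * 100 / (sinus_fraction * Bvol * density)` in ml/100 g/min,
#' where `sinus_fraction` is the fraction of total cerebral blood flow
#' drained by the superior sagittal sinus and `density` the brain tissue
#' mass density.
#'
#' @param bf Blood flux in ml/min.
#' @param bvol Total brain volume (GM + WM) in ml.
#' @param sinus_fraction Fraction of whole-brain flow in the sinus (0.46).
#' @param density Brain mass density in g/ml (1.06).
#' @return CBF in ml/100 g/min.
#' @export
compute_cbf <- function(bf, bvol, sinus_fraction = 0.46, density = 1.06) {
  if (any(bvol <= 0)) stop("brain volume must be positive", call. = FALSE)
  bf * 100 / (sinus_fraction * bvol * density)
}

#' CBF-based cerebrovascular reactivity
#'
#' `CVR = ((CBF_HC - CBF_RA) / CBF_RA * 100) / (EtCO2_HC - EtCO2_RA)` in
#' %/mmHg.  Because the brain-volume factor cancels in the ratio, fluxes
#' (ml/min) may be passed instead of CBF values.
#'
#' @param cbf_ra,cbf_hc Room-air and hypercapnic CBF (or flux) values.
#' @param etco2_ra,etco2_hc Scan-matched EtCO2 values, mmHg.
#' @return List with `cvr` (%/mmHg) and the `basis` quadruple.
#' @export
compute_cbf_cvr <- function(cbf_ra, cbf_hc, etco2_ra, etco2_hc) {
  if (etco2_hc == etco2_ra)
    stop("EtCO2 values are equal: CVR undefined", call. = FALSE)
  if (cbf_ra <= 0)
    stop("baseline CBF must be positive", call. = FALSE)
  cvr <- ((cbf_hc - cbf_ra) / cbf_ra * 100) / (etco2_hc - etco2_ra)
  list(cvr = cvr,
       basis = list(cbf_ra = cbf_ra, cbf_hc = cbf_hc,
                    etco2_ra = etco2_ra, etco2_hc = etco2_hc))
}

#' Threshold-based sinus ROI helper (synthetic data only)
#'
#' Convenience for tests on generated data, standing in for the manual ROI
#' drawing used on real complex-difference images: selects voxels whose
#' complex-difference magnitude exceeds the given percentile within a seed
#' box.
#'
#' @param cd_magnitude Complex-difference magnitude image.
#' @param box Optional list `(rows, cols)` of index ranges to search.
#' @param percentile Quantile threshold within the box (default 0.75).
#' @return Logical mask.
#' @export
threshold_sinus_roi <- function(cd_magnitude, box = NULL, percentile = 0.75) {
  m <- matrix(FALSE, nrow(cd_magnitude), ncol(cd_magnitude))
  if (is.null(box)) box <- list(seq_len(nrow(m)), seq_len(ncol(m)))
  sub <- cd_magnitude[box[[1]], box[[2]]]
  thr <- stats::quantile(sub, percentile)
  m[box[[1]], box[[2]]] <- sub > thr
  m
}
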