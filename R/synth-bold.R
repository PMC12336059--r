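#' 4D BOLD study container
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr Repetition time, seconds.
#' @param mask Logical 3D brain mask (defaults to all voxels).
#' @param protocol The gas [protocol()] under which the series was acquired.
#' @param voxdim Voxel dimensions in mm (used by spatial smoothing).
#' @return A `bold_study` object.
#' @export
bold_study <- function(data, tr, mask = NULL, protocol = NULL,
                       voxdim = c(3.43, 3.43, 3.8)) {
  stopifnot(length(dim(data)) == 4, tr > 0)
  if (dim(data)[4] < 10) stop("need at least 10 dynamics", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  stopifnot(all(dim(mask) == dim(data)[1:3]))
  if (!any(mask)) stop("empty brain mask", call. = FALSE)
  structure(
    list(data = data, tr = tr, mask = mask, protocol = protocol,
         voxdim = voxdim),
    class = "bold_study"
  )
}

#' Scan-time grid of a BOLD study
#' @param study A `bold_study`.
#' @return Numeric vector of dynamic times, seconds (first dynamic at 0).
#' @export
bold_times <- function(study) (seq_len(dim(study$data)[4]) - 1) * study$tr

#' Simulate a 4D BOLD series from a CVR map and an EtCO2 curve
#'
#' Forward model (the same linear model the analysis fits): for voxel v,
#' `S_v(t) = beta0 * (1 + cvr_v/100 * (EtCO2(t - bold_delay) - etco2_ref))
#'  + drift_slope * l(t) + N(0, noise_sd)`,
#' where `l(t)` is the zero-centred unit-step linear trend and `etco2_ref`
#' is the room-air reference level, so `cvr_v` is the percent signal change
#' per mmHg relative to the room-air state.  No hemodynamic-response
#' convolution is applied; the response is a pure temporal shift of the
#' EtCO2 envelope.
#'
#' @param protocol A [protocol()] (supplies TR and n_dynamics).
#' @param cvr_map 3D array of true CVR in %/mmHg (defines the grid).
#' @param etco2 An [etco2_curve()] (breath-wise values; resampled
#'   internally at the shifted scan grid), or a numeric vector already on
#'   the TR grid, in which case its length must equal `n_dynamics` and the
#'   delay is assumed already applied.
#' @param etco2_ref Room-air reference EtCO2, mmHg.  Defaults to the
#'   minimum breath-wise value of the curve.
#' @param beta0 Baseline signal level.
#' @param drift_slope Linear drift, signal units per dynamic.
#' @param noise_sd Gaussian noise SD, signal units.
#' @param bold_delay Hemodynamic delay of the BOLD response behind EtCO2,
#'   seconds.
#' @param seed Integer seed.
#' @return A [bold_study()] with attribute `truth` recording the inputs.
#' @export
generate_bold_series <- function(protocol, cvr_map, etco2,
                                 etco2_ref = NULL,
                                 beta0 = 1000, drift_slope = 0.02,
                                 noise_sd = 10, bold_delay = 6, seed = 1L) {
  stopifnot(length(dim(cvr_map)) == 3)
  set.seed(seed)
  nt <- protocol$n_dynamics
  times <- (seq_len(nt) - 1) * protocol$tr
  if (is.numeric(etco2)) {
    if (length(etco2) != nt)
      stop("EtCO2 vector length does not match n_dynamics", call. = FALSE)
    e <- etco2
    if (is.null(etco2_ref)) etco2_ref <- min(e)
  } else {
    e <- resample_etco2(etco2, times, shift_s = bold_delay)$resampled_etco2
    if (is.null(etco2_ref)) etco2_ref <- min(etco2$breath_etco2)
  }
  l <- seq_len(nt) - (nt + 1) / 2
  nvox <- length(cvr_map)
  # nvox x nt signal matrix: beta0 * (1 + cvr/100 * dEtCO2) + drift + noise
  sig <- outer(as.vector(cvr_map) * (beta0 / 100), e - etco2_ref)
  sig <- sig + rep(beta0 + drift_slope * l, each = nvox)
  if (noise_sd > 0) sig <- sig + stats::rnorm(nvox * nt, 0, noise_sd)
  data <- sig
  dim(data) <- c(dim(cvr_map), nt)
  study <- bold_study(data, tr = protocol$tr, protocol = protocol)
  attr(study, "truth") <- list(cvr_map = cvr_map, etco2_ref = etco2_ref,
                               beta0 = beta0, drift_slope = drift_slope,
                               noise_sd = noise_sd, bold_delay = bold_delay)
  study
}
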