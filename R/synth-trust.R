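#' Simulate a TRUST label/control series
#'
#' Renders label/control image pairs at each effective TE.  The venous
#' blood signal in the sinus voxels decays mono-exponentially,
#' `S0 * exp(-eTE / T2)`, with `T2 = calib_t2(calib, yv_true, hct)`;
#' static tissue is identical in label and control within a pair and
#' cancels on subtraction.  Gaussian noise is added independently to every
#' image.
#'
#' @param yv_true True venous oxygenation, fraction.
#' @param hct Hematocrit fraction.
#' @param etes Effective TEs in ms (default 0, 40, 80, 160).
#' @param calib A [trust_calibration()].
#' @param s0 Venous blood signal at eTE = 0.
#' @param n_pairs Label/control pairs per eTE.
#' @param grid Image dimensions (default 32 x 32).
#' @param n_sinus Number of bright sinus voxels (default 4, matching the
#'   top-4 selection).
#' @param static_value Static-tissue signal level.
#' @param noise_sd Gaussian image noise SD.
#' @param seed Integer seed.
#' @return A list with `volumes` (per eTE, list of `list(label, control)`),
#'   `etes`, `roi` (mask around the sinus), `sinus` (true sinus indices)
#'   and `truth`.
#' @export
generate_trust_series <- function(yv_true, hct, etes = c(0, 40, 80, 160),
                                  calib = trust_calibration(), s0 = 100,
                                  n_pairs = 3, grid = c(32, 32), n_sinus = 4,
                                  static_value = 50, noise_sd = 2, seed = 1L) {
  if (any(etes < 0) || is.unsorted(etes, strictly = TRUE))
    stop("etes must be non-negative and strictly increasing", call. = FALSE)
  t2 <- calib_t2(calib, yv_true, hct)   # errors if yv outside domain
  set.seed(seed)
  cx <- round(grid[1] / 2); cy <- round(grid[2] / 2)
  sinus_rc <- cbind(cx + c(0, 1, 0, 1, 0, 1, -1, -1)[seq_len(n_sinus)],
                    cy + c(0, 0, 1, 1, -1, -1, 0, 1)[seq_len(n_sinus)])
  sinus <- sinus_rc[, 1] + (sinus_rc[, 2] - 1) * grid[1]
  roi <- matrix(FALSE, grid[1], grid[2])
  roi[(cx - 2):(cx + 3), (cy - 2):(cy + 3)] <- TRUE

  blood <- matrix(0, grid[1], grid[2])
  static <- matrix(static_value, grid[1], grid[2])
  volumes <- lapply(etes, function(ete) {
    b <- blood; b[sinus] <- s0 * exp(-ete / t2)
    lapply(seq_len(n_pairs), function(p) {
      lab <- static
      ctl <- static + b
      if (noise_sd > 0) {
        lab <- lab + matrix(stats::rnorm(length(lab), 0, noise_sd), grid[1])
        ctl <- ctl + matrix(stats::rnorm(length(ctl), 0, noise_sd), grid[1])
      }
      list(label = lab, control = ctl)
    })
  })
  list(volumes = volumes, etes = etes, roi = roi, sinus = sort(sinus),
       truth = list(yv_true = yv_true, hct = hct, t2 = t2, s0 = s0,
                    noise_sd = noise_sd))
}
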