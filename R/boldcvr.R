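#' Preprocess a BOLD study
#'
#' Spatial smoothing with a normalized separable Gaussian kernel and
#' intensity-threshold brain masking (voxels whose temporal-mean signal
#' exceeds `mask_frac` of the robust maximum, the 98th percentile).  Motion
#' correction is an identity hook: generated series are motion-free, and
#' realigned real data should be supplied already corrected.
#'
#' @param study A [bold_study()].
#' @param fwhm Smoothing kernel full width at half maximum, mm (0 = none).
#' @param mask_frac Masking threshold as a fraction of the robust maximum.
#' @return The preprocessed [bold_study()].
#' @export
preprocess_bold <- function(study, fwhm = 0, mask_frac = 0.5) {
  stopifnot(fwhm >= 0)
  data <- study$data
  if (fwhm > 0) {
    sd_vox <- fwhm / (2 * sqrt(2 * log(2))) / study$voxdim
    for (t in seq_len(dim(data)[4]))
      data[, , , t] <- gaussian_smooth_3d(data[, , , t, drop = FALSE][, , , 1],
                                          sd_vox)
  }
  mvol <- array(rowMeans(matrix(data, prod(dim(data)[1:3]), dim(data)[4])),
                dim(data)[1:3])
  thr <- mask_frac * stats::quantile(mvol, 0.98)
  mask <- study$mask & (mvol > thr)
  if (!any(mask)) stop("empty brain mask after intensity thresholding", call. = FALSE)
  out <- bold_study(data, tr = study$tr, mask = mask, protocol = study$protocol,
                    voxdim = study$voxdim)
  attr(out, "truth") <- attr(study, "truth")
  out
}

# Separable 3D Gaussian smoothing; per-axis kernels are normalized to unit
# sum, so the total image mass is conserved when the support stays inside
# the volume (zero padding at the edges).
gaussian_smooth_3d <- function(vol, sd_vox) {
  smooth_axis <- function(v, sd, axis) {
    if (sd <= 0) return(v)
    r <- max(1L, ceiling(4 * sd))
    k <- stats::dnorm(-r:r, sd = sd)
    k <- k / sum(k)
    n <- dim(v)[axis]
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(v, perm), nrow = n)
    K <- matrix(0, n, n)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- seq_len(n)
      src <- idx + off
      ok <- src >= 1 & src <= n
      K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[j]
    }
    K <- K / rowSums(K)   # renormalize truncated edge rows
    out <- K %*% m
    aperm(array(out, dim(v)[perm]), order(perm))
  }
  for (a in 1:3) vol <- smooth_axis(vol, sd_vox[a], a)
  vol
}

#' Global (mask-mean) BOLD time course
#' @param study A [bold_study()].
#' @return Numeric vector, one value per dynamic.
#' @export
global_signal <- function(study) {
  m <- matrix(study$data, prod(dim(study$data)[1:3]), dim(study$data)[4])
  colMeans(m[as.vector(study$mask), , drop = FALSE])
}

#' Align an EtCO2 curve with the global BOLD signal
#'
#' Searches a discrete grid of time shifts and returns the curve shifted by
#' the value maximizing the Pearson correlation between the shifted,
#' resampled EtCO2 and the global (mask-mean) BOLD time course.  A linear
#' trend is removed from both signals before correlation: the GLM models
#' drift separately, and symmetric detrending keeps the zero-shift
#' correlation exact on trend-free data.  Ties break toward the smallest
#' |shift|.
#' One global shift is estimated per scan (no voxelwise delays).
#'
#' @param study A [bold_study()].
#' @param curve An [etco2_curve()].
#' @param search Shift search range `(min, max)` in seconds.
#' @param step Search grid step, seconds.
#' @param min_corr Correlation floor below which alignment is considered
#'   undefined.
#' @param on_fail `"error"` (default) or `"zero"`: behavior when the best
#'   correlation falls below `min_corr` (`"zero"` warns and returns the
#'   unshifted curve).
#' @return The aligned curve, resampled on the scan grid, with attribute
#'   `alignment` holding the shift grid and correlations.
#' @export
align_etco2 <- function(study, curve, search = c(-30, 30), step = 0.1,
                        min_corr = 0.2, on_fail = c("error", "zero")) {
  on_fail <- match.arg(on_fail)
  stopifnot(search[2] > search[1], step > 0)
  g <- global_signal(study)
  if (stats::sd(g) == 0)
    stop("global BOLD signal is constant: alignment undefined", call. = FALSE)
  times <- bold_times(study)
  # remove the linear trend from both sides so the comparison is symmetric
  Xt <- cbind(1, times)
  detrend <- function(v) v - Xt %*% solve(crossprod(Xt), crossprod(Xt, v))
  g <- detrend(g)
  shifts <- seq(search[1], search[2], by = step)
  cors <- vapply(shifts, function(s) {
    e <- stats::approx(curve$breath_times, curve$breath_etco2,
                       xout = times - s, rule = 2)$y
    if (stats::sd(e) == 0) return(NA_real_)
    stats::cor(detrend(e), g)
  }, numeric(1))
  if (all(is.na(cors)))
    stop("EtCO2 curve constant over every tested shift: alignment undefined",
         call. = FALSE)
  best <- max(cors, na.rm = TRUE)
  if (best < min_corr) {
    msg <- sprintf("best EtCO2/BOLD correlation %.2f below floor %.2f", best, min_corr)
    if (on_fail == "error") stop(msg, call. = FALSE)
    warning(msg, "; using shift 0", call. = FALSE)
    s_star <- 0
  } else {
    cand <- which(!is.na(cors) & cors >= best - 1e-12)
    s_star <- shifts[cand[which.min(abs(shifts[cand]))]]
  }
  out <- resample_etco2(curve, times, shift_s = s_star)
  attr(out, "alignment") <- list(shifts = shifts, correlations = cors,
                                 best_corr = best)
  out
}

#' Voxelwise GLM of the BOLD series on the shifted EtCO2 regressor
#'
#' Ordinary least squares per voxel on the design
#' `[1, zero-mean shifted EtCO2, l]`, where `l` is the unit-step linear
#' trend centred on zero (`-(N-1)/2, ..., (N-1)/2`).  Returns the intercept
#' `beta0` (signal units), the EtCO2 coefficient `beta1` (signal units per
#' mmHg), the drift coefficient `beta2` (signal units per dynamic) and the
#' residual SD, each as a 3D array.
#'
#' @param study A [bold_study()].
#' @param curve An aligned [etco2_curve()] resampled on the scan grid (see
#'   [align_etco2()]).
#' @return A `glm_fit` list with arrays `beta0`, `beta1`, `beta2`,
#'   `residual_sd`, the `mask`, and the curve used.
#' @export
fit_glm <- function(study, curve) {
  nt <- dim(study$data)[4]
  e <- curve$resampled_etco2
  if (is.null(e) || length(e) != nt)
    stop("EtCO2 curve must be resampled onto the scan grid", call. = FALSE)
  if (stats::sd(e) == 0)
    stop("constant EtCO2 regressor: design is rank deficient", call. = FALSE)
  l <- seq_len(nt) - (nt + 1) / 2
  X <- cbind(1, e - mean(e), l)
  M <- matrix(study$data, prod(dim(study$data)[1:3]), nt)     # nvox x nt
  # normal equations: X is 3-column and well conditioned (centred regressors)
  XtX <- crossprod(X)
  B <- solve(XtX, t(M %*% X))                                 # 3 x nvox
  # RSS = sum(y^2) - b' X'X b, avoiding an nt x nvox residual matrix
  rss <- pmax(0, rowSums(M * M) - colSums(B * (XtX %*% B)))
  rsd <- sqrt(rss / (nt - ncol(X)))
  d3 <- dim(study$data)[1:3]
  structure(
    list(beta0 = array(B[1, ], d3), beta1 = array(B[2, ], d3),
         beta2 = array(B[3, ], d3), residual_sd = array(rsd, d3),
         mask = study$mask, curve = curve),
    class = "glm_fit"
  )
}

#' Room-air-referenced BOLD-CVR map
#'
#' `CVR = beta1 / (beta0 - beta1 * (mean_etco2 - baseline_etco2)) * 100`
#' in %/mmHg, referencing the percent signal change to the room-air state
#' (the bottom-25% EtCO2 baseline) rather than to the scan mean.  Voxels
#' with a non-positive denominator are flagged invalid (NA) and excluded
#' from ROI summaries rather than clipped.
#'
#' @param fit A [fit_glm()] result.
#' @param summary EtCO2 summary of the aligned curve (see
#'   [summarize_etco2()]); defaults to summarizing `fit$curve`.
#' @return A `cvr_map` list with the CVR array (`cvr`), validity mask,
#'   global `shift_s`, and the EtCO2 `summary` used.
#' @export
compute_cvr_map <- function(fit, summary = summarize_etco2(fit$curve)) {
  denom <- fit$beta0 - fit$beta1 * (summary$mean_etco2 - summary$baseline_etco2)
  valid <- fit$mask & denom > 0
  cvr <- fit$beta1 / denom * 100
  cvr[!valid] <- NA_real_
  n_bad <- sum(fit$mask & !valid)
  if (n_bad > 0)
    warning(sprintf("%d voxel(s) with non-positive CVR denominator excluded", n_bad),
            call. = FALSE)
  structure(
    list(cvr = cvr, valid = valid, shift_s = fit$curve$shift_s,
         summary = summary),
    class = "cvr_map"
  )
}

#' Adjust BOLD-CVR for baseline and delta EtCO2
#'
#' Multiplicative linear adjustment normalizing CVR to reference baseline
#' EtCO2 and EtCO2 change:
#' `cvr_adj = cvr * (1 + coef_b/100 * (b_etco2 - ref_b))
#'              * (1 + coef_d/100 * (d_etco2 - ref_d))`.
#' Default slopes: CVR varies by ~2% per mmHg of baseline EtCO2 and ~4% per
#' mmHg of EtCO2 change; default reference baseline 38.1 mmHg (population
#' mean), reference change 8 mmHg (typical 5% CO2 challenge).
#'
#' @param cvr CVR value(s), %/mmHg.
#' @param b_etco2 Subject baseline EtCO2, mmHg.
#' @param d_etco2 Subject EtCO2 change, mmHg.
#' @param ref_b,ref_d Reference baseline / change, mmHg.
#' @param coef_b,coef_d Adjustment slopes, % per mmHg.
#' @return Adjusted CVR, same shape as `cvr`.
#' @export
adjust_cvr <- function(cvr, b_etco2, d_etco2, ref_b = 38.1, ref_d = 8,
                       coef_b = 2, coef_d = 4) {
  stopifnot(is.finite(coef_b), is.finite(coef_d))
  f <- (1 + coef_b / 100 * (b_etco2 - ref_b)) *
       (1 + coef_d / 100 * (d_etco2 - ref_d))
  if (any(f <= 0))
    stop("adjustment factor is non-positive", call. = FALSE)
  cvr * f
}

#' ROI means of a CVR map
#'
#' Mean CVR over valid voxels for each named ROI mask.  ROIs without any
#' valid voxel are omitted with a warning.
#'
#' @param map A [compute_cvr_map()] result.
#' @param rois Named list of logical 3D masks on the map grid.
#' @return Named numeric vector of ROI mean CVR, %/mmHg.
#' @export
roi_summary <- function(map, rois) {
  stopifnot(length(rois) > 0, !is.null(names(rois)))
  out <- numeric(0)
  for (nm in names(rois)) {
    m <- rois[[nm]]
    stopifnot(all(dim(m) == dim(map$cvr)))
    sel <- m & map$valid
    if (!any(sel)) {
      warning(sprintf("ROI '%s' has no valid voxels; omitted", nm), call. = FALSE)
      next
    }
    out[nm] <- mean(map$cvr[sel])
  }
  out
}
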