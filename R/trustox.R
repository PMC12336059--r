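#' Blood T2 / venous oxygenation calibration model
#'
#' Strictly monotone mapping between venous blood T2 and oxygen saturation
#' at fixed hematocrit, of the quadratic-relaxivity form
#' `R2(Yv, Hct) = a(Hct) + b(Hct) * (1 - Yv) + c(Hct) * (1 - Yv)^2` (R2 in
#' 1/s, T2 = 1000 / R2 in ms), with each coefficient linear in Hct:
#' `a = a1 + a2 * Hct`, etc.  Coefficients are supplied via a YAML file;
#' the file shipped with the package
#' (`trust_calibration_synthetic.yaml`) contains synthetic default
#' coefficients chosen to give physiologically plausible venous T2 values
#' -- they are a documented stand-in, not published calibration constants,
#' and every pipeline test relies only on round-trip consistency of the
#' model, never on specific coefficient values.
#'
#' @param path YAML file with fields `a1, a2, b1, b2, c1, c2` and optional
#'   `yv_min`, `yv_max` domain bounds.  Default: the synthetic file shipped
#'   in `inst/extdata`.
#' @return A `trust_calibration` object.
#' @export
trust_calibration <- function(path = system.file("extdata",
                                                 "trust_calibration_synthetic.yaml",
                                                 package = "cvrquant")) {
  cfg <- yaml::read_yaml(path)
  need <- c("a1", "a2", "b1", "b2", "c1", "c2")
  if (!all(need %in% names(cfg)))
    stop("calibration file must define ", paste(need, collapse = ", "),
         call. = FALSE)
  cal <- structure(
    list(a1 = cfg$a1, a2 = cfg$a2, b1 = cfg$b1, b2 = cfg$b2,
         c1 = cfg$c1, c2 = cfg$c2,
         yv_min = if (is.null(cfg$yv_min)) 0.05 else cfg$yv_min,
         yv_max = if (is.null(cfg$yv_max)) 0.98 else cfg$yv_max),
    class = "trust_calibration"
  )
  # monotonicity in Yv requires positive relaxivity terms at working Hct
  for (h in c(0.3, 0.55)) {
    if (with(cal, b1 + b2 * h) <= 0 || with(cal, c1 + c2 * h) < 0)
      stop("calibration coefficients do not give a monotone T2(Yv) mapping",
           call. = FALSE)
  }
  cal
}

cal_coefs <- function(calib, hct) {
  list(a = calib$a1 + calib$a2 * hct,
       b = calib$b1 + calib$b2 * hct,
       c = calib$c1 + calib$c2 * hct)
}

#' Forward calibration: venous oxygenation to blood T2
#'
#' @param calib A [trust_calibration()].
#' @param yv Venous oxygen saturation, fraction in the calibration domain.
#' @param hct Hematocrit, fraction.
#' @return Blood T2 in ms.
#' @export
calib_t2 <- function(calib, yv, hct) {
  if (any(yv < calib$yv_min | yv > calib$yv_max))
    stop(sprintf("Yv outside calibration domain [%.2f, %.2f]",
                 calib$yv_min, calib$yv_max), call. = FALSE)
  k <- cal_coefs(calib, hct)
  x <- 1 - yv
  1000 / (k$a + k$b * x + k$c * x^2)
}

#' Inverse calibration: blood T2 to venous oxygenation
#'
#' Solves the quadratic relaxivity model for `1 - Yv`, taking the branch on
#' which T2 is monotone increasing in Yv.
#'
#' @param calib A [trust_calibration()].
#' @param t2 Blood T2 in ms.
#' @param hct Hematocrit, fraction.
#' @return Venous oxygenation, fraction.
#' @export
calib_yv <- function(calib, t2, hct) {
  lo <- calib_t2(calib, calib$yv_min, hct)
  hi <- calib_t2(calib, calib$yv_max, hct)
  if (any(t2 < lo | t2 > hi))
    stop(sprintf("T2 %.1f ms outside calibration domain [%.1f, %.1f] ms",
                 t2[1], lo, hi), call. = FALSE)
  k <- cal_coefs(calib, hct)
  r2 <- 1000 / t2
  x <- if (k$c > 0) {
    (-k$b + sqrt(k$b^2 - 4 * k$c * (k$a - r2))) / (2 * k$c)
  } else {
    (r2 - k$a) / k$b
  }
  1 - x
}

#' Hematocrit from participant sex
#'
#' Literature-standard assumed values: 0.40 for females, 0.42 for males.
#'
#' @param sex Character vector, `"F"` or `"M"`.
#' @return Hematocrit fraction(s).
#' @export
hct_from_sex <- function(sex) {
  if (!all(sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'", call. = FALSE)
  ifelse(sex == "F", 0.40, 0.42)
}

#' Pairwise label/control subtraction of a TRUST series
#'
#' For each effective TE, averages `control - label` over the acquired
#' pairs; static tissue is identical within a pair and cancels, leaving the
#' pure venous blood signal.
#'
#' @param series A [generate_trust_series()] result or any list with
#'   `volumes[[i]]` = list of `list(label, control)` pairs and `etes`.
#' @return List of difference images, one per eTE (named by eTE).
#' @export
subtract_pairs <- function(series) {
  out <- lapply(seq_along(series$etes), function(i) {
    pairs <- series$volumes[[i]]
    if (!length(pairs)) stop("no label/control pairs at eTE ", series$etes[i],
                             call. = FALSE)
    for (p in pairs)
      if (is.null(p$label) || is.null(p$control) ||
          !all(dim(p$label) == dim(p$control)))
        stop("unpaired or mismatched label/control volumes", call. = FALSE)
    Reduce(`+`, lapply(pairs, function(p) p$control - p$label)) / length(pairs)
  })
  names(out) <- as.character(series$etes)
  out
}

#' Select the brightest voxels of the venous difference image
#'
#' The k highest-intensity voxels within the ROI of the difference image at
#' the shortest eTE; ties break deterministically toward the lower linear
#' voxel index.
#'
#' @param diff0 Difference image at the shortest eTE.
#' @param roi Logical mask around the sinus.
#' @param k Number of voxels (default 4).
#' @return Integer vector of linear voxel indices, sorted.
#' @export
select_voxels <- function(diff0, roi, k = 4) {
  stopifnot(all(dim(roi) == dim(diff0)))
  idx <- which(roi)
  if (length(idx) < k)
    stop(sprintf("ROI has %d voxels, fewer than k = %d", length(idx), k),
         call. = FALSE)
  ord <- idx[order(-diff0[idx], idx)]
  sort(ord[seq_len(k)])
}

#' Mono-exponential T2 fit across effective TEs
#'
#' Nonlinear least squares of `S(eTE) = S0 * exp(-eTE / T2)`, initialized
#' from the log-linear regression of `log(S)` on eTE (falling back to a
#' configurable T2 start when non-positive signals preclude the log fit).
#'
#' @param signals Mean difference signal per eTE.
#' @param etes Effective TEs in ms, strictly increasing, length >= 3.
#' @param t2_start Fallback initial T2 in ms.
#' @return A `t2_fit` list with `t2` (ms), `s0`, `rss`.
#' @export
fit_t2 <- function(signals, etes, t2_start = 60) {
  if (length(signals) != length(etes) || length(etes) < 3)
    stop("need signals at >= 3 effective TEs", call. = FALSE)
  if (is.unsorted(etes, strictly = TRUE) || any(etes < 0))
    stop("etes must be non-negative and strictly increasing", call. = FALSE)
  if (all(signals > 0)) {
    lf <- stats::lm(log(signals) ~ etes)
    t2_0 <- unname(-1 / stats::coef(lf)[2])
    s0_0 <- unname(exp(stats::coef(lf)[1]))
    if (!is.finite(t2_0) || t2_0 <= 0) t2_0 <- t2_start
  } else {
    t2_0 <- t2_start
    s0_0 <- max(signals[1], 1e-6)
  }
  fit <- minpack.lm::nlsLM(
    signals ~ s0 * exp(-etes / t2),
    start = list(s0 = s0_0, t2 = t2_0),
    lower = c(1e-9, 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  structure(list(t2 = unname(co["t2"]), s0 = unname(co["s0"]),
                 rss = sum(stats::residuals(fit)^2)),
            class = "t2_fit")
}

#' Convert a fitted blood T2 to venous oxygenation
#'
#' @param t2 Blood T2 in ms.
#' @param hct Hematocrit fraction.
#' @param calib A [trust_calibration()].
#' @return List with `yv` (fraction), `hct`, `t2`.
#' @export
t2_to_yv <- function(t2, hct, calib = trust_calibration()) {
  yv <- calib_yv(calib, t2, hct)
  list(yv = yv, hct = hct, t2 = t2)
}

#' Full TRUST processing chain
#'
#' Pairwise subtraction, top-k voxel selection on the shortest-eTE
#' difference image, spatial averaging, mono-exponential T2 fit and
#' calibration to venous oxygenation.
#'
#' @param series A TRUST series (see [generate_trust_series()]).
#' @param hct Hematocrit fraction (see [hct_from_sex()]).
#' @param calib A [trust_calibration()].
#' @param k Number of voxels to average (default 4).
#' @return List with `yv`, `t2`, `s0`, `hct`, `signals`, `voxels`.
#' @export
run_trust <- function(series, hct, calib = trust_calibration(), k = 4) {
  diffs <- subtract_pairs(series)
  vox <- select_voxels(diffs[[1]], series$roi, k = k)
  sig <- vapply(diffs, function(d) mean(d[vox]), numeric(1))
  fit <- fit_t2(unname(sig), series$etes)
  ox <- t2_to_yv(fit$t2, hct, calib)
  list(yv = ox$yv, t2 = fit$t2, s0 = fit$s0, hct = hct,
       signals = unname(sig), voxels = vox)
}
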