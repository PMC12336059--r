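#' End-tidal CO2 curve
#'
#' Holds the breath-wise end-tidal values (one per detected breath) and
#' their resampling onto a uniform analysis grid, together with any time
#' shift applied during alignment with the BOLD signal.
#'
#' @param breath_times Times of the breath peaks, seconds.
#' @param breath_etco2 End-tidal CO2 per breath, mmHg.
#' @param resampled_times Uniform grid times, seconds (may be `NULL` until
#'   resampling is requested).
#' @param resampled_etco2 EtCO2 linearly interpolated onto the grid,
#'   constant-extrapolated at the edges.
#' @param shift_s Time shift applied to the curve, seconds (0 until aligned).
#' @return An `etco2_curve` object.
#' @export
etco2_curve <- function(breath_times, breath_etco2,
                        resampled_times = NULL, resampled_etco2 = NULL,
                        shift_s = 0) {
  stopifnot(length(breath_times) == length(breath_etco2))
  if (is.unsorted(breath_times, strictly = TRUE))
    stop("breath_times must be strictly increasing", call. = FALSE)
  structure(
    list(breath_times = breath_times, breath_etco2 = breath_etco2,
         resampled_times = resampled_times, resampled_etco2 = resampled_etco2,
         shift_s = shift_s),
    class = "etco2_curve"
  )
}

#' @export
print.etco2_curve <- function(x, ...) {
  cat("EtCO2 curve:", length(x$breath_times), "breaths,",
      sprintf("%.1f-%.1f mmHg", min(x$breath_etco2), max(x$breath_etco2)),
      if (!is.null(x$resampled_times))
        sprintf("; resampled to %d points", length(x$resampled_times)),
      if (x$shift_s != 0) sprintf("; shifted %+.2f s", x$shift_s), "\n")
  invisible(x)
}

# Local maxima with topographic prominence.  Returns indices of samples that
# are strict local maxima, have prominence >= min_prominence, and survive a
# greedy minimum-separation pass (taller peaks win).
find_peaks <- function(x, min_distance, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  k <- length(cand)
  # minima of the segments delimited by the candidate peaks (incl. both ends)
  bounds <- c(1L, cand, n)
  segmin <- vapply(seq_len(k + 1), function(j)
    min(x[bounds[j]:bounds[j + 1]]), numeric(1))
  # prominence: drop to the lowest point before higher terrain on each side;
  # higher terrain on a side implies a higher candidate peak on that side
  prom <- vapply(seq_len(k), function(i) {
    h <- x[cand[i]]
    base_l <- segmin[i]
    j <- i - 1L
    while (j >= 1 && x[cand[j]] <= h) { base_l <- min(base_l, segmin[j]); j <- j - 1L }
    base_r <- segmin[i + 1]
    j <- i + 1L
    while (j <= k && x[cand[j]] <= h) { base_r <- min(base_r, segmin[j + 1]); j <- j + 1L }
    h - max(base_l, base_r)
  }, numeric(1))
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  # greedy separation: accept in order of descending height
  keep <- logical(length(cand))
  for (j in order(x[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[j]) < min_distance)) keep[j] <- TRUE
  }
  sort(cand[keep])
}

#' Detect the end-tidal envelope of a capnograph trace
#'
#' Identifies one end-tidal value per breath as a prominence-filtered local
#' maximum of the CO2 waveform, with breaths separated by at least
#' `min_breath_interval`.  The breath-wise values are linearly interpolated
#' onto a uniform grid (one point per TR when `tr`/`n_dynamics` are given)
#' and constant-extrapolated before the first and after the last breath.
#'
#' @param trace A [capno_trace()].
#' @param min_breath_interval Minimum separation of breath peaks, seconds.
#' @param min_prominence Minimum peak prominence in mmHg (rejects ripple).
#' @param tr,n_dynamics Optional TR grid for resampling; when `NULL` the
#'   curve is resampled at 1 Hz over the trace support.
#' @return An [etco2_curve()].
#' @export
detect_envelope <- function(trace, min_breath_interval = 2,
                            min_prominence = 1,
                            tr = NULL, n_dynamics = NULL) {
  rate <- capno_rate(trace)
  idx <- find_peaks(trace$pco2,
                    min_distance = max(1, round(min_breath_interval * rate)),
                    min_prominence = min_prominence)
  if (length(idx) < 3)
    stop("fewer than 3 breaths detected: capnograph signal quality insufficient",
         call. = FALSE)
  bt <- trace$time[idx]
  be <- trace$pco2[idx]
  if (!is.null(tr) && !is.null(n_dynamics)) {
    grid <- (seq_len(n_dynamics) - 1) * tr
  } else {
    grid <- seq(floor(min(trace$time)), ceiling(max(trace$time)), by = 1)
  }
  res <- stats::approx(bt, be, xout = grid, rule = 2)$y
  etco2_curve(bt, be, resampled_times = grid, resampled_etco2 = res)
}

#' Resample an EtCO2 curve onto a scan grid, optionally time-shifted
#'
#' Evaluates the breath-wise envelope at `times - shift_s` by linear
#' interpolation with constant extrapolation, so a positive shift moves the
#' curve later in time (toward the lagging BOLD response).
#'
#' @param curve An [etco2_curve()].
#' @param times Target grid, seconds.
#' @param shift_s Shift in seconds.
#' @return The curve with `resampled_*` fields replaced and `shift_s` set.
#' @export
resample_etco2 <- function(curve, times, shift_s = curve$shift_s) {
  res <- stats::approx(curve$breath_times, curve$breath_etco2,
                       xout = times - shift_s, rule = 2)$y
  etco2_curve(curve$breath_times, curve$breath_etco2,
              resampled_times = times, resampled_etco2 = res,
              shift_s = shift_s)
}

#' Scalar EtCO2 summaries of a curve
#'
#' `mean_etco2` is the arithmetic mean of the resampled values;
#' `baseline_etco2` is the mean of the lowest 25% of the resampled values
#' (duration-weighted, since resampling is uniform in time).  Without a
#' protocol, `delta_etco2 = mean - baseline` (the quantity entering the
#' room-air-referenced CVR map); with a protocol, `delta_etco2` is the
#' hypercapnic-plateau minus room-air block mean.
#'
#' @param curve An [etco2_curve()] with resampled values.
#' @param protocol Optional [protocol()] supplying the block schedule.
#' @return List with `mean_etco2`, `baseline_etco2`, `delta_etco2` (mmHg).
#' @export
summarize_etco2 <- function(curve, protocol = NULL) {
  v <- curve$resampled_etco2
  if (is.null(v) || !length(v)) stop("curve has no resampled values", call. = FALSE)
  m <- mean(v)
  k <- max(1L, ceiling(length(v) * 0.25))
  baseline <- mean(sort(v)[seq_len(k)])
  if (is.null(protocol)) {
    delta <- m - baseline
  } else {
    cond <- protocol_condition_at(protocol, curve$resampled_times)
    if (!any(cond == "hypercapnia"))
      delta <- 0
    else
      delta <- mean(v[cond == "hypercapnia"]) - mean(v[cond == "room_air"])
  }
  list(mean_etco2 = m, baseline_etco2 = baseline, delta_etco2 = delta)
}

#' Mean breath-wise EtCO2 inside an acquisition window
#'
#' Used to attach an EtCO2 value to each phase-contrast scan: the mean of
#' the end-tidal values of all breaths whose peaks fall inside the window.
#'
#' @param curve An [etco2_curve()].
#' @param window Numeric `(start, end)` in seconds.
#' @return Mean EtCO2 in mmHg.
#' @export
etco2_during_scan <- function(curve, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  sel <- curve$breath_times >= window[1] & curve$breath_times <= window[2]
  if (!any(sel))
    stop("no breaths inside the requested window", call. = FALSE)
  mean(curve$breath_etco2[sel])
}
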