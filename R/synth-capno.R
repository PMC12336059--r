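#' Simulate a raw capnograph trace for a gas protocol
#'
#' Renders a 20 Hz (configurable) CO2 partial-pressure waveform of
#' raised-cosine breaths.  Each breath's end-tidal peak equals the protocol
#' condition at the moment of the peak: `etco2_ra` during room air and
#' `etco2_hc` during hypercapnia, so the end-tidal envelope follows the
#' block schedule within one breath of each transition.  Only the per-breath
#' maxima matter downstream; the intra-breath shape is a convenience.
#'
#' @param protocol A [protocol()] object.
#' @param etco2_ra End-tidal CO2 during room air, mmHg.
#' @param etco2_hc End-tidal CO2 during hypercapnia, mmHg (ignored when the
#'   protocol has no hypercapnic block).
#' @param breath_period Breath duration in seconds (default 4 s, i.e. 15
#'   breaths/min).
#' @param trough Inter-breath trough value in mmHg.
#' @param noise_sd Gaussian noise added to every sample, mmHg (default 0).
#' @param seed Integer seed; the trace is deterministic given the seed.
#' @return A `capno_trace`: data.frame with columns `time` (s) and `pco2`
#'   (mmHg, floored at 0).
#' @export
generate_capno_trace <- function(protocol, etco2_ra, etco2_hc = etco2_ra,
                                 breath_period = 4, trough = 2,
                                 noise_sd = 0, seed = 1L) {
  if (breath_period <= 2 / protocol$capno_rate)
    stop("breath_period must exceed two capnograph samples", call. = FALSE)
  if (etco2_ra <= trough || etco2_hc <= trough)
    stop("end-tidal targets must exceed the trough value", call. = FALSE)
  total <- protocol_duration(protocol)
  if (total < breath_period)
    stop("protocol too short for a single breath", call. = FALSE)
  set.seed(seed)
  n <- floor(total * protocol$capno_rate)
  time <- (seq_len(n) - 1) / protocol$capno_rate

  n_breaths <- floor(total / breath_period)
  starts <- (seq_len(n_breaths) - 1) * breath_period
  peaks_t <- starts + breath_period / 2
  cond <- protocol_condition_at(protocol, peaks_t)
  peak_val <- ifelse(cond == "hypercapnia", etco2_hc, etco2_ra)

  # raised cosine within each breath: trough at breath edges, peak mid-breath
  breath_idx <- pmin(floor(time / breath_period) + 1L, n_breaths)
  phase <- (time - starts[breath_idx]) / breath_period
  pco2 <- trough + (peak_val[breath_idx] - trough) *
    0.5 * (1 - cos(2 * pi * phase))
  if (noise_sd > 0) pco2 <- pco2 + stats::rnorm(n, 0, noise_sd)
  capno_trace(time, pmax(pco2, 0))
}

#' Construct a capnograph trace object
#'
#' @param time Sample times in seconds; must be uniform within 1%.
#' @param pco2 CO2 partial pressure in mmHg, non-negative.
#' @return A `capno_trace` data.frame.
#' @export
capno_trace <- function(time, pco2) {
  stopifnot(length(time) == length(pco2), length(time) >= 2)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if ((max(dt) - min(dt)) > 0.01 * mean(dt))
    stop("capnograph sampling must be uniform within 1%", call. = FALSE)
  if (any(pco2 < 0)) stop("pco2 must be non-negative", call. = FALSE)
  structure(data.frame(time = time, pco2 = pco2),
            class = c("capno_trace", "data.frame"))
}

#' Sampling rate of a capnograph trace (Hz)
#' @param trace A `capno_trace`.
#' @return Numeric scalar, Hz.
#' @export
capno_rate <- function(trace) 1 / mean(diff(trace$time))

#' Write / read a capnograph trace as 2-column CSV
#'
#' Plain-text interchange format: columns `time_s`, `pco2_mmhg`.
#'
#' @param trace A `capno_trace`.
#' @param path Output CSV path.
#' @return `write_capno`: the path, invisibly. `read_capno`: a `capno_trace`.
#' @export
write_capno <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time, pco2_mmhg = trace$pco2),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_capno
#' @export
read_capno <- function(path) {
  df <- utils::read.csv(path)
  capno_trace(df$time_s, df$pco2_mmhg)
}
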