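#' Gas-challenge protocol description
#'
#' A protocol is an ordered block schedule of breathing conditions
#' (`room_air` / `hypercapnia`) together with the MR acquisition grid it
#' accompanies: repetition time, number of dynamics and the capnograph
#' sampling rate.
#'
#' @param blocks data.frame with columns `condition` (character,
#'   `"room_air"` or `"hypercapnia"`) and `duration` (seconds).
#' @param tr Repetition time in seconds.
#' @param n_dynamics Number of acquired dynamics (time points).
#' @param capno_rate Capnograph sampling rate in Hz.
#' @return An object of class `cvr_protocol`.
#' @export
protocol <- function(blocks, tr, n_dynamics, capno_rate = 20) {
  stopifnot(is.data.frame(blocks), all(c("condition", "duration") %in% names(blocks)))
  if (!all(blocks$condition %in% c("room_air", "hypercapnia")))
    stop("unknown condition in block schedule", call. = FALSE)
  if (any(blocks$duration <= 0))
    stop("block durations must be positive", call. = FALSE)
  if (tr <= 0 || n_dynamics < 1 || capno_rate <= 0)
    stop("tr, n_dynamics and capno_rate must be positive", call. = FALSE)
  if (sum(blocks$duration) < tr * n_dynamics)
    stop("block schedule shorter than the scan (sum(duration) < tr * n_dynamics)",
         call. = FALSE)
  structure(
    list(blocks = blocks, tr = tr, n_dynamics = n_dynamics,
         capno_rate = capno_rate),
    class = "cvr_protocol"
  )
}

#' @export
print.cvr_protocol <- function(x, ...) {
  cat("CVR protocol:", nrow(x$blocks), "blocks,",
      sum(x$blocks$duration), "s total; TR", x$tr, "s x",
      x$n_dynamics, "dynamics; capnograph", x$capno_rate, "Hz\n")
  invisible(x)
}

#' Total duration of a protocol in seconds
#' @param p A `cvr_protocol`.
#' @return Numeric scalar, seconds.
#' @export
protocol_duration <- function(p) sum(p$blocks$duration)

#' Condition at a given time
#'
#' @param p A `cvr_protocol`.
#' @param t Numeric vector of times in seconds (0 = scan start).
#' @return Character vector of conditions; times beyond the schedule carry
#'   the last block's condition.
#' @export
protocol_condition_at <- function(p, t) {
  edges <- cumsum(p$blocks$duration)
  idx <- findInterval(t, c(0, edges), rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  idx[idx > nrow(p$blocks)] <- nrow(p$blocks)
  p$blocks$condition[idx]
}

#' Block-design BOLD-CVR protocol
#'
#' The default BOLD acquisition: 15 s of room air, then two 55 s hypercapnic
#' phases interleaved with 75 s room-air phases, with the final room-air
#' phase extended to the end of the 300 s scan (TR 1.5 s, 200 dynamics).
#'
#' @param tr Repetition time in seconds.
#' @param n_dynamics Number of dynamics.
#' @return A `cvr_protocol`.
#' @export
bold_protocol <- function(tr = 1.5, n_dynamics = 200) {
  total <- tr * n_dynamics
  lead <- 15 + 55 + 75 + 55
  blocks <- data.frame(
    condition = c("room_air", "hypercapnia", "room_air", "hypercapnia", "room_air"),
    duration  = c(15, 55, 75, 55, max(75, total - lead))
  )
  protocol(blocks, tr = tr, n_dynamics = n_dynamics)
}

#' Phase-contrast CVR protocol
#'
#' Three consecutive 1-minute phase-contrast scans: the first during room
#' air, the second and third after the switch to hypercapnic gas.  CVR uses
#' scans 1 and 3; scan 2 falls in the physiological transient and is
#' excluded.
#'
#' @param scan_duration Duration of each PC scan in seconds.
#' @return A `cvr_protocol` whose attribute `scan_windows` holds the three
#'   (start, end) acquisition windows in seconds.
#' @export
pc_protocol <- function(scan_duration = 60) {
  blocks <- data.frame(
    condition = c("room_air", "hypercapnia"),
    duration  = c(scan_duration, 2 * scan_duration)
  )
  p <- protocol(blocks, tr = scan_duration, n_dynamics = 3)
  attr(p, "scan_windows") <- lapply(0:2, function(i)
    c(i * scan_duration, (i + 1) * scan_duration))
  p
}
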