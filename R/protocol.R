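#' Force protocols
#'
#' A force protocol is an ordered sequence of segments, each a constant-force
#' hold or a linear ramp. `protocol_hold()`, `protocol_ramp()` and
#' `protocol_jump()` build single segments (a jump is a fast ramp, >= 50
#' pN/s, reaching its target within 0.1 s, emulating maximum-speed magnet
#' motion); `force_protocol()` concatenates them. Forces must stay within
#' 0-20 pN.
#'
#' @param force,from,to Forces in pN.
#' @param duration Segment duration in s.
#' @param rate Loading rate in pN/s (sign inferred from `from`/`to`).
#' @param ... Segments (tibbles from the single-segment constructors) or
#'   lists of segments.
#' @return A tibble of class `force_protocol` with columns `mode`,
#'   `start_force`, `end_force`, `rate`, `duration`.
#' @examples
#' fp <- force_protocol(protocol_hold(10, 0.5), protocol_jump(10, 14),
#'                      protocol_hold(14, 30))
#' protocol_force(fp, c(0, 0.55, 1))
#' @export
force_protocol <- function(...) {
  segs <- list(...)
  segs <- purrr::map(segs, function(s) if (is_tibble(s)) list(s) else s) |>
    purrr::list_flatten() |> list_rbind()
  if (nrow(segs) == 0) abort("empty protocol")
  if (any(c(segs$start_force, segs$end_force) < 0) ||
      any(c(segs$start_force, segs$end_force) > 20)) {
    abort("protocol forces must stay within [0, 20] pN")
  }
  class(segs) <- c("force_protocol", class(segs))
  segs
}

#' @rdname force_protocol
#' @export
protocol_hold <- function(force, duration) {
  tibble(mode = "hold", start_force = force, end_force = force,
         rate = 0, duration = duration)
}

#' @rdname force_protocol
#' @export
protocol_ramp <- function(from, to, rate = 1) {
  rate <- abs(rate) * sign(to - from)
  tibble(mode = "ramp", start_force = from, end_force = to,
         rate = rate, duration = abs(to - from) / abs(rate))
}

#' @rdname force_protocol
#' @export
protocol_jump <- function(from, to, rate = 100) {
  if (abs(rate) < 50) abort("force jumps use |rate| >= 50 pN/s")
  seg <- protocol_ramp(from, to, rate)
  if (seg$duration > 0.1) {
    abort("jump must reach its target within 0.1 s; increase the rate")
  }
  seg$mode <- "jump"
  seg
}

#' Evaluate a protocol's force at given times
#'
#' @param protocol A [force_protocol()].
#' @param time Times in s from the start of the protocol; vectorized.
#' @return Forces in pN (times beyond the protocol end hold the final force).
#' @export
protocol_force <- function(protocol, time) {
  ends <- cumsum(protocol$duration)
  starts <- c(0, ends[-length(ends)])
  idx <- pmin(findInterval(time, starts, left.open = FALSE), nrow(protocol))
  idx[idx < 1] <- 1
  within <- pmin(pmax(time - starts[idx], 0), protocol$duration[idx])
  protocol$start_force[idx] + protocol$rate[idx] * within
}

#' @rdname protocol_force
#' @export
protocol_duration <- function(protocol) sum(protocol$duration)
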