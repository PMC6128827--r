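#' Bell-equation rate parameters
#'
#' A single-barrier transition under force follows the Bell equation
#' `k(F) = k_w exp((-dG + F dx) / kBT)`, equivalently
#' `k(F) = k_ref exp((F - F_ref) dx / kBT)`. `bell_params()` uses the
#' reference-rate parameterization; `bell_from_barrier()` the barrier one
#' (barrier height `dG` in kBT via the attempt frequency `k_w`). The two
#' interconvert exactly.
#'
#' @param k_ref Rate at the reference force, s^-1 (> 0).
#' @param F_ref Reference force, pN.
#' @param delta_x Distance to the transition state along the pulling
#'   coordinate, nm; positive if force accelerates the transition.
#' @param dG Barrier height at zero force, kBT units.
#' @param k_w Attempt frequency, s^-1.
#' @param kBT Thermal energy, pN nm.
#' @return An object of class `bell_params`.
#' @examples
#' b <- bell_from_barrier(dG = 15, delta_x = 0, F_ref = 14)
#' rate_at_force(b, 14) # 1e6 * exp(-15)
#' @export
bell_params <- function(k_ref, F_ref = 14, delta_x = 0, kBT = kBT_pN_nm()) {
  stopifnot(k_ref > 0, is.finite(delta_x))
  structure(list(k_ref = k_ref, F_ref = F_ref, delta_x = delta_x, kBT = kBT),
            class = "bell_params")
}

#' @rdname bell_params
#' @export
bell_from_barrier <- function(dG, delta_x = 0, F_ref = 0, k_w = k_attempt(),
                              kBT = kBT_pN_nm()) {
  # dG is the barrier measured at F_ref (force-tilted), in kBT units.
  bell_params(k_ref = k_w * exp(-dG), F_ref = F_ref, delta_x = delta_x,
              kBT = kBT)
}

#' @export
print.bell_params <- function(x, ...) {
  cat(sprintf("<bell_params> k(%g pN) = %.4g /s, dx = %.3g nm\n",
              x$F_ref, x$k_ref, x$delta_x))
  invisible(x)
}

#' Force-dependent transition rate
#'
#' Evaluates the Bell equation `k(F) = k_ref exp((F - F_ref) dx / kBT)`;
#' vectorized over `force`.
#'
#' @param edge A [bell_params()].
#' @param force Force in pN (>= 0).
#' @return Rate in s^-1.
#' @export
rate_at_force <- function(edge, force) {
  stopifnot(inherits(edge, "bell_params"))
  if (any(force < 0)) abort("force must be >= 0")
  edge$k_ref * exp((force - edge$F_ref) * edge$delta_x / edge$kBT)
}

#' Force-tilted barrier height from a rate
#'
#' Converts a measured rate into the height of the single dominant energy
#' barrier at that force, `dG(F) = kBT ln(k_w / k)`, in kBT units, using the
#' diffusion-limited attempt frequency `k_w` (default 1e6 s^-1).
#'
#' @param rate Transition rate, s^-1; vectorized.
#' @param k_w Attempt frequency, s^-1.
#' @return Barrier height in kBT units.
#' @export
barrier_at_force <- function(rate, k_w = k_attempt()) {
  if (any(rate <= 0)) abort("rate must be > 0")
  if (any(rate > k_w)) {
    abort("rate > attempt frequency: no barrier (barrierless limit)")
  }
  log(k_w / rate)
}
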