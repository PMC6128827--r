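#' Kinetic schemes over conformational states
#'
#' A kinetic scheme is a set of named states connected by directed edges,
#' each carrying Bell-equation rate parameters. Schemes drive the kinetic
#' Monte Carlo simulator and serve as ground truth for the inference
#' pipeline.
#'
#' @param states Character vector of state names.
#' @param edges A data frame with columns `from`, `to`, `k_ref`, `F_ref`,
#'   `delta_x` (one Bell edge per row) and optionally `max_force` (pN): the
#'   edge is inactive above that force (e.g. SNAP-25 rebinding only under
#'   2 pN), making the destination effectively absorbing at high force.
#' @param kBT Thermal energy, pN nm.
#' @return An object of class `kinetic_scheme`.
#' @seealso [scheme_from_landscape()], [scheme_two_state()],
#'   [scheme_three_state()]
#' @export
kinetic_scheme <- function(states, edges, kBT = kBT_pN_nm()) {
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to", "k_ref", "F_ref", "delta_x") %in% names(edges)))
  if (!"max_force" %in% names(edges)) edges$max_force <- Inf
  bad <- setdiff(c(edges$from, edges$to), states)
  if (length(bad) > 0) {
    abort(paste0("edge endpoints not declared as states: ",
                 paste(bad, collapse = ", ")))
  }
  if (any(edges$k_ref < 0) || any(!is.finite(edges$k_ref))) {
    abort("edge rates must be non-negative and finite")
  }
  structure(list(states = states, edges = edges, kBT = kBT),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme> %d states: %s\n", length(x$states),
              paste(x$states, collapse = ", ")))
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat(sprintf("  %s -> %s : k(%g pN) = %.4g /s, dx = %+.2f nm\n",
                e$from, e$to, e$F_ref, e$k_ref, e$delta_x))
  }
  invisible(x)
}

#' All edge rates of a scheme at a force
#'
#' @param scheme A [kinetic_scheme()].
#' @param force Force in pN (scalar).
#' @return The scheme's edge table with an added `k` column (s^-1).
#' @export
scheme_rates <- function(scheme, force) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  ed <- scheme$edges
  ed$k <- ed$k_ref * exp((force - ed$F_ref) * ed$delta_x / scheme$kBT) *
    (force <= ed$max_force)
  ed
}

#' Build a kinetic scheme from an energy landscape
#'
#' Given zero-force free energies `G_i` (kBT) and extension coordinates
#' `x_i` (nm) for each state, plus one barrier (position `x_b` nm, height
#' `G_b` kBT at zero force) per connected pair, constructs Kramers/Bell rates
#' `k_ij(F) = k_w exp(-(G_b - G_i - F (x_b - x_i)) / kBT)`. Forward and
#' backward rates then satisfy detailed balance,
#' `k_ij / k_ji = exp(-(G_j - G_i - F (x_j - x_i)) / kBT)`, at every force.
#'
#' @param energies Named numeric: per-state free energy at the reference
#'   force `F_ref`, kBT.
#' @param positions Named numeric: per-state extension coordinate, nm.
#' @param barriers Data frame with columns `from`, `to`, `position`
#'   (nm), `height` (kBT at `F_ref`); each row generates both directed
#'   edges.
#' @param k_w Attempt frequency, s^-1.
#' @param kBT Thermal energy, pN nm.
#' @param F_ref Force at which energies and barrier heights are specified,
#'   pN. Barriers must lie above their flanking states at this force.
#' @return A [kinetic_scheme()].
#' @export
scheme_from_landscape <- function(energies, positions, barriers,
                                  k_w = k_attempt(), kBT = kBT_pN_nm(),
                                  F_ref = 0) {
  stopifnot(setequal(names(energies), names(positions)))
  barriers <- as_tibble(barriers)
  edges <- purrr::pmap(barriers, function(from, to, position, height, ...) {
    for (s in c(from, to)) {
      if (height < energies[[s]]) {
        abort(sprintf("barrier %s-%s (%.2f kBT) lies below state %s (%.2f kBT)",
                      from, to, height, s, energies[[s]]))
      }
    }
    ends <- c(from, to)
    tibble(from = ends, to = rev(ends),
           k_ref = unname(k_w * exp(-(height - energies[ends]))),
           F_ref = F_ref,
           delta_x = unname(position - positions[ends]))
  }) |> list_rbind()
  kinetic_scheme(names(energies), edges, kBT = kBT)
}

#' Boltzmann equilibrium populations of a scheme's landscape
#'
#' Occupancies `p_i(F)` proportional to `exp(-(G_i - F x_i)/kBT)` for a
#' state model given as zero-force energies (kBT) and positions (nm).
#'
#' @param energies,positions Named numerics as in [scheme_from_landscape()].
#' @param force Force in pN (scalar).
#' @param kBT Thermal energy, pN nm.
#' @return Named numeric of populations summing to 1.
#' @export
boltzmann_populations <- function(energies, positions, force,
                                  kBT = kBT_pN_nm()) {
  g <- energies - force * positions / kBT
  w <- exp(-(g - min(g)))
  w / sum(w)
}

#' Two-state unzipping/rezipping scheme
#'
#' The coarse-grained scheme behind force-ramp and force-jump experiments:
#' a zippered state (all conformations before the main unzipping) and an
#' unzipped state, connected by Bell edges. Defaults pin the no-Cpx
#' condition: unzipping barrier 15 kBT at 14 pN (k = 1e6 exp(-15) ~ 0.31
#' s^-1) with dx = +7 nm, rezipping barrier 16.5 kBT at 14 pN with dx = -5
#' nm (placing simulated rezip forces in the 8-12 pN signature window).
#' `condition = "cpx"` raises the unzipping barrier to 19 kBT (the 4.3 kBT
#' zippered-state stabilization) and uses dx = +5.5 nm, which also broadens
#' the simulated unzip-force distribution; rezipping is unchanged.
#'
#' @param condition `"none"` or `"cpx"`.
#' @param dG_unzip,dx_unzip,dG_rezip,dx_rezip Override barrier heights (kBT
#'   at `F_ref`) and transition-state distances (nm).
#' @param F_ref Reference force, pN.
#' @param k_w Attempt frequency, s^-1.
#' @param kBT Thermal energy, pN nm.
#' @return A [kinetic_scheme()] with states `zippered`, `unzipped`.
#' @export
scheme_two_state <- function(condition = c("none", "cpx"),
                             dG_unzip = NULL, dx_unzip = NULL,
                             dG_rezip = 16.5, dx_rezip = -5,
                             F_ref = 14, k_w = k_attempt(),
                             kBT = kBT_pN_nm()) {
  condition <- match.arg(condition)
  dG_unzip <- dG_unzip %||% if (condition == "none") 15 else 19
  dx_unzip <- dx_unzip %||% if (condition == "none") 7 else 5.5
  sch <- kinetic_scheme(
    states = c("zippered", "unzipped"),
    edges = tibble(
      from = c("zippered", "unzipped"),
      to = c("unzipped", "zippered"),
      k_ref = k_w * exp(-c(dG_unzip, dG_rezip)),
      F_ref = F_ref,
      delta_x = c(dx_unzip, dx_rezip)),
    kBT = kBT)
  attr(sch, "condition") <- condition
  sch
}

#' Full stretch-relax cycle scheme including SNAP-25 dissociation
#'
#' Extends [scheme_two_state()] with the SNAP-25 layer of the signature
#' cycle: above ~15 pN the unzipped construct loses SNAP-25 (a further ~5 nm
#' unfolding step), and with free SNAP-25 in the buffer the complex refolds
#' only under 2 pN (pseudo-first-order rebinding, default 1 s^-1, gated by
#' `max_force`). Used for simulating QC-complete force-ramp cycles.
#'
#' @inheritParams scheme_two_state
#' @param k_unfold16 SNAP-25 dissociation rate at 16 pN, s^-1.
#' @param dx_unfold Its transition-state distance, nm.
#' @param k_refold SNAP-25 rebinding rate below `refold_max_force`, s^-1.
#' @param refold_max_force Gate force for rebinding, pN.
#' @return A [kinetic_scheme()] with states `zippered`, `unzipped`,
#'   `snap25_off`.
#' @export
scheme_ramp_cycle <- function(condition = c("none", "cpx"),
                              k_unfold16 = 0.12, dx_unfold = 5,
                              k_refold = 1, refold_max_force = 2,
                              k_w = k_attempt(), kBT = kBT_pN_nm()) {
  condition <- match.arg(condition)
  two <- scheme_two_state(condition, k_w = k_w, kBT = kBT)
  edges <- bind_rows(
    two$edges,
    tibble(from = c("unzipped", "snap25_off"),
           to = c("snap25_off", "zippered"),
           k_ref = c(k_unfold16, k_refold),
           F_ref = c(16, 0),
           delta_x = c(dx_unfold, 0),
           max_force = c(Inf, refold_max_force)))
  sch <- kinetic_scheme(c("zippered", "unzipped", "snap25_off"), edges,
                        kBT = kBT)
  attr(sch, "condition") <- condition
  sch
}

# Per-condition three-state landscape parameters (zero-force energies in kBT,
# positions in nm) for the zippered intermediates, plus barrier placements.
# Conditions follow the Cpx truncation series: none, WT (full length),
# NAC (no C-terminal domain), AC (accessory + central helices), C (central
# helix only). Energies are chosen so the force-dependent equilibria
# reproduce the observed behaviour: intermediates appear only above ~13 pN;
# with WT/NAC Cpx the linker-open state dominates above 14.5 pN while the
# half-zippered state is nearly abolished; AC and C suppress the
# half-zippered state without promoting the linker-open one.
.CPX_CONDITIONS <- tibble(
  label = c("none", "WT", "NAC", "AC", "C"),
  cpx_uM = c(0, 5, 5, 5, 5),
  G_linker_open = c(18.83, 17.80, 17.80, 19.80, 19.10),
  G_half_zippered = c(46.81, 49.97, 49.97, 51.00, 48.50),
  x_linker_open = 5.3,
  x_half_zippered = 13.0,
  # forward rates at 14 pN fixing the barrier placements
  k14_fz_lo = 200,
  k14_lo_hz = c(80, 1.316, 1.316, 2.77, 14.7),
  barrier1_x = 2.5,
  barrier2_x = 9.0
)

#' Experimental conditions (Cpx variants)
#'
#' The named conditions used across simulations: no Cpx and the Cpx
#' truncation series (WT full length, NAC lacking the C-terminal domain,
#' AC accessory+central helices, C central helix only), each with a pinned
#' three-state landscape (zero-force free energies and extension
#' coordinates of the zippered intermediates) and kinetic barrier
#' placements.
#'
#' @return A tibble, one row per condition.
#' @export
cpx_conditions <- function() .CPX_CONDITIONS

#' Three-state scheme among the zippered intermediates
#'
#' Kinetics among fully zippered, linker-open and half-zippered states for a
#' named experimental condition (see [cpx_conditions()]), built with
#' [scheme_from_landscape()] so detailed balance holds by construction.
#' `rate_scale` multiplies all rates (equivalently shifts both barriers),
#' preserving the equilibrium; use it to emulate slower/faster exchange.
#'
#' @param condition One of `"none"`, `"WT"`, `"NAC"`, `"AC"`, `"C"`.
#' @param rate_scale Multiplier applied to every rate.
#' @param k_w Attempt frequency, s^-1.
#' @param kBT Thermal energy, pN nm.
#' @return A [kinetic_scheme()] with attribute `landscape` (energies,
#'   positions).
#' @export
scheme_three_state <- function(condition = "none", rate_scale = 1,
                               k_w = k_attempt(), kBT = kBT_pN_nm()) {
  row <- .CPX_CONDITIONS[.CPX_CONDITIONS$label == condition, ]
  if (nrow(row) != 1) {
    abort(sprintf("unknown condition '%s'; see cpx_conditions()", condition))
  }
  energies <- c(fully_zippered = 0,
                linker_open = row$G_linker_open,
                half_zippered = row$G_half_zippered)
  positions <- c(fully_zippered = 0,
                 linker_open = row$x_linker_open,
                 half_zippered = row$x_half_zippered)
  # landscape anchored at 14 pN, where the experiments live: force-tilted
  # state energies, with barrier heights fixed by the forward rates there
  tilted <- energies - 14 * positions / kBT
  h1 <- tilted[["fully_zippered"]] + log(k_w / (row$k14_fz_lo * rate_scale))
  h2 <- tilted[["linker_open"]] + log(k_w / (row$k14_lo_hz * rate_scale))
  scheme <- scheme_from_landscape(
    tilted, positions,
    barriers = tibble(from = c("fully_zippered", "linker_open"),
                      to = c("linker_open", "half_zippered"),
                      position = c(row$barrier1_x, row$barrier2_x),
                      height = c(h1, h2)),
    k_w = k_w, kBT = kBT, F_ref = 14)
  attr(scheme, "landscape") <- list(energies = energies, positions = positions)
  attr(scheme, "condition") <- condition
  scheme
}
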