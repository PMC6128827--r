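# Independent numerical oracles and shared simulation helpers for the tests.

# Generic bisection on a monotone function with a sign change on [lo, hi];
# written without uniroot so it is independent of the package's solvers.
bisect_root <- function(f, lo, hi, iters = 200) {
  flo <- f(lo)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(flo)) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-13 * max(1, abs(hi))) break
  }
  (lo + hi) / 2
}

# Forward Marko-Siggia force at a given extension for extensible dsDNA
# (implicit in F because of the stretch term), solved by bisection in F.
oracle_dsdna_force <- function(x, bp = 1020, P = 45, nm_per_bp = 0.338,
                               K = 1200, kBT = 4.11) {
  L <- bp * nm_per_bp
  g <- function(l) 1 / (4 * (1 - l)^2) - 0.25 + l
  bisect_root(function(F) kBT / P * g(x / L - F / K) - F, 0, 150)
}

# Extension at a given force via bisection in x on the forward relation.
oracle_dsdna_extension <- function(force, bp = 1020, P = 45,
                                   nm_per_bp = 0.338, K = 1200, kBT = 4.11) {
  L <- bp * nm_per_bp
  bisect_root(function(x) oracle_dsdna_force(x, bp, P, nm_per_bp, K, kBT) -
                force, 0, L * (1 + force / K) * 0.9999)
}

# Three-state scheme with stationary weights 0.55 / 0.20 / 0.25 at 14 pN
# (state levels 0 / 5.3 / 13.0 nm) and forward exchange rates 50 /s --
# the high-speed equilibrium demo conditions.
demo_scheme <- function(k_exchange = 50, weights = c(0.55, 0.20, 0.25),
                        k_w = 1e6, kBT = 4.11) {
  g <- -log(weights / weights[1])   # tilted energies at 14 pN, kBT
  names(g) <- c("fully_zippered", "linker_open", "half_zippered")
  pos <- c(fully_zippered = 0, linker_open = 5.3, half_zippered = 13.0)
  barriers <- tibble::tibble(
    from = c("fully_zippered", "linker_open"),
    to = c("linker_open", "half_zippered"),
    position = c(2.5, 9.0),
    height = c(g[["fully_zippered"]], g[["linker_open"]]) + log(k_w / k_exchange))
  scheme_from_landscape(g, pos, barriers, k_w = k_w, kBT = kBT, F_ref = 14)
}

demo_offsets <- c(fully_zippered = 0, linker_open = 5.3, half_zippered = 13.0)

# Simulated force-jump dwell experiment: n traces jumping 10 -> `force` pN,
# held until `cap` seconds. Returns the traces.
sim_jump_traces <- function(scheme, force, n, cap, sampling_rate = 100,
                            seed = 1) {
  prot <- force_protocol(protocol_hold(10, 0.2), protocol_jump(10, force),
                         protocol_hold(force, cap))
  lapply(seq_len(n), function(i) {
    simulate_trace(scheme, prot, extension = c(zippered = 0, unzipped = 25),
                   sampling_rate = sampling_rate, seed = seed + i)
  })
}

# Dwell -> rate pipeline at one force: extract latencies and fit the
# censored exponential.
jump_rate_at <- function(scheme, force, n, cap, seed) {
  traces <- sim_jump_traces(scheme, force, n, cap, seed = seed)
  dw <- extract_latencies(traces, target_force = force)
  fit_exponential_mle(dw)
}
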