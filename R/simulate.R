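#' Measurement noise model
#'
#' Gaussian per-frame noise standing in for camera-sampled bead Brownian
#' motion. Defaults are sampling-rate dependent: 2.5 nm per frame at high
#' speed (>= 600 Hz) and 1.0 nm at 100 Hz, chosen so that the three zippered
#' intermediates are resolvable at 1.2 kHz but merge at 100 Hz. An optional
#' Ornstein-Uhlenbeck mode adds frame-to-frame correlation.
#'
#' @param sigma Per-frame standard deviation, nm; `NULL` picks the
#'   rate-dependent default at simulation time.
#' @param correlation_time Optional correlation time in s for the OU mode.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = NULL, correlation_time = NULL) {
  if (!is.null(sigma) && sigma < 0) abort("sigma must be >= 0")
  structure(list(sigma = sigma, correlation_time = correlation_time),
            class = "noise_model")
}

.noise_sigma <- function(noise, sampling_rate) {
  noise$sigma %||% if (sampling_rate >= 600) 2.5 else 1.0
}

.draw_noise <- function(noise, n, sampling_rate) {
  sigma <- .noise_sigma(noise, sampling_rate)
  eps <- rnorm(n, 0, sigma)
  if (!is.null(noise$correlation_time) && noise$correlation_time > 0) {
    rho <- exp(-1 / (sampling_rate * noise$correlation_time))
    eps <- as.numeric(stats::filter(eps * sqrt(1 - rho^2), rho,
                                    method = "recursive"))
    eps[1] <- rnorm(1, 0, sigma)
  }
  eps
}

.local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Kinetic Monte Carlo state path under a force protocol: exact exponential
# waiting times during holds; time-discretized thinning (per-step survival
# exp(-k dt), dt = 1 ms) during ramps/jumps. Returns the transition events
# and the visited-state intervals.
.simulate_path <- function(scheme, protocol, initial_state, dt = 1e-3) {
  seg_ends <- cumsum(protocol$duration)
  seg_starts <- c(0, seg_ends[-length(seg_ends)])
  s <- initial_state
  t <- 0
  ev_time <- numeric(0); ev_from <- character(0); ev_to <- character(0)

  exit_edges <- function(state) scheme$edges[scheme$edges$from == state, ]

  for (i in seq_len(nrow(protocol))) {
    t1 <- seg_ends[i]
    mode <- protocol$mode[i]
    while (t < t1 - 1e-12) {
      ed <- exit_edges(s)
      if (nrow(ed) == 0) { t <- t1; break }
      if (mode == "hold") {
        F <- protocol$start_force[i]
        k <- ed$k_ref * exp((F - ed$F_ref) * ed$delta_x / scheme$kBT) *
          (F <= ed$max_force)
        K <- sum(k)
        t_next <- if (K > 0) t + rexp(1, K) else Inf
        if (t_next >= t1) { t <- t1; break }
        dest <- sample(ed$to, 1, prob = k)
        ev_time <- c(ev_time, t_next); ev_from <- c(ev_from, s)
        ev_to <- c(ev_to, dest)
        s <- dest; t <- t_next
      } else {
        n_steps <- ceiling((t1 - t) / dt)
        step_t <- t + (seq_len(n_steps) - 1) * dt
        step_dt <- pmin(dt, t1 - step_t)
        Fs <- protocol_force(protocol[i, , drop = FALSE] |>
                               `class<-`(c("force_protocol", "tbl_df",
                                           "tbl", "data.frame")),
                             step_t + step_dt / 2 - seg_starts[i])
        K <- rep(0, n_steps)
        for (j in seq_len(nrow(ed))) {
          K <- K + ed$k_ref[j] *
            exp((Fs - ed$F_ref[j]) * ed$delta_x[j] / scheme$kBT) *
            (Fs <= ed$max_force[j])
        }
        hit <- which(runif(n_steps) < 1 - exp(-K * step_dt))[1]
        if (is.na(hit)) { t <- t1; break }
        t_next <- step_t[hit] + step_dt[hit]
        F_ev <- Fs[hit]
        k <- ed$k_ref * exp((F_ev - ed$F_ref) * ed$delta_x / scheme$kBT) *
          (F_ev <= ed$max_force)
        dest <- sample(ed$to, 1, prob = k)
        ev_time <- c(ev_time, t_next); ev_from <- c(ev_from, s)
        ev_to <- c(ev_to, dest)
        s <- dest; t <- t_next
      }
    }
  }
  list(events = tibble(time = ev_time, from = ev_from, to = ev_to),
       final_state = s)
}

# Per-state extension evaluator. `extension` is either a snare_construct
# (with an optional scheme-state -> construct-state map) or a named numeric
# vector of fixed per-state extension offsets in nm.
.extension_evaluator <- function(extension, states, force_range,
                                 state_map = NULL) {
  if (inherits(extension, "snare_construct")) {
    state_map <- state_map %||%
      c(zippered = "fully_zippered", unzipped = "unzipped",
        setNames(snare_states(), snare_states()))
    mapped <- state_map[states]
    if (anyNA(mapped)) {
      abort("no construct state mapped for some scheme states; pass state_map")
    }
    grid <- seq(max(force_range[1] - 0.1, 0), force_range[2] + 0.1,
                length.out = 256)
    luts <- lapply(setNames(mapped, states), function(cs) {
      y <- state_extension(extension, grid, cs)
      function(f) approx(grid, y, xout = f, rule = 2)$y
    })
    function(force, state) luts[[state]](force)
  } else {
    offs <- extension
    if (is.null(names(offs)) || !all(states %in% names(offs))) {
      abort("extension offsets must be a named vector covering all scheme states")
    }
    function(force, state) rep(offs[[state]], length(force))
  }
}

#' Simulate a magnetic-tweezers trace
#'
#' Generates a synthetic bead-extension trace: a continuous-time Markov state
#' path over the scheme's states (kinetic Monte Carlo; exact exponential
#' waiting times during holds, 1-ms thinning during ramps), sampled on the
#' camera frame grid, with the state-dependent construct extension plus
#' Gaussian measurement noise. The exact transition events are stored in the
#' `events` attribute (the simulator's ground truth).
#'
#' @param scheme A [kinetic_scheme()].
#' @param protocol A [force_protocol()].
#' @param extension Either a [snare_construct()] or a named numeric vector of
#'   per-state extension offsets in nm.
#' @param sampling_rate Frames per second (100 and 1200 Hz are the typical
#'   camera rates).
#' @param noise A [noise_model()].
#' @param seed Integer seed; identical seeds give identical traces.
#' @param initial_state Starting state (default: first scheme state).
#' @param state_map Optional named map from scheme states to construct states.
#' @return A tibble of class `snare_trace` with columns `time`, `force`,
#'   `extension`, `state`, and attributes `sampling_rate`, `seed`, `events`,
#'   `protocol`, `condition`.
#' @export
simulate_trace <- function(scheme, protocol, extension,
                           sampling_rate = 100, noise = noise_model(),
                           seed = NULL, initial_state = scheme$states[1],
                           state_map = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(protocol, "force_protocol"))
  if (!initial_state %in% scheme$states) abort("unknown initial state")
  total <- protocol_duration(protocol)
  n <- floor(total * sampling_rate + 1e-9)
  times <- (seq_len(n) - 1) / sampling_rate
  forces <- protocol_force(protocol, times)

  .local_seed(seed, {
    path <- .simulate_path(scheme, protocol, initial_state)
    ev <- path$events
    state_seq <- c(initial_state, ev$to)
    frame_state <- state_seq[findInterval(times, ev$time) + 1]

    evalr <- .extension_evaluator(extension, scheme$states, range(forces),
                                  state_map)
    ext <- numeric(n)
    for (s in unique(frame_state)) {
      idx <- frame_state == s
      ext[idx] <- evalr(forces[idx], s)
    }
    ext <- ext + .draw_noise(noise, n, sampling_rate)

    # missed-event regime check: exit rates over the forces at which each
    # state was actually occupied
    max_exit <- max(vapply(unique(frame_state), function(s) {
      ed <- scheme$edges[scheme$edges$from == s, ]
      if (nrow(ed) == 0) return(0)
      fr <- range(forces[frame_state == s])
      max(vapply(seq(fr[1], fr[2], length.out = 8), function(f) {
        sum(ed$k_ref * exp((f - ed$F_ref) * ed$delta_x / scheme$kBT) *
              (f <= ed$max_force))
      }, numeric(1)))
    }, numeric(1)))
    if (max_exit > 10 * sampling_rate) {
      warn(sprintf(paste0("total exit rate (%.3g /s) exceeds 10x the sampling",
                          " rate: missed-event regime"), max_exit))
    }

    new_snare_trace(
      tibble(time = times, force = forces, extension = ext,
             state = frame_state),
      sampling_rate = sampling_rate, seed = seed, events = ev,
      protocol = protocol, condition = attr(scheme, "condition"))
  })
}

#' Construct / inspect a trace object
#'
#' `new_snare_trace()` stamps a data frame (columns `time`, `force`,
#' `extension`, optionally `state`) as a `snare_trace`, carrying the
#' sampling rate and provenance attributes. `trace_events()` returns the
#' simulator's true transition events (if present), `trace_sampling_rate()`
#' the sampling rate (inferred from the time grid when not recorded).
#'
#' @param x A data frame with trace columns.
#' @param sampling_rate Frames per second.
#' @param seed,events,protocol,condition Provenance attributes.
#' @return A `snare_trace` tibble.
#' @export
new_snare_trace <- function(x, sampling_rate = NULL, seed = NULL,
                            events = NULL, protocol = NULL,
                            condition = NULL) {
  x <- as_tibble(x)
  stopifnot(all(c("time", "force", "extension") %in% names(x)))
  structure(x,
            class = c("snare_trace", class(x)),
            sampling_rate = sampling_rate, seed = seed, events = events,
            protocol = protocol, condition = condition)
}

#' @rdname new_snare_trace
#' @param trace A `snare_trace`.
#' @export
trace_events <- function(trace) attr(trace, "events")

#' @rdname new_snare_trace
#' @export
trace_sampling_rate <- function(trace) {
  attr(trace, "sampling_rate") %||% round(1 / median(diff(trace$time)))
}

#' @export
print.snare_trace <- function(x, ...) {
  cat(sprintf("<snare_trace> %d frames @ %g Hz, force %.2f-%.2f pN\n",
              nrow(x), trace_sampling_rate(x), min(x$force), max(x$force)))
  NextMethod()
}
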