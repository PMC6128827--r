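#' Detect unzipping/rezipping steps in a trace
#'
#' Two-sided moving-median change-point detector: for each frame the medians
#' of the trailing and leading `window` frames are compared; runs of frames
#' whose difference exceeds `min_step` are collapsed to the frame of maximum
#' difference (candidates closer than one window are merged). The event force
#' is the protocol force at the change-point frame, and the step size is the
#' leading-minus-trailing median difference there. Events are classified by
#' sign and size: steps of at least `large_step` nm are the main SNARE
#' unzip/rezip transitions; smaller ones are SNAP-25 unfold/refold events.
#'
#' @param trace A `snare_trace` (or data frame with `time`, `force`,
#'   `extension`).
#' @param min_step Minimum absolute median difference, nm.
#' @param window Frames per side; default 11 at <= 300 Hz, else 61.
#' @param large_step Size boundary (nm) between unzip/rezip and
#'   unfold/refold classification.
#' @return A tibble of transition events: `time`, `frame`, `force`,
#'   `step_size`, `direction`, sorted by time.
#' @export
detect_steps <- function(trace, min_step = 10, window = NULL,
                         large_step = 15) {
  x <- trace$extension
  n <- length(x)
  rate <- trace_sampling_rate(trace)
  window <- window %||% if (rate <= 300) 11L else 61L
  if (window >= n / 2) abort("window must be smaller than half the trace")
  if (window %% 2 == 0) window <- window + 1L

  # trailing median over x[t-window+1 .. t], leading over x[t+1 .. t+window]
  med_right <- zoo::rollmedian(x, k = window, align = "right", fill = NA)
  med_left <- zoo::rollmedian(x, k = window, align = "left", fill = NA)
  d <- c(med_left[-1], NA) - med_right
  d[is.na(d)] <- 0

  cand <- which(abs(d) >= min_step)
  if (length(cand) == 0) {
    return(tibble(time = numeric(0), frame = integer(0), force = numeric(0),
                  step_size = numeric(0), direction = character(0)))
  }
  # split candidates into clusters separated by at least one window; the
  # change point is the middle of the plateau of maximal difference
  grp <- cumsum(c(1, diff(cand) > window))
  frames <- vapply(split(cand, grp), function(idx) {
    top <- idx[abs(d[idx]) >= max(abs(d[idx])) - 1e-9]
    top[ceiling(length(top) / 2)]
  }, numeric(1))
  frames <- as.integer(sort(frames))

  step <- d[frames]
  dir <- ifelse(step > 0,
                ifelse(abs(step) >= large_step, "unzip", "unfold"),
                ifelse(abs(step) >= large_step, "rezip", "refold"))
  tibble(time = trace$time[frames], frame = frames,
         force = trace$force[frames], step_size = step, direction = dir)
}

# Signature force windows (pN) for a genuine single SNARE complex tether.
.QC_WINDOWS <- list(unzip = c(12, 16), rezip = c(8, 12),
                    unfold = c(15, 18), refold = c(0, 2))

#' Signature quality control for a stretch-relax cycle
#'
#' A tether passes only if a full cycle shows all four signature events in
#' their force windows: SNARE unzipping at 12-16 pN, rezipping at 8-12 pN,
#' SNAP-25 unfolding at 15-18 pN, and refolding under 2 pN. Always returns a
#' verdict with the reasons for failure.
#'
#' @param events Event tibble from [detect_steps()] covering at least one
#'   full cycle.
#' @param windows Named list of force windows, pN.
#' @return A list with elements `pass` (logical) and `reasons` (character).
#' @export
qc_signature <- function(events, windows = .QC_WINDOWS) {
  reasons <- character(0)
  for (class in names(windows)) {
    win <- windows[[class]]
    f <- events$force[events$direction == class]
    if (length(f) == 0) {
      reasons <- c(reasons, sprintf("missing %s event", class))
    } else if (!any(f >= win[1] & f <= win[2])) {
      reasons <- c(reasons,
                   sprintf("%s outside %g-%g pN (observed %s)", class,
                           win[1], win[2],
                           paste(sprintf("%.1f", f), collapse = ", ")))
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Normalize per-bead unzip forces to the global mean
#'
#' Bead-to-bead force-calibration variation is removed by rescaling each
#' pulling construct so that its mean no-Cpx unzipping force equals the
#' global average (14.4 pN). Beads with fewer than `min_events` unzip events
#' are excluded with a warning. The operation is idempotent.
#'
#' @param forces Data frame with columns `bead` and `force` (one row per
#'   unzip event, measured without Cpx).
#' @param global_mean Global mean unzipping force, pN.
#' @param min_events Minimum unzip events per bead.
#' @return The input rows for retained beads with an added `force_scaled`
#'   column; attribute `scales` holds the per-bead tibble (`bead`, `n`,
#'   `bead_mean`, `scale`).
#' @export
normalize_to_global <- function(forces, global_mean = 14.4, min_events = 3) {
  stopifnot(all(c("bead", "force") %in% names(forces)))
  scales <- forces |>
    group_by(.data$bead) |>
    summarise(n = n(), bead_mean = mean(.data$force), .groups = "drop") |>
    mutate(scale = global_mean / .data$bead_mean)
  drop <- scales$bead[scales$n < min_events]
  if (length(drop) > 0) {
    warn(sprintf("excluding bead(s) with < %d unzip events: %s", min_events,
                 paste(drop, collapse = ", ")))
    scales <- scales[!scales$bead %in% drop, ]
  }
  out <- forces |>
    filter(!.data$bead %in% drop) |>
    left_join(select(scales, "bead", "scale"), by = "bead") |>
    mutate(force_scaled = .data$force * .data$scale) |>
    select(-"scale")
  attr(out, "scales") <- scales
  out
}

#' Transition-force histogram and summary
#'
#' Bins event forces and reports unbinned summary statistics (mean, sd, n).
#' With a single event the sd is undefined and reported as `NA`.
#'
#' @param events Event tibble with a `force` column (>= 1 row).
#' @param bin_width Bin width, pN.
#' @return Object of class `force_histogram`: list with `counts` (tibble
#'   `bin_mid`, `count`) and `summary` (tibble `mean`, `sd`, `n`).
#' @export
transition_force_histogram <- function(events, bin_width = 0.5) {
  f <- events$force
  if (length(f) == 0) abort("at least one event is required")
  lo <- floor(min(f) / bin_width) * bin_width
  breaks <- seq(lo, max(f) + bin_width, by = bin_width)
  h <- graphics::hist(f, breaks = breaks, plot = FALSE)
  structure(list(
    counts = tibble(bin_mid = h$mids, count = h$counts),
    summary = tibble(mean = mean(f),
                     sd = if (length(f) > 1) sd(f) else NA_real_,
                     n = length(f))),
    class = "force_histogram")
}

#' @export
print.force_histogram <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<force_histogram> n = %d, mean = %.2f pN, sd = %s pN\n",
              s$n, s$mean, ifelse(is.na(s$sd), "NA", sprintf("%.2f", s$sd))))
  invisible(x)
}
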