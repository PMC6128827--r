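#' Extract unzip/rezip latencies from force-jump traces
#'
#' For each trace, locates the completion of the force jump (first frame at
#' the target force), discards the settling transient (`settle_time`, the
#' instrument reaches target forces within 0.1 s), and measures the latency
#' to the first detected transition in the requested direction. Traces
#' ending without a transition yield right-censored records carrying the
#' observation-window length; traces whose force never reaches the target
#' are skipped with a warning.
#'
#' @param traces A `snare_trace` or list of them.
#' @param target_force Hold force after the jump, pN.
#' @param direction `"unzip"` (upward step) or `"rezip"` (downward step).
#' @param settle_time Settling transient excluded from timing, s.
#' @param min_step,window Passed to [detect_steps()].
#' @param force_tol Tolerance for "at target force", pN.
#' @return A tibble of dwell records: `trace_id`, `force`, `duration`,
#'   `censored`, `sub_resolution`, `condition`.
#' @export
extract_latencies <- function(traces, target_force,
                              direction = c("unzip", "rezip"),
                              settle_time = 0.1, min_step = 10,
                              window = NULL, force_tol = 0.05) {
  direction <- match.arg(direction)
  if (inherits(traces, "snare_trace")) traces <- list(traces)
  recs <- imap(traces, function(tr, id) {
    at_target <- which(abs(tr$force - target_force) <= force_tol)
    if (length(at_target) == 0) {
      warn(sprintf("trace %s never settles at %.2f pN; skipped",
                   as.character(id), target_force))
      return(NULL)
    }
    t0 <- tr$time[at_target[1]] + settle_time
    t_end <- tr$time[nrow(tr)]
    ev <- detect_steps(tr, min_step = min_step, window = window)
    rate <- trace_sampling_rate(tr)
    win <- window %||% if (rate <= 300) 11L else 61L
    # transitions during the jump itself surface as change points up to one
    # detection window before the settled frame; keep them (sub-resolution)
    ev <- ev[ev$direction == direction &
               ev$time > tr$time[at_target[1]] - win / rate, ]
    cond <- attr(tr, "condition") %||% NA_character_
    if (nrow(ev) == 0) {
      tibble(trace_id = as.character(id), force = target_force,
             duration = t_end - t0, censored = TRUE,
             sub_resolution = FALSE, condition = cond)
    } else {
      dur <- ev$time[1] - t0
      sub <- dur <= win / rate
      tibble(trace_id = as.character(id), force = target_force,
             duration = max(dur, 1 / rate), censored = FALSE,
             sub_resolution = sub, condition = cond)
    }
  })
  list_rbind(purrr::compact(recs))
}

#' Censored-exponential maximum likelihood fit of dwell times
#'
#' Dwell times behind a single energy barrier are exponential; dwells
#' censored at the end of the observation window enter through their
#' observed length. The MLE of the rate is
#' (number of uncensored dwells) / (total observed time), with a 95%
#' profile-likelihood confidence interval. Without censoring the mean
#' reduces to the sample mean.
#'
#' @param dwells Tibble with `duration` and `censored` columns (or a bare
#'   numeric vector, taken as uncensored).
#' @param conf_level Confidence level for the profile interval.
#' @param min_uncensored Minimum number of uncensored dwells.
#' @return Object of class `exp_fit`: rate (s^-1), mean (s), CI, counts.
#' @export
fit_exponential_mle <- function(dwells, conf_level = 0.95,
                                min_uncensored = 5) {
  if (is.numeric(dwells)) {
    dwells <- tibble(duration = dwells, censored = FALSE)
  }
  stopifnot(all(c("duration", "censored") %in% names(dwells)),
            all(dwells$duration > 0))
  d <- sum(!dwells$censored)
  if (d == 0) abort("all dwells censored: rate unidentifiable")
  if (d < min_uncensored) {
    abort(sprintf("need >= %d uncensored dwells (got %d)", min_uncensored, d))
  }
  total <- sum(dwells$duration)
  rate <- d / total
  ll <- function(k) d * log(k) - k * total
  crit <- qchisq(conf_level, df = 1) / 2
  g <- function(k) ll(rate) - ll(k) - crit
  lower <- uniroot(g, lower = rate * 1e-6, upper = rate, tol = 1e-12)$root
  upper <- uniroot(g, lower = rate, upper = rate * 1e3, tol = 1e-12)$root
  structure(list(rate = rate, mean = 1 / rate,
                 conf_low = lower, conf_high = upper,
                 conf_level = conf_level,
                 n_uncensored = d, n_censored = sum(dwells$censored),
                 total_time = total, logLik = ll(rate)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_fit> rate = %.4g /s (95%% CI %.4g-%.4g), mean = %.3g s, n = %d (+%d censored)\n",
    x$rate, x$conf_low, x$conf_high, x$mean, x$n_uncensored, x$n_censored))
  invisible(x)
}

#' Fit the Bell equation to force-dependent rates
#'
#' Weighted linear regression of `ln(k / k_w)` on force:
#' `ln(k/k_w) = -dG + F dx / kBT`, so the slope gives the distance to the
#' transition state `dx` (nm; negative for transitions opposed by force) and
#' the intercept the zero-force barrier height `dG` (kBT units). Weights are
#' the inverse variances of `ln k` derived from per-force confidence
#' intervals when present, otherwise the fit is unweighted.
#'
#' @param rates Tibble with columns `force`, `rate`, optionally `conf_low`,
#'   `conf_high`.
#' @param k_w Attempt frequency, s^-1.
#' @param kBT Thermal energy, pN nm.
#' @return Object of class `bell_fit` with elements `delta_x` (nm),
#'   `delta_G` (kBT at zero force), standard errors, the underlying `lm`
#'   fit and the force range used.
#' @export
fit_bell <- function(rates, k_w = k_attempt(), kBT = kBT_pN_nm()) {
  stopifnot(all(c("force", "rate") %in% names(rates)))
  rates <- rates[is.finite(rates$rate) & rates$rate > 0, ]
  if (length(unique(rates$force)) < 2) {
    abort("rank-deficient design: need rates at >= 2 (recommended >= 3) distinct forces")
  }
  y <- log(rates$rate / k_w)
  w <- NULL
  if (all(c("conf_low", "conf_high") %in% names(rates)) &&
      all(is.finite(rates$conf_low)) && all(rates$conf_low > 0)) {
    se_ln <- (log(rates$conf_high) - log(rates$conf_low)) / (2 * qnorm(0.975))
    w <- 1 / pmax(se_ln, 1e-6)^2
  }
  fit <- lm(y ~ force, data = tibble(y = y, force = rates$force), weights = w)
  b <- coef(fit)
  # exact input rates make the fit perfect; the summary warning is benign
  V <- suppressWarnings(vcov(fit))
  structure(list(delta_x = unname(b[2]) * kBT,
                 delta_G = -unname(b[1]),
                 se_delta_x = sqrt(V[2, 2]) * kBT,
                 se_delta_G = sqrt(V[1, 1]),
                 vcov = V, fit = fit,
                 force_range = range(rates$force),
                 k_w = k_w, kBT = kBT, data = as_tibble(rates)),
            class = "bell_fit")
}

#' @export
print.bell_fit <- function(x, ...) {
  cat(sprintf(
    "<bell_fit> dx = %.3g +/- %.2g nm, dG(0) = %.3g +/- %.2g kBT (k_w = %g /s)\n",
    x$delta_x, x$se_delta_x, x$delta_G, x$se_delta_G, x$k_w))
  invisible(x)
}

#' Evaluate a Bell fit: tilted barrier and extrapolated rate
#'
#' `bell_barrier()` returns the force-tilted barrier height
#' `dG(F) = dG - F dx / kBT` (kBT units) and `bell_rate()` the predicted
#' rate `k(F) = k_w exp(-dG(F))` at arbitrary forces (including
#' extrapolation to F = 0).
#'
#' @param fit A [fit_bell()] result.
#' @param force Force in pN; vectorized.
#' @return Numeric vector.
#' @export
bell_barrier <- function(fit, force) {
  stopifnot(inherits(fit, "bell_fit"))
  fit$delta_G - force * fit$delta_x / fit$kBT
}

#' @rdname bell_barrier
#' @export
bell_rate <- function(fit, force) {
  fit$k_w * exp(-bell_barrier(fit, force))
}

#' Coarse-grained energy landscape from unzip and rezip Bell fits
#'
#' Reconstructs the one-dimensional landscape at a chosen force: the
#' zippered state at (0 nm, 0 kBT), the barrier at the unzipping
#' transition-state distance with height `dG_unzip(F)`, and the unzipped
#' state at `dx_unzip + |dx_rezip|` with energy
#' `dG_unzip(F) - dG_rezip(F)`. With `anchor = "unzipped"` the landscape is
#' shifted so the unzipped state sits at 0 kBT, which is the natural frame
#' for comparing conditions whose rezipping kinetics agree (a condition that
#' only stabilizes the zippered side then changes only the well and the
#' barrier).
#'
#' @param unzip_fit,rezip_fit [fit_bell()] results for the two directions.
#' @param force Evaluation force, pN.
#' @param anchor `"zippered"` (default) or `"unzipped"`.
#' @return Object of class `energy_landscape`: tibble with `label`,
#'   `position` (nm), `energy` (kBT); attributes `force`, `anchor`.
#' @export
build_landscape <- function(unzip_fit, rezip_fit, force,
                            anchor = c("zippered", "unzipped")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(unzip_fit, "bell_fit"), inherits(rezip_fit, "bell_fit"))
  if (unzip_fit$force_range[1] > rezip_fit$force_range[2] ||
      rezip_fit$force_range[1] > unzip_fit$force_range[2]) {
    abort("unzip and rezip fits must share overlapping force ranges")
  }
  barrier <- bell_barrier(unzip_fit, force)
  unzipped_energy <- barrier - bell_barrier(rezip_fit, force)
  if (barrier < 0 || barrier < unzipped_energy) {
    abort("inconsistent fits: barrier lies below a state")
  }
  out <- tibble(
    label = c("zippered", "barrier", "unzipped"),
    position = c(0, unzip_fit$delta_x,
                 unzip_fit$delta_x + abs(rezip_fit$delta_x)),
    energy = c(0, barrier, unzipped_energy))
  if (anchor == "unzipped") out$energy <- out$energy - unzipped_energy
  structure(out, class = c("energy_landscape", class(out)),
            force = force, anchor = anchor)
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("<energy_landscape> at %.1f pN (anchor: %s)\n",
              attr(x, "force"), attr(x, "anchor")))
  NextMethod()
}
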