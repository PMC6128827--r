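#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidiers for fitted objects
#'
#' broom-style `tidy()` (one row per estimated quantity) and `glance()`
#' (one-row model summary) methods for the package's fitted objects:
#' exponential dwell fits, Bell fits, Gaussian mixtures, HMMs and
#' three-state equilibrium models.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name snarezip-tidiers
NULL

#' @rdname snarezip-tidiers
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble(term = c("rate", "mean"),
         estimate = c(x$rate, x$mean),
         conf_low = c(x$conf_low, 1 / x$conf_high),
         conf_high = c(x$conf_high, 1 / x$conf_low))
}

#' @rdname snarezip-tidiers
#' @export
glance.exp_fit <- function(x, ...) {
  tibble(rate = x$rate, mean = x$mean, n_uncensored = x$n_uncensored,
         n_censored = x$n_censored, total_time = x$total_time,
         logLik = x$logLik)
}

#' @rdname snarezip-tidiers
#' @export
tidy.bell_fit <- function(x, ...) {
  tibble(term = c("delta_x", "delta_G"),
         estimate = c(x$delta_x, x$delta_G),
         std_error = c(x$se_delta_x, x$se_delta_G))
}

#' @rdname snarezip-tidiers
#' @export
glance.bell_fit <- function(x, ...) {
  tibble(delta_x = x$delta_x, delta_G = x$delta_G,
         n_forces = length(unique(x$data$force)),
         force_min = x$force_range[1], force_max = x$force_range[2],
         r_squared = suppressWarnings(summary(x$fit))$r.squared)
}

#' @rdname snarezip-tidiers
#' @export
tidy.gmm_fit <- function(x, ...) {
  x$components |> mutate(component = dplyr::row_number(), .before = 1)
}

#' @rdname snarezip-tidiers
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble(K = x$K, n = x$n, logLik = x$logLik,
         bic = -2 * x$logLik + (3 * x$K - 1) * log(x$n))
}

#' @rdname snarezip-tidiers
#' @export
tidy.hmm_fit <- function(x, ...) x$states

#' @rdname snarezip-tidiers
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble(K = x$K, logLik = x$logLik, n_iter = x$n_iter,
         converged = x$converged, sampling_rate = x$sampling_rate)
}

#' @rdname snarezip-tidiers
#' @export
tidy.three_state_model <- function(x, ...) x$states

#' @rdname snarezip-tidiers
#' @export
glance.three_state_model <- function(x, ...) {
  tibble(logLik = x$logLik, n_forces = nrow(x$data),
         converged = x$convergence == 0)
}

#' @rdname snarezip-tidiers
#' @export
tidy.force_histogram <- function(x, ...) x$counts

#' @rdname snarezip-tidiers
#' @export
glance.force_histogram <- function(x, ...) x$summary

#' Plot methods
#'
#' `autoplot()` methods: a trace as extension vs time (colored by true
#' state when present), an energy landscape as an interpolated profile, a
#' Gaussian mixture over the extension histogram, a population table as
#' force-dependent equilibria, and a Bell fit as log-rate vs force with the
#' fitted line.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name snarezip-plots
NULL

#' @rdname snarezip-plots
#' @export
autoplot.snare_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                            y = .data$extension))
  if ("state" %in% names(object) && !all(is.na(object$state))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(color = .data$state,
                                             group = 1), linewidth = 0.3)
  } else {
    p <- p + ggplot2::geom_line(linewidth = 0.3)
  }
  p + ggplot2::labs(x = "time (s)", y = "extension (nm)")
}

#' @rdname snarezip-plots
#' @export
autoplot.energy_landscape <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data$energy)) +
    ggplot2::geom_line(linetype = 2) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -1) +
    ggplot2::labs(x = "position along pulling coordinate (nm)",
                  y = "free energy (kBT)",
                  title = sprintf("Energy landscape at %.1f pN",
                                  attr(object, "force")))
}

#' @rdname snarezip-plots
#' @export
autoplot.gmm_fit <- function(object, ...) {
  dat <- tibble(extension = object$data)
  grid <- seq(min(dat$extension), max(dat$extension), length.out = 400)
  dens <- purrr::pmap(object$components, function(mean, sd, weight) {
    tibble(extension = grid, density = weight * dnorm(grid, mean, sd))
  }) |> list_rbind(names_to = "component")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$extension)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 80, fill = "grey80") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    color = factor(.data$component))) +
    ggplot2::labs(x = "extension (nm)", y = "density", color = "component")
}

#' @rdname snarezip-plots
#' @export
autoplot.population_table <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), dplyr::all_of(unname(.p_cols)),
                              names_to = "state", values_to = "population")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$force, y = .data$population,
                                     color = .data$state)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "force (pN)", y = "population")
}

#' @rdname snarezip-plots
#' @export
autoplot.bell_fit <- function(object, ...) {
  dat <- object$data |> mutate(log_rate = log(.data$rate))
  grid <- seq(object$force_range[1], object$force_range[2], length.out = 50)
  line <- tibble(force = grid, log_rate = log(bell_rate(object, grid)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$force, y = .data$log_rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, linetype = 2) +
    ggplot2::labs(x = "force (pN)", y = "ln rate (1/s)")
}
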