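#' Hidden Markov idealization of a high-speed trace
#'
#' Fits a K-state Gaussian-emission hidden Markov model to the extension
#' channel of a (typically 1.2 kHz, constant-force) trace by Baum-Welch.
#' Emission parameters are initialized from a Gaussian mixture fit of the
#' same trace; by default the emission means stay frozen at those measured
#' levels (the priors adopted from the extension distributions) while the
#' standard deviations and the transition matrix are re-estimated.
#' Convergence: change in log-likelihood below `tol` (default 1e-6), at
#' most `max_iter` iterations; non-convergence returns the last iterate
#' with a warning.
#'
#' @param trace A `snare_trace` (or numeric vector of extensions).
#' @param init A [fit_gmm()] result with K >= 2 components (or a tibble
#'   with `mean`, `sd`, `weight`).
#' @param fix_means Keep emission means frozen at their initial values.
#' @param fix_sds Keep emission sds frozen.
#' @param self_prob Initial self-transition probability.
#' @param tol,max_iter Convergence controls.
#' @return Object of class `hmm_fit`: `states` tibble (`state`, `mean`,
#'   `sd`), per-frame transition matrix `A`, initial distribution `pi`,
#'   `logLik`, `n_iter`, `converged`, `sampling_rate`.
#' @export
fit_hmm <- function(trace, init, fix_means = TRUE, fix_sds = FALSE,
                    self_prob = 0.98, tol = 1e-6, max_iter = 1000) {
  x <- if (is.numeric(trace)) trace else trace$extension
  rate <- if (is.numeric(trace)) NA_real_ else trace_sampling_rate(trace)
  comp <- if (inherits(init, "gmm_fit")) init$components else as_tibble(init)
  K <- nrow(comp)
  if (K < 2) abort("K = 1 carries no kinetics; need >= 2 states")
  means <- comp$mean
  sds <- pmax(comp$sd, 1e-3)
  pi0 <- comp$weight / sum(comp$weight)
  A <- matrix((1 - self_prob) / (K - 1), K, K)
  diag(A) <- self_prob

  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    fb <- hmm_forward_backward(x, means, sds, A, pi0)
    g <- fb$gamma
    rs <- rowSums(fb$xi)
    occupied <- rs > 1e-10
    A_new <- fb$xi / pmax(rs, .Machine$double.xmin)
    A[occupied, ] <- A_new[occupied, ]   # keep priors for unvisited states
    pi0 <- pmax(g[1, ], 1e-12)
    pi0 <- pi0 / sum(pi0)
    wsum <- pmax(colSums(g), 1e-10)
    if (!fix_means) means <- colSums(g * x) / wsum
    if (!fix_sds) {
      sds <- sqrt(colSums(g * outer(x, means, "-")^2) / wsum)
      sds <- pmax(sds, 1e-3)
    }
    if (abs(fb$loglik - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- fb$loglik
  }
  if (!converged) {
    warn(sprintf("Baum-Welch did not converge in %d iterations", max_iter))
  }
  ord <- order(means)
  structure(list(
    states = tibble(state = seq_len(K), mean = means[ord], sd = sds[ord]),
    A = A[ord, ord, drop = FALSE], pi = pi0[ord],
    logLik = fb$loglik, n_iter = iter, converged = converged,
    K = K, sampling_rate = rate),
    class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> K = %d, logLik = %.1f (%d iterations%s)\n",
              x$K, x$logLik, x$n_iter,
              if (x$converged) "" else ", not converged"))
  print(x$states)
  invisible(x)
}

#' Most likely state path of a trace
#'
#' Viterbi decoding of a trace under a fitted HMM. Warns when the trace is
#' everywhere more than 5 emission sds from every state (a scale mismatch
#' between model and trace).
#'
#' @param model A [fit_hmm()] result (or a one-row-per-state tibble with
#'   `mean`, `sd` and optional matrix attribute; single-state models give a
#'   constant path).
#' @param trace A `snare_trace` or numeric vector of extensions.
#' @return Integer vector of state indices (sorted by emission mean), same
#'   length as the trace.
#' @export
viterbi_path <- function(model, trace) {
  x <- if (is.numeric(trace)) trace else trace$extension
  st <- model$states
  if (nrow(st) == 1) return(rep(1L, length(x)))
  z <- vapply(seq_len(nrow(st)),
              function(k) abs(x - st$mean[k]) / st$sd[k],
              numeric(length(x)))
  if (all(apply(z, 1, min) > 5)) {
    warn("trace lies > 5 sd from every model state: emission/trace scale mismatch")
  }
  hmm_viterbi_path(x, st$mean, st$sd, model$A, model$pi)
}

#' Kinetic rates from an idealized state path
#'
#' Dwell-count estimator: `k_ij` = (number of i -> j transitions) /
#' (total time spent in i). Rates outside the reliability band (1-1e3
#' s^-1 at 1.2 kHz sampling) are flagged `reliable = FALSE`; states never
#' visited have no outgoing rows.
#'
#' @param path Integer/character state path per frame.
#' @param sampling_rate Frames per second.
#' @param state_names Optional labels for the integer states.
#' @param reliable_band Two-sided band of reliably measurable rates, s^-1.
#' @return Tibble of class `rate_table`: `from`, `to`, `k`,
#'   `n_transitions`, `time_in_from`, `reliable`.
#' @export
rates_from_path <- function(path, sampling_rate, state_names = NULL,
                            reliable_band = c(1, 1000)) {
  stopifnot(length(path) > 1)
  lev <- if (is.null(state_names)) sort(unique(path)) else state_names
  s <- if (is.null(state_names)) match(path, lev) else as.integer(path)
  K <- length(lev)
  time_in <- tabulate(s, nbins = K) / sampling_rate
  from <- s[-length(s)]
  to <- s[-1]
  ch <- from != to
  counts <- matrix(0L, K, K)
  if (any(ch)) {
    tab <- table(factor(from[ch], levels = seq_len(K)),
                 factor(to[ch], levels = seq_len(K)))
    counts <- matrix(as.integer(tab), K, K)
  }
  out <- tidyr::expand_grid(i = seq_len(K), j = seq_len(K)) |>
    filter(.data$i != .data$j) |>
    mutate(from = lev[.data$i], to = lev[.data$j],
           n_transitions = counts[cbind(.data$i, .data$j)],
           time_in_from = time_in[.data$i],
           k = .data$n_transitions / .data$time_in_from) |>
    filter(.data$time_in_from > 0) |>
    mutate(reliable = .data$k >= reliable_band[1] &
             .data$k <= reliable_band[2]) |>
    select("from", "to", "k", "n_transitions", "time_in_from", "reliable")
  class(out) <- c("rate_table", class(out))
  out
}

#' Rates implied by the per-frame transition matrix
#'
#' Secondary estimator converting the fitted per-frame transition
#' probabilities into rates, `k_ij = -log(A_ii) * A_ij / (1 - A_ii) *
#' rate` (exact for an embedded two-point jump process; ~ `A_ij * rate`
#' for small off-diagonals). The dwell-count estimator
#' ([rates_from_path()]) is the canonical one; this one is reported for
#' comparison.
#'
#' @param model A [fit_hmm()] result.
#' @param sampling_rate Frames per second (defaults to the model's).
#' @return Tibble `from`, `to`, `k`.
#' @export
rates_from_transition_matrix <- function(model, sampling_rate = NULL) {
  rate <- sampling_rate %||% model$sampling_rate
  A <- model$A
  K <- nrow(A)
  out <- tidyr::expand_grid(from = seq_len(K), to = seq_len(K)) |>
    filter(.data$from != .data$to) |>
    mutate(k = purrr::map2_dbl(.data$from, .data$to, function(i, j) {
      pii <- min(max(A[i, i], 1e-12), 1 - 1e-12)
      -log(pii) * A[i, j] / (1 - pii) * rate
    }))
  out
}

#' Bell fit of one transition across forces
#'
#' Applies [fit_bell()] to the rates of a single state pair gathered over a
#' set of holding forces (e.g. C-terminal zip = half-zippered to
#' linker-open, linker unzip = fully zippered to linker-open).
#'
#' @param rate_tables Tibble with columns `force`, `from`, `to`, `k`
#'   (stacked [rates_from_path()] outputs with a `force` column added).
#' @param pair Length-2 vector `c(from, to)`.
#' @param k_w,kBT Passed to [fit_bell()].
#' @return A `bell_fit`.
#' @export
bell_per_transition <- function(rate_tables, pair, k_w = k_attempt(),
                                kBT = kBT_pN_nm()) {
  sel <- rate_tables |>
    filter(.data$from == pair[1], .data$to == pair[2], .data$k > 0)
  if (length(unique(sel$force)) < 3) {
    abort("need rates at >= 3 forces for a per-transition Bell fit")
  }
  fit_bell(tibble(force = sel$force, rate = sel$k), k_w = k_w, kBT = kBT)
}

#' Free-energy differences between connected states
#'
#' At a given force the free-energy difference between two exchanging
#' states follows from the rate ratio, `dG_ij = kBT ln(k_ij / k_ji)` (in
#' kBT units; positive when the i -> j direction is downhill). Pairs
#' missing the reverse rate are skipped.
#'
#' @param rates A [rates_from_path()] table (optionally with a `force`
#'   column; the value is carried through).
#' @return Tibble `from`, `to`, `delta_G` (kBT), antisymmetric under pair
#'   reversal.
#' @export
state_energies_from_rates <- function(rates) {
  out <- rates |>
    mutate(pair_key = paste(pmin(.data$from, .data$to),
                            pmax(.data$from, .data$to)))
  res <- out |>
    group_by(.data$pair_key) |>
    filter(n() == 2, all(.data$k > 0)) |>
    ungroup()
  if (nrow(res) == 0) {
    return(tibble(from = character(0), to = character(0),
                  delta_G = numeric(0)))
  }
  rev_k <- res$k[match(paste(res$to, res$from), paste(res$from, res$to))]
  res |>
    mutate(delta_G = log(.data$k / rev_k)) |>
    select("from", "to", "delta_G")
}
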