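#' Gaussian mixture fit of an extension distribution
#'
#' Decomposes a sample of bead extensions into K Gaussian components by EM
#' (tolerance 1e-8 in log-likelihood, at most 500 iterations), taking the
#' best of `n_restarts` seeded restarts. The first restart starts from
#' `init_means` (or equally spaced quantiles); later restarts jitter the
#' initial means. The EM engine is mclust's unequal-variance univariate
#' model. Components are reported sorted by mean; degenerate solutions
#' (vanishing component sd) are discarded and the fit fails only if every
#' restart degenerates.
#'
#' @param extensions Numeric vector of extensions, nm (or a `snare_trace`,
#'   whose `extension` column is used).
#' @param K Number of components (1-4).
#' @param init_means Optional numeric vector of K starting means.
#' @param equal_var Constrain all components to a common variance. The
#'   per-frame tracking noise is state-independent, so the equal-variance
#'   model is the better-identified choice when components overlap; the
#'   default keeps the general unequal-variance model.
#' @param n_restarts Number of EM restarts.
#' @param seed Integer seed for the restart jitter.
#' @param tol,max_iter EM convergence controls.
#' @return Object of class `gmm_fit`: `components` (tibble `mean`, `sd`,
#'   `weight`), `K`, `logLik`, `n`.
#' @export
fit_gmm <- function(extensions, K, init_means = NULL, equal_var = FALSE,
                    n_restarts = 10, seed = NULL, tol = 1e-8,
                    max_iter = 500) {
  if (inherits(extensions, "data.frame")) extensions <- extensions$extension
  x <- as.numeric(extensions)
  x <- x[is.finite(x)]
  stopifnot(K >= 1, K <= 4)
  if (K == 1) {
    comp <- tibble(mean = mean(x), sd = sd(x), weight = 1)
    ll <- sum(dnorm(x, comp$mean, comp$sd, log = TRUE))
    return(structure(list(components = comp, K = 1L, logLik = ll,
                          n = length(x), data = x), class = "gmm_fit"))
  }
  if (is.null(init_means)) {
    init_means <- unname(stats::quantile(x, probs = (seq_len(K) - 0.5) / K))
  }
  stopifnot(length(init_means) == K)

  .local_seed(seed, {
    best <- NULL
    s0 <- sd(x)
    for (r in seq_len(n_restarts)) {
      mu <- sort(init_means + if (r == 1) 0 else rnorm(K, 0, s0 / 4))
      # soft assignment with a common spread initializes the responsibilities
      dens <- vapply(mu, function(m) dnorm(x, m, s0 / K), numeric(length(x)))
      z <- dens / pmax(rowSums(dens), .Machine$double.xmin)
      em_fun <- if (equal_var) mclust::meE else mclust::meV
      fit <- tryCatch(
        em_fun(data = x, z = z,
               control = mclust::emControl(tol = tol, itmax = max_iter)),
        error = function(e) NULL)
      if (is.null(fit) || is.na(fit$loglik)) next
      sds <- sqrt(fit$parameters$variance$sigmasq)
      if (any(!is.finite(sds)) || any(sds < 1e-6)) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (is.null(best)) abort("persistent degeneracy: no valid EM solution")
    ord <- order(best$parameters$mean)
    sds <- sqrt(best$parameters$variance$sigmasq)
    if (length(sds) == 1) sds <- rep(sds, K)
    comp <- tibble(mean = unname(best$parameters$mean[ord]),
                   sd = unname(sds[ord]),
                   weight = unname(best$parameters$pro[ord]))
    comp$weight <- comp$weight / sum(comp$weight)
    structure(list(components = comp, K = as.integer(K),
                   logLik = best$loglik, n = length(x), data = x),
              class = "gmm_fit")
  })
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit> K = %d, n = %d, logLik = %.1f\n",
              x$K, x$n, x$logLik))
  print(x$components)
  invisible(x)
}
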