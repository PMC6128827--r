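#' Force-dependent populations of the zippered intermediates
#'
#' Fits a Gaussian mixture to each constant-force trace of an equilibrium
#' scan (0.2 pN grid, 12-16 pN; > 15 s per force) and assigns each
#' component to the nearest of the three zippered states (fully zippered,
#' linker-open, half-zippered) within `assign_tol` nm; unassigned
#' components (e.g. the unzipped level) are excluded and the assigned
#' weights renormalized. Below `K3_threshold` pN two components are fitted,
#' at or above it three, matching the observed number of resolvable levels;
#' override via `K_rule`. Grid forces with less than `min_seconds` of data
#' are flagged low-confidence.
#'
#' @param traces List of constant-force `snare_trace`s (one per grid force).
#' @param state_means Named numeric with entries `fully_zippered`,
#'   `linker_open`, `half_zippered`: expected extension level of each state
#'   (nm, same frame as the traces), or a `function(force)` returning such a
#'   vector.
#' @param K_rule Optional `function(force)` returning the number of GMM
#'   components; default 2 below `K3_threshold`, else 3.
#' @param K3_threshold Force (pN) above which three components are fitted.
#' @param assign_tol Maximum |component mean - state level| for assignment,
#'   nm.
#' @param min_seconds Minimum data per grid force, s.
#' @param equal_var Passed to [fit_gmm()]; common component variance by
#'   default, since the tracking noise does not depend on the state.
#' @param n_restarts,seed Passed to [fit_gmm()].
#' @return A tibble of class `population_table`: `force`,
#'   `p_fully_zippered`, `p_linker_open`, `p_half_zippered`, `n_frames`,
#'   `seconds`, `low_confidence`; rows sorted by force, populations summing
#'   to 1.
#' @export
population_scan <- function(traces, state_means, K_rule = NULL,
                            K3_threshold = 13, assign_tol = 2.5,
                            min_seconds = 15, equal_var = TRUE,
                            n_restarts = 10, seed = NULL) {
  if (inherits(traces, "snare_trace")) traces <- list(traces)
  state_names <- c("fully_zippered", "linker_open", "half_zippered")
  rows <- imap(traces, function(tr, id) {
    f <- median(tr$force)
    rate <- trace_sampling_rate(tr)
    means <- if (is.function(state_means)) state_means(f) else state_means
    stopifnot(all(state_names %in% names(means)))
    means <- means[state_names]
    K <- if (is.null(K_rule)) (if (f < K3_threshold) 2L else 3L)
         else K_rule(f)
    K <- min(K, 4L)
    gf <- fit_gmm(tr$extension, K = K, init_means = sort(means)[seq_len(K)],
                  equal_var = equal_var, n_restarts = n_restarts, seed = seed)
    w <- setNames(rep(0, 3), state_names)
    for (i in seq_len(nrow(gf$components))) {
      dist <- abs(gf$components$mean[i] - means)
      j <- which.min(dist)
      if (dist[j] <= assign_tol) w[j] <- w[j] + gf$components$weight[i]
    }
    if (sum(w) <= 0) {
      abort(sprintf("no GMM component within %.1f nm of any state level at %.2f pN",
                    assign_tol, f))
    }
    w <- w / sum(w)
    tibble(force = f,
           p_fully_zippered = w[["fully_zippered"]],
           p_linker_open = w[["linker_open"]],
           p_half_zippered = w[["half_zippered"]],
           n_frames = nrow(tr), seconds = nrow(tr) / rate,
           low_confidence = nrow(tr) / rate < min_seconds)
  })
  out <- list_rbind(rows) |> arrange(.data$force)
  structure(out, class = c("population_table", class(out)),
            condition = attr(traces[[1]], "condition"))
}

.p_cols <- c(fully_zippered = "p_fully_zippered",
             linker_open = "p_linker_open",
             half_zippered = "p_half_zippered")

#' Three-state equilibrium model of the zippered conformations
#'
#' The relative populations of the fully zippered, linker-open and
#' half-zippered states at force F follow Boltzmann weights over
#' force-tilted free energies,
#' `p_i(F) = exp(-(G_i - F x_i)/kBT) / sum_j exp(-(G_j - F x_j)/kBT)`,
#' with the fully zippered state as reference (`G = 0`, `x = 0`). The fit
#' maximizes the multinomial likelihood over the grid forces, using the
#' per-force frame counts as multinomial sizes; starting values come from
#' log-ratio regression. `fix_x` constrains the extension coordinates to
#' given values (e.g. construct-model deltas); by default they are free.
#'
#' @param table A [population_scan()] result (or tibble with `force`,
#'   population and `n_frames` columns).
#' @param fix_x Optional named numeric fixing `linker_open` and/or
#'   `half_zippered` extension coordinates, nm.
#' @param kBT Thermal energy, pN nm.
#' @return Object of class `three_state_model`: `states` tibble (`state`,
#'   `G` in kBT, `x` in nm), `logLik`, fitted populations.
#' @export
fit_three_state <- function(table, fix_x = NULL, kBT = kBT_pN_nm()) {
  stopifnot(all(c("force", .p_cols) %in% names(table)))
  n_eff <- if ("n_frames" %in% names(table)) table$n_frames else
    rep(1000, nrow(table))
  P <- as.matrix(table[, .p_cols])
  F <- table$force
  if (nrow(table) < 3 || max(apply(P, 2, function(p) diff(range(p)))) < 1e-10) {
    abort("non-identifiable: populations do not vary across forces")
  }

  # log-ratio starting values: log(p_i / p_fz) = (-G_i + F x_i)/kBT, so the
  # intercept gives -G_i/kBT and the slope x_i/kBT
  lr <- lapply(2:3, function(i) {
    ok <- P[, i] > 1e-8 & P[, 1] > 1e-8
    if (sum(ok) >= 2) coef(lm(log(P[ok, i] / P[ok, 1]) ~ F[ok]))
    else c(-20, c(5.3, 13.0)[i - 1] / kBT)
  })
  g0 <- vapply(lr, function(cf) -cf[[1]], numeric(1))
  x0 <- vapply(lr, function(cf) cf[[2]] * kBT, numeric(1))

  free_x <- c(is.null(fix_x) || !"linker_open" %in% names(fix_x),
              is.null(fix_x) || !"half_zippered" %in% names(fix_x))
  if (!free_x[1]) x0[1] <- fix_x[["linker_open"]]
  if (!free_x[2]) x0[2] <- fix_x[["half_zippered"]]

  pack <- function(G, x) c(G, x[free_x])
  unpack <- function(par) {
    G <- par[1:2]
    x <- x0
    x[free_x] <- par[-(1:2)]
    list(G = G, x = x)
  }
  # dimensionless tilted energies: G is in kBT, the force tilt F*x in pN nm
  pops <- function(G, x, force) {
    e <- cbind(0, G[1] - force * x[1] / kBT, G[2] - force * x[2] / kBT)
    w <- exp(-(e - apply(e, 1, min)))
    w / rowSums(w)
  }
  nll <- function(par) {
    th <- unpack(par)
    p <- pops(th$G, th$x, F)
    -sum(n_eff * rowSums(P * log(pmax(p, 1e-300))))
  }
  opt <- optim(pack(g0, x0), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  opt <- optim(opt$par, nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  th <- unpack(opt$par)
  fitted <- pops(th$G, th$x, F)
  colnames(fitted) <- .p_cols
  structure(list(
    states = tibble(state = names(.p_cols),
                    G = c(0, th$G), x = c(0, th$x)),
    logLik = -opt$value,
    fitted = as_tibble(cbind(tibble(force = F), as_tibble(fitted))),
    data = as_tibble(table), kBT = kBT,
    fix_x = fix_x, convergence = opt$convergence),
    class = "three_state_model")
}

#' @export
print.three_state_model <- function(x, ...) {
  cat("<three_state_model> (G in kBT at zero force, x in nm)\n")
  print(x$states)
  invisible(x)
}

#' Predicted populations from a three-state model
#'
#' @param model A [fit_three_state()] result, or a list with named numerics
#'   `G` and `x` over the three states.
#' @param force Forces in pN; vectorized.
#' @param kBT Thermal energy, pN nm.
#' @return Tibble with `force` and the three population columns.
#' @export
three_state_populations <- function(model, force, kBT = kBT_pN_nm()) {
  if (inherits(model, "three_state_model")) {
    G <- setNames(model$states$G, model$states$state)
    x <- setNames(model$states$x, model$states$state)
    kBT <- model$kBT
  } else {
    G <- model$G; x <- model$x
  }
  sn <- names(.p_cols)
  e <- outer(force, x[sn], function(f, xi) -f * xi) / kBT
  e <- sweep(e, 2, G[sn], "+")
  w <- exp(-(e - apply(e, 1, min)))
  p <- w / rowSums(w)
  colnames(p) <- .p_cols
  dplyr::bind_cols(tibble(force = force), as_tibble(p))
}

#' Population fold change between conditions
#'
#' Ratio of a state's population between a condition and a reference table
#' at a given grid force, with delta-method uncertainty propagation when the
#' tables carry per-row standard deviations (columns `<p>_sd`).
#'
#' @param table_cond,table_ref [population_scan()] results (or compatible
#'   tibbles).
#' @param force Grid force, pN.
#' @param state One of `"fully_zippered"`, `"linker_open"`,
#'   `"half_zippered"`.
#' @param tol Force matching tolerance, pN.
#' @return Tibble with `state`, `force`, `ratio` and (if sds available)
#'   `se`.
#' @export
fold_change <- function(table_cond, table_ref, force, state, tol = 1e-6) {
  col <- .p_cols[[state]]
  pick <- function(tab) {
    row <- tab[abs(tab$force - force) <= tol + 1e-12, ]
    if (nrow(row) == 0) {
      abort(sprintf("no row at %.2f pN in population table", force))
    }
    row[1, ]
  }
  rc <- pick(table_cond); rr <- pick(table_ref)
  p_c <- rc[[col]]; p_r <- rr[[col]]
  if (p_r <= 0) abort("reference population is zero: fold change undefined")
  out <- tibble(state = state, force = force, ratio = p_c / p_r)
  sd_col <- paste0(col, "_sd")
  if (sd_col %in% names(table_cond) && sd_col %in% names(table_ref)) {
    out$se <- out$ratio *
      sqrt((rc[[sd_col]] / p_c)^2 + (rr[[sd_col]] / p_r)^2)
  }
  out
}
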