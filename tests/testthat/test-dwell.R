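make_jump_trace <- function(step_time = NULL, total = 20, target = 14,
                            rate = 100, sigma = 1, seed = 1) {
  set.seed(seed)
  n <- total * rate
  t <- (seq_len(n) - 1) / rate
  force <- protocol_force(force_protocol(protocol_hold(10, 0.5),
                                         protocol_jump(10, target),
                                         protocol_hold(target, total)), t)
  x <- rnorm(n, 0, sigma)
  if (!is.null(step_time)) x <- x + 25 * (t >= step_time)
  new_snare_trace(tibble::tibble(time = t, force = force, extension = x),
                  sampling_rate = rate)
}

test_that("latency extraction measures, censors, and flags sub-resolution dwells", {
  t_settle <- 0.5 + 0.04 + 0.1   # hold + jump segment + settling transient
  tr_mid <- make_jump_trace(step_time = 3.2, seed = 2)
  tr_none <- make_jump_trace(step_time = NULL, seed = 3)
  tr_instant <- make_jump_trace(step_time = 0.56, seed = 4)
  dw <- extract_latencies(list(tr_mid, tr_none, tr_instant), 14)
  expect_equal(nrow(dw), 3)
  expect_false(dw$censored[1])
  expect_equal(dw$duration[1], 3.2 - t_settle, tolerance = 0.05)
  expect_true(dw$censored[2])
  expect_equal(dw$duration[2], 20 - t_settle, tolerance = 0.2)
  expect_false(dw$censored[3])
  expect_true(dw$sub_resolution[3])
  # a trace that never reaches the target force is skipped with a warning
  flat <- new_snare_trace(tibble::tibble(time = (0:999) / 100, force = 10,
                                         extension = rnorm(1000)),
                          sampling_rate = 100)
  expect_warning(dw2 <- extract_latencies(list(flat), 14), "never settles")
  expect_equal(nrow(dw2), 0)
})

test_that("simulated jump latencies recover the programmed mean", {
  sch <- kinetic_scheme(c("zippered", "unzipped"), tibble::tibble(
    from = "zippered", to = "unzipped", k_ref = 0.5, F_ref = 14,
    delta_x = 0))
  traces <- sim_jump_traces(sch, 14, n = 100, cap = 40, seed = 600)
  dw <- extract_latencies(traces, 14)
  obs <- dw$duration[!dw$censored]
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - 2), 2 * se + 0.05)
})

test_that("censored exponential MLE matches its closed forms", {
  f1 <- fit_exponential_mle(tibble::tibble(duration = c(1, 2, 3),
                                           censored = FALSE),
                            min_uncensored = 3)
  expect_equal(f1$rate, 0.5)
  expect_equal(f1$mean, 2)
  f2 <- fit_exponential_mle(tibble::tibble(duration = c(1, 2, 3),
                                           censored = c(FALSE, FALSE, TRUE)),
                            min_uncensored = 2)
  expect_equal(f2$rate, 2 / 6)
  expect_error(fit_exponential_mle(tibble::tibble(duration = c(2, 3),
                                                  censored = TRUE)),
               "unidentifiable")
  expect_error(fit_exponential_mle(rexp(4)), ">= 5")
})

test_that("profile-likelihood CIs achieve nominal coverage with censoring", {
  k <- 0.3
  cens_at <- stats::qexp(0.9, k)   # ~10% censoring
  cover <- 0L
  for (i in 1:500) {
    set.seed(9000 + i)
    x <- rexp(200, k)
    cens <- x > cens_at
    dw <- tibble::tibble(duration = pmin(x, cens_at), censored = cens)
    fit <- fit_exponential_mle(dw)
    if (fit$conf_low <= k && k <= fit$conf_high) cover <- cover + 1L
  }
  expect_gte(cover / 500, 0.93)
})

test_that("Bell fits reproduce slope and intercept identities", {
  # rates doubling per +1 pN: dx = kBT ln 2
  r <- tibble::tibble(force = c(13, 14, 15), rate = c(0.1, 0.2, 0.4))
  fit <- fit_bell(r)
  expect_equal(fit$delta_x, 4.11 * log(2), tolerance = 1e-9)
  # force-independent rates: dx = 0 and dG = -kBT ln(k / k_w) exactly
  r2 <- tibble::tibble(force = c(13, 14, 15), rate = 0.05)
  fit2 <- fit_bell(r2)
  expect_equal(fit2$delta_x, 0, tolerance = 1e-12)
  expect_equal(fit2$delta_G, -log(0.05 / 1e6), tolerance = 1e-9)
  expect_error(fit_bell(tibble::tibble(force = 14, rate = 1)),
               "rank-deficient")
})

test_that("Bell fits recover pinned parameters under multiplicative noise", {
  true_dx <- 7; true_dG <- 15 + 14 * 7 / 4.11  # zero-force barrier
  forces <- seq(13.6, 14.4, by = 0.2)
  k_true <- 1e6 * exp(-true_dG + forces * true_dx / 4.11)
  est <- vapply(1:500, function(i) {
    set.seed(i)
    obs <- k_true * exp(rnorm(5, 0, 0.15))
    fit_bell(tibble::tibble(force = forces, rate = obs))$delta_x
  }, numeric(1))
  expect_lt(abs(median(est) - true_dx) / true_dx, 0.05)
})

test_that("scheme rates and barrier heights are mutually consistent", {
  edge <- bell_from_barrier(dG = 15, delta_x = 7, F_ref = 14)
  for (f in c(13, 14, 15.5)) {
    expect_equal(barrier_at_force(rate_at_force(edge, f)),
                 15 - (f - 14) * 7 / 4.11, tolerance = 1e-9)
  }
})

test_that("condition differences in barrier height are independent of k_w", {
  k1 <- 0.31; k2 <- 0.31 * exp(-4.3)
  for (kw in c(1e5, 1e6, 1e7)) {
    expect_equal(barrier_at_force(k2, kw) - barrier_at_force(k1, kw), 4.3,
                 tolerance = 1e-12)
  }
})

test_that("landscape reconstruction places states and barriers correctly", {
  forces <- c(13.5, 14, 14.5)
  mk_fit <- function(dG14, dx) {
    fit_bell(tibble::tibble(
      force = forces,
      rate = 1e6 * exp(-(dG14 - (forces - 14) * dx / 4.11))))
  }
  up <- mk_fit(15, 7)
  down_sym <- mk_fit(15, -7)
  ls <- build_landscape(up, down_sym, force = 14)
  expect_equal(ls$energy[ls$label == "zippered"], 0)
  expect_equal(ls$energy[ls$label == "unzipped"], 0, tolerance = 1e-6)
  expect_equal(ls$energy[ls$label == "barrier"], 15, tolerance = 1e-6)
  expect_equal(ls$position[ls$label == "unzipped"], 14, tolerance = 1e-6)
  # inconsistent fits: a negative tilted barrier (rate above k_w) at this force
  expect_error(build_landscape(mk_fit(-1, 7), mk_fit(15, -7), force = 14),
               "below")
})

test_that("Cpx reshapes only the zippered side when rezipping is unchanged", {
  forces <- c(13.5, 14, 14.5)
  mk_fit <- function(dG14, dx) {
    fit_bell(tibble::tibble(
      force = forces,
      rate = 1e6 * exp(-(dG14 - (forces - 14) * dx / 4.11))))
  }
  rezip <- mk_fit(16.5, -5)
  ctrl <- build_landscape(mk_fit(15, 7), rezip, 14, anchor = "unzipped")
  cpx <- build_landscape(mk_fit(19.3, 7), rezip, 14, anchor = "unzipped")
  expect_equal(cpx$energy[cpx$label == "unzipped"],
               ctrl$energy[ctrl$label == "unzipped"])
  # the Cpx zippered well sits 4.3 kBT below the control well
  expect_equal(ctrl$energy[ctrl$label == "zippered"] -
                 cpx$energy[cpx$label == "zippered"], 4.3,
               tolerance = 1e-6)
  expect_equal(cpx$energy[cpx$label == "barrier"] -
                 ctrl$energy[ctrl$label == "barrier"], 0, tolerance = 1e-6)
})

test_that("simulate-extract-fit recovers the generating Bell parameters", {
  true_dx <- 7
  forces <- c(13.8, 14, 14.2)
  sch <- scheme_two_state("none", dx_unzip = true_dx)
  in_region <- 0L
  n_rep <- 15
  for (rep in seq_len(n_rep)) {
    rates <- purrr::map(seq_along(forces), function(j) {
      fit <- jump_rate_at(sch, forces[j], n = 19, cap = 40,
                          seed = rep * 1000 + j * 100)
      tibble::tibble(force = forces[j], rate = fit$rate,
                     conf_low = fit$conf_low, conf_high = fit$conf_high)
    }) |> purrr::list_rbind()
    bf <- fit_bell(rates)
    # Wald ellipse in (intercept, slope) of the log-rate regression
    b <- stats::coef(bf$fit)
    truth <- c(-(15 + 14 * true_dx / 4.11), true_dx / 4.11)
    dlt <- b - truth
    stat <- drop(t(dlt) %*% solve(bf$vcov) %*% dlt)
    if (stat <= stats::qchisq(0.95, df = 2)) in_region <- in_region + 1L
  }
  expect_gte(in_region, round(0.6 * n_rep))
})

test_that("end-to-end barrier recovery hits the programmed landscape", {
  sch <- scheme_two_state("none")
  forces <- c(13.8, 14, 14.2)
  rates <- purrr::map(seq_along(forces), function(j) {
    fit <- jump_rate_at(sch, forces[j], n = 25, cap = 40, seed = 31 + j)
    tibble::tibble(force = forces[j], rate = fit$rate,
                   conf_low = fit$conf_low, conf_high = fit$conf_high)
  }) |> purrr::list_rbind()
  bf <- fit_bell(rates)
  expect_lt(abs(bell_barrier(bf, 14) - 15), 1)
})
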