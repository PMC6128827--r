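two_level_path <- function(n_dwell = 50, n_cycles = 40) {
  rep(rep(c(1L, 2L), n_cycles), each = n_dwell)
}

test_that("noiseless two-level traces are idealized and counted exactly", {
  path <- two_level_path()
  x <- c(0, 10)[path]
  init <- tibble::tibble(mean = c(0, 10), sd = c(0.5, 0.5),
                         weight = c(0.5, 0.5))
  fit <- fit_hmm(x, init, fix_means = TRUE, fix_sds = TRUE)
  vp <- viterbi_path(fit, x)
  expect_identical(as.integer(vp), path)
  # off-diagonal transition probability = transitions / frames in state
  n_trans <- sum(path[-length(path)] == 1 & path[-1] == 2)
  frames_1 <- sum(path == 1)
  expect_equal(fit$A[1, 2], n_trans / frames_1, tolerance = 0.05)
  rt <- rates_from_path(vp, sampling_rate = 1000)
  expect_equal(rt$k[rt$from == 1 & rt$to == 2],
               n_trans / (frames_1 / 1000))
})

test_that("paper-grade three-state traces are >= 95% frame-accurate", {
  tr <- simulate_trace(demo_scheme(), force_protocol(protocol_hold(14, 15)),
                       demo_offsets, sampling_rate = 1200, seed = 23)
  g <- fit_gmm(tr, K = 3, init_means = c(0, 5.3, 13.0), seed = 1)
  h <- fit_hmm(tr, g)
  vp <- viterbi_path(h, tr)
  truth <- match(tr$state, c("fully_zippered", "linker_open",
                             "half_zippered"))
  expect_gte(mean(vp == truth), 0.95)
})

test_that("idealization accuracy degrades as noise grows", {
  acc <- vapply(c(1, 3.5, 6), function(sigma) {
    tr <- simulate_trace(demo_scheme(), force_protocol(protocol_hold(14, 10)),
                         demo_offsets, sampling_rate = 1200, seed = 31,
                         noise = noise_model(sigma = sigma))
    init <- tibble::tibble(mean = c(0, 5.3, 13.0), sd = sigma,
                           weight = c(1, 1, 1) / 3)
    h <- fit_hmm(tr, init)
    truth <- match(tr$state, c("fully_zippered", "linker_open",
                               "half_zippered"))
    mean(viterbi_path(h, tr) == truth)
  }, numeric(1))
  expect_true(all(diff(acc) < 0))
})

test_that("degenerate models error or warn appropriately", {
  expect_error(fit_hmm(rnorm(100), tibble::tibble(mean = 0, sd = 1,
                                                  weight = 1)),
               "kinetics")
  init <- tibble::tibble(mean = c(0, 10), sd = c(1, 1), weight = c(0.5, 0.5))
  fit <- fit_hmm(c(rnorm(200), rnorm(200, 10)), init)
  expect_warning(viterbi_path(fit, rnorm(100, 500)), "scale mismatch")
  # single-state model gives a constant path
  one <- list(states = tibble::tibble(state = 1, mean = 0, sd = 1))
  expect_identical(viterbi_path(one, rnorm(50)), rep(1L, 50))
})

test_that("dwell counting recovers rates inside the reliable band", {
  # plain arithmetic: 10 transitions over 5 s in the source state
  path <- rep(c(rep(1L, 600), rep(2L, 120)), 10)   # at 1200 Hz
  rt <- rates_from_path(path, 1200)
  expect_equal(rt$k[rt$from == 1 & rt$to == 2], 10 / 5, tolerance = 1e-12)
  # k = 100 /s at 1.2 kHz recovered within 15% through the full pipeline
  sch <- kinetic_scheme(c("a", "b"), tibble::tibble(
    from = c("a", "b"), to = c("b", "a"), k_ref = 100, F_ref = 14,
    delta_x = 0))
  tr <- simulate_trace(sch, force_protocol(protocol_hold(14, 20)),
                       c(a = 0, b = 25), sampling_rate = 1200, seed = 77)
  g <- fit_gmm(tr, K = 2, init_means = c(0, 25), seed = 1)
  h <- fit_hmm(tr, g)
  rt2 <- rates_from_path(viterbi_path(h, tr), 1200)
  for (k_hat in rt2$k) expect_lt(abs(k_hat - 100) / 100, 0.15)
  expect_true(all(rt2$reliable))
  # rates above the 1-1e3 /s band are flagged unreliable
  fast <- rep(c(1L, 2L), 3000)
  rt3 <- rates_from_path(fast, 1200)
  expect_true(all(!rt3$reliable))
  expect_true(all(rt3$k > 1000))
})

test_that("refitting data simulated from a fitted model is self-consistent", {
  tr <- simulate_trace(demo_scheme(), force_protocol(protocol_hold(14, 10)),
                       demo_offsets, sampling_rate = 1200, seed = 41)
  g <- fit_gmm(tr, K = 3, init_means = c(0, 5.3, 13.0), seed = 1)
  h1 <- fit_hmm(tr, g)
  # regenerate a trace from the fitted chain and emissions
  set.seed(8)
  n <- nrow(tr)
  s <- integer(n); s[1] <- sample(3, 1, prob = h1$pi)
  for (t in 2:n) s[t] <- sample(3, 1, prob = h1$A[s[t - 1], ])
  x <- rnorm(n, h1$states$mean[s], h1$states$sd[s])
  h2 <- fit_hmm(x, tibble::tibble(mean = h1$states$mean, sd = h1$states$sd,
                                  weight = h1$pi))
  expect_equal(h2$states$mean, h1$states$mean, tolerance = 0.01)
  expect_lt(max(abs(diag(h2$A) - diag(h1$A))), 0.02)
})

test_that("per-transition Bell fits extrapolate and keep their sign conventions", {
  # exact Bell rates: extrapolation to F = 0 returns the closed form
  dx <- 3.7; k14 <- 120
  forces <- c(13.5, 14, 14.5)
  tabs <- tibble::tibble(force = forces, from = "linker_open",
                         to = "half_zippered",
                         k = k14 * exp((forces - 14) * dx / 4.11))
  bf <- bell_per_transition(tabs, c("linker_open", "half_zippered"))
  expect_equal(bf$delta_x, dx, tolerance = 1e-6)
  expect_equal(bell_rate(bf, 0), k14 * exp(-14 * dx / 4.11),
               tolerance = 1e-6)
  # zippering rates decrease with force: negative slope
  tabs2 <- tibble::tibble(force = forces, from = "linker_open",
                          to = "fully_zippered",
                          k = 400 * exp(-(forces - 14) * 2.8 / 4.11))
  bf2 <- bell_per_transition(tabs2, c("linker_open", "fully_zippered"))
  expect_lt(bf2$delta_x, 0)
  expect_error(bell_per_transition(tabs[1:2, ],
                                   c("linker_open", "half_zippered")),
               "3 forces")
})

test_that("pipeline Bell fits recover the pinned per-pair parameters", {
  # slow-exchange regime (8 /s, dwells ~150 frames) where dwell counting is
  # well inside the reliable band; the force-accelerated pair still carries
  # a systematic occupancy-misattribution bias and gets a wider band
  sch <- demo_scheme(k_exchange = 8)
  forces <- c(13.2, 14, 14.8)
  est <- purrr::map(1:5, function(rep) {
    tabs <- purrr::map(forces, function(f) {
      tr <- simulate_trace(sch, force_protocol(protocol_hold(f, 30)),
                           demo_offsets, sampling_rate = 1200,
                           seed = rep * 977 + round(f * 10))
      init <- tibble::tibble(mean = c(0, 5.3, 13.0), sd = 2.5,
                             weight = c(1, 1, 1) / 3)
      h <- fit_hmm(tr, init)
      vp <- viterbi_path(h, tr)
      rates_from_path(vp, 1200) |> dplyr::mutate(force = f)
    }) |> purrr::list_rbind()
    c(bell_per_transition(tabs, c(1L, 2L))$delta_x,
      bell_per_transition(tabs, c(2L, 1L))$delta_x)
  })
  est <- do.call(rbind, est)
  r <- scheme_rates(sch, 14)
  dx_fz_lo <- r$delta_x[r$from == "fully_zippered" & r$to == "linker_open"]
  dx_lo_fz <- r$delta_x[r$from == "linker_open" & r$to == "fully_zippered"]
  expect_lt(abs(median(est[, 2]) - dx_lo_fz) / abs(dx_lo_fz), 0.10)
  expect_lt(abs(median(est[, 1]) - dx_fz_lo) / abs(dx_fz_lo), 0.25)
  expect_gt(median(est[, 1]), 0)   # unzipping accelerated by force
  expect_lt(median(est[, 2]), 0)   # zippering opposed by force
})

test_that("free-energy differences from rates are antisymmetric and close cycles", {
  rt <- tibble::tibble(from = c("a", "b"), to = c("b", "a"),
                       k = c(exp(1) * 5, 5))
  dg <- state_energies_from_rates(rt)
  expect_equal(dg$delta_G[dg$from == "a"], 1, tolerance = 1e-12)
  expect_equal(dg$delta_G[dg$from == "a"], -dg$delta_G[dg$from == "b"])
  rt2 <- tibble::tibble(from = "a", to = "b", k = 5)
  expect_equal(nrow(state_energies_from_rates(rt2)), 0)
  # exact scheme rates invert to the programmed tilted energies
  sch <- scheme_three_state("none")
  r <- scheme_rates(sch, 14) |> dplyr::rename(k_exact = k)
  dg2 <- state_energies_from_rates(dplyr::mutate(r, k = k_exact))
  ls <- attr(sch, "landscape")
  g14 <- ls$energies - 14 * ls$positions / 4.11
  expect_equal(
    dg2$delta_G[dg2$from == "fully_zippered" & dg2$to == "linker_open"],
    g14[["fully_zippered"]] - g14[["linker_open"]], tolerance = 1e-9)
  # cycle closure on an estimated path
  tr <- simulate_trace(sch, force_protocol(protocol_hold(14.6, 15)),
                       demo_offsets, sampling_rate = 1200, seed = 55)
  init <- tibble::tibble(mean = c(0, 5.3, 13.0), sd = 2.5,
                         weight = c(1, 1, 1) / 3)
  h <- fit_hmm(tr, init)
  rt3 <- rates_from_path(viterbi_path(h, tr), 1200)
  dg3 <- state_energies_from_rates(rt3)
  cyc <- dg3$delta_G[dg3$from == 1 & dg3$to == 2] +
    dg3$delta_G[dg3$from == 2 & dg3$to == 3] +
    (if (any(dg3$from == 3 & dg3$to == 1)) {
      dg3$delta_G[dg3$from == 3 & dg3$to == 1]
    } else {
      -(dg3$delta_G[dg3$from == 1 & dg3$to == 3])
    })
  skip_if(!any(dg3$from == 3 & dg3$to == 1) &&
            !any(dg3$from == 1 & dg3$to == 3),
          "no direct 1-3 exchanges observed")
  expect_lt(abs(cyc), 0.6)
})

test_that("HMM rates agree with dwell-based rates for slow kinetics", {
  sch <- kinetic_scheme(c("a", "b"), tibble::tibble(
    from = c("a", "b"), to = c("b", "a"), k_ref = 1.5, F_ref = 14,
    delta_x = 0))
  tr <- simulate_trace(sch, force_protocol(protocol_hold(14, 150)),
                       c(a = 0, b = 25), sampling_rate = 1200, seed = 66)
  g <- fit_gmm(tr, K = 2, init_means = c(0, 25), seed = 1)
  h <- fit_hmm(tr, g)
  vp <- viterbi_path(h, tr)
  rt <- rates_from_path(vp, 1200)
  # dwell-duration route: segment the idealized path into dwells and fit
  runs <- rle(as.integer(vp))
  for (s in 1:2) {
    durs <- runs$lengths[runs$values == s] / 1200
    durs <- durs[-length(durs)]   # drop the open final dwell
    ef <- fit_exponential_mle(tibble::tibble(duration = durs,
                                             censored = FALSE))
    k_hmm <- rt$k[rt$from == s]
    expect_lt(abs(k_hmm - ef$rate) / ef$rate, 0.1)
  }
})

test_that("Cpx shifts the four transition rates in the observed directions", {
  none <- scheme_three_state("none")
  wt <- scheme_three_state("WT")
  k <- function(sch, f, from, to) {
    r <- scheme_rates(sch, f)
    r$k[r$from == from & r$to == to]
  }
  for (f in c(13.5, 14, 14.5, 15)) {
    # C-terminal zippering accelerated, C-terminal unzipping suppressed
    expect_gt(k(wt, f, "half_zippered", "linker_open"),
              k(none, f, "half_zippered", "linker_open"))
    expect_lt(k(wt, f, "linker_open", "half_zippered"),
              k(none, f, "linker_open", "half_zippered"))
    # linker zippering decelerated, linker unzipping roughly unchanged
    expect_lt(k(wt, f, "linker_open", "fully_zippered"),
              k(none, f, "linker_open", "fully_zippered"))
    expect_equal(k(wt, f, "fully_zippered", "linker_open"),
                 k(none, f, "fully_zippered", "linker_open"),
                 tolerance = 0.05)
  }
  # and the pipeline sees the C-terminal unzipping suppression
  rate_lo_hz <- function(sch, seed) {
    tr <- simulate_trace(sch, force_protocol(protocol_hold(14.6, 12)),
                         demo_offsets, sampling_rate = 1200, seed = seed)
    init <- tibble::tibble(mean = c(0, 5.3, 13.0), sd = 2.5,
                           weight = c(1, 1, 1) / 3)
    h <- fit_hmm(tr, init)
    rt <- rates_from_path(viterbi_path(h, tr), 1200)
    hit <- rt$k[rt$from == 2 & rt$to == 3]
    if (length(hit) == 0) 0 else hit
  }
  expect_lt(rate_lo_hz(wt, 91), 0.5 * rate_lo_hz(none, 92))
})
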