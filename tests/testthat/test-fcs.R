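# One moderately long simulated trace is shared by several blocks below.
shared_trace <- NULL
get_shared_trace <- function() {
  if (is.null(shared_trace)) {
    spec <- fcs_sim_spec(12, alpha = 1, mean_molecules_in_volume = 2,
                         brightness = 2e4, bin_width = 1e-5, duration = 10)
    shared_trace <<- simulate_fcs_trace(spec, focal_volume(0.25, 1.25),
                                        seed = 99)
  }
  shared_trace
}

test_that("anomalous ACF model at alpha = 1 equals the normal model pointwise", {
  tau <- 10^seq(-6, 0, length.out = 200)
  expect_equal(acf_model_anomalous(tau, 2.6, 1.3e-3, 1, 1 / 25),
               acf_model_normal(tau, 2.6, 1.3e-3, 1 / 25),
               tolerance = 1e-15)
})

test_that("ACF models have amplitude 1/N and decay monotonically", {
  for (a in c(0.5, 1)) {
    g <- acf_model_anomalous(10^seq(-12, 1, length.out = 300), 2, 1e-3, a, 0.04)
    expect_equal(g[1], 0.5, tolerance = 1e-3)
    expect_true(all(diff(g) < 0))
  }
})

test_that("multi-tau correlator agrees with the direct correlation oracle", {
  set.seed(7)
  counts <- stats::rpois(4096, 2 + 1.5 * sin(2 * pi * seq_len(4096) / 200))
  acf <- multitau_acf(counts, bin_width = 1e-4)
  # level 0: exact agreement at the linear channels
  lvl0 <- acf[acf$level == 0, ]
  want <- direct_acf(counts, round(lvl0$lag / 1e-4))
  expect_equal(lvl0$g, want, tolerance = 1e-12)
  # deeper levels: direct correlation of the independently binned trace
  binned <- (counts[seq(1, 4096, 2)] + counts[seq(2, 4096, 2)]) / 2
  lvl1 <- acf[acf$level == 1, ]
  want1 <- direct_acf(binned, round(lvl1$lag / 2e-4))
  expect_equal(lvl1$g, want1, tolerance = 1e-12)
})

test_that("constant traces give identically zero correlation", {
  acf <- multitau_acf(rep(5L, 2000), bin_width = 1e-4)
  expect_true(all(acf$g == 0))
  expect_error(multitau_acf(rep(5L, 100), bin_width = 1e-4), "at least 1000")
})

test_that("photobleaching gate rejects decaying traces and accepts stationary ones", {
  set.seed(21)
  n <- 10 / 1e-3
  flat <- stats::rpois(n, 50)
  expect_true(exclude_photobleaching(flat, bin_width = 1e-3)$accept)
  decaying <- stats::rpois(n, 50 * seq(1, 0.5, length.out = n))
  verdict <- exclude_photobleaching(decaying, bin_width = 1e-3)
  expect_false(verdict$accept)
  expect_gt(verdict$decay_fraction, 0.2)
  # false-positive rate on repeated stationary traces
  accepts <- vapply(1:10, function(i) {
    exclude_photobleaching(stats::rpois(n, 30), bin_width = 1e-3)$accept
  }, TRUE)
  expect_gte(mean(accepts), 0.95)
  expect_error(exclude_photobleaching(stats::rpois(100, 5), bin_width = 1e-3),
               "at least 5 s")
})

test_that("model fits recover noiseless synthetic parameters to 1e-6", {
  tau <- 10^seq(-5.5, -0.5, length.out = 60)
  curve_n <- tibble::tibble(lag = tau,
                            g = acf_model_normal(tau, 2, 1e-3, 1 / 25),
                            g_se = NA_real_)
  fit <- fit_acf_normal(curve_n, structure = 1 / 25,
                        lag_range = range(tau))
  expect_true(fit$converged)
  expect_equal(fit$n_molecules, 2, tolerance = 1e-6)
  expect_equal(fit$tau_d, 1e-3, tolerance = 1e-6)
  expect_equal(fit$g0, 0.5, tolerance = 1e-6)
  curve_a <- tibble::tibble(lag = tau,
                            g = acf_model_anomalous(tau, 3, 2e-3, 0.61, 1 / 25),
                            g_se = NA_real_)
  fita <- fit_acf_anomalous(curve_a, structure = 1 / 25,
                            lag_range = range(tau))
  expect_equal(fita$n_molecules, 3, tolerance = 1e-6)
  expect_equal(fita$tau_d, 2e-3, tolerance = 1e-6)
  expect_equal(fita$alpha, 0.61, tolerance = 1e-6)
  # fitting the anomalous model to a Brownian curve lands on alpha = 1
  fitab <- fit_acf_anomalous(curve_n, structure = 1 / 25,
                             lag_range = range(tau))
  expect_equal(fitab$alpha, 1, tolerance = 1e-4)
})

test_that("simulated Brownian trace yields the analytic residence time and amplitude", {
  trace <- get_shared_trace()
  expect_true(exclude_photobleaching(trace)$accept)
  acf <- multitau_acf(trace)
  fit <- fit_acf_normal(acf, structure = 0.04, w0 = 0.25)
  expect_true(fit$converged)
  # tau_d = w0^2 / (4 D) = 1.30 ms
  expect_lt(abs(fit$tau_d - 1.302e-3) / 1.302e-3, 0.15)
  # amplitude: g0 = 1/N with N = 2 expected in the effective volume
  expect_lt(abs(fit$g0 - 0.5) / 0.5, 0.20)
  fita <- fit_acf_anomalous(acf, structure = 0.04, w0 = 0.25)
  expect_gte(fita$alpha, 0.90)
  expect_lte(fita$alpha, 1.15)
})

test_that("static emitters produce a flat fluctuation ACF", {
  spec <- fcs_sim_spec(0, mean_molecules_in_volume = 2, brightness = 5e4,
                       bin_width = 1e-4, duration = 5)
  trace <- simulate_fcs_trace(spec, focal_volume(0.25, 1.25), seed = 3)
  acf <- multitau_acf(trace)
  early <- acf$g[acf$lag <= 0.01]
  # no molecular dynamics: only uncorrelated shot noise, so the
  # fluctuation ACF is zero at every positive lag up to estimator noise
  expect_true(all(abs(early) < 0.02))
  # brightness zero gives an all-zero trace
  dark <- fcs_sim_spec(1, brightness = 0, bin_width = 1e-4, duration = 1)
  expect_true(all(simulate_fcs_trace(dark, seed = 1)$counts == 0))
})

test_that("number of molecules inverts the amplitude", {
  expect_equal(number_of_molecules(0.5), 2)
  expect_equal(number_of_molecules(1 / 2.6), 2.6, tolerance = 1e-12)
  fit <- list(g0 = 0.25, converged = TRUE)
  class(fit) <- "fcs_fit"
  expect_equal(number_of_molecules(fit), 4)
  expect_warning(n <- number_of_molecules(-1), "undefined")
  expect_true(is.na(n))
  # round trip N -> model -> G(0) -> N
  g0 <- acf_model_normal(1e-12, 3.7, 1e-3, 0.04)
  expect_equal(number_of_molecules(g0), 3.7, tolerance = 1e-6)
})

test_that("effective volume follows the amplitude-concentration identity", {
  # 10 nM is 6.022 molecules/um^3; g0 = 1/3.011 gives 0.5 um^3
  expect_equal(effective_volume(1 / 3.011, 1e-8), 0.5, tolerance = 1e-3)
  v1 <- effective_volume(0.4, 1e-8)
  expect_equal(effective_volume(0.4, 2e-8), v1 / 2, tolerance = 1e-12)
  # V_eff * (N_A c) * g0 = 1
  expect_equal(v1 * (1e-8 * 6.02214076e23 / 1e15) * 0.4, 1, tolerance = 1e-12)
})

test_that("focal volume calibration converts residence time to beam waists", {
  fit <- list(g0 = 1 / 3.011, n_molecules = 3.011, tau_d = 29.1e-6,
              alpha = 1, structure = 1 / 25, converged = TRUE)
  class(fit) <- "fcs_fit"
  cal <- calibrate_focal_volume(fit, reference_d = 536, concentration = 1e-8)
  expect_equal(cal$w0, sqrt(4 * 536 * 29.1e-6), tolerance = 1e-12)
  expect_equal(cal$w0, 0.2498, tolerance = 1e-3)
  expect_equal(cal$z0, cal$w0 * 5, tolerance = 1e-12)
  expect_equal(cal$v_eff, 0.5, tolerance = 1e-3)
  # quadrupling the reference D doubles w0
  cal4 <- calibrate_focal_volume(fit, reference_d = 4 * 536,
                                 concentration = 1e-8)
  expect_equal(cal4$w0, 2 * cal$w0, tolerance = 1e-12)
  fit$alpha <- 0.8
  expect_warning(calibrate_focal_volume(fit), "deviates")
})

test_that("end-to-end calibration recovers a known beam waist", {
  vol <- focal_volume(0.25, 1.25)
  spec <- fcs_sim_spec(536, mean_molecules_in_volume = 3,
                       brightness = 5e4, bin_width = 1e-6, duration = 1)
  trace <- simulate_fcs_trace(spec, vol, seed = 55)
  acf <- multitau_acf(trace, max_lag = 0.01)
  fit <- fit_acf_normal(acf, structure = (vol$w0 / vol$z0)^2,
                        lag_range = c(2e-6, 0.01))
  conc <- 3 / vol$v_eff / (6.02214076e23 / 1e15) # mol/L matching the truth
  cal <- calibrate_focal_volume(fit, reference_d = 536, concentration = conc)
  expect_lt(abs(cal$w0 - 0.25) / 0.25, 0.10)
})

test_that("concentration bookkeeping from a fit", {
  fit <- list(g0 = 1 / 2.6, n_molecules = 2.6, converged = TRUE)
  class(fit) <- "fcs_fit"
  out <- concentration_from_fit(fit, v_eff = 0.186)
  expect_equal(out$molecules_per_um3, 2.6 / 0.186, tolerance = 1e-12)
  expect_equal(out$molecules_per_um3, 14.0, tolerance = 0.01)
  # round trip: density * v_eff = N
  expect_equal(out$molecules_per_um3 * 0.186, 2.6, tolerance = 1e-12)
  zero <- concentration_from_fit(0, v_eff = 0.2)
  expect_equal(zero$molecules_per_um3, 0)
})
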