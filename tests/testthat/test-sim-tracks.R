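test_that("identical seeds give bit-identical trajectories", {
  cfg <- sim_config(n_tracks = 20)
  a <- simulate_brownian_tracks(1, cfg, seed = 42)
  b <- simulate_brownian_tracks(1, cfg, seed = 42)
  expect_identical(a, b)
  fa <- simulate_fbm_tracks(0.1, 0.6, cfg, seed = 42)
  fb <- simulate_fbm_tracks(0.1, 0.6, cfg, seed = 42)
  expect_identical(fa, fb)
})

test_that("zero diffusion and zero noise give constant tracks", {
  cfg <- sim_config(n_tracks = 5, localization_sigma = 0)
  tr <- simulate_brownian_tracks(0, cfg, seed = 1)
  spread <- tapply(tr$x, tr$track_id, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("Brownian single-step moment matches 4 D dt within 3 SE", {
  cfg <- sim_config(n_tracks = 1000, localization_sigma = 0)
  tr <- simulate_brownian_tracks(1, cfg, seed = 7)
  steps <- dplyr::group_by(tr, track_id)
  steps <- dplyr::summarise(steps, dx = list(diff(x)), dy = list(diff(y)))
  d2 <- unlist(Map(function(a, b) a^2 + b^2, steps$dx, steps$dy))
  se <- stats::sd(d2) / sqrt(length(d2))
  expect_lt(abs(mean(d2) - 0.04), 3 * se)
})

test_that("localization noise adds 4 sigma^2 to the lag-1 ensemble MSD", {
  cfg <- sim_config(n_tracks = 1000, localization_sigma = 0.05)
  tr <- simulate_brownian_tracks(1, cfg, seed = 8)
  steps <- dplyr::group_by(tr, track_id)
  steps <- dplyr::summarise(steps, dx = list(diff(x)), dy = list(diff(y)))
  d2 <- unlist(Map(function(a, b) a^2 + b^2, steps$dx, steps$dy))
  se <- stats::sd(d2) / sqrt(length(d2))
  # lag-1 MSD = 4 d dt + 4 sigma^2 + ... = 0.04 + 0.01, noise doubles in a
  # difference so the offset is 2 * 2 sigma^2
  expect_lt(abs(mean(d2) - 0.05), 3 * se)
})

test_that("track lengths follow the truncated geometric photobleaching law", {
  cfg <- sim_config(n_tracks = 4000)
  tr <- simulate_brownian_tracks(0.5, cfg, seed = 9)
  lens <- as.integer(table(tr$track_id))
  expect_true(all(lens >= 11))
  # conditioned geometric: mean = min - 1 + mean_track_length = 30
  expect_lt(abs(mean(lens) - 30), 3 * stats::sd(lens) / sqrt(length(lens)))
})

test_that("fGn Cholesky factor reproduces the closed-form fBm covariance", {
  d <- 0.02
  alpha <- 0.31
  dt <- 0.01
  lk <- sptfcs:::fgn_chol(3, d, alpha, dt)
  sigma_inc <- lk %*% t(lk)
  # map increment covariance to position covariance at t = dt, 2dt, 3dt
  A <- lower.tri(matrix(1, 3, 3), diag = TRUE) * 1
  sigma_pos <- A %*% sigma_inc %*% t(A)
  times <- (1:3) * dt
  expected <- outer(times, times, fbm_cov_closed, d = d, alpha = alpha)
  expect_equal(unname(sigma_pos), expected, tolerance = 1e-8)
})

test_that("fBm increments at alpha = 1 are uncorrelated", {
  inc <- sptfcs:::fgn_davies_harte(1e5, 0.5, 1, 0.01)
  rho <- stats::cor(inc[-1], inc[-length(inc)])
  expect_lt(abs(rho), 0.02)
})

test_that("Davies-Harte sampler matches the fGn covariance", {
  set.seed(11)
  n <- 5
  reps <- 20000
  X <- t(replicate(reps, cumsum(sptfcs:::fgn_davies_harte(n, 0.5, 0.6, 0.01))))
  emp <- stats::cov(X)
  times <- (1:n) * 0.01
  expected <- outer(times, times, fbm_cov_closed, d = 0.5, alpha = 0.6)
  expect_lt(max(abs(emp - expected)) / max(expected), 0.05)
})

test_that("fBm self-similarity: MSD rescales as c^alpha", {
  cfg <- sim_config(n_tracks = 2000, localization_sigma = 0,
                    mean_track_length = 30)
  for (alpha in c(0.5, 1.4)) {
    tr <- simulate_fbm_tracks(0.1, alpha, cfg, seed = 13)
    est <- dplyr::group_by(tr, track_id)
    msd24 <- dplyr::summarise(est,
      m2 = mean((x[-(1:2)] - x[1:(dplyr::n() - 2)])^2 +
                (y[-(1:2)] - y[1:(dplyr::n() - 2)])^2),
      m4 = if (dplyr::n() > 4)
        mean((x[-(1:4)] - x[1:(dplyr::n() - 4)])^2 +
             (y[-(1:4)] - y[1:(dplyr::n() - 4)])^2) else NA_real_)
    ratio <- mean(msd24$m4, na.rm = TRUE) / mean(msd24$m2)
    expect_equal(ratio, 2^alpha, tolerance = 0.02 * 2^alpha)
  }
})

test_that("ensemble log-log MSD slope recovers a subdiffusive exponent", {
  cfg <- sim_config(n_tracks = 1500, localization_sigma = 0,
                    mean_track_length = 25)
  tr <- simulate_fbm_tracks(0.02, 0.31, cfg, seed = 21)
  ens <- dplyr::group_by(tr, track_id)
  lags <- 1:6
  msd_by_lag <- vapply(lags, function(n) {
    g <- dplyr::summarise(ens, m = if (dplyr::n() > n)
      mean((x[-(1:n)] - x[1:(dplyr::n() - n)])^2 +
           (y[-(1:n)] - y[1:(dplyr::n() - n)])^2) else NA_real_)
    mean(g$m, na.rm = TRUE)
  }, 0.0)
  slope <- stats::coef(stats::lm(log(msd_by_lag) ~ log(lags * 0.01)))[2]
  expect_equal(unname(slope), 0.31, tolerance = 0.03 / 0.31)
})

test_that("alpha outside (0, 2] is rejected", {
  cfg <- sim_config(n_tracks = 2)
  expect_error(simulate_fbm_tracks(0.1, 0, cfg), "must lie in \\(0, 2\\]")
  expect_error(simulate_fbm_tracks(0.1, 2.1, cfg), "must lie in \\(0, 2\\]")
})

test_that("mixing honours fractions within one track and keeps truth labels", {
  cfg <- sim_config(n_tracks = 300)
  a <- simulate_brownian_tracks(1, cfg, label = "a", seed = 1)
  b <- simulate_brownian_tracks(0.1, cfg, label = "b", seed = 2)
  mixed <- mix_track_sets(list(a, b), c(0.5, 0.5), n_total = 500, seed = 3)
  per_track <- dplyr::distinct(mixed, track_id, truth_label)
  counts <- table(per_track$truth_label)
  expect_equal(length(unique(mixed$track_id)), 500)
  expect_lte(abs(counts[["a"]] - 250), 1)
  expect_lte(abs(counts[["b"]] - 250), 1)
  # labels partition: every track has exactly one label
  expect_equal(nrow(per_track), 500)
})

test_that("degenerate mixing fractions reduce to a one-set subsample", {
  cfg <- sim_config(n_tracks = 50)
  a <- simulate_brownian_tracks(1, cfg, label = "a", seed = 1)
  b <- simulate_brownian_tracks(0.1, cfg, label = "b", seed = 2)
  mixed <- mix_track_sets(list(a, b), c(1, 0), n_total = 30, seed = 3)
  expect_true(all(mixed$truth_label == "a"))
  expect_error(mix_track_sets(list(a, b), c(0.5, 0.5), n_total = 200),
               "exceeds available")
  expect_error(mix_track_sets(list(a, b), c(0.7, 0.7)), "must sum to 1")
})

test_that("mixed subsets preserve the per-label step distribution", {
  cfg <- sim_config(n_tracks = 400)
  a <- simulate_brownian_tracks(1, cfg, label = "a", seed = 5)
  b <- simulate_brownian_tracks(0.2, cfg, label = "b", seed = 6)
  mixed <- mix_track_sets(list(a, b), c(0.5, 0.5), n_total = 400, seed = 7)
  step_sq <- function(tr) {
    g <- dplyr::group_by(tr, track_id)
    s <- dplyr::summarise(g, v = mean(diff(x)^2 + diff(y)^2))
    s$v
  }
  ks <- suppressWarnings(
    stats::ks.test(step_sq(mixed[mixed$truth_label == "a", ]),
                   step_sq(a))$statistic)
  expect_lt(unname(ks), 0.1)
})

test_that("RPB1-like mixture has the configured composition", {
  cfg <- sim_config(n_tracks = 200)
  tr <- simulate_rpb1_like_mixture(cfg, seed = 4)
  per_track <- dplyr::distinct(tr, track_id, truth_label)
  counts <- table(per_track$truth_label)
  expect_equal(sum(counts), 200)
  expect_equal(unname(counts[["immobile"]]), 40)
  expect_equal(unname(counts[["subdiffusive"]]), 110)
  expect_equal(unname(counts[["mobile"]]), 50)
  expect_identical(tr, simulate_rpb1_like_mixture(cfg, seed = 4))
  expect_error(
    simulate_rpb1_like_mixture(cfg, fractions = c(immobile = 0.5,
                                                  subdiffusive = 0.2,
                                                  mobile = 0.2)),
    "sum to 1")
})
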