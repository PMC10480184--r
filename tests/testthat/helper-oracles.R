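# Independent oracles used across the suite.  These are deliberately
# naive implementations kept separate from the package's own code paths.

# O(L^2) time-averaged MSD: loop over every pair of localizations
brute_ta_msd <- function(x, y, frames, frame_interval, max_lag_fraction = 1) {
  span <- frames[length(frames)] - frames[1]
  max_n <- max(1L, floor(max_lag_fraction * span))
  msd <- rep(NA_real_, max_n)
  npair <- integer(max_n)
  for (n in seq_len(max_n)) {
    acc <- 0
    cnt <- 0L
    for (i in seq_along(frames)) {
      for (j in seq_along(frames)) {
        if (frames[j] - frames[i] == n) {
          acc <- acc + (x[j] - x[i])^2 + (y[j] - y[i])^2
          cnt <- cnt + 1L
        }
      }
    }
    npair[n] <- cnt
    if (cnt > 0) msd[n] <- acc / cnt
  }
  list(msd = msd, n_pairs = npair)
}

# direct symmetric-normalized fluctuation ACF at integer lags
direct_acf <- function(counts, lags) {
  vapply(lags, function(k) {
    n <- length(counts)
    head_x <- counts[1:(n - k)]
    tail_x <- counts[(k + 1):n]
    mean(head_x * tail_x) / (mean(head_x) * mean(tail_x)) - 1
  }, 0.0)
}

# closed-form fBm covariance for Var X(t) = 2 d t^alpha:
# Cov(X(s), X(t)) = d (s^alpha + t^alpha - |t - s|^alpha)
fbm_cov_closed <- function(s, t, d, alpha) {
  d * (abs(s)^alpha + abs(t)^alpha - abs(t - s)^alpha)
}

# direct 2D Gaussian mixture density via solve()/det(), independent of
# the package's own evaluation
brute_mixture_density <- function(x, model) {
  total <- 0
  for (j in seq_len(model$k)) {
    S <- model$covariances[, , j]
    mu <- model$means[j, ]
    dvec <- x - mu
    q <- as.numeric(t(dvec) %*% solve(S) %*% dvec)
    total <- total + model$weights[j] *
      exp(-q / 2) / (2 * pi * sqrt(det(S)))
  }
  total
}

msd_tibble <- function(lag, msd) {
  tibble::tibble(lag = lag, msd = msd, n_pairs = rev(seq_along(lag)))
}
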