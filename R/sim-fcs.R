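# Photon-count trace generator: point emitters diffusing through a 3D
# Gaussian focal volume in a periodic box, Poisson shot noise per bin.

#' Gaussian focal volume specification
#'
#' @param w0 Lateral 1/e^2 radius in micrometres.
#' @param z0 Axial 1/e^2 radius in micrometres (`z0 >= w0`).
#'
#' @return List of class `"focal_volume"` with `w0`, `z0`,
#'   `structure_parameter` (`z0/w0`) and `v_eff`
#'   (`pi^(3/2) w0^2 z0`, the effective volume for which the
#'   zero-lag amplitude of the fluctuation ACF is `1/N`).
#' @export
focal_volume <- function(w0 = 0.25, z0 = 1.25) {
  check_positive(w0, "w0")
  check_positive(z0, "z0")
  if (z0 < w0) stop_domain("`z0` must be >= `w0`")
  structure(
    list(w0 = w0, z0 = z0, structure_parameter = z0 / w0,
         v_eff = pi^1.5 * w0^2 * z0),
    class = "focal_volume"
  )
}

#' FCS trace simulation specification
#'
#' @param diffusion_coefficient Diffusion coefficient in um^2/s
#'   (um^2/s^alpha when `alpha != 1`).
#' @param alpha Anomalous exponent in (0, 2]; 1 is Brownian.
#' @param mean_molecules_in_volume Expected number of molecules in the
#'   effective focal volume (sets the amplitude `G(0) = 1/N`).
#' @param brightness Photon count rate of one molecule at the beam centre,
#'   counts/s.
#' @param bin_width Sampling bin in seconds (default 1e-5 s).
#' @param duration Trace duration in seconds.
#' @param box_halfwidths Half-widths (um) of the periodic simulation box in
#'   x, y, z; must each be at least `3 * (w0, w0, z0)` so that box re-entry
#'   artefacts stay below the ACF noise floor.  Default `NULL` uses exactly
#'   that minimum.
#' @param rng_seed Optional integer seed.
#'
#' @return List of class `"fcs_sim_spec"`.
#' @export
fcs_sim_spec <- function(diffusion_coefficient,
                         alpha = 1,
                         mean_molecules_in_volume = 2,
                         brightness = 2e4,
                         bin_width = 1e-5,
                         duration = 10,
                         box_halfwidths = NULL,
                         rng_seed = NULL) {
  if (diffusion_coefficient < 0) stop_domain("`diffusion_coefficient` must be >= 0")
  if (alpha <= 0 || alpha > 2) stop_domain("`alpha` must lie in (0, 2]")
  check_positive(mean_molecules_in_volume, "mean_molecules_in_volume")
  if (brightness < 0) stop_domain("`brightness` must be >= 0")
  check_positive(bin_width, "bin_width")
  check_positive(duration, "duration")
  structure(
    list(diffusion_coefficient = diffusion_coefficient, alpha = alpha,
         mean_molecules_in_volume = mean_molecules_in_volume,
         brightness = brightness, bin_width = bin_width, duration = duration,
         box_halfwidths = box_halfwidths,
         rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
    class = "fcs_sim_spec"
  )
}

# fractional Gaussian noise by circulant embedding (Davies-Harte);
# increment variance 2 * d * dt^alpha, i.e. fBm with Var X(t) = 2 d t^alpha
fgn_davies_harte <- function(n, d_alpha, alpha, dt) {
  if (alpha == 1) return(stats::rnorm(n, 0, sqrt(2 * d_alpha * dt)))
  g <- fgn_cov(0:(n - 1), d_alpha, alpha, dt)
  # first row of the 2m-circulant: g_0..g_{n-1}, g_{n}, g_{n-1}..g_1
  gn <- fgn_cov(n, d_alpha, alpha, dt)
  circ <- c(g, gn, rev(g[-1]))
  lambda <- Re(stats::fft(circ))
  if (min(lambda) < -1e-8 * max(lambda)) {
    # embedding not nonnegative (can happen for alpha near 2): fall back
    # to exact Cholesky sampling
    return(as.vector(fgn_chol(n, d_alpha, alpha, dt) %*% stats::rnorm(n)))
  }
  lambda[lambda < 0] <- 0
  m2 <- length(circ)
  z <- complex(real = stats::rnorm(m2), imaginary = stats::rnorm(m2))
  # Re of the inverse DFT of sqrt(lambda) * z has exactly the circulant
  # covariance (cos(theta_p - theta_q) identity), no extra 1/sqrt(2)
  w <- stats::fft(sqrt(lambda) * z, inverse = TRUE) / sqrt(m2)
  Re(w)[seq_len(n)]
}

#' Simulate an FCS photon-count trace
#'
#' Molecules perform 3D Brownian (or fractional Brownian when
#' `alpha != 1`) motion in a periodic box around a Gaussian focal volume;
#' each occupies the box at a concentration matching
#' `mean_molecules_in_volume` in the effective volume.  Photon counts per
#' bin are Poisson with rate
#' `sum_molecules brightness * exp(-2 (x^2+y^2)/w0^2 - 2 z^2/z0^2)`.
#'
#' @param spec An [fcs_sim_spec()].
#' @param volume A [focal_volume()].
#' @param seed Optional seed overriding `spec$rng_seed`.
#'
#' @return Tibble with columns `t` (s) and `counts` (integer photon counts
#'   per bin); attributes `bin_width`, `duration`, `n_molecules`, `spec`,
#'   `volume`.
#' @export
simulate_fcs_trace <- function(spec, volume = focal_volume(), seed = NULL) {
  stopifnot(inherits(spec, "fcs_sim_spec"), inherits(volume, "focal_volume"))
  half_min <- 3 * c(volume$w0, volume$w0, volume$z0)
  half <- spec$box_halfwidths %||% half_min
  if (length(half) != 3 || any(half < half_min - 1e-12)) {
    stop_domain("box half-widths must be at least 3 * (w0, w0, z0)")
  }
  n_bins <- round(spec$duration / spec$bin_width)
  v_box <- prod(2 * half)
  conc <- spec$mean_molecules_in_volume / volume$v_eff
  n_mol <- max(1L, round(conc * v_box))
  dt <- spec$bin_width
  d <- spec$diffusion_coefficient
  with_seed_maybe(seed %||% spec$rng_seed, {
    rate <- numeric(n_bins)
    for (m in seq_len(n_mol)) {
      pos <- lapply(1:3, function(ax) {
        p0 <- stats::runif(1, -half[ax], half[ax])
        if (d > 0) {
          inc <- fgn_davies_harte(n_bins - 1L, d, spec$alpha, dt)
          p <- p0 + cumsum(c(0, inc))
          ((p + half[ax]) %% (2 * half[ax])) - half[ax]
        } else {
          rep(p0, n_bins)
        }
      })
      rate <- rate + exp(-2 * (pos[[1]]^2 + pos[[2]]^2) / volume$w0^2 -
                           2 * pos[[3]]^2 / volume$z0^2)
    }
    counts <- if (spec$brightness > 0) {
      stats::rpois(n_bins, spec$brightness * dt * rate)
    } else {
      integer(n_bins)
    }
    out <- tibble::tibble(t = (seq_len(n_bins) - 1) * dt, counts = counts)
    attr(out, "bin_width") <- dt
    attr(out, "duration") <- n_bins * dt
    attr(out, "n_molecules") <- n_mol
    attr(out, "spec") <- spec
    attr(out, "volume") <- volume
    out
  })
}
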