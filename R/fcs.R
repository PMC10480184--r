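# FCS analysis: multi-tau autocorrelation, photobleaching gate, normal and
# anomalous model fits, molecule numbers, effective volume, calibration.

#' Multi-tau autocorrelation of an intensity trace
#'
#' Normalized fluctuation autocorrelation
#' `G(tau) = <dF(t) dF(t+tau)> / <F>^2` on a quasi-logarithmic lag grid:
#' a linear block of `channels_per_octave` lags at full time resolution,
#' then per octave the upper half of the channels with the trace binned by
#' a further factor of two.  Symmetric normalization (head and tail means)
#' is used, so for an ideal dilute system `G(0+) -> 1/N`.
#'
#' @param trace Tibble with a `counts` column (photon counts per bin) and a
#'   `bin_width` attribute, or an integer vector plus `bin_width`.
#' @param channels_per_octave Linear channels per octave (default 16).
#' @param bin_width Bin width in seconds (defaults to the trace attribute).
#' @param max_lag Largest lag computed, in seconds (default: a quarter of
#'   the trace duration).
#'
#' @return Tibble with columns `lag` (s), `g`, `g_se` (rough per-lag
#'   standard error used for weighting), `n_pairs` and `level` (octave);
#'   attributes `bin_width`, `duration`, `mean_rate`.
#' @export
multitau_acf <- function(trace, channels_per_octave = 16, bin_width = NULL,
                         max_lag = NULL) {
  if (is.data.frame(trace)) {
    counts <- as.numeric(trace$counts)
    bin_width <- bin_width %||% attr(trace, "bin_width")
  } else {
    counts <- as.numeric(trace)
  }
  if (is.null(bin_width)) stop_domain("`bin_width` is required")
  n <- length(counts)
  if (n < 1000) stop_domain("trace must have at least 1000 bins")
  duration <- n * bin_width
  max_lag <- max_lag %||% (duration / 4)
  m <- as.integer(channels_per_octave)
  x <- counts
  level <- 0L
  width <- bin_width
  rows <- list()
  repeat {
    lags <- if (level == 0L) seq_len(m) else seq(m %/% 2 + 1L, m)
    for (k in lags) {
      tau <- k * width
      if (tau > max_lag || k >= length(x)) next
      nk <- length(x) - k
      head_x <- x[seq_len(nk)]
      tail_x <- x[(k + 1):length(x)]
      mh <- mean(head_x)
      mt <- mean(tail_x)
      if (mh == 0 || mt == 0) {
        g <- 0
        se <- NA_real_
      } else {
        prod_x <- head_x * tail_x
        g <- mean(prod_x) / (mh * mt) - 1
        se <- stats::sd(prod_x) / (sqrt(nk) * mh * mt)
      }
      rows[[length(rows) + 1L]] <- c(tau, g, se, nk, level)
    }
    # coarsen by two for the next octave
    nx <- length(x) %/% 2
    if (nx < 2 * m) break
    x <- (x[seq(1, 2 * nx, by = 2)] + x[seq(2, 2 * nx, by = 2)]) / 2
    width <- width * 2
    level <- level + 1L
    if (m %/% 2 + 1 > length(x) || (m %/% 2 + 1) * width > max_lag) break
  }
  mat <- do.call(rbind, rows)
  out <- tibble::tibble(lag = mat[, 1], g = mat[, 2], g_se = mat[, 3],
                        n_pairs = as.integer(mat[, 4]),
                        level = as.integer(mat[, 5]))
  out <- out[order(out$lag), ]
  attr(out, "bin_width") <- bin_width
  attr(out, "duration") <- duration
  attr(out, "mean_rate") <- mean(counts) / bin_width
  out
}

#' Photobleaching exclusion gate
#'
#' Fits a linear trend to the coarsely binned intensity and rejects traces
#' whose fitted fractional decay over the measurement exceeds
#' `decay_threshold` with a significantly negative slope, the signature of
#' photobleaching (stationarity is a prerequisite of the ACF analysis).
#'
#' @param trace Intensity trace (tibble with `counts` + `bin_width`
#'   attribute, or vector plus `bin_width`).
#' @param bin_width Bin width in seconds.
#' @param trend_bin Coarse bin for the trend fit, seconds (default 1 s).
#' @param decay_threshold Fractional decay needed for rejection
#'   (default 0.2).
#' @param p_threshold Two-sided p-value threshold on the slope
#'   (default 0.01).
#'
#' @return List: `accept` (logical), `decay_fraction`, `slope`
#'   (counts/s per s), `p_value`.
#' @export
exclude_photobleaching <- function(trace, bin_width = NULL, trend_bin = 1,
                                   decay_threshold = 0.2, p_threshold = 0.01) {
  if (is.data.frame(trace)) {
    counts <- as.numeric(trace$counts)
    bin_width <- bin_width %||% attr(trace, "bin_width")
  } else {
    counts <- as.numeric(trace)
  }
  if (is.null(bin_width)) stop_domain("`bin_width` is required")
  duration <- length(counts) * bin_width
  if (duration < 5) stop_domain("trace must last at least 5 s")
  per <- max(1L, round(trend_bin / bin_width))
  nb <- length(counts) %/% per
  rate <- vapply(seq_len(nb), function(i) {
    sum(counts[((i - 1) * per + 1):(i * per)]) / (per * bin_width)
  }, 0.0)
  tt <- (seq_len(nb) - 0.5) * per * bin_width
  fit <- stats::lm(rate ~ tt)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  p <- sm$coefficients[2, 4]
  f_start <- unname(stats::predict(fit, data.frame(tt = tt[1])))
  f_end <- unname(stats::predict(fit, data.frame(tt = tt[nb])))
  decay <- if (f_start > 0) (f_start - f_end) / f_start else 0
  list(accept = !(decay > decay_threshold && slope < 0 && p < p_threshold),
       decay_fraction = decay, slope = slope, p_value = p)
}

#' Normal (Brownian) 3D FCS model
#'
#' `G(tau) = (1/N) / (1 + tau/tau_d) / sqrt(1 + s * tau/tau_d)` with
#' `s = (w0/z0)^2` the squared inverse structure parameter.
#'
#' @param tau Lag times, s.
#' @param n_molecules Mean molecules in the effective volume.
#' @param tau_d Residence (diffusion) time, s.
#' @param structure `(w0/z0)^2`.
#' @return `G(tau)`.
#' @export
acf_model_normal <- function(tau, n_molecules, tau_d, structure) {
  x <- tau / tau_d
  (1 / n_molecules) / (1 + x) / sqrt(1 + structure * x)
}

#' Anomalous-diffusion FCS model
#'
#' Same as [acf_model_normal()] with `tau/tau_d` replaced by
#' `(tau/tau_d)^alpha`; reduces exactly to the normal model at
#' `alpha = 1`.
#'
#' @inheritParams acf_model_normal
#' @param alpha Anomalous exponent.
#' @return `G(tau)`.
#' @export
acf_model_anomalous <- function(tau, n_molecules, tau_d, alpha, structure) {
  x <- (tau / tau_d)^alpha
  (1 / n_molecules) / (1 + x) / sqrt(1 + structure * x)
}

select_fit_lags <- function(acf, lag_range) {
  lag_min <- lag_range[1]
  lag_max <- lag_range[2]
  use <- acf$lag >= lag_min & acf$lag <= lag_max & is.finite(acf$g)
  # drop the first two correlator channels (afterpulsing regime)
  idx <- which(use)
  if (length(idx) > 2) use[idx[1:2]] <- FALSE
  use
}

fit_acf_engine <- function(acf, model, structure, w0, lag_range, weighted) {
  if (is.null(lag_range)) {
    duration <- attr(acf, "duration") %||% (max(acf$lag) * 4)
    lag_range <- c(1e-5, duration / 100)
  }
  use <- select_fit_lags(acf, lag_range)
  if (sum(use) < 10) stop_domain("need at least 10 ACF points in the fit range")
  df <- data.frame(tau = acf$lag[use], g = acf$g[use])
  w <- rep(1, nrow(df))
  if (weighted && all(is.finite(acf$g_se[use])) && all(acf$g_se[use] > 0)) {
    w <- 1 / acf$g_se[use]^2
  }
  g0_guess <- max(stats::quantile(df$g, 0.95), 1e-4)
  below <- df$tau[df$g < g0_guess / 2]
  tau_guess <- if (length(below)) min(below) else stats::median(df$tau)
  start <- list(N = 1 / g0_guess, tau_d = tau_guess)
  lower <- c(N = 1e-4, tau_d = 1e-8)
  upper <- c(N = 1e8, tau_d = 1e4)
  if (model == "anomalous") {
    start$alpha <- 1
    lower <- c(lower, alpha = 0.1)
    upper <- c(upper, alpha = 2)
  }
  formula <- if (model == "normal") {
    g ~ acf_model_normal(tau, N, tau_d, structure)
  } else {
    g ~ acf_model_anomalous(tau, N, tau_d, alpha, structure)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = df, start = start,
                      lower = lower, upper = upper, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out <- list(model = model, converged = FALSE,
                message = conditionMessage(fit))
    class(out) <- "fcs_fit"
    return(out)
  }
  co <- stats::coef(fit)
  alpha_hat <- if (model == "anomalous") unname(co["alpha"]) else 1
  resid <- df$g - stats::predict(fit)
  d_coeff <- if (!is.null(w0)) w0^2 / (4 * unname(co["tau_d"])^alpha_hat) else NA_real_
  out <- list(
    model = model,
    n_molecules = unname(co["N"]),
    tau_d = unname(co["tau_d"]),
    alpha = alpha_hat,
    structure = structure,
    g0 = 1 / unname(co["N"]),
    d_coefficient = d_coeff,
    w0 = w0,
    residual_ss = sum(resid^2),
    n_points = nrow(df),
    converged = TRUE
  )
  class(out) <- "fcs_fit"
  out
}

#' Fit the normal diffusion model to an ACF
#'
#' Constrained nonlinear least squares (Levenberg-Marquardt trust region)
#' over `N > 0`, `tau_d > 0`, with the structure parameter fixed from
#' calibration by default.  Points are weighted by inverse variance when
#' per-lag uncertainties are available.
#'
#' @param acf ACF tibble from [multitau_acf()] (or read from file).
#' @param structure `(w0/z0)^2`; default `1/25` (structure parameter 5).
#' @param w0 Optional lateral beam radius (um) to convert `tau_d` into a
#'   diffusion coefficient `w0^2 / (4 tau_d)`.
#' @param lag_range Fit window in seconds; default 10 us to
#'   `duration / 100`.  The first two correlator channels are always
#'   excluded (afterpulsing regime; no triplet term is modelled).
#' @param weighted Use inverse-variance weights (default `TRUE`).
#'
#' @return Object of class `"fcs_fit"`: `n_molecules`, `tau_d`, `alpha`
#'   (fixed at 1), `structure`, `g0 = 1/N`, `d_coefficient`,
#'   `residual_ss`, `converged`.
#' @export
fit_acf_normal <- function(acf, structure = 1 / 25, w0 = NULL,
                           lag_range = NULL, weighted = TRUE) {
  fit_acf_engine(acf, "normal", structure, w0, lag_range, weighted)
}

#' Fit the anomalous diffusion model to an ACF
#'
#' As [fit_acf_normal()] with the anomalous exponent free in
#' `[0.1, 2]`; at `alpha = 1` the model coincides with the normal one.
#' When `w0` is given the generalised coefficient
#' `w0^2 / (4 tau_d^alpha)` is reported.
#'
#' @inheritParams fit_acf_normal
#' @return Object of class `"fcs_fit"` (with fitted `alpha`).
#' @export
fit_acf_anomalous <- function(acf, structure = 1 / 25, w0 = NULL,
                              lag_range = NULL, weighted = TRUE) {
  fit_acf_engine(acf, "anomalous", structure, w0, lag_range, weighted)
}

#' @export
print.fcs_fit <- function(x, ...) {
  if (!x$converged) {
    cat("FCS fit (", x$model, "): did not converge\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("FCS %s model fit: N = %.3g, tau_d = %.3g s, alpha = %.3g, SSE = %.3g\n",
              x$model, x$n_molecules, x$tau_d, x$alpha, x$residual_ss))
  if (!is.na(x$d_coefficient)) {
    cat(sprintf("  D = %.3g um^2/s^alpha (w0 = %g um)\n", x$d_coefficient, x$w0))
  }
  invisible(x)
}

#' Number of molecules from the ACF amplitude
#'
#' `N = 1 / G(0)`.
#'
#' @param fit An `"fcs_fit"` or a numeric `G(0)` amplitude.
#' @return Mean number of molecules in the effective volume (`NA` with a
#'   warning when `G(0) <= 0`).
#' @export
number_of_molecules <- function(fit) {
  g0 <- if (inherits(fit, "fcs_fit")) fit$g0 else fit
  if (!is.finite(g0) || g0 <= 0) {
    warning("G(0) <= 0: number of molecules undefined")
    return(NA_real_)
  }
  1 / g0
}

#' Effective observation volume from a calibration measurement
#'
#' `V_eff = 1 / (G(0) N_A c)` for a dye of known concentration.
#'
#' @param g0 Zero-lag ACF amplitude.
#' @param concentration Calibration concentration in mol/L.
#' @return Effective volume in um^3 (1 L = 1e15 um^3).
#' @export
effective_volume <- function(g0, concentration) {
  check_positive(g0, "g0")
  check_positive(concentration, "concentration")
  molecules_per_um3 <- concentration * avogadro_n() / 1e15
  1 / (g0 * molecules_per_um3)
}

#' Calibrate the focal volume from a reference-dye fit
#'
#' Converts the fitted residence time of a dye of known diffusion
#' coefficient into beam waists: `w0 = sqrt(4 D tau_d)`,
#' `z0 = w0 / sqrt(structure)`; the effective volume follows from the
#' amplitude and the known concentration.
#'
#' @param fit Converged `"fcs_fit"` of the reference dye.
#' @param reference_d Reference diffusion coefficient in um^2/s
#'   (default 536, a common green calibration dye near 36 C).
#' @param concentration Dye concentration in mol/L (default 10 nM).
#'
#' @return List of class `"fcs_calibration"`: `w0`, `z0` (um), `v_eff`
#'   (um^3), `structure_parameter` (`z0/w0`), `reference_d`,
#'   `reference_concentration`.  A warning is issued when the fitted
#'   `alpha` deviates more than 10% from 1 (the calibration dye must
#'   diffuse freely).
#' @export
calibrate_focal_volume <- function(fit, reference_d = 536,
                                   concentration = 1e-8) {
  stopifnot(inherits(fit, "fcs_fit"))
  if (!fit$converged) stop_domain("calibration fit did not converge")
  check_positive(reference_d, "reference_d")
  if (abs(fit$alpha - 1) > 0.1) {
    warning("calibration fit alpha deviates more than 10% from 1")
  }
  w0 <- sqrt(4 * reference_d * fit$tau_d)
  z0 <- w0 / sqrt(fit$structure)
  structure(
    list(w0 = w0, z0 = z0,
         v_eff = effective_volume(fit$g0, concentration),
         structure_parameter = z0 / w0,
         reference_d = reference_d,
         reference_concentration = concentration),
    class = "fcs_calibration"
  )
}

#' @export
print.fcs_calibration <- function(x, ...) {
  cat(sprintf("Focal volume calibration: w0 = %.3g um, z0 = %.3g um, V_eff = %.3g um^3\n",
              x$w0, x$z0, x$v_eff))
  invisible(x)
}

#' Molecular concentration from an FCS fit
#'
#' @param fit Converged `"fcs_fit"`.
#' @param v_eff Effective volume in um^3.
#' @return List with `molecules_per_um3` (`N / V_eff`) and `mol_per_l`.
#' @export
concentration_from_fit <- function(fit, v_eff) {
  check_positive(v_eff, "v_eff")
  n <- if (inherits(fit, "fcs_fit")) fit$n_molecules else fit
  dens <- n / v_eff
  list(molecules_per_um3 = dens,
       mol_per_l = dens * 1e15 / avogadro_n())
}
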