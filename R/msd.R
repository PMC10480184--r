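# Per-trajectory time-averaged MSD analysis: filtering, TA-MSD, D_60ms,
# anomalous exponent, immobile classification, detection density maps.

#' Filter tracks by detection count
#'
#' Keeps only tracks with strictly more than `min_detections` localizations
#' (short tracks destabilise per-trajectory MSD fits).
#'
#' @param tracks Track tibble (columns `track_id`, `frame`, `x`, `y`).
#' @param min_detections Strict lower bound on detections per track
#'   (default 10: a track with exactly 10 detections is excluded).
#'
#' @return The filtered track tibble, order and ids preserved.
#' @export
filter_tracks <- function(tracks, min_detections = 10) {
  if (min_detections < 2) stop_domain("`min_detections` must be >= 2")
  if (nrow(tracks) == 0) return(tracks)
  n_by_id <- table(tracks$track_id)
  keep_ids <- names(n_by_id)[n_by_id > min_detections]
  out <- tracks[as.character(tracks$track_id) %in% keep_ids, , drop = FALSE]
  attr(out, "frame_interval") <- attr(tracks, "frame_interval")
  out
}

#' Time-averaged mean squared displacement of one trajectory
#'
#' For each lag `tau = n * dt` the TA-MSD averages the squared 2D
#' displacement over all (overlapping) pairs of localizations separated by
#' `n` frames.
#'
#' @param x,y Coordinates in micrometres.
#' @param frames Integer frame indices, strictly increasing.  Defaults to
#'   contiguous frames.
#' @param frame_interval Frame interval in seconds.
#' @param max_lag_fraction Largest lag computed, as a fraction of the
#'   maximal available lag (default 1: all lags).
#'
#' @return A tibble with columns `lag` (s), `msd` (um^2) and `n_pairs`.
#' @export
ta_msd <- function(x, y, frames = seq_along(x) - 1L,
                   frame_interval = 0.01, max_lag_fraction = 1) {
  len <- length(x)
  if (len < 2 || length(y) != len || length(frames) != len) {
    stop_domain("track must have at least 2 localizations of equal length")
  }
  if (any(diff(frames) <= 0)) stop_domain("frames must be strictly increasing")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_domain("positions must be finite")
  }
  if (max_lag_fraction <= 0 || max_lag_fraction > 1) {
    stop_domain("`max_lag_fraction` must lie in (0, 1]")
  }
  span <- frames[len] - frames[1]
  max_n <- max(1L, floor(max_lag_fraction * span))
  contiguous <- all(diff(frames) == 1L)
  msd <- numeric(max_n)
  npair <- integer(max_n)
  if (contiguous) {
    for (n in seq_len(max_n)) {
      dx <- x[(1 + n):len] - x[1:(len - n)]
      dy <- y[(1 + n):len] - y[1:(len - n)]
      msd[n] <- mean(dx * dx + dy * dy)
      npair[n] <- len - n
    }
  } else {
    # gapped frames: average over pairs at exact frame separation n
    for (n in seq_len(max_n)) {
      j <- match(frames + n, frames)
      ok <- !is.na(j)
      npair[n] <- sum(ok)
      if (npair[n] > 0) {
        dx <- x[j[ok]] - x[ok]
        dy <- y[j[ok]] - y[ok]
        msd[n] <- mean(dx * dx + dy * dy)
      } else {
        msd[n] <- NA_real_
      }
    }
  }
  tibble::tibble(lag = seq_len(max_n) * frame_interval,
                 msd = msd, n_pairs = npair)
}

#' Instantaneous diffusion coefficient from the first 60 ms of the TA-MSD
#'
#' Fits `MSD(tau) = 4 sigma^2 + 4 D tau` over the lags from `2 dt` up to
#' `max_lag_s`, excluding the first lag point, whose value is dominated by
#' the static localization error.  With `intercept = "fixed"` (the default)
#' the intercept is pinned at the known localization offset `4 sigma^2` and
#' only the slope is estimated, which roughly halves the spread of the
#' per-track estimate relative to a free-intercept fit; `intercept = "free"`
#' estimates both by ordinary least squares.
#'
#' @param msd TA-MSD tibble from [ta_msd()].
#' @param localization_sigma Static localization error in um (used only by
#'   the fixed-intercept fit).
#' @param max_lag_s Upper end of the fitted lag window in seconds
#'   (default 0.06 s, i.e. points 2..6 at 100 Hz).
#' @param intercept `"fixed"` or `"free"` (see above).
#'
#' @return A list with `d_60ms` (um^2/s; can be slightly negative for
#'   stationary emitters after noise-offset subtraction), `intercept`,
#'   `r2`, `n_points` and `ok`.  When fewer than 2 lags are usable the
#'   estimate is flagged unfit (`ok = FALSE`, `d_60ms = NA`) rather than
#'   extrapolated.
#' @export
fit_d60 <- function(msd, localization_sigma = 0.05, max_lag_s = 0.06,
                    intercept = c("fixed", "free")) {
  intercept <- match.arg(intercept)
  dt <- msd$lag[1]
  use <- msd$lag > dt + 1e-12 & msd$lag <= max_lag_s + 1e-12 &
    is.finite(msd$msd)
  tau <- msd$lag[use]
  m <- msd$msd[use]
  unfit <- list(d_60ms = NA_real_, intercept = NA_real_, r2 = NA_real_,
                n_points = sum(use), ok = FALSE)
  if (sum(use) < 2) return(unfit)
  if (intercept == "fixed") {
    b0 <- 4 * localization_sigma^2
    slope <- sum((m - b0) * tau) / sum(tau^2)
  } else {
    fit <- stats::lm.fit(cbind(1, tau), m)
    b0 <- fit$coefficients[1]
    slope <- fit$coefficients[2]
  }
  resid <- m - (b0 + slope * tau)
  tss <- sum((m - mean(m))^2)
  r2 <- if (tss > 0) 1 - sum(resid^2) / tss else NA_real_
  list(d_60ms = unname(slope) / 4, intercept = unname(b0), r2 = unname(r2),
       n_points = length(tau), ok = TRUE)
}

#' Anomalous exponent from the log-log TA-MSD
#'
#' Unweighted linear regression of `log(MSD)` on `log(tau)` over the first
#' third of the curve (minimum 3 points), excluding the first lag point.
#' The slope is the anomalous exponent `alpha`; the intercept gives the
#' generalised coefficient `D_alpha = exp(intercept) / 4` (natural
#' logarithms; any consistent base gives the same `D_alpha`).
#'
#' @param msd TA-MSD tibble from [ta_msd()].
#'
#' @return A list with `alpha`, `d_alpha`, `r2`, `n_points`, `ok`.
#'   Non-positive MSD values in the window are dropped; if fewer than 3
#'   points remain the estimate is flagged unfit.
#' @export
fit_alpha_powerlaw <- function(msd) {
  n_lags <- nrow(msd)
  last <- max(ceiling(n_lags / 3), 4)
  idx <- seq(2, min(last, n_lags))
  unfit <- list(alpha = NA_real_, d_alpha = NA_real_, r2 = NA_real_,
                n_points = 0L, ok = FALSE)
  if (length(idx) < 3) return(unfit)
  v <- msd$msd[idx]
  tau <- msd$lag[idx]
  keep <- is.finite(v) & v > 0
  if (sum(keep) < 3) return(unfit)
  fit <- stats::lm.fit(cbind(1, log(tau[keep])), log(v[keep]))
  co <- fit$coefficients
  r2 <- {
    yy <- log(v[keep])
    tss <- sum((yy - mean(yy))^2)
    if (tss > 0) 1 - sum(fit$residuals^2) / tss else NA_real_
  }
  list(alpha = unname(co[2]), d_alpha = exp(unname(co[1])) / 4,
       r2 = unname(r2), n_points = sum(keep), ok = TRUE)
}

#' Classify mobility from the instantaneous diffusion coefficient
#'
#' A trajectory is immobile when its `d_60ms` falls strictly below the
#' threshold (default 5e-3 um^2/s, the noise-floor cut for a 50 nm
#' localization error).
#'
#' @param d_60ms Numeric vector of instantaneous diffusion coefficients.
#' @param threshold Immobility threshold in um^2/s.
#'
#' @return Character vector `"immobile"`/`"mobile"` (`NA` stays `NA`).
#' @export
classify_immobile <- function(d_60ms, threshold = 5e-3) {
  out <- ifelse(d_60ms < threshold, "immobile", "mobile")
  out[!is.finite(d_60ms)] <- NA_character_
  out
}

#' Per-trajectory diffusion estimates for a track set
#'
#' Runs the TA-MSD, D_60ms, and anomalous-exponent fits on every track
#' surviving the detection filter, and classifies mobility.
#'
#' @param tracks Track tibble.
#' @param frame_interval Frame interval in seconds; defaults to the tibble's
#'   `frame_interval` attribute.
#' @param localization_sigma Static localization error in um.
#' @param min_detections Strict detection filter passed to
#'   [filter_tracks()].
#' @param immobile_threshold Threshold for [classify_immobile()].
#' @param d60_intercept Intercept handling for [fit_d60()].
#'
#' @return A tibble with one row per kept track: `track_id`,
#'   `n_detections`, `d_60ms`, `d_alpha`, `alpha`, `r2` (of the D_60ms
#'   fit), `alpha_r2`, `mobility_class` and `truth_label` (when present in
#'   the input).
#' @export
estimate_diffusion <- function(tracks,
                               frame_interval = NULL,
                               localization_sigma = 0.05,
                               min_detections = 10,
                               immobile_threshold = 5e-3,
                               d60_intercept = "fixed") {
  frame_interval <- frame_interval %||% attr(tracks, "frame_interval") %||% 0.01
  tracks <- filter_tracks(tracks, min_detections)
  ids <- unique(tracks$track_id)
  has_label <- "truth_label" %in% names(tracks)
  rows <- vector("list", length(ids))
  split_idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  for (i in seq_along(ids)) {
    sel <- split_idx[[as.character(ids[i])]]
    tr <- tracks[sel, , drop = FALSE]
    msd <- ta_msd(tr$x, tr$y, tr$frame, frame_interval)
    f60 <- fit_d60(msd, localization_sigma, intercept = d60_intercept)
    fal <- fit_alpha_powerlaw(msd)
    rows[[i]] <- tibble::tibble(
      track_id = ids[i],
      n_detections = nrow(tr),
      d_60ms = f60$d_60ms,
      d_alpha = fal$d_alpha,
      alpha = fal$alpha,
      r2 = f60$r2,
      alpha_r2 = fal$r2,
      truth_label = if (has_label) tr$truth_label[1] else NA_character_
    )
  }
  out <- dplyr::bind_rows(rows)
  out$mobility_class <- classify_immobile(out$d_60ms, immobile_threshold)
  out
}

#' Summarise a set of diffusion estimates
#'
#' @param estimates Tibble from [estimate_diffusion()].
#'
#' @return One-row tibble with track counts, means and SDs of `d_60ms`,
#'   `d_alpha` and `alpha`, the immobile fraction, and the mean number of
#'   detections per trajectory.
#' @export
summarize_tracks <- function(estimates) {
  if (nrow(estimates) == 0) {
    return(tibble::tibble(
      n_tracks = 0L, mean_detections = NA_real_,
      mean_d60 = NA_real_, sd_d60 = NA_real_,
      mean_d_alpha = NA_real_, sd_d_alpha = NA_real_,
      mean_alpha = NA_real_, sd_alpha = NA_real_,
      immobile_fraction = NA_real_
    ))
  }
  tibble::tibble(
    n_tracks = nrow(estimates),
    mean_detections = mean(estimates$n_detections),
    mean_d60 = mean(estimates$d_60ms, na.rm = TRUE),
    sd_d60 = stats::sd(estimates$d_60ms, na.rm = TRUE),
    mean_d_alpha = mean(estimates$d_alpha, na.rm = TRUE),
    sd_d_alpha = stats::sd(estimates$d_alpha, na.rm = TRUE),
    mean_alpha = mean(estimates$alpha, na.rm = TRUE),
    sd_alpha = stats::sd(estimates$alpha, na.rm = TRUE),
    immobile_fraction = mean(estimates$mobility_class == "immobile",
                             na.rm = TRUE)
  )
}

#' Detection density (oversampling) map
#'
#' 2D histogram of all localizations on a pixel grid, the projection used
#' to reveal subdomains repeatedly visited by fast-moving molecules.
#'
#' @param tracks Track tibble.
#' @param pixel_size Pixel size in micrometres.
#' @param bounds Numeric `c(xmin, xmax, ymin, ymax)`; defaults to the data
#'   range.  Detections outside the bounds are tallied as discarded.
#' @param frame_range Optional inclusive `c(first, last)` frame filter.
#'
#' @return List of class `"detection_density_map"`: `grid` (matrix of
#'   counts, rows = x bins), `pixel_size`, `x_breaks`, `y_breaks`,
#'   `n_discarded`, `frame_range`.  The grid total plus discards equals the
#'   number of detections considered.
#' @export
detection_density_map <- function(tracks, pixel_size, bounds = NULL,
                                  frame_range = NULL) {
  check_positive(pixel_size, "pixel_size")
  pts <- tracks
  if (!is.null(frame_range)) {
    pts <- pts[pts$frame >= frame_range[1] & pts$frame <= frame_range[2], ]
  }
  if (is.null(bounds)) {
    bounds <- c(min(pts$x), max(pts$x), min(pts$y), max(pts$y))
  }
  x_breaks <- seq(bounds[1], bounds[2] + pixel_size, by = pixel_size)
  y_breaks <- seq(bounds[3], bounds[4] + pixel_size, by = pixel_size)
  ix <- findInterval(pts$x, x_breaks, rightmost.closed = FALSE)
  iy <- findInterval(pts$y, y_breaks, rightmost.closed = FALSE)
  inside <- ix >= 1 & ix < length(x_breaks) & iy >= 1 & iy < length(y_breaks)
  grid <- matrix(0L, nrow = length(x_breaks) - 1, ncol = length(y_breaks) - 1)
  if (any(inside)) {
    tab <- table(factor(ix[inside], levels = seq_len(nrow(grid))),
                 factor(iy[inside], levels = seq_len(ncol(grid))))
    grid <- matrix(as.integer(tab), nrow = nrow(grid))
  }
  structure(
    list(grid = grid, pixel_size = pixel_size,
         x_breaks = x_breaks, y_breaks = y_breaks,
         n_discarded = sum(!inside), frame_range = frame_range),
    class = "detection_density_map"
  )
}

#' @export
print.detection_density_map <- function(x, ...) {
  cat(sprintf("Detection density map: %d x %d pixels of %g um, %d detections (%d discarded)\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size,
              sum(x$grid) + x$n_discarded, x$n_discarded))
  invisible(x)
}
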