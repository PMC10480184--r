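# Trajectory generators: Brownian motion, fractional Brownian motion,
# and mixtures with retained truth labels.

new_track_tibble <- function(track_id, frame, x, y, truth_label,
                             frame_interval) {
  out <- tibble::tibble(
    track_id = track_id,
    frame = frame,
    t = frame * frame_interval,
    x = x,
    y = y,
    truth_label = truth_label
  )
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Simulate 2D Brownian trajectories
#'
#' Generates `config$n_tracks` trajectories of a particle with diffusion
#' coefficient `d`, sampled at the configured frame interval, with geometric
#' track lengths and independent Gaussian localization error on every
#' detection.
#'
#' @param d Diffusion coefficient in um^2/s (`d = 0` gives a stationary
#'   emitter observed through localization noise only).
#' @param config A [sim_config()].
#' @param label Optional truth label stored with every localization
#'   (used for truth-based scoring of mixtures).
#' @param seed Optional seed overriding `config$rng_seed`.
#'
#' @return A tibble with columns `track_id`, `frame` (0-based), `t` (s),
#'   `x`, `y` (um) and `truth_label`, ordered by (track_id, frame), with a
#'   `frame_interval` attribute.  Each step increment per axis has variance
#'   `2 * d * frame_interval`.
#' @export
simulate_brownian_tracks <- function(d, config = sim_config(),
                                     label = NA_character_, seed = NULL) {
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d < 0) {
    stop_domain("`d` must be a single finite value >= 0")
  }
  stopifnot(inherits(config, "sim_config"))
  with_seed_maybe(seed %||% config$rng_seed, {
    lengths <- draw_track_lengths(config$n_tracks, config)
    step_sd <- sqrt(2 * d * config$frame_interval)
    parts <- vector("list", config$n_tracks)
    for (i in seq_len(config$n_tracks)) {
      len <- lengths[i]
      x0 <- stats::runif(1, 0, config$field_size)
      y0 <- stats::runif(1, 0, config$field_size)
      x <- x0 + cumsum(c(0, stats::rnorm(len - 1, 0, step_sd)))
      y <- y0 + cumsum(c(0, stats::rnorm(len - 1, 0, step_sd)))
      if (config$localization_sigma > 0) {
        x <- x + stats::rnorm(len, 0, config$localization_sigma)
        y <- y + stats::rnorm(len, 0, config$localization_sigma)
      }
      parts[[i]] <- list(id = i, x = x, y = y)
    }
    assemble_tracks(parts, label, config$frame_interval)
  })
}

assemble_tracks <- function(parts, label, frame_interval) {
  lens <- vapply(parts, function(p) length(p$x), 0L)
  new_track_tibble(
    track_id = rep.int(vapply(parts, `[[`, 0L, "id"), lens),
    frame = unlist(lapply(lens, function(l) 0:(l - 1L)), use.names = FALSE),
    x = unlist(lapply(parts, `[[`, "x"), use.names = FALSE),
    y = unlist(lapply(parts, `[[`, "y"), use.names = FALSE),
    truth_label = rep(label, sum(lens)),
    frame_interval = frame_interval
  )
}

# Covariance of fractional Gaussian noise increments at frame spacing dt:
# with per-axis variance 2 * d * t^alpha, the increment autocovariance at
# integer spacing k is d * dt^alpha * (|k+1|^a - 2|k|^a + |k-1|^a).
fgn_cov <- function(k, d_alpha, alpha, dt) {
  d_alpha * dt^alpha *
    (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha)
}

# Lower Cholesky factor of the fGn covariance for n increments; leading
# principal blocks of the factor serve shorter tracks (Cholesky nests).
fgn_chol <- function(n, d_alpha, alpha, dt) {
  k <- abs(outer(seq_len(n), seq_len(n), `-`))
  sigma <- fgn_cov(k, d_alpha, alpha, dt)
  t(chol(sigma + diag(1e-12 * fgn_cov(0, d_alpha, alpha, dt), n)))
}

#' Simulate 2D fractional Brownian trajectories
#'
#' Each coordinate is an independent fractional Brownian motion with Hurst
#' exponent `H = alpha / 2`, scaled so the ensemble 2D mean squared
#' displacement is `4 * d_alpha * t^alpha`.  `alpha = 1` reduces to
#' [simulate_brownian_tracks()] in distribution; `alpha < 1` gives
#' anti-correlated (subdiffusive) increments.
#'
#' @param d_alpha Generalised diffusion coefficient in um^2/s^alpha.
#' @param alpha Anomalous exponent in (0, 2].
#' @inheritParams simulate_brownian_tracks
#'
#' @return Same layout as [simulate_brownian_tracks()].
#'
#' @details Increments are drawn from the exact fractional Gaussian noise
#'   covariance via a Cholesky factorisation shared across tracks.  The
#'   ballistic boundary `alpha = 2` (perfectly correlated increments) is
#'   handled as a straight line with a Gaussian random velocity.
#' @export
simulate_fbm_tracks <- function(d_alpha, alpha, config = sim_config(),
                                label = NA_character_, seed = NULL) {
  check_positive(d_alpha, "d_alpha")
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0 || alpha > 2) {
    stop_domain("`alpha` must lie in (0, 2]")
  }
  stopifnot(inherits(config, "sim_config"))
  dt <- config$frame_interval
  with_seed_maybe(seed %||% config$rng_seed, {
    lengths <- draw_track_lengths(config$n_tracks, config)
    nmax <- max(lengths) - 1L
    chol_l <- if (alpha < 2) fgn_chol(nmax, d_alpha, alpha, dt) else NULL
    parts <- vector("list", config$n_tracks)
    for (i in seq_len(config$n_tracks)) {
      len <- lengths[i]
      n <- len - 1L
      if (alpha < 2) {
        lk <- chol_l[seq_len(n), seq_len(n), drop = FALSE]
        dx <- as.vector(lk %*% stats::rnorm(n))
        dy <- as.vector(lk %*% stats::rnorm(n))
      } else {
        # ballistic limit: X(t) = sqrt(2 d) * t * Z
        dx <- rep(sqrt(2 * d_alpha) * dt * stats::rnorm(1), n)
        dy <- rep(sqrt(2 * d_alpha) * dt * stats::rnorm(1), n)
      }
      x <- stats::runif(1, 0, config$field_size) + cumsum(c(0, dx))
      y <- stats::runif(1, 0, config$field_size) + cumsum(c(0, dy))
      if (config$localization_sigma > 0) {
        x <- x + stats::rnorm(len, 0, config$localization_sigma)
        y <- y + stats::rnorm(len, 0, config$localization_sigma)
      }
      parts[[i]] <- list(id = i, x = x, y = y)
    }
    assemble_tracks(parts, label, dt)
  })
}

#' Mix trajectory sets in given proportions
#'
#' Subsamples tracks without replacement from each input set so the output
#' honours the requested proportions (within one track), relabels track ids
#' to be unique, and keeps each track's truth label for later scoring.
#'
#' @param sets List of track tibbles (as produced by the simulators).
#' @param fractions Numeric proportions, one per set, summing to 1.
#' @param n_total Total number of tracks requested; defaults to the largest
#'   total the inputs can support at these proportions.
#' @param seed Optional seed for the subsampling.
#'
#' @return A track tibble; `truth_label` partitions the output.
#' @export
mix_track_sets <- function(sets, fractions, n_total = NULL, seed = NULL) {
  stopifnot(is.list(sets), length(sets) == length(fractions))
  check_fraction(fractions, "fractions")
  if (abs(sum(fractions) - 1) > 1e-8) stop_domain("`fractions` must sum to 1")
  if (any(vapply(sets, nrow, 0L) == 0)) stop_domain("each set must be non-empty")
  avail <- vapply(sets, function(s) length(unique(s$track_id)), 0L)
  if (is.null(n_total)) {
    pos <- fractions > 0
    n_total <- floor(min(avail[pos] / fractions[pos]))
  }
  counts <- apportion(n_total, fractions)
  if (any(counts > avail)) {
    stop_domain("requested fraction exceeds available tracks in a set")
  }
  dt <- attr(sets[[1]], "frame_interval")
  with_seed_maybe(seed, {
    pieces <- vector("list", length(sets))
    offset <- 0L
    for (j in seq_along(sets)) {
      ids <- unique(sets[[j]]$track_id)
      take <- sort(sample(ids, counts[j]))
      sub <- sets[[j]][sets[[j]]$track_id %in% take, , drop = FALSE]
      sub$track_id <- offset + match(sub$track_id, take)
      offset <- offset + counts[j]
      pieces[[j]] <- sub
    }
    out <- dplyr::bind_rows(pieces)
    attr(out, "frame_interval") <- dt
    out
  })
}

#' Simulate an RPB1-like three-class trajectory mixture
#'
#' Composite set emulating nuclear RNA polymerase II mobility: an immobile
#' class observed through localization noise only, a strongly subdiffusive
#' slow class, and a near-Brownian mobile class.  Defaults follow the
#' reported population parameters: subdiffusive `D = 0.02 um^2/s^alpha`
#' with `alpha = 0.31`, mobile `D = 0.5 um^2/s^alpha` with `alpha = 0.95`,
#' and a 20% immobile fraction.
#'
#' @param config A [sim_config()]; `config$n_tracks` is the total size.
#' @param fractions Named proportions for classes `immobile`, `subdiffusive`
#'   and `mobile`, summing to 1.
#' @param seed Optional seed.
#'
#' @return A track tibble with `truth_label` in
#'   `c("immobile", "subdiffusive", "mobile")`.
#' @export
simulate_rpb1_like_mixture <- function(config = sim_config(),
                                       fractions = c(immobile = 0.20,
                                                     subdiffusive = 0.55,
                                                     mobile = 0.25),
                                       seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  need <- c("immobile", "subdiffusive", "mobile")
  if (!all(need %in% names(fractions))) {
    stop_domain("`fractions` must be named immobile/subdiffusive/mobile")
  }
  fractions <- fractions[need]
  check_fraction(fractions, "fractions")
  if (abs(sum(fractions) - 1) > 1e-8) stop_domain("`fractions` must sum to 1")
  counts <- apportion(config$n_tracks, fractions)
  with_seed_maybe(seed %||% config$rng_seed, {
    cfg_n <- function(n) {
      cfg <- config
      cfg$n_tracks <- max(n, 1L)
      cfg$rng_seed <- NULL
      cfg
    }
    pieces <- list()
    if (counts[1] > 0) {
      pieces$immobile <- simulate_brownian_tracks(0, cfg_n(counts[1]),
                                                  label = "immobile")
    }
    if (counts[2] > 0) {
      pieces$sub <- simulate_fbm_tracks(0.02, 0.31, cfg_n(counts[2]),
                                        label = "subdiffusive")
    }
    if (counts[3] > 0) {
      pieces$mobile <- simulate_fbm_tracks(0.5, 0.95, cfg_n(counts[3]),
                                           label = "mobile")
    }
    offset <- 0L
    for (j in seq_along(pieces)) {
      n_j <- length(unique(pieces[[j]]$track_id))
      pieces[[j]]$track_id <- pieces[[j]]$track_id + offset
      offset <- offset + n_j
    }
    out <- dplyr::bind_rows(pieces)
    attr(out, "frame_interval") <- config$frame_interval
    out
  })
}
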