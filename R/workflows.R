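# End-to-end seeded workflows: the calibrated-bead benchmark and the
# RPB1-like nuclear mixture analysis.

#' Bead benchmark workflow
#'
#' Simulates Brownian bead trajectories for each requested condition,
#' recovers per-condition diffusion parameters, mixes two conditions and
#' runs the mixture-model selection, and (optionally) simulates an FCS
#' photon trace of a fast condition and fits the anomalous ACF model —
#' reporting recovered values against Stokes-Einstein ground truth.
#'
#' @param d_values Named or unnamed vector of condition diffusion
#'   coefficients in um^2/s (default the 20% and 50% glycerol 100 nm bead
#'   conditions, 3.6 and 1.28).
#' @param config [sim_config()] used for every condition.
#' @param mix_fractions Proportions for the two-condition mixture
#'   (default 50:50 of the first two conditions).
#' @param d_range Sensitivity window applied to the mixture feature table;
#'   the default `c(0.1, Inf)` is the validated SPT benchmark range.
#' @param fcs_d FCS bead condition in um^2/s (default 12; set `NULL` to
#'   skip the FCS stage).
#' @param fcs_duration FCS trace duration in seconds (default 60).
#' @param k_max Largest mixture size scanned.
#' @param seed Master seed; every stage derives from it.
#'
#' @return List of class `"benchmark_report"`: `conditions` (per-condition
#'   recovery tibble), `mixture` (selection + k = 2 weights + truth
#'   fractions), `fcs` (fitted vs true parameters), `seed`, `config_hash`,
#'   `package_version`.
#' @export
run_benchmark_workflow <- function(d_values = c(glycerol20 = 3.6,
                                                glycerol50 = 1.28),
                                   config = sim_config(),
                                   mix_fractions = c(0.5, 0.5),
                                   d_range = c(0.1, Inf),
                                   fcs_d = 12,
                                   fcs_duration = 60,
                                   k_max = 10,
                                   seed = 1L) {
  seed <- as.integer(seed)
  labels <- names(d_values) %||% paste0("condition", seq_along(d_values))
  names(d_values) <- labels
  sets <- vector("list", length(d_values))
  cond_rows <- vector("list", length(d_values))
  for (i in seq_along(d_values)) {
    sets[[i]] <- simulate_brownian_tracks(d_values[i], config,
                                          label = labels[i],
                                          seed = seed + 1000L * i)
    est <- estimate_diffusion(sets[[i]],
                              localization_sigma = config$localization_sigma)
    s <- summarize_tracks(est)
    cond_rows[[i]] <- tibble::tibble(
      condition = labels[i], d_true = unname(d_values[i]),
      n_tracks = s$n_tracks, mean_detections = s$mean_detections,
      median_d60 = stats::median(est$d_60ms, na.rm = TRUE),
      mean_d60 = s$mean_d60, sd_d60 = s$sd_d60,
      mean_alpha = s$mean_alpha, sd_alpha = s$sd_alpha
    )
  }
  mixture <- NULL
  if (length(sets) >= 2) {
    mixed <- mix_track_sets(sets[1:2], mix_fractions, seed = seed + 77L)
    est <- estimate_diffusion(mixed,
                              localization_sigma = config$localization_sigma)
    feats <- build_feature_table(est, d_range = d_range)
    sel <- model_selection_curves(feats, k_max = k_max, seed = seed)
    g2 <- fit_gmm_k(feats, 2, seed = seed)
    pops <- summarize_populations(g2)
    truth <- table(est$truth_label) / nrow(est)
    mixture <- list(
      selected_k = sel$selected_k,
      selection = sel$curve,
      populations_k2 = pops,
      weights_k2 = pops$weight,
      truth_fractions = as.list(truth),
      n_features = nrow(feats),
      exclusions = attr(feats, "exclusions")
    )
  }
  fcs <- NULL
  if (!is.null(fcs_d)) {
    vol <- focal_volume(0.25, 1.25)
    spec <- fcs_sim_spec(fcs_d, alpha = 1, mean_molecules_in_volume = 2,
                         brightness = 2e4, bin_width = 1e-5,
                         duration = fcs_duration)
    trace <- simulate_fcs_trace(spec, vol, seed = seed + 555L)
    acf <- multitau_acf(trace)
    fit <- fit_acf_anomalous(acf, structure = (vol$w0 / vol$z0)^2,
                             w0 = vol$w0)
    fcs <- list(
      d_true = fcs_d, tau_d_true = vol$w0^2 / (4 * fcs_d),
      alpha_fitted = fit$alpha, tau_d_fitted = fit$tau_d,
      d_fitted = fit$d_coefficient, n_fitted = fit$n_molecules,
      converged = fit$converged
    )
  }
  structure(
    list(conditions = dplyr::bind_rows(cond_rows),
         mixture = mixture, fcs = fcs, seed = seed,
         config_hash = rlang::hash(list(d_values, config, mix_fractions,
                                        d_range, fcs_d, fcs_duration, k_max)),
         package_version = as.character(utils::packageVersion("sptfcs"))),
    class = "benchmark_report"
  )
}

#' RPB1-like mixture workflow
#'
#' Simulates the three-class nuclear mixture (immobile / subdiffusive /
#' mobile), runs the per-trajectory analysis, separates the immobile
#' fraction, selects and fits the mixture model on the mobile features,
#' converts population centres to transit times, and assembles the
#' molecule-budget report.
#'
#' @param config [sim_config()]; `n_tracks` is the total mixture size.
#' @param fractions Truth class fractions (see
#'   [simulate_rpb1_like_mixture()]).
#' @param total_density Total molecular density for the budget,
#'   molecules/um^3 (default 37).
#' @param fcs_fraction Fraction of molecules assumed visible to FCS only
#'   (default 1/3).
#' @param k_max Largest mixture size scanned.
#' @param seed Master seed.
#'
#' @return List of class `"rpb1_report"`: `estimates_summary`,
#'   `immobile_fraction`, `selection`, `populations` (with transit times),
#'   `budget`, `seed`, `config_hash`, `package_version`.
#' @export
run_rpb1_workflow <- function(config = sim_config(n_tracks = 1000),
                              fractions = c(immobile = 0.20,
                                            subdiffusive = 0.55,
                                            mobile = 0.25),
                              total_density = 37,
                              fcs_fraction = 1 / 3,
                              k_max = 10,
                              seed = 1L) {
  seed <- as.integer(seed)
  tracks <- simulate_rpb1_like_mixture(config, fractions, seed = seed)
  est <- estimate_diffusion(tracks,
                            localization_sigma = config$localization_sigma)
  immobile_fraction <- mean(est$mobility_class == "immobile", na.rm = TRUE)
  feats <- build_feature_table(est)
  sel <- model_selection_curves(feats, k_max = k_max, seed = seed)
  k_use <- max(sel$selected_k, 2L)
  model <- sel$models[[k_use]] %||% fit_gmm_k(feats, k_use, seed = seed)
  pops <- summarize_populations(model)
  tts <- transit_time(pops$d, pmin(pmax(pops$mean_alpha, 1e-6), 2),
                      source = "SPT")
  pops$tt <- tts$tt
  # mobile GMM classes scaled into the non-immobile share of the budget
  mobile_share <- 1 - immobile_fraction
  class_fracs <- c(immobile = immobile_fraction,
                   stats::setNames(pops$weight * mobile_share,
                                   paste0("population", pops$population)))
  budget <- molecule_budget(total_density, fcs_fraction, class_fracs)
  structure(
    list(
      estimates_summary = summarize_tracks(est),
      truth_fractions = fractions,
      immobile_fraction = immobile_fraction,
      selection = sel$curve,
      selected_k = sel$selected_k,
      populations = pops,
      budget = budget,
      seed = seed,
      config_hash = rlang::hash(list(config, fractions, total_density,
                                     fcs_fraction, k_max)),
      package_version = as.character(utils::packageVersion("sptfcs"))
    ),
    class = "rpb1_report"
  )
}

#' Write a workflow report as JSON
#'
#' @param report A `"benchmark_report"` or `"rpb1_report"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else {
    x
  }
}
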