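# Cross-method unification: transit times in a reference volume and
# molecule-budget bookkeeping.

#' Transit time within a reference volume
#'
#' Diffusion coefficients fitted with different anomalous exponents carry
#' different time units (um^2/s^alpha) and cannot be compared directly.
#' The transit time normalises both SPT and FCS outputs to one metric: the
#' time for the isotropic 3D mean squared displacement `6 D tau^alpha` to
#' cross the reference length `L = V^(1/3)`, divided by the reference
#' volume:
#' `tau = (L^2 / (6 D))^(1/alpha)`, `Tt = tau / V` (s/um^3).
#'
#' @param d Diffusion coefficient, um^2/s^alpha (vectorised).
#' @param alpha Anomalous exponent in (0, 2].
#' @param reference_volume Reference volume in um^3 (default 1).
#' @param source Label `"SPT"` or `"FCS"` recorded in the output.
#'
#' @return Tibble with columns `tt` (s/um^3), `residence_time` (s), `d`,
#'   `alpha`, `reference_volume`, `source`.  `d <= 0` (stationary class)
#'   yields `NA` transit time.
#' @export
transit_time <- function(d, alpha = 1, reference_volume = 1,
                         source = "SPT") {
  if (any(alpha <= 0 | alpha > 2)) stop_domain("`alpha` must lie in (0, 2]")
  check_positive(reference_volume, "reference_volume")
  len <- max(length(d), length(alpha))
  d <- rep_len(d, len)
  alpha <- rep_len(alpha, len)
  l_ref <- reference_volume^(1 / 3)
  tau <- ifelse(d > 0, (l_ref^2 / (6 * d))^(1 / alpha), NA_real_)
  tibble::tibble(
    tt = tau / reference_volume,
    residence_time = tau,
    d = d,
    alpha = alpha,
    reference_volume = reference_volume,
    source = source
  )
}

#' Compare SPT and FCS transit-time ranges
#'
#' Summarises the transit times seen by each method and quantifies their
#' separation: when the slowest (largest-Tt) FCS measurement is still
#' faster than the fastest SPT class, the two methods probe disjoint
#' mobility regimes.
#'
#' @param spt_tt Numeric vector of SPT transit times (s/um^3).
#' @param fcs_tt Numeric vector of FCS transit times (s/um^3).
#'
#' @return List: `summary` (tibble of min/median/max per method),
#'   `gap_ratio` (`min(SPT) / max(FCS)`), `overlap` (`TRUE` when the
#'   ranges touch, i.e. gap ratio <= 1).
#' @export
compare_fcs_spt <- function(spt_tt, fcs_tt) {
  spt_tt <- spt_tt[is.finite(spt_tt)]
  fcs_tt <- fcs_tt[is.finite(fcs_tt)]
  if (length(spt_tt) == 0 || length(fcs_tt) == 0) {
    stop_domain("both SPT and FCS transit-time sets must be non-empty")
  }
  summary <- tibble::tibble(
    source = c("SPT", "FCS"),
    n = c(length(spt_tt), length(fcs_tt)),
    min_tt = c(min(spt_tt), min(fcs_tt)),
    median_tt = c(stats::median(spt_tt), stats::median(fcs_tt)),
    max_tt = c(max(spt_tt), max(fcs_tt))
  )
  gap_ratio <- min(spt_tt) / max(fcs_tt)
  list(summary = summary, gap_ratio = gap_ratio, overlap = gap_ratio <= 1)
}

#' Molecule-budget bookkeeping
#'
#' Splits a total molecular density between the fraction seen by FCS and
#' the remainder observable by SPT, and distributes the SPT share over
#' mobility classes.
#'
#' @param total_density Total density in molecules/um^3.
#' @param fcs_fraction Fraction of molecules detected by FCS, in `[0, 1]`.
#' @param spt_class_fractions Named fractions of SPT trajectories per
#'   mobility class, summing to 1.
#'
#' @return List of class `"molecule_budget"`: `total_density`,
#'   `fcs_fraction`, `spt_fraction`, `fcs_density`, `spt_density`
#'   (exact and rounded), and a `classes` tibble with per-class
#'   `fraction_of_spt`, `fraction_of_total`, `percent_of_total` (rounded
#'   half away from zero, the reporting convention), `density`
#'   (molecules/um^3, exact) and `density_rounded`.  Class densities sum
#'   exactly to `spt_fraction * total_density` before rounding.
#' @export
molecule_budget <- function(total_density, fcs_fraction,
                            spt_class_fractions) {
  check_positive(total_density, "total_density")
  check_fraction(fcs_fraction, "fcs_fraction")
  check_fraction(spt_class_fractions, "spt_class_fractions")
  if (abs(sum(spt_class_fractions) - 1) > 1e-8) {
    stop_domain("`spt_class_fractions` must sum to 1")
  }
  spt_fraction <- 1 - fcs_fraction
  frac_total <- spt_class_fractions * spt_fraction
  dens <- frac_total * total_density
  classes <- tibble::tibble(
    class = names(spt_class_fractions) %||%
      paste0("class", seq_along(spt_class_fractions)),
    fraction_of_spt = as.numeric(spt_class_fractions),
    fraction_of_total = as.numeric(frac_total),
    percent_of_total = round_half_up(100 * as.numeric(frac_total)),
    density = as.numeric(dens),
    density_rounded = round_half_up(as.numeric(dens))
  )
  structure(
    list(
      total_density = total_density,
      fcs_fraction = fcs_fraction,
      spt_fraction = spt_fraction,
      fcs_density = fcs_fraction * total_density,
      spt_density = spt_fraction * total_density,
      spt_density_rounded = round_half_up(spt_fraction * total_density),
      classes = classes
    ),
    class = "molecule_budget"
  )
}

#' @export
print.molecule_budget <- function(x, ...) {
  cat(sprintf("Molecule budget: %g molecules/um^3 total; FCS %.1f%% (%.1f/um^3), SPT %.1f%% (%.1f/um^3, ~%d)\n",
              x$total_density, 100 * x$fcs_fraction, x$fcs_density,
              100 * x$spt_fraction, x$spt_density, x$spt_density_rounded))
  print(x$classes)
  invisible(x)
}
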