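#' Stokes-Einstein diffusion coefficient
#'
#' Computes the theoretical diffusion coefficient `D = kT / (6 pi r mu)` of a
#' sphere in a viscous medium, the standard for calibration beads in
#' water/glycerol mixtures.
#'
#' @param radius_nm Hydrodynamic radius in nanometres (bead diameter / 2).
#' @param viscosity_cp Dynamic viscosity in centipoise (1 cP = 1 mPa s).
#' @param temperature_k Absolute temperature in Kelvin.
#'
#' @return Diffusion coefficient in um^2/s.  Inputs are vectorised and
#'   recycled by the usual rules.
#'
#' @details The Boltzmann constant is the CODATA value 1.380649e-23 J/K.
#'   `D` is exactly inversely proportional to both radius and viscosity, so
#'   doubling either halves the result.
#'
#' @examples
#' stokes_einstein_d(20, 0.8, 310.15)  # 40 nm bead in water at 37 C
#' @export
stokes_einstein_d <- function(radius_nm, viscosity_cp, temperature_k) {
  check_positive(radius_nm, "radius_nm")
  check_positive(viscosity_cp, "viscosity_cp")
  check_positive(temperature_k, "temperature_k")
  r_m <- radius_nm * 1e-9
  mu_pas <- viscosity_cp * 1e-3
  d_m2s <- boltzmann_k() * temperature_k / (6 * pi * r_m * mu_pas)
  d_m2s * 1e12 # m^2/s -> um^2/s
}

#' Water/glycerol viscosity reference table
#'
#' The five standard glycerol weight fractions used for bead calibration,
#' with their dynamic viscosities and the published reference diffusion
#' coefficients for 40 nm and 100 nm beads.  The reference columns are kept
#' for comparison only; [build_bead_conditions()] always recomputes the
#' theoretical values from the Stokes-Einstein formula.
#'
#' @return A tibble with columns `glycerol_fraction` (weight fraction),
#'   `viscosity_cp`, `d40_ref` and `d100_ref` (um^2/s).
#' @export
glycerol_viscosity_table <- function() {
  tibble::tibble(
    glycerol_fraction = c(0, 0.1, 0.2, 0.5, 0.8),
    viscosity_cp = c(0.8, 1.0, 1.3, 3.8, 27.8),
    d40_ref = c(15.1, 12.1, 9.0, 3.2, 0.4),
    d100_ref = c(6.0, 4.8, 3.6, 1.28, 0.2)
  )
}

#' Build bead benchmark conditions
#'
#' Expands a (glycerol fraction, viscosity) table over a set of bead
#' diameters and attaches the Stokes-Einstein theoretical diffusion
#' coefficient to each condition.
#'
#' @param table Data frame with columns `glycerol_fraction` (in `[0, 1]`) and
#'   `viscosity_cp` (> 0).  Defaults to [glycerol_viscosity_table()].
#' @param diameters_nm Bead diameters in nanometres.
#' @param temperature_k Absolute temperature; default 310.15 K (37 C, the
#'   temperature at which samples are kept).
#'
#' @return A tibble with one row per (condition, diameter): columns
#'   `glycerol_fraction`, `viscosity_cp`, `bead_diameter_nm`,
#'   `temperature_k`, `d_theory` (um^2/s).
#' @export
build_bead_conditions <- function(table = glycerol_viscosity_table(),
                                  diameters_nm = c(40, 100),
                                  temperature_k = 310.15) {
  stopifnot(is.data.frame(table),
            all(c("glycerol_fraction", "viscosity_cp") %in% names(table)))
  check_fraction(table$glycerol_fraction, "glycerol_fraction")
  check_positive(table$viscosity_cp, "viscosity_cp")
  check_positive(temperature_k, "temperature_k")
  if (anyDuplicated(table$glycerol_fraction)) {
    stop_domain("duplicate glycerol fractions in condition table")
  }
  if (length(diameters_nm) == 0) {
    return(tibble::tibble(
      glycerol_fraction = numeric(), viscosity_cp = numeric(),
      bead_diameter_nm = numeric(), temperature_k = numeric(),
      d_theory = numeric()
    ))
  }
  check_positive(diameters_nm, "diameters_nm")
  grid <- expand.grid(
    row = seq_len(nrow(table)),
    bead_diameter_nm = diameters_nm,
    KEEP.OUT.ATTRS = FALSE
  )
  out <- tibble::tibble(
    glycerol_fraction = table$glycerol_fraction[grid$row],
    viscosity_cp = table$viscosity_cp[grid$row],
    bead_diameter_nm = grid$bead_diameter_nm,
    temperature_k = temperature_k,
  )
  out$d_theory <- stokes_einstein_d(out$bead_diameter_nm / 2,
                                    out$viscosity_cp, out$temperature_k)
  out
}
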