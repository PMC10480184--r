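# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_domain <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_domain(sprintf("`%s` must be finite and > 0", name))
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_domain(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# run `expr` under a fixed seed when `seed` is non-NULL, leaving the
# caller's RNG state untouched; otherwise use the current RNG stream
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# largest-remainder apportionment of n into parts proportional to `fractions`
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Boltzmann constant (CODATA 2018)
#'
#' @return Boltzmann constant in J/K.
#' @keywords internal
boltzmann_k <- function() 1.380649e-23

#' Avogadro constant (exact, SI 2019)
#'
#' @return Avogadro constant in 1/mol.
#' @keywords internal
avogadro_n <- function() 6.02214076e23
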