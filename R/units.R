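## Physical constants and unit conversions. Internal haemodynamics is CGS
## (cm, g, s; pressure in barye = dyn/cm^2); user-facing pressures are mmHg
## and elastic moduli Pa. Conversions are defined once, here.

#' Unit conversion and physical constants
#'
#' A named list of the conversion factors and physical constants used
#' throughout the package: \code{Pa_to_barye} (10), \code{mmHg_to_barye}
#' (1333.22), \code{mmHg_to_Pa} (133.322), Faraday's constant \code{F_const}
#' (C/mol) and the gas constant \code{R_gas} (J/(mol K)).
#'
#' @format Named list of scalars.
#' @export
ngvu_constants <- list(
  Pa_to_barye   = 10,
  mmHg_to_barye = 1333.22,
  mmHg_to_Pa    = 133.322,
  F_const       = 96485.332,   # C / mol
  R_gas         = 8.314462     # J / (mol K)
)

#' Blood viscosity laws
#'
#' Diameter-dependent in-vitro viscosity after Pries and co-workers, or a
#' constant-viscosity fallback. The in-vitro law gives the relative apparent
#' viscosity of blood flowing in a glass tube of diameter \code{d_um}
#' (micrometres) at discharge haematocrit \code{hct}, scaled by the plasma
#' viscosity (1.2e-3 Pa s).
#'
#' @param d_um vessel diameter in micrometres.
#' @param hct discharge haematocrit (default 0.45).
#' @return dynamic viscosity in Pa s.
#' @examples
#' viscosity_pries(100)   # falls near 3e-3 Pa s for a 100 um tube
#' viscosity_constant(8)
#' @export
viscosity_pries <- function(d_um, hct = 0.45) {
  stopifnot(all(d_um > 0))
  mu_plasma <- 1.2e-3
  mu045 <- 220 * exp(-1.3 * d_um) + 3.2 - 2.44 * exp(-0.06 * d_um^0.645)
  C <- (0.8 + exp(-0.075 * d_um)) *
    (-1 + 1 / (1 + 1e-11 * d_um^12)) + 1 / (1 + 1e-11 * d_um^12)
  mu_rel <- 1 + (mu045 - 1) *
    ((1 - hct)^C - 1) / ((1 - 0.45)^C - 1)
  mu_plasma * mu_rel
}

#' @rdname viscosity_pries
#' @param mu constant dynamic viscosity in Pa s (default 3.5e-3).
#' @export
viscosity_constant <- function(d_um, mu = 3.5e-3) {
  rep_len(mu, length(d_um))
}

#' Resolve a viscosity law by name
#'
#' @param law \code{"pries"} or \code{"constant"}.
#' @return function of diameter in micrometres returning Pa s.
#' @export
viscosity_law <- function(law = c("pries", "constant")) {
  law <- match.arg(law)
  if (law == "pries") viscosity_pries else viscosity_constant
}
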