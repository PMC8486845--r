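#' Physical constants and unit conversions
#'
#' The conductance quantum \eqn{G_0 = 2e^2/h} is the natural unit of
#' single-molecule conductance; molecular junction plateaus are reported in
#' \eqn{mG_0} (\eqn{10^{-3} G_0}). Tunnelling decay constants \eqn{\beta}
#' follow the convention \eqn{G \propto \exp(-\beta z)} with \eqn{z} in
#' Angstrom (natural log), so \eqn{1\,\mathrm{\AA}^{-1} = 10\,nm^{-1}}.
#'
#' @name zj-constants
#' @format `G0_SIEMENS` is the conductance quantum in siemens (77.48 uS).
NULL

#' @rdname zj-constants
#' @export
G0_SIEMENS <- 7.748e-5

# Boltzmann constant in pN nm / K
KB_PN_NM <- 1.380649e-2

# 1 kcal/mol in pN nm (per molecule)
KCAL_MOL_PN_NM <- 6.947695

# gas constant in kcal / (mol K)
R_KCAL_MOL_K <- 1.987204e-3

#' Convert a tunnelling decay constant between Angstrom and nm conventions
#'
#' `beta` values are quoted in inverse Angstrom for the natural-log decay
#' `G = G_ref * exp(-beta * z_Angstrom)`. Internally traces carry
#' displacement in nm and conductance in log10, so fits produce slopes in
#' decades/nm; these helpers centralise the conversion.
#'
#' @param beta_A decay constant in 1/Angstrom.
#' @param slope_dec_nm slope of log10(G) per nm (signed).
#' @return the converted value.
#' @export
#' @examples
#' beta_A_to_dec_per_nm(2.2)
#' dec_per_nm_to_beta_A(-beta_A_to_dec_per_nm(2.2))
beta_A_to_dec_per_nm <- function(beta_A) beta_A * 10 / log(10)

#' @rdname beta_A_to_dec_per_nm
#' @export
dec_per_nm_to_beta_A <- function(slope_dec_nm) -slope_dec_nm * log(10) / 10

# thermal energy in pN nm at temperature T (K)
kT_pN_nm <- function(temperature) KB_PN_NM * temperature

# kcal/mol -> units of kT at temperature T
kcal_to_kT <- function(dg_kcal, temperature) dg_kcal / (R_KCAL_MOL_K * temperature)
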