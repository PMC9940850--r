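#' @useDynLib mldroplet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm lm.fit coef optimize uniroot runif rnorm var sd
#'   quantile setNames complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

## Physical constants (kJ/mol, nm, ps, Da, elementary charges).
.GAS_R <- 0.00831446261815324   # kJ mol^-1 K^-1
.AVOGADRO <- 6.02214076e23
## 1 Da / nm^3 expressed in mg/mL: 1e24 nm^3/L / N_A * 1000 mg/g
.DA_NM3_TO_MGML <- 1.66053907

#' Thermal energy in kJ/mol
#'
#' @param temperature Temperature in kelvin.
#' @return kT in kJ/mol (about 2.494 at 300 K).
#' @export
kT_kJmol <- function(temperature = 300) .GAS_R * temperature

#' Convert a surface tension from mN/m to kT/nm^2
#'
#' 1 mN/m = 1e-21 J/nm^2 = 0.602214 kJ mol^-1 nm^-2; dividing by kT gives
#' about 0.24143 kT/nm^2 at 300 K.
#'
#' @param sigma_mN_m Surface tension in mN/m.
#' @param temperature Temperature in kelvin.
#' @return Dimensionless surface tension per nm^2 (beta*sigma).
#' @export
sigma_to_kT_nm2 <- function(sigma_mN_m, temperature = 300) {
  sigma_mN_m * 1e-3 * 1e-18 * .AVOGADRO / 1e3 / kT_kJmol(temperature)
}

#' @rdname sigma_to_kT_nm2
#' @param beta_sigma Dimensionless surface tension in kT/nm^2.
#' @export
sigma_from_kT_nm2 <- function(beta_sigma, temperature = 300) {
  beta_sigma * kT_kJmol(temperature) * 1e3 / (.AVOGADRO * 1e-21)
}

#' Mass-density / number-density conversions
#'
#' Protein densities appear both as mg/mL (experimental convention) and as
#' chains/nm^3 (the molar density entering the droplet thermodynamics). The
#' two are tied by the chain molar mass:
#' rho\[mg/mL\] = rho\[nm^-3\] * chain_mass\[Da\] * 1.66054.
#'
#' @param rho_mgml Mass density in mg/mL.
#' @param chain_mass Chain molar mass in Da (g/mol).
#' @return Number density in chains/nm^3.
#' @export
mgml_to_nm3 <- function(rho_mgml, chain_mass) {
  rho_mgml / (chain_mass * .DA_NM3_TO_MGML)
}

#' @rdname mgml_to_nm3
#' @param rho_nm3 Number density in chains/nm^3.
#' @export
nm3_to_mgml <- function(rho_nm3, chain_mass) {
  rho_nm3 * chain_mass * .DA_NM3_TO_MGML
}
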