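## Physical constants in the package's internal unit system:
## energy kcal/mol, length nm, time ps, mass amu, charge e.
## 1 amu nm^2/ps^2 = 1 kJ/mol exactly (to the precision of N_A), hence
## KCAL_PER_INTERNAL below.

#' Physical constants used throughout the package
#'
#' A named list of constants in the internal unit system (kcal/mol, nm, ps,
#' amu, elementary charge). `coulomb` is \eqn{N_A e^2 / (4\pi\epsilon_0)} in
#' kcal nm / mol so that the Coulomb energy between unit charges is
#' `coulomb / (eps * r)`. `molarPerPerNm3` converts a number density in
#' nm^-3 to mol/L (1 nm^-3 = 1.66054 M); its reciprocal `perNm3PerMolar`
#' (0.602214) is the number of particles per nm^3 in a 1 M solution.
#'
#' @return A named list of numeric constants.
#' @examples
#' tisConstants()$kB * 310.15  # thermal energy at 37 C, kcal/mol
#' @export
tisConstants <- function() {
  list(
    kB = 0.0019872041,        # kcal/mol/K
    coulomb = 33.2058,        # kcal nm/mol, N_A e^2/(4 pi eps0)
    molarPerPerNm3 = 1.66054, # mol/L per nm^-3
    perNm3PerMolar = 0.602214,# nm^-3 per mol/L  (N_A / 1e24)
    kcalPerInternal = 0.2390057, # kcal/mol per (amu nm^2/ps^2)
    internalPerKcal = 4.184      # (amu nm^2/ps^2) per kcal/mol
  )
}

#' Relative dielectric constant of water
#'
#' Empirical temperature dependence (Malmberg-Maryott polynomial), valid
#' between 0 and 100 degrees Celsius. Water is implicit in the model; all
#' electrostatics are screened by this dielectric.
#'
#' @param temperatureC temperature in degrees Celsius.
#' @return Dimensionless relative permittivity.
#' @examples
#' waterDielectric(25)  # ~78.3
#' @export
waterDielectric <- function(temperatureC) {
  stopifnot(is.numeric(temperatureC), all(temperatureC >= 0), all(temperatureC <= 100))
  87.740 - 0.40008 * temperatureC + 9.398e-4 * temperatureC^2 -
    1.410e-6 * temperatureC^3
}

#' Bjerrum length of water
#'
#' Distance at which the Coulomb attraction between two unit charges in
#' water balances the thermal energy,
#' \eqn{l_B = e^2 / (4\pi\epsilon_0\,\epsilon(T)\,k_B T)}, with the
#' empirical dielectric constant of water at the given temperature. Used as
#' the cutoff distance for counting condensed ions: a cation closer than
#' l_B to a phosphate is bound more strongly than thermal motion can
#' disrupt.
#'
#' @param temperatureC temperature in degrees Celsius (0..100).
#' @return Bjerrum length in nm (about 0.73 nm at 37 C).
#' @examples
#' round(bjerrumLength(37), 2)  # 0.73
#' @export
bjerrumLength <- function(temperatureC) {
  stopifnot(is.numeric(temperatureC), all(temperatureC >= 0), all(temperatureC <= 100))
  cst <- tisConstants()
  TK <- temperatureC + 273.15
  cst$coulomb / (waterDielectric(temperatureC) * cst$kB * TK)
}

#' Theoretical collapse-time estimate for an RNA chain
#'
#' Scaling estimate \eqn{\tau_c \approx \tau_0 N^\alpha} for the time of
#' the initial nonspecific/specific collapse of an N-nucleotide chain, with
#' prefactor tau0 on the order of 0.1-1 microseconds and exponent alpha
#' close to 1.
#'
#' @param N number of nucleotides (>= 1).
#' @param tau0 prefactor in ms (default 5e-4 ms = 0.5 us).
#' @param alpha scaling exponent (default 1).
#' @return Collapse time in ms.
#' @examples
#' collapseTimeEstimate(195)  # 0.0975 ms
#' @export
collapseTimeEstimate <- function(N, tau0 = 5e-4, alpha = 1) {
  stopifnot(N >= 1, tau0 > 0)
  tau0 * N^alpha
}
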