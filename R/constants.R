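#' Physical constants and unit bridges
#'
#' All spectroscopic quantities in the package use the unit system common to
#' solid-state infrared work: frequencies as wavenumbers in cm^-1, cell
#' volumes in Angstrom^3, Born effective charges in units of the elementary
#' charge, and mode intensities (oscillator-strength traces) in
#' (D/A)^2/amu, where D is the Debye.  Two derived constants bridge these
#' units:
#'
#' * `gamma_eps`: the permittivity contribution of one oscillator is
#'   `gamma_eps * S / (V * nu^2)` with `S` in (D/A)^2/amu, `V` in A^3 and
#'   `nu` in cm^-1.  This is the `4*pi/V` prefactor of the Lorentz sum
#'   evaluated in Gaussian units: `4*pi * (1e-20 esu^2 / amu_g) /
#'   ((2*pi*c)^2 * 1e-24 cm^3)`.
#' * `e_to_debye_per_angstrom`: one elementary charge displaced by one
#'   Angstrom is this many Debye, so intensities in e^2/amu are multiplied
#'   by its square (~23.071) to land in (D/A)^2/amu.
#' * `molar_absorption_unit`: integrated molar absorption coefficient in
#'   L mol^-1 cm^-2 per unit intensity in (D/A)^2/amu,
#'   `N_A*pi/(3000 c^2)` after the esu^2/g conversion (~4225.6).
#'
#' @return Named list of constants (see details).
#' @examples
#' unit_constants()$gamma_eps
#' @export
unit_constants <- function() {
  c_cm <- 2.99792458e10           # speed of light, cm/s (exact)
  n_avogadro <- 6.02214076e23     # 1/mol (exact)
  amu_g <- 1 / n_avogadro         # g per amu
  e_coulomb <- 1.602176634e-19    # C (exact)
  e_esu <- e_coulomb * 2.99792458e9   # statC
  # e * Angstrom in Debye: (esu * 1e-8 cm) / (1e-18 esu cm per D)
  e_to_d_per_a <- e_esu * 1e-8 / 1e-18
  # (D/A)^2/amu  ->  esu^2/g
  conv <- 1e-20 / amu_g
  gamma_eps <- 4 * pi * conv / ((2 * pi * c_cm)^2 * 1e-24)
  molar_abs <- n_avogadro * pi / (3000 * c_cm^2) * conv
  list(
    c_cm = c_cm,
    n_avogadro = n_avogadro,
    amu_g = amu_g,
    e_to_debye_per_angstrom = e_to_d_per_a,
    e2_amu_to_intensity = e_to_d_per_a^2,
    gamma_eps = gamma_eps,
    # same bridge expressed for squared-frequency units (cm^-2) with charges
    # still in e^2: used by the non-analytic LO correction
    gamma_lo = gamma_eps * e_to_d_per_a^2,
    molar_absorption_unit = molar_abs
  )
}
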