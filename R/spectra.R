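#' Wavenumber grid
#'
#' Inclusive arithmetic grid from `v_min` to `v_max` in steps of
#' `increment`; the final point is emitted if it falls within half a step of
#' `v_max`.
#'
#' @param v_min,v_max Grid limits, cm^-1.
#' @param increment Step, cm^-1 (> 0).
#' @return Numeric vector of wavenumbers.
#' @export
spectral_grid <- function(v_min = 0, v_max = 300, increment = 0.2) {
  if (v_min > v_max) stop("`v_min` must be <= `v_max`", call. = FALSE)
  if (increment <= 0) stop("`increment` must be > 0", call. = FALSE)
  n <- floor((v_max - v_min) / increment + 0.5 + 1e-9)
  v_min + increment * 0:n
}

#' Complex refractive index from the permittivity
#'
#' `N = n + i*kappa` is the square root of the complex permittivity with the
#' physical (absorbing) branch `kappa >= 0`.
#'
#' @param eps_eff Complex vector of effective permittivities.
#' @return Complex vector with non-negative imaginary part.
#' @export
refractive_index <- function(eps_eff) {
  N <- sqrt(as.complex(eps_eff))
  flip <- Im(N) < 0
  N[flip] <- -N[flip]
  N
}

#' Decadic absorption coefficient
#'
#' `alpha = 4 pi nu kappa log10(e)` in cm^-1, with `nu` in cm^-1 and
#' `kappa` the imaginary refractive index.
#'
#' @param nu Wavenumber(s), cm^-1.
#' @param kappa Imaginary part(s) of the refractive index.
#' @return Absorption coefficient(s), cm^-1.
#' @export
absorption_coefficient <- function(nu, kappa) {
  stopifnot(all(nu >= 0))
  4 * pi * nu * kappa * log10(exp(1))
}

#' Concentration of unit cells
#'
#' Moles of unit cells per litre at volume fraction `f`:
#' `C = f * 1000 / (V * 1e-24 * N_A)` with `V` in Angstrom^3.
#'
#' @param volume_fraction Volume fraction of crystal, (0, 1].
#' @param cell_volume Unit-cell volume, Angstrom^3.
#' @return Concentration in mol/L.
#' @export
concentration <- function(volume_fraction, cell_volume) {
  stopifnot(volume_fraction > 0, volume_fraction <= 1, cell_volume > 0)
  uc <- unit_constants()
  volume_fraction * 1000 / (cell_volume * 1e-24 * uc$n_avogadro)
}

#' Integrated molar absorption coefficient of a transition
#'
#' Converts a transition intensity in (D/A)^2/amu to the integrated molar
#' absorption coefficient `A_k` in L mol^-1 cm^-2 (1 L mol^-1 cm^-2 =
#' 0.01 km/mol); one intensity unit corresponds to ~4225.6 L mol^-1 cm^-2,
#' i.e. ~42.256 km/mol.
#'
#' @param intensity Transition intensity, (D/A)^2/amu (>= 0).
#' @param degeneracy Mode degeneracy g_k (default 1).
#' @return Integrated molar absorption coefficient, L mol^-1 cm^-2.
#' @export
integrated_molar_absorption <- function(intensity, degeneracy = 1) {
  stopifnot(all(intensity >= 0), all(degeneracy >= 1))
  unit_constants()$molar_absorption_unit * degeneracy * intensity
}

#' Molecular-route absorption spectrum
#'
#' Sums normalized Lorentzian bands: band k contributes
#' `a_k(nu) = (2 A_k / pi) * sigma_k / (4 (nu - nu_k)^2 + sigma_k^2)`, whose
#' integral over wavenumber is `A_k` and whose peak height is
#' `2 A_k / (pi sigma_k)`.  The absorption coefficient is `alpha = C a`.
#'
#' @param bands Data frame with columns `frequency` (cm^-1), `a_integrated`
#'   (L mol^-1 cm^-2), `sigma` (FWHM, cm^-1, > 0); optional `degeneracy`
#'   already folded into `a_integrated`.
#' @param grid Wavenumber grid, cm^-1.
#' @param concentration Concentration C, mol/L, used for the absorption
#'   column.
#' @return Tibble with `wavenumber`, `molar_absorption`
#'   (L mol^-1 cm^-1) and `absorption` (cm^-1).
#' @export
molecular_spectrum <- function(bands, grid, concentration = 1) {
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("frequency", "a_integrated", "sigma") %in% names(bands)),
            all(bands$sigma > 0))
  a <- numeric(length(grid))
  for (k in seq_len(nrow(bands))) {
    a <- a + (2 * bands$a_integrated[k] / pi) * bands$sigma[k] /
      (4 * (grid - bands$frequency[k])^2 + bands$sigma[k]^2)
  }
  tibble::tibble(
    wavenumber = grid,
    molar_absorption = a,
    absorption = concentration * a
  )
}

#' Powder absorption spectrum via effective-medium theory
#'
#' The full pipeline: evaluate the crystal's Lorentz-oscillator permittivity
#' tensor on the grid, homogenize it with the scenario's mixing rule,
#' take the physical complex refractive index, and convert to decadic
#' absorption and molar absorption coefficients (per mole of unit cells,
#' concentration including the volume fraction).
#'
#' @param model A [dielectric_model()].
#' @param scenario A [mixing_scenario()]; its `inclusion_volume` is ignored
#'   in favour of the model's cell volume.
#' @param grid Wavenumber grid, cm^-1.
#' @return A tibble of class `spectrum_table` with columns `wavenumber`,
#'   `eps_real`, `eps_imag`, `absorption` (cm^-1), `molar_absorption`
#'   (L mol^-1 cm^-1) and `converged`; attributes `scenario` and
#'   `concentration` (mol/L).
#' @examples
#' mgo <- from_oscillator_table(reference_models()$mgo, sigma = 10)
#' sc <- mixing_scenario("maxwell", 0.1, 2,
#'                       depolarization(shape_spec("sphere")),
#'                       mgo$cell_volume)
#' sp <- powder_spectrum(mgo, sc, spectral_grid(300, 800, 2))
#' sp$wavenumber[which.max(sp$molar_absorption)]
#' @export
powder_spectrum <- function(model, scenario, grid) {
  stopifnot(inherits(model, "dielectric_model"),
            inherits(scenario, "mixing_scenario"))
  scenario$inclusion_volume <- model$cell_volume
  scenario$number_density <- scenario$volume_fraction / model$cell_volume
  eps_i <- permittivity(model, grid)
  eff <- effective_medium(scenario, eps_i)
  N <- refractive_index(eff$values)
  alpha <- absorption_coefficient(grid, Im(N))
  C <- concentration(scenario$volume_fraction, model$cell_volume)
  out <- tibble::tibble(
    wavenumber = as.numeric(grid),
    eps_real = Re(eff$values),
    eps_imag = Im(eff$values),
    absorption = alpha,
    molar_absorption = alpha / C,
    converged = eff$converged
  )
  attr(out, "scenario") <- scenario
  attr(out, "concentration") <- C
  class(out) <- c("spectrum_table", class(out))
  out
}

#' Locate spectrum peaks
#'
#' Finds local maxima of a spectrum column and refines each position by
#' quadratic interpolation through the three points around the grid maximum
#' (peak positions are usually quoted finer than the grid step).
#'
#' @param spectrum A tibble with a `wavenumber` column (e.g. a
#'   `spectrum_table`).
#' @param column Column to search (default `"molar_absorption"`).
#' @param min_height Discard maxima below this fraction of the global
#'   maximum (default 0.01).
#' @return Tibble with `wavenumber` (interpolated) and `height`, sorted by
#'   wavenumber.
#' @export
find_spectrum_peaks <- function(spectrum, column = "molar_absorption",
                                min_height = 0.01) {
  y <- spectrum[[column]]
  x <- spectrum$wavenumber
  n <- length(y)
  if (n < 3) return(tibble::tibble(wavenumber = numeric(), height = numeric()))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  idx <- idx[y[idx] >= min_height * max(y)]
  refine <- function(i) {
    y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
    d <- y0 - 2 * y1 + y2
    if (d >= 0) return(c(x[i], y1))   # flat/degenerate: keep grid point
    s <- 0.5 * (y0 - y2) / d
    h <- x[i + 1] - x[i]
    c(x[i] + s * h, y1 - 0.25 * (y0 - y2) * s)
  }
  pk <- t(vapply(idx, refine, numeric(2)))
  tibble::tibble(wavenumber = pk[, 1], height = pk[, 2])
}
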