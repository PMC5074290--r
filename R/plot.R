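#' Plot a powder spectrum
#'
#' @param object A `spectrum_table` from [powder_spectrum()].
#' @param quantity One of `"molar_absorption"`, `"absorption"`,
#'   `"real"`, `"imaginary"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.spectrum_table <- function(object,
                                    quantity = c("molar_absorption",
                                                 "absorption", "real",
                                                 "imaginary"),
                                    ...) {
  quantity <- match.arg(quantity)
  col <- switch(quantity, real = "eps_real", imaginary = "eps_imag",
                quantity)
  lab <- switch(quantity,
                molar_absorption = "molar absorption (L mol⁻¹ cm⁻¹)",
                absorption = "absorption (cm⁻¹)",
                real = "Re ε_eff", imaginary = "Im ε_eff")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$wavenumber, y = .data[[col]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = lab) +
    ggplot2::theme_minimal()
}

#' @export
plot.spectrum_table <- function(x, ...) print(autoplot(x, ...))

#' Overlay several scenario spectra
#'
#' @param spectra Named list of `spectrum_table`s (e.g. from
#'   [run_powderspec()]).
#' @param quantity As in [autoplot.spectrum_table()].
#' @return A ggplot object with one line per scenario.
#' @export
plot_spectra <- function(spectra, quantity = "molar_absorption") {
  col <- switch(quantity, real = "eps_real", imaginary = "eps_imag", quantity)
  df <- dplyr::bind_rows(
    lapply(names(spectra), function(k) {
      tibble::tibble(scenario = k,
                     wavenumber = spectra[[k]]$wavenumber,
                     value = spectra[[k]][[col]])
    })
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, y = .data$value,
                                   colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = quantity) +
    ggplot2::theme_minimal()
}

#' Tidy the oscillators of a dielectric model
#'
#' One row per oscillator: mode number, TO frequency, intensity, damping,
#' activity flag, plus the integrated molar absorption coefficient and
#' Lorentzian peak height implied by the intensity.
#'
#' @param x A [dielectric_model()].
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy
#' @export
tidy.dielectric_model <- function(x, ...) {
  osc <- x$oscillators
  tibble::tibble(
    mode = osc$mode,
    frequency = osc$frequency,
    intensity = osc$intensity,
    sigma = osc$sigma,
    active = osc$active,
    a_integrated = integrated_molar_absorption(pmax(osc$intensity, 0)),
    peak_height = 2 * integrated_molar_absorption(pmax(osc$intensity, 0)) /
      (pi * osc$sigma)
  )
}

#' One-line summary of a dielectric model
#'
#' @param x A [dielectric_model()].
#' @param ... Unused.
#' @return A one-row tibble: oscillator counts, cell volume, the isotropic
#'   averages of the optical and static permittivities.
#' @importFrom generics glance
#' @export
glance.dielectric_model <- function(x, ...) {
  eps0 <- permittivity(x, 0)[, , 1]
  tibble::tibble(
    n_oscillators = nrow(x$oscillators),
    n_active = sum(x$oscillators$active),
    cell_volume = x$cell_volume,
    eps_optical = mean(diag(x$epsilon_inf)),
    eps_static = mean(Re(diag(eps0)))
  )
}

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance
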