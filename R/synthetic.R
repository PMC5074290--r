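#' Random but physically valid synthetic crystal
#'
#' Generates a toy `phonon_data` object for testing: a mildly distorted
#' cell, random positive masses, Born charge tensors obeying the acoustic
#' sum rule (they sum to the zero tensor), an orthonormal eigenvector set
#' containing the three exact translational modes (which therefore carry
#' zero frequency and, by the sum rule, zero oscillator strength), random
#' optical frequencies, and a random symmetric positive-definite optical
#' permittivity.  Deterministic under `seed`.
#'
#' @param n_atoms Number of atoms (>= 2).
#' @param seed Integer seed.
#' @param anisotropy Scale of the anisotropic perturbation applied to the
#'   cell and the optical permittivity (0 gives a cubic cell and isotropic
#'   epsilon_inf).
#' @param freq_range Range (cm^-1) for the random optical-mode frequencies.
#' @return A validated [phonon_data()] object.
#' @export
make_toy_crystal <- function(n_atoms = 3, seed = 1, anisotropy = 0.1,
                             freq_range = c(50, 1500)) {
  stopifnot(n_atoms >= 2)
  set.seed(seed)
  n3 <- 3 * n_atoms
  lat <- diag(3) * 5 + matrix(stats::rnorm(9, sd = anisotropy), 3, 3)
  cell <- crystal_cell(lat)
  masses <- stats::runif(n_atoms, 1, 40)
  # Born charges with acoustic sum rule
  zs <- lapply(seq_len(n_atoms), function(i) {
    matrix(stats::rnorm(9), 3, 3) + diag(3) * stats::runif(1, -2, 2)
  })
  zsum <- Reduce(`+`, zs) / n_atoms
  zs <- lapply(zs, function(z) z - zsum)
  # translations in mass-weighted coordinates: t_b[a, alpha] ~ sqrt(m_a) d_ab
  tr <- matrix(0, 3, n3)
  for (b in 1:3) tr[b, seq(b, n3, by = 3)] <- sqrt(masses)
  tr <- tr / sqrt(sum(masses))
  # complete to an orthonormal basis, then randomize the optical subspace
  q <- qr.Q(qr(cbind(t(tr), matrix(stats::rnorm(n3 * (n3 - 3)), n3))))
  # fix possible sign flips of the first three columns
  for (b in 1:3) if (sum(q[, b] * tr[b, ]) < 0) q[, b] <- -q[, b]
  opt <- q[, 4:n3, drop = FALSE]
  mix <- qr.Q(qr(matrix(stats::rnorm((n3 - 3)^2), n3 - 3)))
  u <- rbind(tr, t(opt %*% mix))
  freqs <- c(0, 0, 0,
             sort(stats::runif(n3 - 3, freq_range[1], freq_range[2])))
  a <- matrix(stats::rnorm(9, sd = anisotropy), 3, 3)
  eps_inf <- diag(3) * 2.5 + (a + t(a)) / 2
  eps_inf <- eps_inf + diag(3) * max(0, 1.05 - min(eigen(eps_inf)$values))
  phonon_data(
    cell = cell,
    atoms = tibble::tibble(
      label = paste0("X", seq_len(n_atoms)), mass = masses),
    born_charges = zs,
    frequencies = freqs,
    eigenvectors = u,
    optical_permittivity = eps_inf
  )
}

#' Synthetic isotropic single-oscillator crystal
#'
#' Builds a two-atom cubic crystal whose three degenerate optic modes
#' reproduce a requested TO frequency and per-axis intensity, with isotropic
#' Born charges chosen so the intensity is exact (the charge is derived
#' from `intensity = e2_amu_to_intensity * Z^2 / mu` with `mu` the reduced
#' mass).  Useful as an analytic reference: the non-analytic correction on
#' this crystal obeys the Lyddane-Sachs-Teller relation exactly.
#'
#' @param nu_to TO frequency, cm^-1.
#' @param intensity Per-axis mode intensity, (D/A)^2/amu.
#' @param eps_inf Scalar optical permittivity.
#' @param volume Cell volume, Angstrom^3.
#' @param masses Two atomic masses, amu.
#' @return A validated [phonon_data()] object.
#' @export
single_oscillator_crystal <- function(nu_to, intensity, eps_inf, volume,
                                      masses = c(24.305, 15.999)) {
  stopifnot(nu_to > 0, intensity >= 0, eps_inf >= 1, volume > 0,
            length(masses) == 2, all(masses > 0))
  uc <- unit_constants()
  mu <- prod(masses) / sum(masses)
  z <- sqrt(intensity * mu / uc$e2_amu_to_intensity)
  m1 <- masses[1]; m2 <- masses[2]; M <- sum(masses)
  # mass-weighted translation and optic vectors per Cartesian axis
  u <- matrix(0, 6, 6)
  for (ax in 1:3) {
    u[ax, c(ax, ax + 3)] <- sqrt(c(m1, m2) / M)          # translation
    u[ax + 3, c(ax, ax + 3)] <- c(sqrt(m2 / M), -sqrt(m1 / M)) # optic
  }
  phonon_data(
    cell = crystal_cell(diag(3) * volume^(1 / 3)),
    atoms = tibble::tibble(label = c("A", "B"), mass = masses),
    born_charges = list(diag(3) * z, -diag(3) * z),
    frequencies = c(0, 0, 0, rep(nu_to, 3)),
    eigenvectors = u,
    optical_permittivity = diag(3) * eps_inf
  )
}

#' Oscillator-table crystal model
#'
#' A reduced description of a crystal as printed in reference tables:
#' cell parameters, the diagonal optical permittivity in the crystal frame,
#' and a band list of (symmetry label, TO frequency, intensity).  The
#' unique (optic) axis is taken as the Cartesian z axis.  `A` labels a
#' non-degenerate band polarized along the unique axis; `E` labels a doubly
#' degenerate band whose printed intensity is carried by *each* of the two
#' perpendicular partners; `T` labels a triply degenerate band carrying its
#' printed intensity on each Cartesian axis.
#'
#' @param name Model name.
#' @param cell_volume Unit-cell volume, Angstrom^3.
#' @param eps_inf Length-3 diagonal of the optical permittivity (x, y,
#'   z = unique axis).
#' @param bands Data frame with columns `symmetry` ("A", "E" or "T"),
#'   `frequency` (cm^-1) and `intensity` ((D/A)^2/amu).
#' @param partial Logical: TRUE if the table is known to list only a subset
#'   of the IR-active bands (static permittivities will not be fully
#'   reproduced).
#' @return Object of class `oscillator_table_model`.
#' @export
oscillator_table_model <- function(name, cell_volume, eps_inf, bands,
                                   partial = FALSE) {
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("symmetry", "frequency", "intensity") %in% names(bands)),
            all(bands$symmetry %in% c("A", "E", "T")),
            cell_volume > 0, length(eps_inf) == 3)
  if (any(bands$intensity < 0)) {
    stop("band intensities must be non-negative", call. = FALSE)
  }
  structure(
    list(name = name, cell_volume = cell_volume, eps_inf = eps_inf,
         bands = bands, partial = partial),
    class = "oscillator_table_model"
  )
}

#' @export
print.oscillator_table_model <- function(x, ...) {
  cat("<oscillator_table_model> ", x$name, ": ", nrow(x$bands), " bands, V = ",
      format(x$cell_volume), " A^3", if (x$partial) " (partial)", "\n",
      sep = "")
  invisible(x)
}

#' Dielectric model from an oscillator table
#'
#' Expands an [oscillator_table_model()] into a [dielectric_model()]:
#' each `A` band becomes one oscillator with its intensity along z; each
#' `E` band becomes two partner oscillators, one along x and one along y,
#' each carrying the printed intensity; each `T` band becomes three
#' partners (x, y, z).  With `shared_intensity = TRUE` the printed
#' intensity is instead split evenly over the partners (for sensitivity
#' checks of the per-partner reading).
#'
#' @param table An `oscillator_table_model`.
#' @param sigma Damping factor, cm^-1, applied to every oscillator.
#' @param shared_intensity Split the printed intensity across degenerate
#'   partners instead of repeating it (default FALSE).
#' @return A `dielectric_model`.
#' @export
from_oscillator_table <- function(table, sigma = 5, shared_intensity = FALSE) {
  stopifnot(inherits(table, "oscillator_table_model"), sigma > 0)
  axes <- list(A = 3L, E = c(1L, 2L), T = 1:3)
  rows <- list()
  for (i in seq_len(nrow(table$bands))) {
    ax <- axes[[table$bands$symmetry[i]]]
    inten <- table$bands$intensity[i]
    if (shared_intensity) inten <- inten / length(ax)
    for (a in ax) {
      s <- matrix(0, 3, 3)
      s[a, a] <- inten
      rows[[length(rows) + 1]] <- tibble::tibble(
        frequency = table$bands$frequency[i],
        strength = list(s), intensity = inten
      )
    }
  }
  osc <- dplyr::bind_rows(rows)
  osc$mode <- seq_len(nrow(osc))
  osc$sigma <- sigma
  osc$active <- TRUE
  dielectric_model(diag(table$eps_inf), osc[, c("mode", "frequency",
                                                "strength", "intensity",
                                                "sigma", "active")],
                   table$cell_volume)
}

#' Built-in reference crystal models
#'
#' Oscillator-table models for five well-studied materials, transcribed
#' from published gamma-point lattice-dynamics results: cubic MgO (one
#' triply degenerate band), wurtzite ZnO, rhombohedral calcite, hexagonal
#' fluoroapatite and monoclinic l-aspartic acid.  The fluoroapatite and
#' aspartic-acid tables are partial (only the strongest/selected bands),
#' and the aspartic-acid bands lack directional assignments, so that model
#' is suitable for smoke tests only.
#'
#' Cell volumes are computed from the printed cell parameters; the MgO
#' entry of 2.1234 Angstrom is half the conventional cubic edge, so its
#' primitive face-centred volume is `(2*2.1234)^3/4`.
#'
#' @return Named list of [oscillator_table_model()] objects:
#'   `mgo`, `zno`, `calcite`, `fluoroapatite`, `l_aspartic_acid`.
#' @export
reference_models <- function() {
  hex_volume <- function(a, c) a^2 * c * sqrt(3) / 2
  rhomb_volume <- function(a, alpha) {
    ca <- cospi(alpha / 180)
    a^3 * sqrt(1 - 3 * ca^2 + 2 * ca^3)
  }
  mono_volume <- function(a, b, c, beta) a * b * c * sinpi(beta / 180)
  band <- function(symmetry, frequency, intensity) {
    tibble::tibble(symmetry = symmetry, frequency = frequency,
                   intensity = intensity)
  }
  list(
    mgo = oscillator_table_model(
      "MgO", cell_volume = (2 * 2.1234)^3 / 4,
      eps_inf = c(3.14, 3.14, 3.14),
      bands = band("T", 388.3, 9.29)
    ),
    zno = oscillator_table_model(
      "ZnO", cell_volume = hex_volume(3.295, 5.285),
      eps_inf = c(5.09, 5.09, 6.0),
      bands = band(c("A", "E"), c(350.0, 372.1), c(17.1, 16.4))
    ),
    calcite = oscillator_table_model(
      "calcite", cell_volume = rhomb_volume(6.376, 46.0),
      eps_inf = c(1.91, 1.91, 2.0),
      bands = band(
        c("E", "A", "A", "E", "A", "E", "A", "E"),
        c(114.8, 127.4, 249.3, 320.7, 338.1, 620.1, 732.0, 1463.6),
        c(2.39, 3.36, 1.23, 5.82, 4.14, 3.38, 26.89, 16.97)
      )
    ),
    fluoroapatite = oscillator_table_model(
      "fluoroapatite", cell_volume = hex_volume(9.447, 6.926),
      eps_inf = c(2.891, 2.891, 2.894),
      bands = band(c("A", "E", "E"),
                   c(981.8, 986.3, 1038.1),
                   c(112.6, 101.0, 7.92)),
      partial = TRUE
    ),
    l_aspartic_acid = oscillator_table_model(
      "l-aspartic acid",
      cell_volume = mono_volume(7.597, 7.028, 5.113, 98.77),
      eps_inf = c(2.68, 2.20, 2.56),
      # directional assignments are not available for these bands; they are
      # placed along the epsilon_inf principal axes cyclically as a purely
      # synthetic convention (smoke tests only)
      bands = band(rep("A", 9),
                   c(84.5, 104.7, 106.0, 115.3, 137.3, 1290.0, 2945.9,
                     2947.3, 3053.7),
                   c(0.120, 0.202, 0.243, 0.474, 0.617, 55.0, 102.8, 48.2,
                     44.1)),
      partial = TRUE
    )
  )
}
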