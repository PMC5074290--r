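#' Oscillator strengths from Born charges and phonon modes
#'
#' For each mode k the mode charge vector is the dipole derivative with
#' respect to the mass-weighted normal coordinate,
#' `Z_k = sum_a Zbar_a U_ka / sqrt(m_a)` (a 3-vector, units e/sqrt(amu)),
#' and the oscillator-strength tensor is its outer product
#' `S_k = Z_k Z_k^T`, converted to (D/A)^2/amu.  The trace of `S_k` is the
#' mode's infrared intensity.  Modes with |frequency| below `low_cutoff`
#' (translational remnants) are flagged inactive.
#'
#' @param data A valid [phonon_data()] object.
#' @param low_cutoff Frequency magnitude (cm^-1) below which a mode is
#'   flagged inactive; default 5.
#' @return A tibble with one row per mode: `mode` (1-based index),
#'   `frequency` (cm^-1, TO), `strength` (list of 3x3 matrices,
#'   (D/A)^2/amu), `intensity` (trace), `sigma` (damping, cm^-1, default 5),
#'   `active` (logical).
#' @export
oscillator_strengths <- function(data, low_cutoff = 5) {
  validate_phonon_data(data)
  uc <- unit_constants()
  n <- nrow(data$atoms)
  inv_sqrt_m <- 1 / sqrt(data$atoms$mass)
  # 3 x 3N block matrix of Born charges weighted by 1/sqrt(m): column block a
  zw <- matrix(0, 3, 3 * n)
  for (a in seq_len(n)) {
    zw[, (3 * a - 2):(3 * a)] <- data$born_charges[[a]] * inv_sqrt_m[a]
  }
  modes <- seq_len(3 * n)
  strengths <- lapply(modes, function(k) {
    zk <- as.numeric(zw %*% data$eigenvectors[k, ])
    uc$e2_amu_to_intensity * tcrossprod(zk)
  })
  tibble::tibble(
    mode = modes,
    frequency = data$frequencies,
    strength = strengths,
    intensity = vapply(strengths, function(s) sum(diag(s)), numeric(1)),
    sigma = 5,
    active = abs(data$frequencies) >= low_cutoff
  )
}

#' Lorentz-oscillator dielectric model
#'
#' Bundles the optical permittivity, the oscillator table and the cell
#' volume into the machine that yields the complex permittivity tensor at
#' any wavenumber.
#'
#' @param epsilon_inf Symmetric 3x3 optical permittivity tensor (a scalar is
#'   promoted to an isotropic tensor).
#' @param oscillators Tibble as returned by [oscillator_strengths()] (columns
#'   `mode`, `frequency`, `strength`, `intensity`, `sigma`, `active`).
#' @param cell_volume Unit-cell volume, Angstrom^3.
#' @return Object of class `dielectric_model`.
#' @seealso [permittivity()], [apply_mode_controls()], [powder_spectrum()]
#' @export
dielectric_model <- function(epsilon_inf, oscillators, cell_volume) {
  if (length(epsilon_inf) == 1) epsilon_inf <- diag(3) * epsilon_inf
  epsilon_inf <- unname(as.matrix(epsilon_inf))
  stopifnot(all(dim(epsilon_inf) == c(3, 3)), cell_volume > 0)
  if (max(abs(epsilon_inf - t(epsilon_inf))) > 1e-8) {
    stop("optical permittivity must be symmetric", call. = FALSE)
  }
  osc <- tibble::as_tibble(oscillators)
  need <- c("mode", "frequency", "strength", "intensity", "sigma", "active")
  miss <- setdiff(need, names(osc))
  if (length(miss)) {
    stop("oscillator table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(osc$sigma <= 0)) stop("damping sigma must be > 0", call. = FALSE)
  structure(
    list(epsilon_inf = epsilon_inf, oscillators = osc,
         cell_volume = cell_volume),
    class = "dielectric_model"
  )
}

#' Dielectric model straight from phonon data
#'
#' Convenience wrapper: [oscillator_strengths()] plus [dielectric_model()].
#'
#' @inheritParams oscillator_strengths
#' @param sigma Global damping factor in cm^-1 applied to every mode.
#' @return A `dielectric_model`.
#' @export
dielectric_model_from_phonons <- function(data, sigma = 5, low_cutoff = 5) {
  osc <- oscillator_strengths(data, low_cutoff = low_cutoff)
  osc$sigma <- sigma
  dielectric_model(data$optical_permittivity, osc, data$cell$volume)
}

#' @export
print.dielectric_model <- function(x, ...) {
  act <- sum(x$oscillators$active)
  cat("<dielectric_model> ", nrow(x$oscillators), " oscillators (",
      act, " active), cell volume ", format(x$cell_volume), " A^3\n", sep = "")
  invisible(x)
}

#' Complex permittivity tensor on a wavenumber grid
#'
#' Evaluates the Lorentz-oscillator sum
#' `eps(nu) = eps_inf + (gamma/V) * sum_k S_k / (nu_k^2 - nu^2 - i sigma_k nu)`
#' over the active oscillators, where `gamma` is the unit bridge of
#' [unit_constants()].
#'
#' @param model A [dielectric_model()].
#' @param grid Numeric vector of wavenumbers (cm^-1), all >= 0.
#' @return A complex array of dimension `c(3, 3, length(grid))`.
#' @examples
#' m <- dielectric_model(3.14, tibble::tibble(
#'   mode = 1L, frequency = 388.3,
#'   strength = list(diag(3) * 9.29 / 3), intensity = 9.29,
#'   sigma = 10, active = TRUE), cell_volume = 19.148)
#' Re(permittivity(m, 0)[1, 1, 1]) # close to the static value
#' @export
permittivity <- function(model, grid) {
  stopifnot(inherits(model, "dielectric_model"))
  grid <- as.numeric(grid)
  if (any(grid < 0)) stop("grid wavenumbers must be >= 0", call. = FALSE)
  uc <- unit_constants()
  osc <- model$oscillators[model$oscillators$active, ]
  out <- array(0 + 0i, dim = c(3, 3, length(grid)))
  pref <- uc$gamma_eps / model$cell_volume
  for (j in seq_along(grid)) {
    nu <- grid[j]
    eps <- model$epsilon_inf + 0i
    for (k in seq_len(nrow(osc))) {
      denom <- osc$frequency[k]^2 - nu^2 - 1i * osc$sigma[k] * nu
      if (abs(denom) == 0) {
        stop("permittivity singular at nu = ", nu,
             " cm^-1 (on a TO frequency with zero damping); use sigma > 0",
             call. = FALSE)
      }
      eps <- eps + pref * osc$strength[[k]] / denom
    }
    out[, , j] <- eps
  }
  out
}

#' LO frequencies from the non-analytic correction
#'
#' Adds the long-wavelength non-analytic correction to the reconstructed
#' mass-weighted dynamical matrix for an approach direction `q` given as
#' integer indices [hkl] of the direct lattice (only the direction of the
#' resulting Cartesian vector matters), then re-diagonalizes:
#'
#' `D_LO[s,a;t,b] = D[s,a;t,b] +
#'   (gamma_lo/V) (q.Z_s)_a (q.Z_t)_b / (sqrt(M_s M_t) * (q . eps_inf . q))`
#'
#' For an isotropic single-oscillator crystal the unique corrected frequency
#' obeys the Lyddane-Sachs-Teller relation `nu_LO = nu_TO sqrt(eps_s/eps_inf)`.
#'
#' @param data A valid [phonon_data()] object.
#' @param q_direction Integer triple (h, k, l); must not be (0, 0, 0).
#' @return Sorted mode frequencies (cm^-1) of the corrected matrix; negative
#'   values encode imaginary frequencies.
#' @export
lo_frequencies <- function(data, q_direction) {
  validate_phonon_data(data)
  q_direction <- as.numeric(q_direction)
  if (length(q_direction) != 3 || all(q_direction == 0)) {
    stop("`q_direction` must be a non-zero (h, k, l) triple", call. = FALSE)
  }
  uc <- unit_constants()
  # Cartesian direction of [hkl] in the direct lattice
  qc <- as.numeric(q_direction %*% data$cell$lattice_vectors)
  qh <- qc / sqrt(sum(qc^2))
  n <- nrow(data$atoms)
  d <- reconstruct_dynamical_matrix(data)
  # w[s-block] = (qhat^T Z_s) / sqrt(M_s), a 3-vector per atom
  w <- numeric(3 * n)
  for (a in seq_len(n)) {
    w[(3 * a - 2):(3 * a)] <-
      as.numeric(qh %*% data$born_charges[[a]]) / sqrt(data$atoms$mass[a])
  }
  screen <- as.numeric(qh %*% data$optical_permittivity %*% qh)
  dlo <- d + (uc$gamma_lo / (data$cell$volume * screen)) * tcrossprod(w)
  lam <- eigen((dlo + t(dlo)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sort(sign(lam) * sqrt(abs(lam)))
}

#' Select, silence and damp individual modes
#'
#' Applies user-facing mode controls to an oscillator table: deactivate
#' listed modes, restrict to listed modes, set a global damping factor, and
#' override damping per mode.  Indices are 1-based mode numbers.
#'
#' @param oscillators Oscillator tibble (see [oscillator_strengths()]).
#' @param ignore Integer vector of modes to deactivate.
#' @param only Integer vector; if non-empty, only these modes stay active.
#' @param sigma Global damping factor (cm^-1) applied to all modes; default 5.
#' @param mode_sigma Named list/vector mapping mode index to a per-mode
#'   damping factor, applied after `sigma`.
#' @return The modified oscillator tibble.
#' @export
apply_mode_controls <- function(oscillators, ignore = integer(),
                                only = integer(), sigma = 5,
                                mode_sigma = NULL) {
  osc <- tibble::as_tibble(oscillators)
  nmax <- nrow(osc)
  chk <- function(idx, what) {
    idx <- as.integer(idx)
    if (length(idx) && (any(idx < 1) || any(idx > nmax))) {
      stop("`", what, "` contains mode indices outside 1..", nmax,
           call. = FALSE)
    }
    idx
  }
  ignore <- chk(ignore, "ignore")
  only <- chk(only, "only")
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  osc$sigma <- rep(sigma, nmax)
  if (!is.null(mode_sigma) && length(mode_sigma)) {
    idx <- chk(names(mode_sigma) %||% stop("`mode_sigma` must be named by ",
                                           "mode index", call. = FALSE),
               "mode_sigma")
    vals <- as.numeric(unlist(mode_sigma, use.names = FALSE))
    if (any(vals <= 0)) stop("per-mode sigma must be > 0", call. = FALSE)
    osc$sigma[idx] <- vals
  }
  if (length(only)) osc$active <- osc$active & osc$mode %in% only
  if (length(ignore)) osc$active <- osc$active & !(osc$mode %in% ignore)
  osc
}
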