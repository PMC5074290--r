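#' Mixing scenario for effective-medium homogenization
#'
#' Describes one homogenization problem: the mixing rule, the volume
#' fraction of crystallites, the (real, frequency-independent) permittivity
#' of the supporting matrix, the particle shape via its depolarization
#' tensor, and the inclusion (unit-cell) volume.  The number density of
#' inclusions is derived as `n = f / V`.
#'
#' @param method One of `"maxwell"` (Maxwell-Garnett), `"bruggeman"`,
#'   `"ap"` (averaged permittivity).
#' @param volume_fraction Volume fraction f of crystal in the matrix,
#'   in (0, 1).
#' @param matrix_permittivity Real scalar permittivity of the matrix, >= 1.
#' @param shape A `depolarization_tensor` (see [shape_depolarization()]).
#' @param inclusion_volume Unit-cell volume of the crystal, Angstrom^3.
#' @return Object of class `mixing_scenario`.
#' @export
mixing_scenario <- function(method = c("maxwell", "bruggeman", "ap"),
                            volume_fraction = 0.1,
                            matrix_permittivity = 2,
                            shape = depolarization(shape_spec("sphere")),
                            inclusion_volume = 1) {
  method <- match.arg(method)
  if (!is.finite(volume_fraction) || volume_fraction <= 0 ||
      volume_fraction >= 1) {
    stop("`volume_fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (matrix_permittivity < 1) {
    stop("`matrix_permittivity` must be >= 1", call. = FALSE)
  }
  stopifnot(inherits(shape, "depolarization_tensor"), inclusion_volume > 0)
  structure(
    list(method = method, volume_fraction = volume_fraction,
         matrix_permittivity = matrix_permittivity, shape = shape,
         inclusion_volume = inclusion_volume,
         number_density = volume_fraction / inclusion_volume),
    class = "mixing_scenario"
  )
}

#' @export
print.mixing_scenario <- function(x, ...) {
  cat("<mixing_scenario> ", x$method, ", f = ", x$volume_fraction,
      ", eps_matrix = ", x$matrix_permittivity, "\n", sep = "")
  invisible(x)
}

#' Polarizability of an ellipsoidal inclusion
#'
#' Closed-form polarizability tensor (crystal frame) of a particle with
#' permittivity `eps_i` (complex 3x3) and volume `V` embedded in a matrix of
#' scalar permittivity `eps_e`:
#' `alpha = V eps_e (eps_i - eps_e I) (eps_e I + L (eps_i - eps_e I))^-1`.
#'
#' @param eps_i Complex (or real) 3x3 inclusion permittivity.
#' @param eps_e Real scalar matrix permittivity.
#' @param L A `depolarization_tensor` or plain 3x3 matrix.
#' @param volume Particle volume (Angstrom^3).
#' @return Complex 3x3 polarizability tensor.
#' @export
polarizability <- function(eps_i, eps_e, L, volume) {
  Lm <- if (inherits(L, "depolarization_tensor")) L$L else as.matrix(L)
  contrast <- eps_i - eps_e * diag(3)
  denom <- eps_e * diag(3) + Lm %*% contrast
  rc <- rcond(abs(denom))
  if (!is.finite(rc) || rc < 1e-14) {
    stop("polarizability denominator is singular (lossless resonance); ",
         "use a damping factor sigma > 0", call. = FALSE)
  }
  volume * eps_e * contrast %*% solve(denom)
}

#' Orientational averages of the polarizability
#'
#' For inclusions uniformly random in orientation the averages of the
#' rotated tensors reduce to thirds of traces:
#' `<alpha> = tr(alpha)/3` and `<alpha L> = tr(alpha L)/3`
#' (both tensors rotate together with the particle).
#'
#' @param alpha Complex 3x3 polarizability (crystal frame).
#' @param L Depolarization tensor (crystal frame) or
#'   `depolarization_tensor`.
#' @return List with scalars `alpha_bar` and `alphaL_bar`.
#' @export
orientational_average <- function(alpha, L) {
  Lm <- if (inherits(L, "depolarization_tensor")) L$L else as.matrix(L)
  list(
    alpha_bar = sum(diag(alpha)) / 3,
    alphaL_bar = sum(diag(alpha %*% Lm)) / 3
  )
}

#' Maxwell-Garnett effective permittivity
#'
#' Homogenizes randomly oriented ellipsoidal inclusions in a host matrix:
#' `eps_mg = eps_e + n <alpha> / (1 - n <alpha L> / eps_e)` per frequency,
#' with `n = f/V` so the inclusion volume cancels against the
#' polarizability's volume factor.
#'
#' @param scenario A [mixing_scenario()].
#' @param eps_i Complex array `c(3, 3, n_freq)` of inclusion permittivities
#'   (e.g. from [permittivity()]).
#' @return Object of class `effective_permittivity`: list with complex
#'   vector `values`, logical `converged` (all TRUE here) and logical
#'   `passive` (`Im >= -1e-10`).
#' @export
maxwell_garnett <- function(scenario, eps_i) {
  stopifnot(inherits(scenario, "mixing_scenario"))
  eps_i <- as_eps_array(eps_i)
  nf <- dim(eps_i)[3]
  ee <- scenario$matrix_permittivity
  n <- scenario$number_density
  V <- scenario$inclusion_volume
  vals <- complex(nf)
  for (j in seq_len(nf)) {
    al <- polarizability(eps_i[, , j], ee, scenario$shape, V)
    av <- orientational_average(al, scenario$shape)
    denom <- 1 - n * av$alphaL_bar / ee
    if (abs(denom) == 0) {
      stop("Maxwell-Garnett denominator vanished at grid point ", j,
           "; use a damping factor sigma > 0", call. = FALSE)
    }
    vals[j] <- ee + n * av$alpha_bar / denom
  }
  effective_permittivity(vals, converged = rep(TRUE, nf))
}

#' Bruggeman effective permittivity
#'
#' Solves, per frequency, the symmetric two-phase condition in which both
#' the crystal (fraction f) and the matrix (fraction 1-f) are polarized
#' against the effective medium, sharing one depolarization tensor.  After
#' orientational averaging the fixed-point update is
#' `eps_new = (f <eps_1 A_1^-1> + (1-f) <eps_2 A_2^-1>) /
#'            (f <A_1^-1> + (1-f) <A_2^-1>)`
#' with `A_i = eps_br I + L (eps_i - eps_br I)` and `< >` the trace/3
#' average.  Iterations start from the Maxwell-Garnett value at the first
#' grid point and from the previous frequency's solution thereafter;
#' convergence is a relative change below `tol`, capped at `max_iter`
#' sweeps.  A converged solution with negative imaginary part is retried
#' from the Maxwell-Garnett seed at that frequency, then flagged.
#'
#' @inheritParams maxwell_garnett
#' @param tol Relative convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap per frequency (default 1000).
#' @return An `effective_permittivity` with per-frequency convergence and
#'   passivity flags.
#' @export
bruggeman <- function(scenario, eps_i, tol = 1e-8, max_iter = 1000) {
  stopifnot(inherits(scenario, "mixing_scenario"))
  eps_i <- as_eps_array(eps_i)
  nf <- dim(eps_i)[3]
  f1 <- scenario$volume_fraction
  f2 <- 1 - f1
  ee <- scenario$matrix_permittivity
  Lm <- scenario$shape$L
  id <- diag(3)

  step <- function(eps_br, e1) {
    avg <- function(em) {
      A <- eps_br * id + Lm %*% (em - eps_br * id)
      Ainv <- solve(A)
      list(top = sum(diag(em %*% Ainv)) / 3, bot = sum(diag(Ainv)) / 3)
    }
    s1 <- avg(e1)
    s2 <- avg(ee * id + 0i)
    (f1 * s1$top + f2 * s2$top) / (f1 * s1$bot + f2 * s2$bot)
  }
  iterate <- function(seed, e1) {
    eps <- seed
    for (it in seq_len(max_iter)) {
      nxt <- tryCatch(step(eps, e1), error = function(e) NA_complex_)
      if (is.na(nxt)) return(list(value = eps, converged = FALSE))
      if (abs(nxt - eps) <= tol * max(abs(nxt), 1e-30)) {
        return(list(value = nxt, converged = TRUE))
      }
      eps <- nxt
    }
    list(value = eps, converged = FALSE)
  }
  mg_at <- function(j) {
    sc <- scenario
    sc$method <- "maxwell"
    maxwell_garnett(sc, eps_i[, , j, drop = FALSE])$values[1]
  }

  vals <- complex(nf)
  conv <- logical(nf)
  seed <- mg_at(1)
  for (j in seq_len(nf)) {
    e1 <- eps_i[, , j]
    res <- iterate(seed, e1)
    if (res$converged && Im(res$value) < -1e-10) {
      retry <- iterate(mg_at(j), e1)
      if (retry$converged) res <- retry
    }
    vals[j] <- res$value
    conv[j] <- res$converged
    seed <- res$value
  }
  effective_permittivity(vals, converged = conv)
}

#' Averaged-permittivity mixing rule
#'
#' Shape-free baseline: `eps_ap = f tr(eps_i)/3 + (1-f) eps_e`.  At low
#' loading its absorption peaks sit at the TO frequencies, so comparison
#' against the shape-aware rules isolates the particle-shape shifts.
#'
#' @inheritParams maxwell_garnett
#' @return An `effective_permittivity`.
#' @export
averaged_permittivity <- function(scenario, eps_i) {
  stopifnot(inherits(scenario, "mixing_scenario"))
  eps_i <- as_eps_array(eps_i)
  nf <- dim(eps_i)[3]
  f <- scenario$volume_fraction
  vals <- vapply(seq_len(nf), function(j) {
    f * sum(diag(eps_i[, , j])) / 3 + (1 - f) * scenario$matrix_permittivity
  }, complex(1))
  effective_permittivity(vals, converged = rep(TRUE, nf))
}

#' Dispatch on a scenario's mixing method
#'
#' @inheritParams maxwell_garnett
#' @param ... Passed to the method-specific function.
#' @return An `effective_permittivity`.
#' @export
effective_medium <- function(scenario, eps_i, ...) {
  switch(scenario$method,
         maxwell = maxwell_garnett(scenario, eps_i),
         bruggeman = bruggeman(scenario, eps_i, ...),
         ap = averaged_permittivity(scenario, eps_i))
}

effective_permittivity <- function(values, converged) {
  structure(
    list(values = values, converged = converged,
         passive = Im(values) >= -1e-10),
    class = "effective_permittivity"
  )
}

#' @export
print.effective_permittivity <- function(x, ...) {
  cat("<effective_permittivity> ", length(x$values), " frequencies; ",
      sum(!x$converged), " non-converged; ", sum(!x$passive),
      " passivity violations\n", sep = "")
  invisible(x)
}

as_eps_array <- function(eps_i) {
  if (is.matrix(eps_i)) eps_i <- array(eps_i, dim = c(dim(eps_i), 1))
  stopifnot(length(dim(eps_i)) == 3, all(dim(eps_i)[1:2] == 3))
  eps_i + 0i
}
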