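#' Particle shape specification
#'
#' Supported morphologies for powder particles: sphere, plate (slab),
#' needle, and spheroidal ellipsoid.  Non-spherical shapes carry an (h k l)
#' triple that fixes the unique axis: for needles and ellipsoids it is the
#' direct-lattice direction [hkl]; for plates it is the normal to the
#' crystal plane (hkl), i.e. the reciprocal-lattice vector, which for
#' non-orthogonal lattices differs from [hkl].
#'
#' @param kind One of `"sphere"`, `"plate"`, `"needle"`, `"ellipsoid"`
#'   (`"slab"` is accepted as a synonym of `"plate"`).
#' @param hkl Integer triple; required (non-zero) for non-spheres.
#' @param z_ratio Ellipsoid only: ratio of unique-axis length to the
#'   perpendicular-axis length (> 1 prolate, < 1 oblate, 1 sphere).
#' @return Object of class `shape_spec`.
#' @export
shape_spec <- function(kind, hkl = c(0L, 0L, 0L), z_ratio = 1) {
  kind <- match.arg(kind, c("sphere", "plate", "slab", "needle", "ellipsoid"))
  if (kind == "slab") kind <- "plate"
  hkl <- as.numeric(hkl)
  if (kind != "sphere" && (length(hkl) != 3 || all(hkl == 0))) {
    stop("shape '", kind, "' needs a non-zero (h k l) triple", call. = FALSE)
  }
  if (kind == "ellipsoid" && (!is.finite(z_ratio) || z_ratio <= 0)) {
    stop("`z_ratio` must be a positive number", call. = FALSE)
  }
  structure(list(kind = kind, hkl = hkl, z_ratio = z_ratio),
            class = "shape_spec")
}

#' @export
print.shape_spec <- function(x, ...) {
  cat("<shape_spec> ", x$kind, sep = "")
  if (x$kind != "sphere") cat(" [", paste(x$hkl, collapse = " "), "]")
  if (x$kind == "ellipsoid") cat(" z =", x$z_ratio)
  cat("\n")
  invisible(x)
}

#' Cartesian unique axis of a shape
#'
#' Resolves the crystallographic direction of a shape's unique axis to a
#' Cartesian orthonormal triad (V1, V2, V3).  V1 is along `h a1 + k a2 +
#' l a3` for needles/ellipsoids (direct lattice) and along `h b1 + k b2 +
#' l b3` for plates (reciprocal-lattice plane normal).  V2 and V3 are a
#' deterministic orthonormal completion (pivot on the smallest component of
#' V1); results downstream are provably independent of the completion.
#'
#' @param cell A [crystal_cell()].
#' @param spec A [shape_spec()].
#' @return 3x3 matrix with rows V1, V2, V3.
#' @export
unique_axis <- function(cell, spec) {
  stopifnot(inherits(cell, "crystal_cell"), inherits(spec, "shape_spec"))
  if (spec$kind == "sphere") {
    return(diag(3))
  }
  basis <- if (spec$kind == "plate") cell$reciprocal_vectors else
    cell$lattice_vectors
  v1 <- as.numeric(spec$hkl %*% basis)
  nv <- sqrt(sum(v1^2))
  if (nv < 1e-12) stop("(h k l) maps to a zero vector", call. = FALSE)
  v1 <- v1 / nv
  # deterministic completion: pivot on the smallest |component| of V1
  p <- which.min(abs(v1))
  e <- c(0, 0, 0); e[p] <- 1
  v2 <- e - sum(e * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  rbind(v1, v2, v3, deparse.level = 0)
}

#' Depolarization tensor of a particle shape
#'
#' Builds the symmetric, unit-trace depolarization tensor L that screens the
#' internal field of an ellipsoidal inclusion:
#' sphere `L = I/3`; plate `L = V1 V1'`; needle `L = (V2 V2' + V3 V3')/2`;
#' spheroid `L = a V1 V1' + b (V2 V2' + V3 V3')` with the prolate
#' (`z > 1`) branch `e = sqrt(1 - z^-2)`,
#' `a = ((1-e^2)/(2 e^3)) (log((1+e)/(1-e)) - 2 e)` and the oblate
#' (`z < 1`) branch `e = sqrt(z^-2 - 1)`,
#' `a = ((1+e^2)/e^3) (e - atan(e))`, both with `b = (1-a)/2`; `z = 1`
#' degenerates to the sphere.
#'
#' @param spec A [shape_spec()].
#' @param axes 3x3 matrix of orthonormal rows (V1, V2, V3) as produced by
#'   [unique_axis()]; defaults to the identity triad (sphere does not use
#'   it).
#' @return Object of class `depolarization_tensor`: list with `L` (3x3) and
#'   `axes`.
#' @export
depolarization <- function(spec, axes = diag(3)) {
  stopifnot(inherits(spec, "shape_spec"))
  axes <- as.matrix(axes)
  if (max(abs(axes %*% t(axes) - diag(3))) > 1e-8) {
    stop("`axes` rows must be orthonormal", call. = FALSE)
  }
  pr <- function(i) tcrossprod(axes[i, ])
  L <- switch(
    spec$kind,
    sphere = diag(3) / 3,
    plate = pr(1),
    needle = (pr(2) + pr(3)) / 2,
    ellipsoid = {
      z <- spec$z_ratio
      if (z <= 0) stop("`z_ratio` must be > 0", call. = FALSE)
      ab <- spheroid_depolarization_factors(z)
      ab[1] * pr(1) + ab[2] * (pr(2) + pr(3))
    }
  )
  structure(list(L = (L + t(L)) / 2, axes = axes),
            class = "depolarization_tensor")
}

#' Spheroid depolarization factors
#'
#' Unique-axis factor `a` and perpendicular factor `b` (`a + 2b = 1`) for a
#' spheroid of aspect ratio `z` (unique over perpendicular axis length).
#' Near `z = 1` the closed forms lose precision; a series limit returns the
#' spherical 1/3 there.
#'
#' @param z Aspect ratio, > 0.
#' @return Numeric vector `c(a, b)`.
#' @export
spheroid_depolarization_factors <- function(z) {
  stopifnot(is.finite(z), z > 0)
  if (abs(z - 1) < 1e-8) return(c(1, 1) / 3)
  if (z > 1) {
    e <- sqrt(1 - z^-2)
    a <- ((1 - e^2) / (2 * e^3)) * (log((1 + e) / (1 - e)) - 2 * e)
  } else {
    e <- sqrt(z^-2 - 1)
    a <- ((1 + e^2) / e^3) * (e - atan(e))
  }
  c(a, (1 - a) / 2)
}

#' @export
print.depolarization_tensor <- function(x, ...) {
  cat("<depolarization_tensor> eigenvalues:",
      paste(format(sort(eigen(x$L, symmetric = TRUE,
                              only.values = TRUE)$values),
                   digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Depolarization tensor for a shape in a given cell
#'
#' Convenience composition of [unique_axis()] and [depolarization()].
#'
#' @inheritParams unique_axis
#' @return A `depolarization_tensor`.
#' @export
shape_depolarization <- function(cell, spec) {
  depolarization(spec, unique_axis(cell, spec))
}
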