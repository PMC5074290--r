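#' Crystal unit cell
#'
#' Builds the geometric frame used throughout the package: the direct lattice
#' vectors (rows of a 3x3 matrix, Angstrom), the reciprocal lattice vectors
#' (2*pi convention, Angstrom^-1) and the cell volume (Angstrom^3).
#'
#' @param lattice_vectors 3x3 numeric matrix; rows are the lattice vectors
#'   a1, a2, a3 in Angstrom.
#' @return An object of class `crystal_cell` with elements
#'   `lattice_vectors`, `reciprocal_vectors` and `volume`.
#' @examples
#' cell <- crystal_cell(diag(3) * 4.2)
#' cell$volume
#' @export
crystal_cell <- function(lattice_vectors) {
  a <- as.matrix(lattice_vectors)
  if (!is.numeric(a) || any(dim(a) != c(3, 3)) || any(!is.finite(a))) {
    stop("`lattice_vectors` must be a finite 3x3 numeric matrix", call. = FALSE)
  }
  vol <- det(a)
  if (abs(vol) < 1e-12) {
    stop("lattice vectors are (nearly) coplanar: cell volume is zero",
         call. = FALSE)
  }
  if (vol < 0) {
    # keep a right-handed frame; volume is |a1 . (a2 x a3)|
    vol <- abs(vol)
  }
  # rows of b solve a %*% t(b) = 2*pi*I
  b <- 2 * pi * t(solve(a))
  structure(
    list(lattice_vectors = a, reciprocal_vectors = b, volume = vol),
    class = "crystal_cell"
  )
}

#' @export
print.crystal_cell <- function(x, ...) {
  cat("<crystal_cell>  volume:", format(x$volume), "A^3\n")
  cat("lattice vectors (rows, A):\n")
  print(unname(x$lattice_vectors))
  invisible(x)
}

#' Unit cell from cell parameters
#'
#' Standard crystallographic construction of lattice vectors from the six
#' cell parameters; `a1` lies along x, `a2` in the xy plane.
#'
#' @param a,b,c Cell edge lengths, Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees (alpha between b and c,
#'   beta between a and c, gamma between a and b).
#' @return A [crystal_cell()].
#' @examples
#' # rhombohedral cell
#' cell_from_parameters(6.376, 6.376, 6.376, 46, 46, 46)$volume
#' @export
cell_from_parameters <- function(a, b = a, c = a, alpha = 90, beta = 90,
                                 gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  ca <- cospi(alpha / 180); cb <- cospi(beta / 180); cg <- cospi(gamma / 180)
  sg <- sinpi(gamma / 180)
  cz <- (ca - cb * cg) / sg
  arg <- 1 - cb^2 - cz^2
  if (arg <= 0) stop("cell angles are geometrically impossible", call. = FALSE)
  lat <- rbind(
    c(a, 0, 0),
    c(b * cg, b * sg, 0),
    c(c * cb, c * cz, c * sqrt(arg))
  )
  crystal_cell(lat)
}

#' Crystal density
#'
#' Mass density of the crystal from its cell volume and atomic masses;
#' needed to convert a mass fraction of powder into a volume fraction.
#'
#' @param cell A [crystal_cell()].
#' @param masses Numeric vector of atomic masses in amu (one per atom in the
#'   cell).
#' @return Density in g/cm^3.
#' @export
crystal_density <- function(cell, masses) {
  stopifnot(inherits(cell, "crystal_cell"), all(masses > 0))
  uc <- unit_constants()
  sum(masses) * uc$amu_g / (cell$volume * 1e-24)
}
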