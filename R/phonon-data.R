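#' Gamma-point phonon data
#'
#' The canonical container for everything a lattice-dynamics calculation
#' provides at the gamma point: the unit cell, the atoms (labels, masses,
#' 3x3 Born effective charge tensors), the 3N mode frequencies, the 3N
#' orthonormal eigenvectors of the mass-weighted dynamical matrix, and the
#' optical (high-frequency electronic) permittivity tensor.
#'
#' Eigenvectors follow the mass-weighted convention: they are dimensionless,
#' orthonormal, and the physical displacement of atom `a` in mode `k` is
#' proportional to `U[k, a]/sqrt(m_a)`.  Imaginary (unstable) frequencies
#' are encoded as negative numbers.
#'
#' @param cell A [crystal_cell()].
#' @param atoms A data frame (or tibble) with columns `label` (character)
#'   and `mass` (amu), one row per atom.
#' @param born_charges List of N 3x3 matrices, elementary-charge units.
#' @param frequencies Numeric vector of 3N mode frequencies, cm^-1.
#' @param eigenvectors 3N x 3N numeric matrix; row k is mode k, with
#'   components ordered (atom1 x,y,z, atom2 x,y,z, ...).
#' @param optical_permittivity Symmetric 3x3 matrix, dimensionless.
#' @param tolerance Orthonormality tolerance for validation.
#' @return An object of class `phonon_data`.
#' @seealso [read_phonon_data()], [write_phonon_data()],
#'   [reconstruct_dynamical_matrix()], [oscillator_strengths()]
#' @export
phonon_data <- function(cell, atoms, born_charges, frequencies, eigenvectors,
                        optical_permittivity, tolerance = 1e-6) {
  x <- structure(
    list(
      cell = cell,
      atoms = tibble::as_tibble(atoms),
      born_charges = lapply(born_charges, function(z) unname(as.matrix(z))),
      frequencies = as.numeric(frequencies),
      eigenvectors = unname(as.matrix(eigenvectors)),
      optical_permittivity = unname(as.matrix(optical_permittivity))
    ),
    class = "phonon_data"
  )
  validate_phonon_data(x, tolerance = tolerance)
}

#' Validate phonon data
#'
#' Checks the structural invariants: 3N frequencies and eigenvectors for N
#' atoms, orthonormal eigenvectors, positive masses, finite numbers, and a
#' symmetric optical permittivity with diagonal entries of at least 1.
#'
#' @param x A `phonon_data` object.
#' @param tolerance Orthonormality tolerance (default 1e-6).
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_phonon_data <- function(x, tolerance = 1e-6) {
  stopifnot(inherits(x, "phonon_data"))
  n <- nrow(x$atoms)
  if (n < 1) stop("phonon data must contain at least one atom", call. = FALSE)
  if (!all(c("label", "mass") %in% names(x$atoms))) {
    stop("`atoms` must have columns `label` and `mass`", call. = FALSE)
  }
  if (any(!is.finite(x$atoms$mass)) || any(x$atoms$mass <= 0)) {
    stop("atomic masses must be positive and finite", call. = FALSE)
  }
  if (length(x$born_charges) != n) {
    stop("need one 3x3 Born charge tensor per atom (", n, " atoms, ",
         length(x$born_charges), " tensors)", call. = FALSE)
  }
  for (i in seq_len(n)) {
    z <- x$born_charges[[i]]
    if (any(dim(z) != c(3, 3)) || any(!is.finite(z))) {
      stop("Born charge tensor for atom ", i, " is not a finite 3x3 matrix",
           call. = FALSE)
    }
  }
  if (length(x$frequencies) != 3 * n) {
    stop("expected ", 3 * n, " mode frequencies for ", n, " atoms, got ",
         length(x$frequencies), call. = FALSE)
  }
  if (any(!is.finite(x$frequencies))) {
    stop("mode frequencies must be finite (imaginary modes are negative)",
         call. = FALSE)
  }
  u <- x$eigenvectors
  if (any(dim(u) != c(3 * n, 3 * n)) || any(!is.finite(u))) {
    stop("eigenvector matrix must be a finite ", 3 * n, "x", 3 * n,
         " matrix (one mode per row)", call. = FALSE)
  }
  dev <- max(abs(u %*% t(u) - diag(3 * n)))
  if (dev > tolerance) {
    stop("eigenvectors are not orthonormal: max deviation ",
         format(dev, digits = 3), " exceeds tolerance ", tolerance,
         call. = FALSE)
  }
  e <- x$optical_permittivity
  if (any(dim(e) != c(3, 3)) || any(!is.finite(e))) {
    stop("optical permittivity must be a finite 3x3 matrix", call. = FALSE)
  }
  if (max(abs(e - t(e))) > 1e-8) {
    stop("optical permittivity must be symmetric", call. = FALSE)
  }
  if (any(diag(e) < 1)) {
    stop("optical permittivity diagonal must be >= 1", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.phonon_data <- function(x, ...) {
  n <- nrow(x$atoms)
  cat("<phonon_data> ", n, " atoms, ", 3 * n, " modes\n", sep = "")
  cat("cell volume:", format(x$cell$volume), "A^3\n")
  cat("frequency range:", format(min(x$frequencies)), "to",
      format(max(x$frequencies)), "cm^-1\n")
  invisible(x)
}

PHONON_FORMAT <- "powderspec-phonon v1"

#' Read a canonical phonon-data file
#'
#' Reads the package's versioned text format (YAML, header key
#' `format: powderspec-phonon v1`).  The reader tolerates comments and blank
#' lines.  Files may store eigenvectors either in the mass-weighted
#' convention (the default) or as Cartesian displacements
#' (`eigenvector_convention: cartesian`); the latter are converted by
#' multiplying each atomic block by `sqrt(m_a)` and re-normalizing.
#'
#' @param path Path to the file.
#' @return A validated [phonon_data()] object.
#' @export
read_phonon_data <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop("cannot parse phonon file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (!identical(doc$format, PHONON_FORMAT)) {
    stop("file '", path, "' missing/unsupported `format` header (expected '",
         PHONON_FORMAT, "')", call. = FALSE)
  }
  need <- c("lattice_vectors", "atoms", "frequencies", "eigenvectors",
            "optical_permittivity")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    stop("phonon file '", path, "' is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  as_mat <- function(x, what) {
    m <- tryCatch(do.call(rbind, lapply(x, as.numeric)),
                  warning = function(w) stop(w), error = function(e) e)
    if (inherits(m, "error") || !is.numeric(m)) {
      stop("field `", what, "` is not a numeric array", call. = FALSE)
    }
    m
  }
  cell <- crystal_cell(as_mat(doc$lattice_vectors, "lattice_vectors"))
  labels <- vapply(doc$atoms, function(a) as.character(a$label), character(1))
  masses <- vapply(doc$atoms, function(a) as.numeric(a$mass), numeric(1))
  zs <- lapply(seq_along(doc$atoms), function(i) {
    as_mat(doc$atoms[[i]]$born_charge, paste0("atoms[", i, "]$born_charge"))
  })
  u <- as_mat(doc$eigenvectors, "eigenvectors")
  conv <- doc$eigenvector_convention %||% "mass_weighted"
  if (identical(conv, "cartesian")) {
    w <- rep(sqrt(masses), each = 3)
    u <- u * rep(w, each = nrow(u))
    nrm <- sqrt(rowSums(u^2))
    if (any(nrm == 0)) stop("zero Cartesian eigenvector row", call. = FALSE)
    u <- u / nrm
  } else if (!identical(conv, "mass_weighted")) {
    stop("unknown eigenvector_convention: ", conv, call. = FALSE)
  }
  phonon_data(
    cell = cell,
    atoms = tibble::tibble(label = labels, mass = masses),
    born_charges = zs,
    frequencies = as.numeric(doc$frequencies),
    eigenvectors = u,
    optical_permittivity = as_mat(doc$optical_permittivity,
                                  "optical_permittivity")
  )
}

#' Write a canonical phonon-data file
#'
#' Serializes a [phonon_data()] object to the versioned YAML format at full
#' double precision, so that a write/read round trip preserves every number
#' to better than 1e-12.
#'
#' @param data A valid `phonon_data` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phonon_data <- function(data, path) {
  validate_phonon_data(data)
  mat_rows <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  doc <- list(
    format = PHONON_FORMAT,
    lattice_vectors = mat_rows(data$cell$lattice_vectors),
    atoms = lapply(seq_len(nrow(data$atoms)), function(i) {
      list(label = data$atoms$label[i],
           mass = data$atoms$mass[i],
           born_charge = mat_rows(data$born_charges[[i]]))
    }),
    frequencies = data$frequencies,
    eigenvectors = mat_rows(data$eigenvectors),
    optical_permittivity = mat_rows(data$optical_permittivity),
    eigenvector_convention = "mass_weighted"
  )
  ok <- tryCatch({
    yaml::write_yaml(doc, path, precision = 17)
    TRUE
  }, error = function(e) {
    stop("cannot write phonon file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

#' Reconstruct the mass-weighted dynamical matrix
#'
#' Rebuilds `D = U' diag(sign(nu) * nu^2) U` from the stored frequencies and
#' eigenvectors, preserving negative eigenvalues for imaginary (unstable)
#' modes.  Re-diagonalizing the result recovers the input frequencies; this
#' is the starting point for the non-analytic LO correction.
#'
#' @param data A valid `phonon_data` object.
#' @return A 3N x 3N symmetric matrix with eigenvalues in cm^-2.
#' @export
reconstruct_dynamical_matrix <- function(data) {
  validate_phonon_data(data)
  lam <- sign(data$frequencies) * data$frequencies^2
  u <- data$eigenvectors                       # rows are modes
  d <- t(u) %*% (lam * u)
  (d + t(d)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
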