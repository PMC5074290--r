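# Shared fixtures built in code.

mgo_model <- function(sigma = 10) {
  from_oscillator_table(reference_models()$mgo, sigma = sigma)
}

mgo_static <- function() {
  m <- mgo_model()
  Re(permittivity(m, 0)[1, 1, 1])
}

sphere_L <- function() depolarization(shape_spec("sphere"))

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# scalar Lorentz permittivity for closed-form cross-checks
scalar_lorentz <- function(nu, nu_to, d_eps, eps_inf, sigma) {
  eps_inf + d_eps * nu_to^2 / (nu_to^2 - nu^2 - 1i * sigma * nu)
}
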