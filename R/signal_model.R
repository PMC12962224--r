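# Forward signal model.
#
# Each component carries an axisymmetric frequency-dependent diffusion
# tensor: the axial and radial eigenvalues follow a Lorentzian dispersion
# from their zero-frequency values (d_par, d_perp) to a common
# high-frequency isotropic plateau d0, with transition rates gamma_par,
# gamma_perp. The measured signal of a component is
#   k = exp(-b : D(omega_cent)) * (1 - exp(-TR * R1)) * exp(-TE * R2),
# where the b-tensor is B = b * [ (1 - b_delta)/3 * I + b_delta * v v^T ]
# and the spectral integral of the encoding is approximated by evaluating
# D at the waveform's centroid frequency. A voxel signal is the
# nonnegative-weighted sum of component kernels, s = K w.

#' Lorentzian diffusivity dispersion
#'
#' `lambda(omega) = d_zero + (d_inf - d_zero) * omega^2 / (omega^2 + gamma^2)`:
#' equal to `d_zero` at zero frequency, approaching the high-frequency
#' plateau `d_inf` with transition rate `gamma`, and monotone in between.
#'
#' @param d_zero Zero-frequency diffusivity (um^2/ms).
#' @param d_inf High-frequency diffusivity (um^2/ms).
#' @param gamma Spectral transition frequency (rad/s); strictly positive.
#' @param omega Angular frequency (rad/s); nonnegative.
#' @return Diffusivity at `omega` (um^2/ms).
#' @examples
#' lorentzian_diffusivity(2.5, 2, 200, 200)  # halfway: 2.25
#' @export
lorentzian_diffusivity <- function(d_zero, d_inf, gamma, omega) {
  if (any(gamma <= 0)) stop("gamma must be strictly positive")
  if (any(omega < 0)) stop("omega must be nonnegative")
  d_zero + (d_inf - d_zero) * omega^2 / (omega^2 + gamma^2)
}

# multiply/add a vector across the columns of an M x N matrix (recycling by
# row is the fast replacement for sweep in the kernel hot path)
colmul <- function(mat, v) mat * rep(v, each = nrow(mat))
coladd <- function(mat, v) mat + rep(v, each = nrow(mat))

# Axial/radial eigenvalues for a component matrix at one or more frequencies.
# Returns a list of two length(omega) x nrow(comps) matrices.
component_eigenvalues <- function(comps, omega) {
  om2 <- omega^2
  frac_par <- om2 / outer(om2, comps[, "gamma_par"]^2, "+")
  frac_perp <- om2 / outer(om2, comps[, "gamma_perp"]^2, "+")
  lam_par <- coladd(colmul(frac_par, comps[, "d0"] - comps[, "d_par"]),
                    comps[, "d_par"])
  lam_perp <- coladd(colmul(frac_perp, comps[, "d0"] - comps[, "d_perp"]),
                     comps[, "d_perp"])
  list(par = lam_par, perp = lam_perp)
}

#' Isotropic diffusivity and squared normalized anisotropy
#'
#' Projects components onto the scalar metrics `Diso(omega)` and
#' `Ddelta^2(omega)`: with axial/radial eigenvalues `lambda_par`,
#' `lambda_perp` at `omega`, `Diso = (lambda_par + 2*lambda_perp)/3` and
#' `Ddelta = (lambda_par - lambda_perp)/(3*Diso)` (so `Ddelta^2` lies in
#' \[0, 1\]).
#'
#' @param comps Component matrix.
#' @param omega Single angular frequency (rad/s).
#' @return List with numeric vectors `d_iso` (um^2/ms) and `d_delta_sq`.
#' @export
diffusion_scalars <- function(comps, omega) {
  validate_components(comps)
  stopifnot(length(omega) == 1L, omega >= 0)
  lam <- component_eigenvalues(comps, omega)
  d_iso <- as.numeric(lam$par + 2 * lam$perp) / 3
  if (any(d_iso <= 0)) stop("degenerate component: d_iso = 0")
  d_delta <- as.numeric(lam$par - lam$perp) / (3 * d_iso)
  list(d_iso = d_iso, d_delta_sq = d_delta^2)
}

# Unit symmetry-axis vectors from polar/azimuthal angles; n x 3 matrix.
axis_vectors <- function(theta, phi) {
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Diffusion-encoding attenuation exponent
#'
#' The generalized scalar product `b : D(omega_cent)` for every
#' (measurement, component) pair:
#' `b * [ (1 - b_delta)/3 * (lambda_par + 2*lambda_perp)
#'        + b_delta * (lambda_perp + (lambda_par - lambda_perp) * cos^2(beta)) ]`
#' with eigenvalues evaluated at the measurement's centroid frequency and
#' `beta` the angle between the encoding axis and the component axis.
#' Nonnegative; zero when `b = 0`.
#'
#' @param p Protocol (M measurements).
#' @param comps Component matrix (N components).
#' @return M x N matrix of dimensionless exponents.
#' @export
encoding_attenuation_exponent <- function(p, comps) {
  validate_components(comps)
  lam <- component_eigenvalues(comps, p$omega_cent)
  u_enc <- axis_vectors(p$theta_enc, p$phi_enc)           # M x 3
  u_cmp <- axis_vectors(comps[, "theta"], comps[, "phi"]) # N x 3
  cos2 <- (u_enc %*% t(u_cmp))^2                          # M x N
  iso <- (lam$par + 2 * lam$perp) / 3
  aniso <- lam$perp + (lam$par - lam$perp) * cos2
  out <- p$b * ((1 - p$b_delta) * iso + p$b_delta * aniso)
  dimnames(out) <- NULL
  out
}

#' Kernel matrix of component signal responses
#'
#' Entry (m, n) is the signal fraction of component n under measurement m:
#' `exp(-b:D) * (1 - exp(-TR*R1)) * exp(-TE*R2)`, always in (0, 1\].
#'
#' @param p Protocol (M measurements).
#' @param comps Component matrix (N components).
#' @return M x N kernel matrix.
#' @export
kernel_matrix <- function(p, comps) {
  if (is.null(dim(comps)) || nrow(comps) == 0L)
    stop("empty component list")
  validate_components(comps)
  kernel_cpp(p$b, p$b_delta, p$theta_enc, p$phi_enc, p$omega_cent,
             p$te, p$tr, comps[, component_fields(), drop = FALSE])
}

#' Kernel value for a single measurement/component pair
#'
#' Scalar convenience wrapper around [kernel_matrix()].
#'
#' @param p Protocol (one or more rows).
#' @param comp Single-row component matrix.
#' @return Numeric vector of kernel values, one per protocol row.
#' @export
kernel_value <- function(p, comp) {
  as.numeric(kernel_matrix(p, comp))
}

#' Synthesize a signal from weighted components
#'
#' `s = K w` with nonnegative weights; linear in `w`.
#'
#' @param p Protocol.
#' @param comps Component matrix (N components).
#' @param weights Nonnegative weight vector of length N.
#' @return Signal vector of length `n_meas(p)`.
#' @export
synthesize_signal <- function(p, comps, weights) {
  if (length(weights) != nrow(comps))
    stop("length(weights) must equal the number of components")
  if (any(weights < 0)) stop("weights must be nonnegative")
  as.numeric(kernel_matrix(p, comps) %*% weights)
}
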