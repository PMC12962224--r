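# Diffusion-relaxation components and their parameter bounds.
#
# A component is one axisymmetric frequency-dependent diffusion tensor plus
# its relaxation rates, described by 9 parameters. Component sets are plain
# numeric matrices (rows = components) with the canonical column names below;
# the matrix representation keeps the bootstrap inner loops fast.

#' Canonical component parameter names
#'
#' Order and meaning of the 9 parameters describing one diffusion-relaxation
#' component: `d_par`, `d_perp` (zero-frequency axial/radial diffusivity,
#' um^2/ms), `theta`, `phi` (symmetry-axis polar/azimuthal angle, rad),
#' `d0` (high-frequency isotropic diffusivity, um^2/ms), `gamma_par`,
#' `gamma_perp` (axial/radial spectral transition frequencies, rad/s),
#' `r1`, `r2` (longitudinal/transverse relaxation rates, 1/s).
#'
#' @export
component_fields <- function() {
  c("d_par", "d_perp", "theta", "phi", "d0",
    "gamma_par", "gamma_perp", "r1", "r2")
}

#' Build a component matrix
#'
#' Assembles one or more diffusion-relaxation components into the canonical
#' n x 9 matrix used throughout the package. All arguments recycle to the
#' longest length.
#'
#' @param d_par,d_perp Zero-frequency axial/radial diffusivity (um^2/ms).
#' @param theta,phi Symmetry-axis angles (rad): `theta` from +z,
#'   `phi` from +x in the xy-plane.
#' @param d0 High-frequency isotropic diffusivity (um^2/ms).
#' @param gamma_par,gamma_perp Axial/radial spectral transition frequencies
#'   (rad/s).
#' @param r1,r2 Longitudinal/transverse relaxation rates (1/s).
#' @return Numeric matrix with one row per component and columns
#'   [component_fields()].
#' @examples
#' components(d_par = 2.5, d_perp = 0.1, theta = 0, phi = 0, d0 = 2,
#'            gamma_par = 200, gamma_perp = 700, r1 = 1.5, r2 = 20)
#' @export
components <- function(d_par, d_perp, theta, phi, d0,
                       gamma_par, gamma_perp, r1, r2) {
  m <- cbind(d_par = d_par, d_perp = d_perp, theta = theta, phi = phi,
             d0 = d0, gamma_par = gamma_par, gamma_perp = gamma_perp,
             r1 = r1, r2 = r2)
  validate_components(m)
  m
}

#' Validate a component matrix
#'
#' Checks the canonical column layout, strict positivity of diffusivities,
#' transition frequencies and relaxation rates, and the angular ranges
#' `0 <= theta <= pi`, `0 <= phi <= 2*pi`. When `bounds` is supplied every
#' field must additionally lie within it.
#'
#' @param comps Component matrix (see [components()]).
#' @param bounds Optional bounds matrix (see [default_bounds()]).
#' @return `comps`, invisibly.
#' @export
validate_components <- function(comps, bounds = NULL) {
  if (!is.matrix(comps) || !identical(colnames(comps), component_fields()))
    stop("components must be a matrix with columns ",
         paste(component_fields(), collapse = ", "))
  if (nrow(comps) == 0L) stop("empty component matrix")
  pos <- c("d_par", "d_perp", "d0", "gamma_par", "gamma_perp", "r1", "r2")
  if (any(comps[, pos] <= 0))
    stop("diffusivities, transition frequencies and relaxation rates must be strictly positive")
  if (any(comps[, "theta"] < 0 | comps[, "theta"] > pi))
    stop("theta must lie in [0, pi]")
  if (any(comps[, "phi"] < 0 | comps[, "phi"] > 2 * pi))
    stop("phi must lie in [0, 2*pi]")
  if (!is.null(bounds)) {
    for (f in component_fields()) {
      if (any(comps[, f] < bounds["min", f] - 1e-12) ||
          any(comps[, f] > bounds["max", f] + 1e-12))
        stop("component field '", f, "' outside bounds")
    }
  }
  invisible(comps)
}

#' Default biologically plausible parameter bounds
#'
#' The sampling/clipping box used by all inversions:
#' diffusivities 0.05-5 um^2/ms, theta 0-pi, phi 0-2*pi,
#' R1 0.2-2 1/s, R2 1-30 1/s, transition frequencies 0.01-1e4 rad/s.
#'
#' @return 2 x 9 matrix with rows `min`, `max` and columns
#'   [component_fields()].
#' @export
default_bounds <- function() {
  b <- rbind(
    min = c(d_par = 0.05, d_perp = 0.05, theta = 0, phi = 0, d0 = 0.05,
            gamma_par = 0.01, gamma_perp = 0.01, r1 = 0.2, r2 = 1),
    max = c(d_par = 5, d_perp = 5, theta = pi, phi = 2 * pi, d0 = 5,
            gamma_par = 1e4, gamma_perp = 1e4, r1 = 2, r2 = 30)
  )
  validate_bounds(b)
}

#' Validate a bounds matrix
#'
#' @param bounds 2 x 9 matrix with rows `min`, `max`.
#' @return `bounds`, invisibly returned after checking `min < max` per field
#'   (equal bounds are allowed only when explicitly degenerate, i.e.
#'   `min == max`).
#' @export
validate_bounds <- function(bounds) {
  if (!is.matrix(bounds) || !identical(rownames(bounds), c("min", "max")) ||
      !identical(colnames(bounds), component_fields()))
    stop("bounds must be a 2 x 9 matrix with rows min/max and the canonical columns")
  if (any(bounds["min", ] > bounds["max", ]))
    stop("bounds must satisfy min <= max for every field")
  bounds
}

#' Clip components to bounds
#'
#' @param comps Component matrix.
#' @param bounds Bounds matrix.
#' @return Component matrix with every field clipped into `[min, max]`.
#' @export
clip_components <- function(comps, bounds = default_bounds()) {
  n <- nrow(comps)
  lo <- matrix(bounds["min", ], n, 9L, byrow = TRUE)
  hi <- matrix(bounds["max", ], n, 9L, byrow = TRUE)
  out <- pmin(pmax(comps, lo), hi)
  dimnames(out) <- dimnames(comps)
  out
}

#' Draw random candidate components
#'
#' Global exploration draws used by the proliferation step: log-uniform for
#' diffusivities and transition frequencies (their bounds span orders of
#' magnitude), uniform for R1/R2, and uniform-on-the-sphere orientations
#' (`cos(theta)` uniform in \[-1, 1\], `phi` uniform). Uses the current R RNG
#' state.
#'
#' @param bounds Bounds matrix; degenerate bounds (`min == max`) yield that
#'   constant.
#' @param count Number of components to draw.
#' @return `count` x 9 component matrix within `bounds`.
#' @export
sample_components <- function(bounds = default_bounds(), count = 1L) {
  validate_bounds(bounds)
  if (count < 1L) stop("count must be >= 1")
  log_fields <- c("d_par", "d_perp", "d0", "gamma_par", "gamma_perp")
  uni_fields <- c("r1", "r2")
  m <- matrix(0, nrow = count, ncol = 9L,
              dimnames = list(NULL, component_fields()))
  for (f in log_fields) {
    lo <- bounds["min", f]; hi <- bounds["max", f]
    m[, f] <- exp(runif(count, log(lo), log(hi)))
  }
  for (f in uni_fields)
    m[, f] <- runif(count, bounds["min", f], bounds["max", f])
  # orientation: uniform over the sphere, then clipped into the angular box
  ct <- runif(count, -1, 1)
  m[, "theta"] <- acos(ct)
  m[, "phi"] <- runif(count, 0, 2 * pi)
  clip_components(m, bounds)
}
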