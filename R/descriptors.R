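# Voxel-wise distributions and scalar descriptors: bootstrap solutions are
# pooled into a discrete weighted distribution over components, then
# projected onto scalar statistics (means/variances/covariances of
# Diso(omega), Ddelta^2(omega), R1, R2), bin fractions in the Diso-Ddelta^2
# plane, and finite-difference frequency dependence rates.

#' Aggregate bootstrap solutions into a voxel distribution
#'
#' Per-bootstrap weights are normalized to sum 1, then pooled with a factor
#' `1 / (number of non-empty bootstraps)`, so the total pooled weight is 1.
#' Empty bootstraps are skipped; if all are empty an empty-distribution
#' sentinel is returned.
#'
#' @param solutions List of `idmc_solution` (one per bootstrap).
#' @return List of class `voxel_distribution` with `components` (pooled
#'   matrix) and `weights` (pooled, summing to 1), or an empty sentinel.
#' @export
aggregate_solutions <- function(solutions) {
  nonempty <- Filter(Negate(is_empty_solution), solutions)
  if (length(nonempty) == 0L)
    return(structure(list(components = NULL, weights = numeric(0)),
                     class = "voxel_distribution"))
  comps <- do.call(rbind, lapply(nonempty, `[[`, "components"))
  w <- unlist(lapply(nonempty, function(s) s$weights / sum(s$weights)))
  structure(list(components = comps, weights = w / length(nonempty)),
            class = "voxel_distribution")
}

#' Is a voxel distribution empty?
#' @param dist A `voxel_distribution`.
#' @return `TRUE` when it has no support.
#' @export
is_empty_distribution <- function(dist) {
  is.null(dist$components) || length(dist$weights) == 0L
}

#' Weighted mean and variance
#'
#' `E = sum(w x) / sum(w)`; `V = sum(w (x - E)^2) / sum(w)`.
#'
#' @param values Numeric vector.
#' @param weights Nonnegative weights with positive total.
#' @return List with `E` and `V`.
#' @export
weighted_stats <- function(values, weights) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  sw <- sum(weights)
  if (sw <= 0) stop("total weight must be positive")
  E <- sum(weights * values) / sw
  V <- sum(weights * (values - E)^2) / sw
  list(E = E, V = V)
}

#' Weighted covariance
#'
#' `C = sum(w (x - E[x]) (y - E[y])) / sum(w)`; symmetric, and equal to the
#' weighted variance when `y = x`.
#'
#' @param x,y Numeric vectors.
#' @param weights Nonnegative weights with positive total.
#' @return Scalar covariance.
#' @export
weighted_cov <- function(x, y, weights) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  sw <- sum(weights)
  if (sw <= 0) stop("total weight must be positive")
  ex <- sum(weights * x) / sw
  ey <- sum(weights * y) / sw
  sum(weights * (x - ex) * (y - ey)) / sw
}

#' Bin definition in the Diso-Ddelta^2 plane
#'
#' Three partial integration regions approximating white matter
#' (anisotropic, low diffusivity), gray matter (isotropic, low diffusivity)
#' and CSF (high diffusivity): bin 3 takes `Diso > diso_threshold` over the
#' full anisotropy range; among the rest, bin 1 takes
#' `Ddelta^2 > ddelta_sq_threshold` and bin 2 the complement. Strict
#' inequalities; components exactly on a threshold fall to bins 1/2.
#'
#' @param diso_threshold Isotropic-diffusivity threshold (um^2/ms),
#'   default 2.5.
#' @param ddelta_sq_threshold Squared-anisotropy threshold, default 0.25.
#' @param f_ref Reference frequency (Hz) at which the omega-dependent
#'   metrics are evaluated, default 6.6 (the lowest sampled frequency).
#' @return List of class `bin_definition`.
#' @export
bin_definition <- function(diso_threshold = 2.5, ddelta_sq_threshold = 0.25,
                           f_ref = 6.6) {
  stopifnot(diso_threshold > 0, ddelta_sq_threshold > 0)
  structure(list(diso_threshold = diso_threshold,
                 ddelta_sq_threshold = ddelta_sq_threshold,
                 f_ref = f_ref),
            class = "bin_definition")
}

#' Assign distribution components to bins
#'
#' @param dist Non-empty `voxel_distribution`.
#' @param bins A [bin_definition()].
#' @return List with integer `labels` (1, 2 or 3 per component) and the
#'   normalized weight fractions `fbin1`, `fbin2`, `fbin3` (summing to 1).
#' @export
assign_bins <- function(dist, bins = bin_definition()) {
  if (is_empty_distribution(dist)) stop("empty distribution")
  sc <- diffusion_scalars(dist$components, 2 * pi * bins$f_ref)
  labels <- ifelse(sc$d_iso > bins$diso_threshold, 3L,
                   ifelse(sc$d_delta_sq > bins$ddelta_sq_threshold, 1L, 2L))
  w <- dist$weights / sum(dist$weights)
  list(labels = labels,
       fbin1 = sum(w[labels == 1L]),
       fbin2 = sum(w[labels == 2L]),
       fbin3 = sum(w[labels == 3L]))
}

# E or V of Diso or Ddelta^2 at one frequency (Hz)
stat_at_freq <- function(dist, f_hz, statistic = c("E", "V"),
                         metric = c("d_iso", "d_delta_sq")) {
  statistic <- match.arg(statistic)
  metric <- match.arg(metric)
  sc <- diffusion_scalars(dist$components, 2 * pi * f_hz)
  st <- weighted_stats(sc[[metric]], dist$weights)
  st[[statistic]]
}

#' Finite-difference frequency dependence of a descriptor
#'
#' `(stat(f_hi) - stat(f_lo)) / (f_hi - f_lo)` per Hz, for the mean or
#' variance of `Diso(omega)` or `Ddelta^2(omega)`.
#'
#' @param dist Non-empty `voxel_distribution`.
#' @param f_lo,f_hi Evaluation frequencies in Hz (default 6.6 and 21, the
#'   sampled centroid-frequency extremes); `f_hi > f_lo`.
#' @param statistic `"E"` or `"V"`.
#' @param metric `"d_iso"` or `"d_delta_sq"`.
#' @return Rate of change per Hz.
#' @export
freq_dependence <- function(dist, f_lo = 6.6, f_hi = 21,
                            statistic = c("E", "V"),
                            metric = c("d_iso", "d_delta_sq")) {
  if (is_empty_distribution(dist)) stop("empty distribution")
  if (f_hi <= f_lo) stop("f_hi must exceed f_lo")
  (stat_at_freq(dist, f_hi, statistic, metric) -
     stat_at_freq(dist, f_lo, statistic, metric)) / (f_hi - f_lo)
}

#' Scalar summary of a voxel distribution
#'
#' Means and variances of `Diso`, `Ddelta^2` (at the bin reference
#' frequency), `R1` and `R2`; the covariance pairs (Diso, Ddelta^2),
#' (Diso, R1), (Diso, R2), (Ddelta^2, R2); bin fractions; and the
#' finite-difference frequency rates of E and V of the diffusivity metrics
#' between `f_lo` and `f_hi`.
#'
#' @param dist `voxel_distribution`; an empty distribution yields all-`NA`.
#' @param bins A [bin_definition()].
#' @param f_lo,f_hi Frequency-dependence evaluation points (Hz).
#' @return Named numeric vector of descriptors.
#' @export
scalar_summary <- function(dist, bins = bin_definition(),
                           f_lo = 6.6, f_hi = 21) {
  fields <- c("E_diso", "V_diso", "E_ddsq", "V_ddsq", "E_r1", "V_r1",
              "E_r2", "V_r2", "C_diso_ddsq", "C_diso_r1", "C_diso_r2",
              "C_ddsq_r2", "fbin1", "fbin2", "fbin3",
              "rate_E_diso", "rate_V_diso", "rate_E_ddsq", "rate_V_ddsq")
  if (is_empty_distribution(dist))
    return(setNames(rep(NA_real_, length(fields)), fields))
  sc <- diffusion_scalars(dist$components, 2 * pi * bins$f_ref)
  w <- dist$weights
  s_diso <- weighted_stats(sc$d_iso, w)
  s_ddsq <- weighted_stats(sc$d_delta_sq, w)
  s_r1 <- weighted_stats(dist$components[, "r1"], w)
  s_r2 <- weighted_stats(dist$components[, "r2"], w)
  fb <- assign_bins(dist, bins)
  out <- c(
    E_diso = s_diso$E, V_diso = s_diso$V,
    E_ddsq = s_ddsq$E, V_ddsq = s_ddsq$V,
    E_r1 = s_r1$E, V_r1 = s_r1$V,
    E_r2 = s_r2$E, V_r2 = s_r2$V,
    C_diso_ddsq = weighted_cov(sc$d_iso, sc$d_delta_sq, w),
    C_diso_r1 = weighted_cov(sc$d_iso, dist$components[, "r1"], w),
    C_diso_r2 = weighted_cov(sc$d_iso, dist$components[, "r2"], w),
    C_ddsq_r2 = weighted_cov(sc$d_delta_sq, dist$components[, "r2"], w),
    fbin1 = fb$fbin1, fbin2 = fb$fbin2, fbin3 = fb$fbin3,
    rate_E_diso = freq_dependence(dist, f_lo, f_hi, "E", "d_iso"),
    rate_V_diso = freq_dependence(dist, f_lo, f_hi, "V", "d_iso"),
    rate_E_ddsq = freq_dependence(dist, f_lo, f_hi, "E", "d_delta_sq"),
    rate_V_ddsq = freq_dependence(dist, f_lo, f_hi, "V", "d_delta_sq")
  )
  out[fields]
}

#' Build 3D descriptor maps from per-voxel distributions
#'
#' @param distributions List of `voxel_distribution`, aligned to the `TRUE`
#'   voxels of `mask` in raster (column-major) order.
#' @param mask Logical 3D array.
#' @param bins,f_lo,f_hi Passed to [scalar_summary()].
#' @return Named list of 3D arrays (one per descriptor); voxels outside the
#'   mask are `NaN`.
#' @export
voxel_maps <- function(distributions, mask, bins = bin_definition(),
                       f_lo = 6.6, f_hi = 21) {
  idx <- which(mask)
  if (length(idx) != length(distributions))
    stop("number of distributions (", length(distributions),
         ") does not match mask voxels (", length(idx), ")")
  summaries <- vapply(distributions, scalar_summary,
                      numeric(19L), bins = bins, f_lo = f_lo, f_hi = f_hi)
  lapply(setNames(seq_len(nrow(summaries)), rownames(summaries)), function(r) {
    m <- array(NaN, dim = dim(mask))
    m[idx] <- summaries[r, ]
    m
  })
}
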