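# Earth Mover's Distance between voxel distributions: exact optimal
# transport between two discrete weighted component sets under a normalized
# Euclidean ground metric.

#' Embed components in the normalized EMD coordinate space
#'
#' Diffusivities, transition frequencies and relaxation rates are mapped to
#' log10 and scaled to \[0, 1\] by their (log10) bounds. Orientation is
#' excluded by default (the scalar projections the distributions are
#' evaluated on are orientation-free); setting `orientation_weight > 0`
#' appends the symmetry-axis unit vector scaled by that weight.
#'
#' @param comps Component matrix.
#' @param bounds Parameter bounds used for scaling.
#' @param orientation_weight Nonnegative scale of the orientation block
#'   (default 0 = excluded).
#' @return Numeric matrix, one row per component.
#' @export
component_embedding <- function(comps, bounds = default_bounds(),
                                orientation_weight = 0) {
  fields <- c("d_par", "d_perp", "d0", "gamma_par", "gamma_perp", "r1", "r2")
  emb <- sapply(fields, function(f) {
    lo <- log10(bounds["min", f]); hi <- log10(bounds["max", f])
    (log10(pmax(comps[, f], .Machine$double.xmin)) - lo) / (hi - lo)
  })
  emb <- matrix(emb, nrow = nrow(comps),
                dimnames = list(NULL, fields))
  if (orientation_weight > 0) {
    u <- axis_vectors(comps[, "theta"], comps[, "phi"]) * orientation_weight
    colnames(u) <- c("ux", "uy", "uz")
    emb <- cbind(emb, u)
  }
  emb
}

#' Earth Mover's Distance between two voxel distributions
#'
#' Exact optimal-transport cost between the two discrete weighted component
#' sets under the Euclidean metric in the normalized coordinate space of
#' [component_embedding()]. Supports are pruned at a relative weight
#' threshold of 1e-6 and renormalized to unit mass before solving, so the
#' distance is invariant to global weight rescaling. Zero iff the pruned
#' supports and weights coincide.
#'
#' @param dist_a,dist_b Non-empty `voxel_distribution` objects.
#' @param bounds Parameter bounds for the embedding.
#' @param orientation_weight See [component_embedding()].
#' @return Nonnegative scalar transport cost.
#' @export
emd <- function(dist_a, dist_b, bounds = default_bounds(),
                orientation_weight = 0) {
  if (is_empty_distribution(dist_a) || is_empty_distribution(dist_b))
    stop("EMD requires non-empty distributions")
  prune <- function(d) {
    w <- d$weights / sum(d$weights)
    keep <- w > 1e-6
    list(components = d$components[keep, , drop = FALSE],
         weights = w[keep] / sum(w[keep]))
  }
  a <- prune(dist_a); b <- prune(dist_b)
  ea <- component_embedding(a$components, bounds, orientation_weight)
  eb <- component_embedding(b$components, bounds, orientation_weight)
  # pairwise Euclidean ground distances
  cost <- sqrt(pmax(outer(rowSums(ea^2), rowSums(eb^2), "+") -
                      2 * ea %*% t(eb), 0))
  emd_cpp(a$weights, b$weights, cost)
}

#' Voxel distribution of a phantom
#'
#' Convenience conversion of a ground-truth phantom into the
#' `voxel_distribution` form accepted by [emd()] and the descriptors.
#'
#' @param phantom A [phantom()] (components + weights).
#' @return A `voxel_distribution`.
#' @export
as_voxel_distribution <- function(phantom) {
  structure(list(components = phantom$components,
                 weights = phantom$weights / sum(phantom$weights)),
            class = "voxel_distribution")
}
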