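# Per-bootstrap inversion solutions: a component set with nonnegative
# weights, the residual of the NNLS fit on the bootstrap-resampled
# measurements, and the fitted resampled signal.

new_solution <- function(components = NULL, weights = numeric(0),
                         residual_norm = NA_real_, fitted_signal = NULL,
                         kernel_evals = 0L, match_index = NA_integer_,
                         match_similarity = NA_real_) {
  structure(list(components = components, weights = weights,
                 residual_norm = residual_norm, fitted_signal = fitted_signal,
                 kernel_evals = kernel_evals, match_index = match_index,
                 match_similarity = match_similarity),
            class = "idmc_solution")
}

#' Is a solution empty?
#' @param sol An `idmc_solution`.
#' @return `TRUE` when the solution retains no components.
#' @export
is_empty_solution <- function(sol) {
  is.null(sol$components) || length(sol$weights) == 0L
}

#' @export
print.idmc_solution <- function(x, ...) {
  if (is_empty_solution(x)) {
    cat("<idmc_solution: empty>\n")
  } else {
    cat(sprintf("<idmc_solution: %d component(s), residual %.4g>\n",
                nrow(x$components), x$residual_norm))
  }
  invisible(x)
}

# NNLS on the resampled rows, then prune zero-weight columns and cap the
# retained set at `nc` components by largest weight (refitting after a cap
# so the reported residual is the NNLS optimum of the kept columns).
fit_prune_cap <- function(comps, kernels_full, s_b, plan_row, nc,
                          init_cols = NULL) {
  Kb <- kernels_full[plan_row, , drop = FALSE]
  fit <- nnls_fit(Kb, s_b, init = init_cols)
  keep <- which(fit$weights > 0)
  if (length(keep) == 0L)
    return(list(components = NULL, weights = numeric(0),
                kernels = NULL, residual = sqrt(sum(s_b^2)),
                fitted = rep(0, length(s_b))))
  if (length(keep) > nc)
    keep <- keep[order(fit$weights[keep], decreasing = TRUE)][seq_len(nc)]
  keep <- sort(keep)
  K_keep <- kernels_full[, keep, drop = FALSE]
  refit <- nnls_fit(K_keep[plan_row, , drop = FALSE], s_b,
                    init = seq_along(keep))
  nz <- which(refit$weights > 0)
  if (length(nz) == 0L)
    return(list(components = NULL, weights = numeric(0),
                kernels = NULL, residual = sqrt(sum(s_b^2)),
                fitted = rep(0, length(s_b))))
  keep <- keep[nz]
  K_keep <- kernels_full[, keep, drop = FALSE]
  w <- refit$weights[nz]
  list(components = comps[keep, , drop = FALSE], weights = w,
       kernels = K_keep,
       residual = refit$residual,
       fitted = as.numeric(K_keep[plan_row, , drop = FALSE] %*% w))
}
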