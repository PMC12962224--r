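#' Nonnegative least squares fit
#'
#' Solves `argmin_{w >= 0} || s - K w ||_2` with a Lawson-Hanson active-set
#' solver (compiled). Termination uses a tolerance of 1e-12 on the gradient
#' (dual feasibility) condition; ties resolve to the lowest column index.
#'
#' @param kernels M x N kernel matrix.
#' @param signal Signal vector of length M.
#' @param init Optional integer vector of 1-based column indices used to
#'   warm-start the passive set (the iterative inversions pass their current
#'   retained columns); the result is still run to full KKT optimality.
#' @return List with `weights` (length N, nonnegative) and `residual`
#'   (the 2-norm of the fit residual).
#' @examples
#' nnls_fit(diag(2), c(0.3, 0.7))$weights
#' @export
nnls_fit <- function(kernels, signal, init = NULL) {
  kernels <- as.matrix(kernels)
  if (nrow(kernels) != length(signal))
    stop("dimension mismatch: nrow(kernels) != length(signal)")
  if (!is.null(init)) init <- as.integer(init) - 1L
  fit <- nnls_cpp(kernels, as.numeric(signal), init = init)
  list(weights = as.numeric(fit$x), residual = fit$residual)
}
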