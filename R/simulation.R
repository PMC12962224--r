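# Synthetic evaluation harness: the four-component ground-truth phantom,
# a synthetic sparse acquisition protocol, Rician noise, bias-controlled
# training sets, reconstruction-quality metrics, and the simulation-study
# driver comparing MC, DM and ID-MC inversions.

#' Construct a phantom (ground-truth voxel)
#'
#' @param components Component matrix.
#' @param weights Nonnegative weights summing to 1 (renormalized on input).
#' @return List of class `idmc_phantom`.
#' @export
phantom <- function(components, weights) {
  validate_components(components)
  if (length(weights) != nrow(components))
    stop("one weight per component required")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative with positive total")
  structure(list(components = components, weights = weights / sum(weights)),
            class = "idmc_phantom")
}

#' Default four-component ground-truth phantom
#'
#' A partial-volume voxel of water in soma (component I: isotropic, low
#' diffusivity), two crossing fiber populations (components II and III:
#' identical tensors rotated in azimuth), and CSF (component IV: free
#' isotropic diffusion, frequency-flat), with signal fractions
#' 0.35/0.25/0.25/0.15.
#'
#' @return An `idmc_phantom`.
#' @examples
#' default_phantom()$weights
#' @export
default_phantom <- function() {
  deg <- pi / 180
  comps <- components(
    d_par     = c(0.5, 2.5, 2.5, 3),
    d_perp    = c(0.5, 0.1, 0.1, 3),
    theta     = c(0, 78, 78, 0) * deg,
    phi       = c(0, 78, 23, 0) * deg,
    d0        = c(2, 2, 2, 3),
    gamma_par = c(250, 200, 200, 1e4),
    gamma_perp = c(250, 700, 700, 1e4),
    r1        = c(1, 1.5, 1.5, 0.3),
    r2        = c(13, 20, 20, 6)
  )
  phantom(comps, c(0.35, 0.25, 0.25, 0.15))
}

#' Generate a synthetic sparse acquisition protocol
#'
#' Emulates a numerically optimized sparse multidimensional sampling scheme
#' as a structured design: exactly one non-diffusion-weighted (`b = 0`)
#' measurement; a low-b spherical "relaxation block" holding a TR ladder
#' (0.62-7.6 s, at the shortest TE) and a TE ladder (0.04-0.15 s, at the
#' longest TR); and diffusion shells cycling b-tensor shape (`b_delta` in
#' {1, 0, -0.5}) against magnitudes in \[0.1, 3\] ms/um^2, with orientations
#' spread over the sphere, centroid frequencies in \[6.6, 21\] Hz, and
#' TE/TR pairs cycled over the stated ranges. Deterministic given `seed`.
#'
#' @param n Total number of measurements including the `b = 0` volume
#'   (default 139).
#' @param seed Integer seed (orientations and centroid frequencies).
#' @return A validated protocol with `n` rows.
#' @export
make_protocol <- function(n = 139L, seed = 1L) {
  if (n < 15L) stop("n must be >= 15")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  # relaxation block: low-b spherical rows encoding R1 (TR ladder) and R2
  # (TE ladder)
  tr_ladder <- exp(seq(log(0.62), log(7.6), length.out = 6))
  te_ladder <- seq(0.04, 0.15, length.out = 6)
  blk <- data.frame(b = 0.1, b_delta = 0, theta_enc = 0, phi_enc = 0,
                    omega_cent = 2 * pi * 6.6,
                    te = c(rep(0.04, 6), te_ladder),
                    tr = c(tr_ladder, rep(7.6, 6)))
  nd <- n - 1L - nrow(blk)
  # diffusion block: shape x b shells, spread orientations, varied centroid
  # frequencies, TE/TR pairs cycled so relaxation and diffusion encoding
  # stay crossed
  shapes <- rep(c(1, 0, -0.5), length.out = nd)
  bvals <- rep(c(0.5, 1, 1.5, 2, 2.5, 3), length.out = nd)
  tetr <- matrix(c(0.04, 7.6, 0.06, 3.0, 0.09, 1.5, 0.12, 0.8, 0.15, 0.62),
                 ncol = 2, byrow = TRUE)
  pr <- tetr[rep(seq_len(nrow(tetr)), length.out = nd), , drop = FALSE]
  ct <- runif(nd, -1, 1)
  dif <- data.frame(b = bvals, b_delta = shapes,
                    theta_enc = acos(ct), phi_enc = runif(nd, 0, 2 * pi),
                    omega_cent = 2 * pi * runif(nd, 6.6, 21),
                    te = pr[, 1], tr = pr[, 2])
  d <- rbind(data.frame(b = 0, b_delta = 0, theta_enc = 0, phi_enc = 0,
                        omega_cent = 2 * pi * 6.6, te = 0.04, tr = 7.6),
             blk, dif)
  protocol(d$b, d$b_delta, d$theta_enc, d$phi_enc, d$omega_cent, d$te, d$tr)
}

#' Add Rician noise to a magnitude signal
#'
#' `S_i = sqrt((S_i + v_i/SNR)^2 + (v'_i/SNR)^2)` with independent standard
#' normal `v`, `v'`; the noise scale is referenced to a unit-amplitude
#' signal. Output is strictly nonnegative. Uses the current RNG state.
#'
#' @param signal Nonnegative signal vector.
#' @param snr Signal-to-noise ratio (> 0).
#' @return Noisy signal vector.
#' @export
add_rician_noise <- function(signal, snr) {
  if (snr <= 0) stop("snr must be positive")
  if (any(signal < 0)) stop("signal must be nonnegative")
  n <- length(signal)
  sqrt((signal + rnorm(n) / snr)^2 + (rnorm(n) / snr)^2)
}

#' Perturb a phantom to emulate a biased training population
#'
#' Every positive component parameter is multiplied by `(1 + eps)` with
#' `eps ~ N(0, sigma_bias^2)` and clipped to bounds; angles are perturbed
#' additively by `N(0, sigma_bias^2)` radians; weights are perturbed
#' multiplicatively (floored at a small positive value) and renormalized.
#' `sigma_bias = 0` returns the phantom unchanged. Uses the current RNG
#' state.
#'
#' @param ph An `idmc_phantom`.
#' @param sigma_bias Relative perturbation SD (>= 0).
#' @param bounds Parameter bounds for clipping.
#' @param perturb_weights Also perturb the weights (default `TRUE`).
#' @return A perturbed `idmc_phantom`.
#' @export
bias_phantom <- function(ph, sigma_bias, bounds = default_bounds(),
                         perturb_weights = TRUE) {
  if (sigma_bias < 0) stop("sigma_bias must be >= 0")
  if (sigma_bias == 0) return(ph)
  comps <- ph$components
  n <- nrow(comps)
  mult_fields <- c("d_par", "d_perp", "d0", "gamma_par", "gamma_perp",
                   "r1", "r2")
  for (f in mult_fields)
    comps[, f] <- comps[, f] * (1 + rnorm(n, 0, sigma_bias))
  comps[, "theta"] <- comps[, "theta"] + rnorm(n, 0, sigma_bias)
  comps[, "phi"] <- comps[, "phi"] + rnorm(n, 0, sigma_bias)
  # a large relative draw can push a positive parameter negative; the clip
  # to bounds also restores positivity
  for (f in mult_fields)
    comps[, f] <- pmax(comps[, f], bounds["min", f])
  comps <- clip_components(comps, bounds)
  w <- ph$weights
  if (perturb_weights)
    w <- pmax(w * (1 + rnorm(n, 0, sigma_bias)), 1e-3)
  phantom(comps, w)
}

#' Generate a bias-controlled noisy training set
#'
#' Each training signal is drawn by perturbing the phantom
#' ([bias_phantom()]), synthesizing the noise-free signal, and adding Rician
#' noise at the draw's SNR; `n_per_snr` signals are generated for every SNR
#' in `snr_list`. Uses the current RNG state.
#'
#' @param ph Ground-truth `idmc_phantom`.
#' @param sigma_bias Training-bias level.
#' @param snr_list SNR levels (e.g. `c(130, 90, 60, 30)`).
#' @param n_per_snr Signals per SNR level.
#' @param p Protocol.
#' @param bounds Parameter bounds.
#' @return (`n_per_snr * length(snr_list)`) x M signal matrix with attribute
#'   `snr` labelling each row's noise level.
#' @export
generate_training_set <- function(ph, sigma_bias, snr_list, n_per_snr, p,
                                  bounds = default_bounds()) {
  M <- n_meas(p)
  n_total <- n_per_snr * length(snr_list)
  out <- matrix(0, nrow = n_total, ncol = M)
  labels <- numeric(n_total)
  row <- 1L
  for (snr in snr_list) {
    for (i in seq_len(n_per_snr)) {
      bp <- bias_phantom(ph, sigma_bias, bounds)
      s <- synthesize_signal(p, bp$components, bp$weights)
      out[row, ] <- add_rician_noise(s, snr)
      labels[row] <- snr
      row <- row + 1L
    }
  }
  attr(out, "snr") <- labels
  out
}

#' Reconstruction similarity and normalized RMSE
#'
#' `signal_similarity` is the cosine similarity between the reconstructed
#' and reference signals; `nrmse` is
#' `||s_hat - s||_2 / (sqrt(M) * (max(s) - min(s)))`.
#'
#' @param s_hat Reconstructed signal.
#' @param s Reference signal (nonconstant for `nrmse`).
#' @return Scalar.
#' @export
signal_similarity <- function(s_hat, s) cosine_similarity(s_hat, s)

#' @rdname signal_similarity
#' @export
nrmse <- function(s_hat, s) {
  if (length(s_hat) != length(s)) stop("length mismatch")
  rng <- max(s) - min(s)
  if (rng == 0) stop("NRMSE undefined for a zero-range reference signal")
  sqrt(sum((s_hat - s)^2)) / (sqrt(length(s)) * rng)
}

# per-bootstrap cosine similarity between each solution's fitted resampled
# signal and the resampled data
bootstrap_similarities <- function(solutions, signal, plan) {
  vapply(seq_along(solutions), function(b) {
    sol <- solutions[[b]]
    if (is_empty_solution(sol)) return(0)
    cosine_similarity(sol$fitted_signal, signal[plan[b, ]])
  }, numeric(1))
}

#' High/low-similarity bootstrap counts
#'
#' For each voxel, counts the bootstrap fits whose similarity exceeds the
#' high threshold or falls below the low threshold. Thresholds can be given
#' directly or computed as percentiles (default 80th/20th) of a training
#' similarity sample.
#'
#' @param similarities Voxels x Nb matrix of per-bootstrap fit similarities.
#' @param thresholds Numeric `c(high, low)`, or `NULL` to derive from
#'   `training_similarities`.
#' @param training_similarities Numeric sample used when `thresholds` is
#'   `NULL`.
#' @param probs Percentiles used to derive thresholds (default
#'   `c(0.8, 0.2)`).
#' @return List with vectors `high_count`, `low_count` (bounded by Nb) and
#'   the `thresholds` used.
#' @export
similarity_count_maps <- function(similarities, thresholds = NULL,
                                  training_similarities = NULL,
                                  probs = c(0.8, 0.2)) {
  similarities <- as.matrix(similarities)
  if (is.null(thresholds)) {
    if (is.null(training_similarities))
      stop("either thresholds or training_similarities must be given")
    thresholds <- as.numeric(quantile(training_similarities, probs))
  }
  list(high_count = rowSums(similarities > thresholds[1]),
       low_count = rowSums(similarities < thresholds[2]),
       thresholds = thresholds)
}

#' Intraclass correlation coefficient, ICC(3,1)
#'
#' Two-way mixed, single-measure, consistency form:
#' `(MSR - MSE) / (MSR + (k - 1) MSE)` from the two-way ANOVA mean squares
#' (subjects x sessions). Invariant to adding a constant; 1 when sessions
#' agree exactly while subjects differ.
#'
#' @param values n x k numeric matrix (n subjects >= 3, k sessions >= 2).
#' @return Scalar ICC estimate.
#' @export
icc <- function(values) {
  x <- as.matrix(values)
  n <- nrow(x); k <- ncol(x)
  if (n < 3L || k < 2L) stop("need >= 3 subjects and >= 2 sessions")
  grand <- mean(x)
  rmn <- rowMeans(x); cmn <- colMeans(x)
  ssr <- k * sum((rmn - grand)^2)
  sse <- sum((x - outer(rmn, rep(1, k)) -
                matrix(cmn, n, k, byrow = TRUE) + grand)^2)
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr + (k - 1) * mse == 0) return(NA_real_)
  (msr - mse) / (msr + (k - 1) * mse)
}

#' Within-subject coefficient of variation
#'
#' `sqrt(mean within-subject variance) / grand mean`; zero when every
#' subject's sessions agree exactly.
#'
#' @param values n x k numeric matrix (subjects x sessions).
#' @return Scalar CVws.
#' @export
cvws <- function(values) {
  x <- as.matrix(values)
  g <- mean(x)
  if (g == 0) stop("CVws undefined for zero grand mean")
  wv <- apply(x, 1, var)
  sqrt(mean(wv)) / g
}
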