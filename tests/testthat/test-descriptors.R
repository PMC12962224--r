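# Voxel distributions and scalar descriptors: aggregation, weighted moments,
# bins, frequency finite-differences, and map assembly.

make_solution <- function(comps, weights) {
  structure(list(components = comps, weights = weights,
                 residual_norm = 0, fitted_signal = NULL, kernel_evals = 0L),
            class = "idmc_solution")
}

test_that("aggregation normalizes per bootstrap and pools with equal mass", {
  ph <- default_phantom()
  s1 <- make_solution(ph$components[1:2, ], c(2, 2))
  d1 <- aggregate_solutions(list(s1))
  expect_equal(d1$weights, c(0.5, 0.5))
  expect_equal(sum(d1$weights), 1)
  # two identical bootstraps give the same summary as one
  d2 <- aggregate_solutions(list(s1, s1))
  expect_equal(sum(d2$weights), 1)
  expect_equal(scalar_summary(d2), scalar_summary(d1))
  # empty bootstraps are skipped; all-empty yields the sentinel
  empty <- structure(list(components = NULL, weights = numeric(0),
                          residual_norm = NA, fitted_signal = NULL,
                          kernel_evals = 0L), class = "idmc_solution")
  d3 <- aggregate_solutions(list(s1, empty))
  expect_equal(sum(d3$weights), 1)
  expect_true(is_empty_distribution(aggregate_solutions(list(empty))))
})

test_that("weighted moments match hand-computed ground-truth values", {
  x <- c(0.5, 0.9, 0.9, 3.0)
  w <- c(0.35, 0.25, 0.25, 0.15)
  st <- weighted_stats(x, w)
  expect_equal(st$E, 1.075)
  expect_equal(st$V, 0.686875, tolerance = 1e-12)
  expect_equal(weighted_stats(rep(2.2, 4), w)$V, 0)
  expect_error(weighted_stats(x, rep(0, 4)), "positive")
  # covariance identities
  expect_equal(weighted_cov(x, x, w), st$V, tolerance = 1e-12)
  expect_equal(weighted_cov(x, rep(1, 4), w), 0)
  y <- c(13, 20, 20, 6)
  expect_equal(weighted_cov(x, y, w), weighted_cov(y, x, w))
  # brute-force expansion on a 3-point case
  x3 <- c(1, 2, 4); y3 <- c(2, 1, 5); w3 <- c(0.2, 0.3, 0.5)
  ex <- sum(w3 * x3); ey <- sum(w3 * y3)
  expect_equal(weighted_cov(x3, y3, w3), sum(w3 * (x3 - ex) * (y3 - ey)),
               tolerance = 1e-12)
})

test_that("bin assignment reproduces the ground-truth fractions", {
  ph <- default_phantom()
  dist <- as_voxel_distribution(ph)
  fb <- assign_bins(dist)
  expect_equal(fb$labels, c(2L, 1L, 1L, 3L))
  expect_equal(c(fb$fbin1, fb$fbin2, fb$fbin3), c(0.50, 0.35, 0.15))
  expect_equal(fb$fbin1 + fb$fbin2 + fb$fbin3, 1)
  # invariant to global weight rescaling
  dist2 <- dist; dist2$weights <- dist$weights * 7
  fb2 <- assign_bins(dist2)
  expect_equal(fb2$fbin1, fb$fbin1)
  # all-isotropic low-diffusivity distribution sits entirely in bin 2
  iso <- as_dist(components(0.7, 0.7, 0, 0, 1, 100, 100, 1, 10), 1)
  expect_equal(assign_bins(iso)$fbin2, 1)
  # boundary: Diso exactly at the threshold stays out of bin 3
  flat25 <- as_dist(components(2.5, 2.5, 0, 0, 2.5, 100, 100, 1, 10), 1)
  expect_equal(assign_bins(flat25)$labels, 2L)
})

test_that("frequency finite-differences match a closed-form evaluation", {
  ph <- default_phantom()
  dist <- as_voxel_distribution(ph)
  # independent evaluation written out from the Lorentzian arithmetic
  lam <- function(d0f, dinf, g, f) d0f + (dinf - d0f) * (2*pi*f)^2 / ((2*pi*f)^2 + g^2)
  e_diso <- function(f) {
    dI <- lam(0.5, 2, 250, f)
    dII <- (lam(2.5, 2, 200, f) + 2 * lam(0.1, 2, 700, f)) / 3
    0.35 * dI + 0.5 * dII + 0.15 * 3
  }
  oracle <- (e_diso(21) - e_diso(6.6)) / (21 - 6.6)
  rate <- freq_dependence(dist, 6.6, 21, "E", "d_iso")
  expect_equal(rate, oracle, tolerance = 1e-12)
  expect_equal(rate, 6.8e-3, tolerance = 1e-2)
  # frequency-flat distribution has zero rate
  flat <- as_dist(components(c(1, 2), c(1, 2), 0, 0, c(1, 2),
                             c(100, 50), c(100, 50), 1, 10), c(0.5, 0.5))
  expect_equal(freq_dependence(flat, 6.6, 21, "E", "d_iso"), 0)
  # antisymmetry: evaluating the difference with the endpoints swapped flips
  # the sign
  v_lo <- idmc:::stat_at_freq(dist, 6.6, "V", "d_delta_sq")
  v_hi <- idmc:::stat_at_freq(dist, 21, "V", "d_delta_sq")
  expect_equal(freq_dependence(dist, 6.6, 21, "V", "d_delta_sq"),
               -(v_lo - v_hi) / (21 - 6.6), tolerance = 1e-12)
  expect_error(freq_dependence(dist, 21, 6.6), "exceed")
})

test_that("scalar summaries are order invariant and maps align with the mask", {
  ph <- default_phantom()
  dist <- as_voxel_distribution(ph)
  perm <- c(4, 2, 1, 3)
  dist_p <- as_dist(ph$components[perm, ], ph$weights[perm])
  expect_equal(scalar_summary(dist_p), scalar_summary(dist))
  sm <- scalar_summary(dist)
  expect_equal(unname(sm["E_diso"]),
               weighted_stats(diffusion_scalars(ph$components, 2*pi*6.6)$d_iso,
                              ph$weights)$E)
  # map assembly: constant phantom volume gives constant maps, NaN outside
  mask <- array(FALSE, dim = c(3, 2, 1))
  mask[1:4] <- TRUE
  maps <- voxel_maps(rep(list(dist), 4), mask)
  expect_true(all(vapply(maps, function(m) identical(dim(m), dim(mask)), TRUE)))
  m1 <- maps[["E_diso"]]
  expect_equal(unname(m1[1:4]), rep(unname(sm["E_diso"]), 4))
  expect_true(all(is.nan(m1[5:6])))
  expect_error(voxel_maps(rep(list(dist), 3), mask), "does not match")
})
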