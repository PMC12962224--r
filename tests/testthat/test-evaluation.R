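# Synthetic evaluation harness: phantom, protocol generator, Rician noise,
# biased training sets, EMD, reconstruction metrics, and reliability
# statistics.

test_that("the default phantom reproduces the four ground-truth components", {
  ph <- default_phantom()
  expect_equal(sum(ph$weights), 1)
  expect_equal(ph$weights, c(0.35, 0.25, 0.25, 0.15))
  cII <- ph$components[2, ]
  expect_equal(unname(cII[c("d_par", "d_perp", "d0")]), c(2.5, 0.1, 2))
  expect_equal(unname(cII["theta"]), 78 * pi / 180)
  expect_equal(unname(cII["phi"]), 78 * pi / 180)
  expect_equal(unname(cII[c("gamma_par", "gamma_perp")]), c(200, 700))
  expect_equal(unname(cII[c("r1", "r2")]), c(1.5, 20))
  # free water is isotropic and frequency flat
  expect_equal(unname(ph$components[4, "d_par"]),
               unname(ph$components[4, "d_perp"]))
  expect_equal(unname(ph$components[4, "d_par"]), 3)
})

test_that("generated protocols respect the acquisition ranges", {
  p <- make_protocol()
  expect_equal(n_meas(p), 139L)
  expect_equal(sum(p$b == 0), 1L)
  expect_true(all(p$b <= 3 & (p$b == 0 | p$b >= 0.1)))
  expect_true(all(p$b_delta %in% c(1, 0, -0.5)))
  f <- p$omega_cent / (2 * pi)
  expect_true(all(f >= 6.6 - 1e-9 & f <= 21 + 1e-9))
  expect_true(all(p$te >= 0.04 & p$te <= 0.15))
  expect_true(all(p$tr >= 0.62 & p$tr <= 7.6))
  expect_identical(make_protocol(139, seed = 4), make_protocol(139, seed = 4))
})

test_that("Rician noise has the magnitude-signal properties", {
  s <- c(0.2, 0.5, 1)
  # no noise draw -> identity is recovered in the infinite-SNR limit
  set.seed(61)
  expect_equal(add_rician_noise(s, 1e9), s, tolerance = 1e-6)
  set.seed(62)
  noisy <- add_rician_noise(rep(0.5, 1e4), 30)
  expect_true(all(noisy >= 0))
  # Rayleigh mean for zero signal: (1/SNR) * sqrt(pi/2)
  set.seed(63)
  zero <- add_rician_noise(rep(0, 1e5), 30)
  expect_equal(mean(zero), sqrt(pi / 2) / 30, tolerance = 0.01)
  # mean absolute deviation shrinks as SNR grows
  set.seed(64)
  mad_lo <- mean(abs(add_rician_noise(rep(0.5, 1e4), 30) - 0.5))
  mad_hi <- mean(abs(add_rician_noise(rep(0.5, 1e4), 130) - 0.5))
  expect_lt(mad_hi, mad_lo)
  expect_error(add_rician_noise(s, 0), "positive")
})

test_that("phantom biasing matches the requested relative spread", {
  ph <- default_phantom()
  expect_identical(bias_phantom(ph, 0), ph)
  set.seed(65)
  draws <- replicate(1e4, bias_phantom(ph, 0.2)$components[2, "d_par"])
  expect_equal(sd(draws / 2.5), 0.2, tolerance = 0.05 * 0.2 + 0.01)
  set.seed(66)
  for (i in 1:20)
    expect_silent(validate_components(bias_phantom(ph, 0.5)$components,
                                      default_bounds()))
  # weights stay a simplex
  set.seed(67)
  bp <- bias_phantom(ph, 0.4)
  expect_equal(sum(bp$weights), 1)
  expect_true(all(bp$weights > 0))
})

test_that("training sets carry per-signal SNR provenance", {
  p <- tiny_protocol()
  ph <- default_phantom()
  set.seed(68)
  tr <- generate_training_set(ph, 0.2, c(130, 90, 60, 30), 50, p)
  expect_equal(dim(tr), c(200L, n_meas(p)))
  expect_equal(unname(table(attr(tr, "snr"))[c("130", "90", "60", "30")]),
               rep(50L, 4), ignore_attr = TRUE)
  # degenerate limit: zero bias and effectively infinite SNR
  set.seed(69)
  tr0 <- generate_training_set(ph, 0, 1e9, 5, p)
  s_gt <- phantom_signal(p, ph)
  for (i in 1:5) expect_equal(tr0[i, ], s_gt, tolerance = 1e-5)
})

test_that("EMD is an exact optimal transport cost", {
  ph <- default_phantom()
  gt <- as_voxel_distribution(ph)
  expect_equal(emd(gt, gt), 0)
  # two unit point masses: cost is the ground distance
  c1 <- components(1, 1, 0, 0, 1, 100, 100, 1, 10)
  c2 <- components(2.5, 0.3, 0, 0, 2, 400, 800, 1.5, 22)
  d <- sqrt(sum((component_embedding(c1) - component_embedding(c2))^2))
  expect_equal(emd(as_dist(c1, 1), as_dist(c2, 1)), d, tolerance = 1e-10)
  # 3 vs 3 atoms against the brute-force LP oracle
  set.seed(70)
  for (rep in 1:5) {
    ca <- sample_components(count = 3)
    cb <- sample_components(count = 3)
    wa <- runif(3); wb <- runif(3)
    da <- as_dist(ca, wa); db <- as_dist(cb, wb)
    ea <- component_embedding(ca); eb <- component_embedding(cb)
    cost <- sqrt(pmax(outer(rowSums(ea^2), rowSums(eb^2), "+") -
                        2 * ea %*% t(eb), 0))
    expect_equal(emd(da, db),
                 emd_lp_oracle(wa / sum(wa), wb / sum(wb), cost),
                 tolerance = 1e-8)
  }
  # distributions on a line: matches the CDF-difference integral
  r2a <- c(2, 8, 25); r2b <- c(4, 15)
  line_a <- components(1, 1, 0, 0, 1, 100, 100, 1, r2a)
  line_b <- components(1, 1, 0, 0, 1, 100, 100, 1, r2b)
  wa <- c(0.2, 0.5, 0.3); wb <- c(0.6, 0.4)
  xa <- component_embedding(line_a)[, "r2"]
  xb <- component_embedding(line_b)[, "r2"]
  expect_equal(emd(as_dist(line_a, wa), as_dist(line_b, wb)),
               emd_1d_oracle(xa, wa, xb, wb), tolerance = 1e-10)
  # symmetry and triangle inequality on random triples
  set.seed(71)
  for (rep in 1:5) {
    ds <- lapply(1:3, function(i) as_dist(sample_components(count = 4), runif(4)))
    expect_equal(emd(ds[[1]], ds[[2]]), emd(ds[[2]], ds[[1]]), tolerance = 1e-10)
    expect_lte(emd(ds[[1]], ds[[3]]),
               emd(ds[[1]], ds[[2]]) + emd(ds[[2]], ds[[3]]) + 1e-10)
  }
  # strictly positive for disjoint supports
  expect_gt(emd(as_dist(c1, 1), as_dist(c2, 1)), 0)
  expect_error(emd(gt, structure(list(components = NULL, weights = numeric(0)),
                                 class = "voxel_distribution")), "non-empty")
})

test_that("similarity and NRMSE behave as reconstruction metrics", {
  s <- c(0.1, 0.5, 0.9, 0.3)
  expect_equal(signal_similarity(s, s), 1)
  expect_equal(nrmse(s, s), 0)
  expect_equal(signal_similarity(2 * s, s), 1)
  expect_gt(nrmse(2 * s, s), 0)
  set.seed(72)
  a <- runif(20); b <- runif(20)
  expect_equal(nrmse(a, b),
               sqrt(sum((a - b)^2)) / (sqrt(20) * (max(b) - min(b))),
               tolerance = 1e-12)
  expect_error(nrmse(a, rep(1, 20)), "zero-range")
})

test_that("similarity counts use thresholds or training percentiles", {
  sims <- rbind(rep(1, 5), c(1, 1, 0.9, 0.9, 0.9))
  counts <- similarity_count_maps(sims, thresholds = c(0.999, 0.997))
  expect_equal(counts$high_count, c(5, 2))
  expect_equal(counts$low_count, c(0, 3))
  expect_true(all(counts$high_count <= ncol(sims)))
  # percentile-derived thresholds reproduce the quantiles of the sample
  set.seed(73)
  train <- runif(1000, 0.9, 1)
  counts2 <- similarity_count_maps(sims, training_similarities = train)
  expect_equal(counts2$thresholds,
               unname(quantile(train, c(0.8, 0.2))))
  expect_error(similarity_count_maps(sims), "thresholds")
})

test_that("ICC and CVws recover known variance structure", {
  # identical sessions with distinct subjects: perfect reliability
  x <- cbind(1:10, 1:10)
  expect_equal(icc(x), 1)
  expect_equal(cvws(x), 0)
  # location invariance
  set.seed(74)
  y <- cbind(rnorm(50), rnorm(50))
  expect_equal(icc(y + 100), icc(y), tolerance = 1e-12)
  # known variance components: between = 3, within = 1 -> ICC ~ 0.75
  set.seed(75)
  subj <- rnorm(200, 0, sqrt(3))
  sess <- cbind(subj + rnorm(200), subj + rnorm(200))
  expect_equal(icc(sess), 0.75, tolerance = 0.05)
  z <- abs(sess) + 5
  expect_equal(cvws(z), sqrt(mean(apply(z, 1, var))) / mean(z),
               tolerance = 1e-12)
  expect_error(icc(cbind(1:2, 1:2)), "subjects")
  expect_error(cvws(cbind(c(-1, 1), c(1, -1))), "zero grand mean")
})
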