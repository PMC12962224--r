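# Forward model: Lorentzian dispersion, scalar projections, b-tensor
# encoding, kernels, and signal synthesis.

test_that("Lorentzian dispersion matches its closed form and limits", {
  expect_equal(lorentzian_diffusivity(2.5, 2, 200, 0), 2.5)
  # omega = gamma sits halfway between the two plateaus
  expect_equal(lorentzian_diffusivity(2.5, 2, 200, 200), 2.25, tolerance = 1e-12)
  # flat spectrum when both plateaus coincide (free water)
  expect_equal(lorentzian_diffusivity(3, 3, 123, 456), 3)
  # monotone between d_zero and d_inf, approaching d_inf
  om <- seq(0, 1e5, length.out = 50)
  lam <- lorentzian_diffusivity(0.5, 2, 250, om)
  expect_true(all(diff(lam) > 0))
  expect_true(all(lam >= 0.5 & lam <= 2))
  expect_equal(lorentzian_diffusivity(0.5, 2, 250, 1e9), 2, tolerance = 1e-6)
  expect_error(lorentzian_diffusivity(1, 2, -1, 0), "gamma")
})

test_that("diffusion scalars reproduce the ground-truth component values", {
  ph <- default_phantom()
  sc0 <- diffusion_scalars(ph$components, 0)
  expect_equal(sc0$d_iso, c(0.5, 0.9, 0.9, 3.0))
  expect_equal(sc0$d_delta_sq[1], 0)
  expect_equal(sc0$d_delta_sq[2], ((2.5 - 0.1) / 2.7)^2, tolerance = 1e-12)
  # symmetric components have zero anisotropy at every frequency
  iso <- components(1.2, 1.2, 0.3, 0.4, 2, 300, 300, 1, 10)
  for (om in c(0, 50, 5000))
    expect_equal(diffusion_scalars(iso, om)$d_delta_sq, 0)
  # d_delta_sq bounded in [0, 1]
  set.seed(7)
  comps <- sample_components(count = 200)
  sc <- diffusion_scalars(comps, 2 * pi * 10)
  expect_true(all(sc$d_delta_sq >= 0 & sc$d_delta_sq <= 1))
})

test_that("encoding attenuation exponent matches hand-derived cases", {
  ph <- default_phantom()
  compII <- ph$components[2, , drop = FALSE]
  # spherical encoding at b = 1 gives b * Diso (omega = 0)
  p_sph <- protocol(b = c(0, 1), b_delta = 0, theta_enc = 0, phi_enc = 0,
                    omega_cent = 0, te = 0.05, tr = 5)
  ex <- encoding_attenuation_exponent(p_sph, compII)
  expect_equal(ex[1, 1], 0)
  expect_equal(ex[2, 1], 0.9, tolerance = 1e-10)
  # linear encoding parallel to the symmetry axis gives b * lambda_par
  p_lin <- protocol(b = c(0, 1), b_delta = 1,
                    theta_enc = unname(compII[, "theta"]), phi_enc = unname(compII[, "phi"]),
                    omega_cent = 0, te = 0.05, tr = 5)
  expect_equal(encoding_attenuation_exponent(p_lin, compII)[2, 1], 2.5,
               tolerance = 1e-10)
  # invariant under simultaneous rotation of encoding and component axes
  set.seed(3)
  comp <- sample_components(count = 1)
  p1 <- protocol(b = c(0, 2), b_delta = 1, theta_enc = 0.7, phi_enc = 1.1,
                 omega_cent = 60, te = 0.05, tr = 5)
  ang <- 0.9  # rotate both about z by the same azimuth
  comp2 <- comp; comp2[, "phi"] <- (comp2[, "phi"] + ang) %% (2 * pi)
  p2 <- protocol(b = c(0, 2), b_delta = 1, theta_enc = 0.7,
                 phi_enc = 1.1 + ang, omega_cent = 60, te = 0.05, tr = 5)
  expect_equal(encoding_attenuation_exponent(p1, comp)[2, 1],
               encoding_attenuation_exponent(p2, comp2)[2, 1],
               tolerance = 1e-12)
  # nonnegative for every shape including planar
  p_all <- tiny_protocol()
  set.seed(4)
  expect_true(all(encoding_attenuation_exponent(p_all,
                                                sample_components(count = 30)) >= 0))
})

test_that("kernel values combine diffusion and relaxation attenuation", {
  comp <- components(1, 1, 0, 0, 1, 100, 100, 1, 13)
  # all attenuation factors -> 1 in the b=0 / long-TR / short-TE limit
  p_lim <- protocol(b = 0, b_delta = 0, theta_enc = 0, phi_enc = 0,
                    omega_cent = 0, te = 1e-9, tr = 1e6)
  expect_equal(kernel_value(p_lim, comp), 1, tolerance = 1e-6)
  # hand-derived relaxation-only kernel
  p0 <- protocol(b = 0, b_delta = 0, theta_enc = 0, phi_enc = 0,
                 omega_cent = 0, te = 0.04, tr = 7.6)
  expect_equal(kernel_value(p0, comp), (1 - exp(-7.6)) * exp(-0.52),
               tolerance = 1e-10)
  # monotone: longer TE decays, longer TR recovers, larger b decays
  p_te <- protocol(b = c(0, 0), b_delta = 0, theta_enc = 0, phi_enc = 0,
                   omega_cent = 0, te = c(0.05, 0.10), tr = 5)
  kv <- kernel_value(p_te, comp)
  expect_lt(kv[2], kv[1])
  p_b <- protocol(b = c(0, 1, 2), b_delta = 0, theta_enc = 0, phi_enc = 0,
                  omega_cent = 0, te = 0.05, tr = 5)
  expect_true(all(diff(kernel_value(p_b, comp)) < 0))
  # kernel entries always in (0, 1]
  set.seed(5)
  K <- kernel_matrix(tiny_protocol(), sample_components(count = 40))
  expect_true(all(K > 0 & K <= 1))
})

test_that("kernel matrix composes kernel values and free water decays as exp(-3b)", {
  ph <- default_phantom()
  p <- protocol(b = c(0, 0.5, 1, 2), b_delta = 0, theta_enc = 0, phi_enc = 0,
                omega_cent = 0, te = 0.04, tr = 7.6)
  K <- kernel_matrix(p, ph$components)
  expect_equal(dim(K), c(4L, 4L))
  # column of the isotropic free-water component: exp(-3b) times relaxation
  relax <- (1 - exp(-7.6 * 0.3)) * exp(-0.04 * 6)
  expect_equal(K[, 4], exp(-3 * c(0, 0.5, 1, 2)) * relax, tolerance = 1e-10)
  # permuting components permutes columns
  perm <- c(3, 1, 4, 2)
  expect_equal(kernel_matrix(p, ph$components[perm, ]), K[, perm])
  expect_error(kernel_matrix(p, ph$components[0, , drop = FALSE]), "empty")
})

test_that("signal synthesis is linear with nonnegative weights", {
  p <- tiny_protocol()
  ph <- default_phantom()
  s <- synthesize_signal(p, ph$components, ph$weights)
  expect_length(s, n_meas(p))
  expect_true(all(s > 0))
  # zero weights give zero signal; unit basis picks one column
  expect_equal(synthesize_signal(p, ph$components, rep(0, 4)), rep(0, n_meas(p)))
  K <- kernel_matrix(p, ph$components)
  expect_equal(synthesize_signal(p, ph$components, c(0, 1, 0, 0)), K[, 2])
  # linearity
  w1 <- c(0.3, 0, 0.2, 0.1); w2 <- c(0.05, 0.25, 0, 0.1)
  expect_equal(synthesize_signal(p, ph$components, w1 + w2),
               synthesize_signal(p, ph$components, w1) +
                 synthesize_signal(p, ph$components, w2),
               tolerance = 1e-12)
  expect_error(synthesize_signal(p, ph$components, c(-0.1, 0.4, 0.4, 0.3)),
               "nonnegative")
  expect_error(synthesize_signal(p, ph$components, c(1, 1)), "length")
})
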