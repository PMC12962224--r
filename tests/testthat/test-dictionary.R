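# Informed dictionary: clustering, construction identities, cosine matching,
# and the pure dictionary-matching (DM) inversion.

test_that("clustering returns actual members, one per well-separated group", {
  p <- tiny_protocol()
  cA <- components(0.5, 0.5, 0, 0, 2, 250, 250, 1, 13)
  cB <- components(3, 3, 0, 0, 3, 1e4, 1e4, 0.3, 6)
  set.seed(41)
  sigs <- rbind(
    t(sapply(1:5, function(i) synthesize_signal(p, cA, 1) * runif(1, 0.8, 1.2)
             + rnorm(n_meas(p), 0, 1e-4))),
    t(sapply(1:5, function(i) synthesize_signal(p, cB, 1) * runif(1, 0.8, 1.2)
             + rnorm(n_meas(p), 0, 1e-4))))
  reps <- cluster_training_signals(sigs, 2, seed = 1)
  idx <- attr(reps, "indices")
  # representatives are rows of the input
  expect_equal(reps[1, ], sigs[idx[1], ])
  expect_equal(reps[2, ], sigs[idx[2], ])
  # they fall in different groups, matching the exhaustive 2-partition
  truth <- best_two_partition(sigs)
  expect_true(truth[idx[1]] != truth[idx[2]])
  # n_reps = V keeps every signal
  all_reps <- cluster_training_signals(sigs, nrow(sigs), seed = 1)
  expect_equal(all_reps, sigs, ignore_attr = TRUE)
  expect_error(cluster_training_signals(sigs, 11), "exceed")
})

test_that("dictionary entries satisfy the synthesis identity", {
  p <- tiny_protocol()
  ph <- default_phantom()
  set.seed(42)
  training <- generate_training_set(ph, 0.2, c(130, 30), 4, p)
  plan <- draw_bootstrap_plan(n_meas(p), 3, seed = 5)
  dict <- build_dictionary(training, p, plan, mc_config(nb = 3, np = 8, nm = 4, seed = 2),
                           n_reps = 4, seed = 6)
  expect_s3_class(dict, "informed_dictionary")
  expect_length(dict$entries, 3L)
  for (b in 1:3) {
    slice <- dict$entries[[b]]
    expect_lte(nrow(slice$signals), 4L)
    for (i in seq_along(slice$params)) {
      syn <- slice$kernels[[i]] %*% slice$weights[[i]]
      expect_equal(as.numeric(syn), slice$signals[i, ], tolerance = 1e-10)
    }
  }
  # deterministic rebuild
  dict2 <- build_dictionary(training, p, plan, mc_config(nb = 3, np = 8, nm = 4, seed = 2),
                            n_reps = 4, seed = 6)
  expect_identical(dict$entries, dict2$entries)
  expect_error(build_dictionary(training[0, ], p, plan, mc_config(nb = 3)), "empty")
})

test_that("cosine similarity is scale invariant and bounded", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(a, b), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(cosine_similarity(a, c(0, 0, 0)), "zero-norm")
})

test_that("matching is an exact exhaustive argmax with lowest-index ties", {
  set.seed(43)
  E <- matrix(rnorm(100 * 12), 100, 12)
  E <- E / sqrt(rowSums(E^2))
  slice <- list(unit_resampled = E)
  q <- rnorm(12)
  m <- match_dictionary(q, slice)
  sims <- as.numeric(E %*% (q / sqrt(sum(q^2))))  # independent loop-free oracle
  expect_equal(m$index, which.max(sims))
  expect_equal(m$similarity, max(sims))
  # query present in the dictionary matches itself with similarity 1
  slice2 <- list(unit_resampled = rbind(E, q / sqrt(sum(q^2))))
  expect_equal(match_dictionary(q, slice2)$similarity, 1, tolerance = 1e-12)
  # duplicated best entry resolves to the lower index
  dup <- rbind(E[3, ], E)
  expect_equal(match_dictionary(E[3, ], list(unit_resampled = dup))$index, 1L)
  # invariance to positive rescaling of the query
  expect_equal(match_dictionary(5 * q, slice)$index, m$index)
})

test_that("DM inversion projects onto matched kernels and enforces plan identity", {
  p <- tiny_protocol()
  ph <- default_phantom()
  set.seed(44)
  training <- generate_training_set(ph, 0.2, c(130, 30), 4, p)
  plan <- draw_bootstrap_plan(n_meas(p), 3, seed = 5)
  cfg <- mc_config(nb = 3, np = 8, nm = 4, seed = 2)
  dict <- build_dictionary(training, p, plan, cfg, n_reps = 4, seed = 6)
  # closure: querying an entry's own signal reproduces a near-zero residual
  entry_sig <- dict$entries[[1]]$signals[2, ]
  sols <- dm_invert_voxel(entry_sig, p, plan, dict)
  expect_length(sols, 3L)
  expect_lt(sols[[1]]$residual_norm, 1e-8)
  for (sol in sols) expect_true(all(sol$weights >= 0))
  # residual equals the NNLS optimum within the matched kernel subspace
  b <- 2
  sol <- sols[[b]]
  slice <- dict$entries[[b]]
  m <- match_dictionary(entry_sig[plan[b, ]], slice)
  ref <- nnls_fit(slice$kernels[[m$index]][plan[b, ], , drop = FALSE],
                  entry_sig[plan[b, ]])
  expect_equal(sol$residual_norm, ref$residual, tolerance = 1e-10)
  # plan mismatch is refused
  other_plan <- draw_bootstrap_plan(n_meas(p), 3, seed = 99)
  expect_error(dm_invert_voxel(entry_sig, p, other_plan, dict), "plan")
  # protocol mismatch is refused
  p2 <- make_protocol(n_meas(p), seed = 999)
  expect_error(dm_invert_voxel(entry_sig, p2, plan, dict), "protocol")
})
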