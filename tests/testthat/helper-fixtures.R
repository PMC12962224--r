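# Shared fixtures and independent oracles. Everything is generated in code;
# the oracles deliberately avoid the package's own computational paths.

# small fast protocol for unit tests (same structure as the default, fewer
# rows)
tiny_protocol <- function(n = 33L, seed = 101L) make_protocol(n, seed = seed)

# ground-truth phantom signal on a protocol
phantom_signal <- function(p, ph = default_phantom()) {
  synthesize_signal(p, ph$components, ph$weights)
}

# brute-force NNLS oracle: best objective over an exhaustive coarse lattice
# of nonnegative weights (N <= 4)
nnls_lattice_oracle <- function(K, s, wmax, step) {
  grid <- seq(0, wmax, by = step)
  W <- as.matrix(expand.grid(rep(list(grid), ncol(K))))
  fits <- K %*% t(W)                       # M x n_lattice
  sqrt(min(colSums((s - fits)^2)))
}

# brute-force transportation LP oracle: enumerate all candidate bases
# (subsets of n_a*n_b cells of size n_a+n_b-1), solve the flow equations,
# keep feasible vertices, return the minimum cost
emd_lp_oracle <- function(a, b, cost) {
  na <- length(a); nb <- length(b)
  cells <- expand.grid(i = seq_len(na), j = seq_len(nb))
  ncell <- nrow(cells)
  nbasic <- na + nb - 1L
  # constraint matrix: row sums and column sums (last column constraint
  # dropped as redundant)
  A <- matrix(0, na + nb - 1L, ncell)
  for (k in seq_len(ncell)) {
    A[cells$i[k], k] <- 1
    if (cells$j[k] < nb) A[na + cells$j[k], k] <- 1
  }
  rhs <- c(a, b[-nb])
  best <- Inf
  combos <- utils::combn(ncell, nbasic)
  for (c_idx in seq_len(ncol(combos))) {
    S <- combos[, c_idx]
    As <- A[, S, drop = FALSE]
    if (abs(det(As)) < 1e-12) next
    f <- solve(As, rhs)
    if (any(f < -1e-9)) next
    cst <- sum(f * cost[cbind(cells$i[S], cells$j[S])])
    if (cst < best) best <- cst
  }
  best
}

# closed-form EMD for distributions supported on a line: integral of the
# absolute difference of the two CDFs along the line coordinate
emd_1d_oracle <- function(x_a, w_a, x_b, w_b) {
  xs <- sort(unique(c(x_a, x_b)))
  cdf <- function(x, w, t) sum(w[x <= t + 1e-15]) / sum(w)
  total <- 0
  for (k in seq_len(length(xs) - 1L)) {
    gap <- xs[k + 1L] - xs[k]
    total <- total + gap * abs(cdf(x_a, w_a, xs[k]) - cdf(x_b, w_b, xs[k]))
  }
  total
}

# wrap a component matrix + weights as a voxel distribution
as_dist <- function(comps, weights) {
  structure(list(components = comps, weights = weights / sum(weights)),
            class = "voxel_distribution")
}

# exhaustive best 2-partition (minimum within-cluster sum of squares on
# unit-normalized signals) for a small signal matrix
best_two_partition <- function(signals) {
  u <- signals / sqrt(rowSums(signals^2))
  V <- nrow(u)
  best <- NULL; best_ss <- Inf
  for (code in 1:(2^(V - 1) - 1)) {
    grp <- c(0L, as.integer(intToBits(code)[1:(V - 1)])) # first point in group 0
    ss <- 0
    for (g in 0:1) {
      rows <- u[grp == g, , drop = FALSE]
      if (nrow(rows) == 0) { ss <- Inf; break }
      ctr <- colMeans(rows)
      ss <- ss + sum((t(rows) - ctr)^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- grp }
  }
  best
}
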