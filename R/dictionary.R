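# Informed dictionary: per-bootstrap triplets of synthesized signals (SbD),
# kernel sets (KbD) and parameter sets (PbD) obtained by MC-inverting
# bootstrap-resampled representatives of a training signal set. Dictionary
# matching (DM) inverts a query by cosine-similarity lookup followed by NNLS
# projection onto the matched kernels.

#' Cluster training signals to representatives
#'
#' Reduces a training set to `n_reps` representative signals: k-means on the
#' unit-normalized signals, with each centroid snapped to its nearest actual
#' member (representatives are always rows of the input). Deterministic
#' given `seed`.
#'
#' @param signals V x M matrix of training signals (rows = voxels).
#' @param n_reps Number of representatives (`1 <= n_reps <= V`).
#' @param seed Integer seed.
#' @return `n_reps` x M matrix of representative signals with attribute
#'   `indices` (their row numbers in `signals`).
#' @export
cluster_training_signals <- function(signals, n_reps, seed = 1L) {
  signals <- as.matrix(signals)
  V <- nrow(signals)
  if (n_reps > V) stop("n_reps must not exceed the number of training signals")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (n_reps == V) {
    attr(signals, "indices") <- seq_len(V)
    return(signals)
  }
  norms <- sqrt(rowSums(signals^2))
  norms[norms == 0] <- 1
  u <- signals / norms

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  dup <- duplicated(round(u, 12))
  if (sum(!dup) <= n_reps) {
    # fewer distinct patterns than representatives: keep the distinct ones
    # and pad with the most common pattern
    idx <- which(!dup)
    idx <- c(idx, rep(idx[1], n_reps - length(idx)))[seq_len(n_reps)]
  } else {
    km <- kmeans(u, centers = n_reps, nstart = 5, iter.max = 100)
    # snap each centroid to the nearest distinct member
    idx <- integer(n_reps)
    taken <- rep(FALSE, V)
    for (k in seq_len(n_reps)) {
      d2 <- colSums((t(u) - km$centers[k, ])^2)
      ord <- order(d2)
      j <- ord[which(!taken[ord])[1]]
      idx[k] <- j
      taken[j] <- TRUE
    }
  }
  reps <- signals[idx, , drop = FALSE]
  attr(reps, "indices") <- idx
  reps
}

#' Build an informed dictionary
#'
#' For every bootstrap row of the plan and every clustered representative:
#' MC-invert the plan-resampled representative signal (proliferation +
#' mutation with `mc_cfg`), store the resulting parameter sets, full-protocol
#' kernel matrix and NNLS weights, and synthesize the entry signal as
#' `kernels %*% weights`. Matching against the dictionary later uses the same
#' plan, so unit-normalized plan-resampled entry signals are precomputed per
#' bootstrap. Deterministic given `seed`.
#'
#' @param training_signals V x M matrix of training signals.
#' @param p Protocol.
#' @param plan Bootstrap plan shared with the inversion
#'   ([draw_bootstrap_plan()]).
#' @param mc_cfg [mc_config()] used for the per-entry MC inversions.
#' @param n_reps Number of clustered representatives (default 256).
#' @param seed Integer seed.
#' @return Object of class `informed_dictionary`.
#' @export
build_dictionary <- function(training_signals, p, plan, mc_cfg = mc_config(),
                             n_reps = 256L, seed = 1L) {
  training_signals <- as.matrix(training_signals)
  if (nrow(training_signals) == 0L) stop("empty training set")
  if (ncol(training_signals) != n_meas(p))
    stop("training signal length must match the protocol")
  reps <- cluster_training_signals(training_signals, n_reps, seed = seed)
  nb <- nrow(plan)
  M <- n_meas(p)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  entry_seeds <- matrix(sample.int(.Machine$integer.max, nb * n_reps),
                        nrow = nb)

  entries <- vector("list", nb)
  for (b in seq_len(nb)) {
    params <- vector("list", n_reps)
    weights <- vector("list", n_reps)
    kernels <- vector("list", n_reps)
    sig <- matrix(0, nrow = n_reps, ncol = M)
    for (i in seq_len(n_reps)) {
      cfg <- mc_cfg
      cfg$seed <- entry_seeds[b, i]
      set.seed(cfg$seed)
      sol <- proliferate(reps[i, ], p, plan[b, ], cfg)
      sol <- mutate_mc(sol, reps[i, ], p, plan[b, ], cfg)
      if (is_empty_solution(sol)) next
      params[[i]] <- sol$components
      weights[[i]] <- sol$weights
      K <- kernel_matrix(p, sol$components)
      kernels[[i]] <- K
      sig[i, ] <- as.numeric(K %*% sol$weights)
    }
    ok <- which(!vapply(params, is.null, logical(1)))
    if (length(ok) == 0L)
      stop("dictionary construction produced no usable entries for bootstrap ", b)
    res <- sig[ok, plan[b, ], drop = FALSE]
    rn <- sqrt(rowSums(res^2))
    entries[[b]] <- list(params = params[ok], weights = weights[ok],
                         kernels = kernels[ok],
                         signals = sig[ok, , drop = FALSE],
                         unit_resampled = res / rn)
  }
  structure(list(version = 1L,
                 protocol_hash = protocol_hash(p),
                 plan = plan,
                 plan_seed = attr(plan, "seed"),
                 n_reps = as.integer(n_reps),
                 seed = as.integer(seed),
                 entries = entries),
            class = "informed_dictionary")
}

#' @export
print.informed_dictionary <- function(x, ...) {
  cat(sprintf("<informed_dictionary: %d bootstraps x %d entries, plan seed %s>\n",
              length(x$entries), x$n_reps, x$plan_seed))
  invisible(x)
}

#' Cosine similarity between two signal vectors
#'
#' `a . b / (||a|| ||b||)`; invariant to positive rescaling of either input.
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero-norm vectors")
  sum(a * b) / (na * nb)
}

#' Match a signal against a dictionary slice
#'
#' Exhaustive exact search: returns the entry with the largest cosine
#' similarity to the query (ties resolve to the lowest index).
#'
#' @param signal Nonzero query vector (already bootstrap-resampled).
#' @param slice One element of `dictionary$entries` (a per-bootstrap slice),
#'   or any list with a row-unit-normalized matrix `unit_resampled`.
#' @return List with `index` and `similarity`.
#' @export
match_dictionary <- function(signal, slice) {
  if (is.null(slice$unit_resampled) || nrow(slice$unit_resampled) == 0L)
    stop("empty dictionary slice")
  ns <- sqrt(sum(signal^2))
  if (ns == 0) stop("cannot match a zero signal")
  sims <- as.numeric(slice$unit_resampled %*% (signal / ns))
  j <- which.max(sims)
  list(index = j, similarity = sims[j])
}

check_dictionary_compat <- function(dictionary, p, plan) {
  if (!inherits(dictionary, "informed_dictionary"))
    stop("not an informed_dictionary")
  if (!identical(dictionary$protocol_hash, protocol_hash(p)))
    stop("dictionary was built under a different protocol")
  dp <- dictionary$plan
  if (!identical(dim(dp), dim(plan)) || !all(dp == plan))
    stop("bootstrap plan does not match the dictionary plan")
  invisible(TRUE)
}

# One bootstrap of the DM inversion: resample, match, NNLS-project.
dm_project <- function(signal, p, plan_row, dictionary, b) {
  s_b <- signal[plan_row]
  if (all(s_b == 0)) return(new_solution(kernel_evals = 1L))
  slice <- dictionary$entries[[b]]
  m <- match_dictionary(s_b, slice)
  K <- slice$kernels[[m$index]]
  comps <- slice$params[[m$index]]
  fit <- nnls_fit(K[plan_row, , drop = FALSE], s_b)
  keep <- which(fit$weights > 0)
  if (length(keep) == 0L)
    return(new_solution(kernel_evals = 1L, match_index = m$index,
                        match_similarity = m$similarity))
  w <- fit$weights[keep]
  Kk <- K[, keep, drop = FALSE]
  new_solution(comps[keep, , drop = FALSE], w, fit$residual,
               as.numeric(Kk[plan_row, , drop = FALSE] %*% w),
               kernel_evals = 1L, match_index = m$index,
               match_similarity = m$similarity)
}

#' Dictionary-matching (DM) inversion of one voxel
#'
#' Per bootstrap row: resample the signal by the shared plan, match against
#' that bootstrap's dictionary entries by cosine similarity, and
#' NNLS-project onto the matched kernel set. No mutation. Deterministic
#' (no randomness beyond the stored plan).
#'
#' @param signal Signal vector (length M).
#' @param p Protocol.
#' @param plan Bootstrap plan; must be identical to the dictionary plan.
#' @param dictionary An `informed_dictionary`.
#' @return List of `idmc_solution`, one per bootstrap row.
#' @export
dm_invert_voxel <- function(signal, p, plan, dictionary) {
  check_dictionary_compat(dictionary, p, plan)
  lapply(seq_len(nrow(plan)), function(b)
    dm_project(signal, p, plan[b, ], dictionary, b))
}

#' Save / load an informed dictionary
#'
#' The dictionary is stored as an R-native hierarchical binary container
#' (RDS) carrying the plan, its seed, the protocol hash and a version field;
#' [idmc_invert_voxel()] and [dm_invert_voxel()] refuse dictionaries built
#' under a different protocol or plan.
#'
#' @param dictionary An `informed_dictionary`.
#' @param path File path.
#' @return `save_dictionary`: `path`, invisibly. `load_dictionary`: the
#'   dictionary.
#' @export
save_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "informed_dictionary"))
  saveRDS(dictionary, path)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  d <- readRDS(path)
  if (!inherits(d, "informed_dictionary")) stop("not a dictionary file")
  d
}
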