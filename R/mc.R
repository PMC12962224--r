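# Baseline Monte Carlo inversion: per-bootstrap stochastic proliferation
# (global candidate sampling + NNLS pruning) followed by mutation (local
# Gaussian refinement of the retained set). The entire inversion is a pure
# function of (signal, protocol, bootstrap plan, config): all randomness is
# derived from the config seed.

#' Monte Carlo inversion configuration
#'
#' @param np Proliferation rounds (default 20).
#' @param nm Mutation rounds (default 20).
#' @param nc Maximum retained components per bootstrap (default 10).
#' @param nb Bootstrap rounds (default 100).
#' @param batch Candidate components sampled per proliferation round
#'   (default 20).
#' @param mut_reps Perturbed replicate sets generated per mutation round
#'   (default 20, mirroring the proliferation batch).
#' @param bounds Parameter bounds (see [default_bounds()]).
#' @param sigma_scheme Per-field mutation scales (see
#'   [default_sigma_scheme()]).
#' @param sigma_ladder Per-replicate multipliers of the mutation scheme,
#'   cycled across the replicate sets of each round so every round mixes
#'   coarse and fine exploration radii (default `c(0.5, 1, 2, 4)`).
#' @param seed Integer seed from which all bootstrap-level RNG streams
#'   derive.
#' @return List of class `mc_config`.
#' @export
mc_config <- function(np = 20L, nm = 20L, nc = 10L, nb = 100L, batch = 20L,
                      mut_reps = 20L, bounds = default_bounds(),
                      sigma_scheme = default_sigma_scheme(),
                      sigma_ladder = c(0.5, 1, 2, 4), seed = 1L) {
  if (any(c(np, nm, nc, nb, batch, mut_reps) < 1L))
    stop("all mc_config counts must be >= 1")
  validate_bounds(bounds)
  structure(list(np = as.integer(np), nm = as.integer(nm),
                 nc = as.integer(nc), nb = as.integer(nb),
                 batch = as.integer(batch), mut_reps = as.integer(mut_reps),
                 bounds = bounds, sigma_scheme = sigma_scheme,
                 sigma_ladder = sigma_ladder, seed = as.integer(seed)),
            class = "mc_config")
}

#' Draw a bootstrap resampling plan
#'
#' `nb` index vectors of length `M`, drawn uniformly with replacement;
#' deterministic given `seed`. The same plan is shared between dictionary
#' construction and inversion so that matched entries and query signals see
#' identical resampling.
#'
#' @param M Number of measurements.
#' @param nb Number of bootstrap rounds.
#' @param seed Integer seed.
#' @return `nb` x `M` integer matrix of 1-based indices with attribute
#'   `seed`.
#' @export
draw_bootstrap_plan <- function(M, nb, seed = 1L) {
  if (M < 1L || nb < 1L) stop("M and nb must be >= 1")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  plan <- matrix(sample.int(M, nb * M, replace = TRUE), nrow = nb)
  attr(plan, "seed") <- as.integer(seed)
  plan
}

# save/restore the global RNG so seeded entry points do not clobber the
# caller's stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Proliferation: global stochastic candidate search
#'
#' Runs `np` rounds of {sample a batch of candidate components; merge with
#' the retained set; NNLS on the bootstrap-resampled measurements; drop
#' zero-weight components; cap at `nc` by largest weight}. A round is
#' accepted only if it does not increase the fit residual, so the residual
#' is non-increasing across rounds. Uses the current RNG state.
#'
#' @param signal Full signal vector (length M).
#' @param p Protocol.
#' @param plan_row Integer resampling indices for this bootstrap (length M).
#' @param config An [mc_config()].
#' @return An `idmc_solution`; empty for an all-zero signal.
#' @export
proliferate <- function(signal, p, plan_row, config) {
  if (length(signal) != n_meas(p))
    stop("signal length must match the protocol")
  if (all(signal == 0)) return(new_solution(kernel_evals = 0L))
  s_b <- signal[plan_row]

  cur <- list(components = NULL, weights = numeric(0), kernels = NULL,
              residual = Inf, fitted = rep(0, length(s_b)))
  evals <- 0L
  for (round in seq_len(config$np)) {
    cand <- sample_components(config$bounds, config$batch)
    evals <- evals + config$batch
    K_cand <- kernel_matrix(p, cand)
    comps <- rbind(cur$components, cand)
    K <- cbind(cur$kernels, K_cand)
    n_cur <- if (is.null(cur$components)) 0L else nrow(cur$components)
    trial <- fit_prune_cap(comps, K, s_b, plan_row, config$nc,
                           init_cols = seq_len(n_cur))
    if (trial$residual <= cur$residual && !is.null(trial$components))
      cur <- trial
  }
  new_solution(cur$components, cur$weights, cur$residual, cur$fitted,
               kernel_evals = evals)
}

#' Mutation: local stochastic refinement of a retained set
#'
#' Runs `nm` rounds of {generate `mut_reps` perturbed copies of the retained
#' components ([perturb_components()]); NNLS over the original plus perturbed
#' kernels on the resampled measurements; keep nonzero weights; cap at `nc`}.
#' Rounds that would increase the residual are rejected, so the residual is
#' non-increasing. Uses the current RNG state.
#'
#' @param solution Non-empty `idmc_solution` from [proliferate()].
#' @param signal Full signal vector.
#' @param p Protocol.
#' @param plan_row Bootstrap resampling indices.
#' @param config An [mc_config()].
#' @return Refined `idmc_solution` (kernel-evaluation counter accumulated).
#' @export
mutate_mc <- function(solution, signal, p, plan_row, config) {
  if (is_empty_solution(solution)) return(solution)
  s_b <- signal[plan_row]
  cur <- list(components = solution$components, weights = solution$weights,
              kernels = kernel_matrix(p, solution$components),
              residual = solution$residual_norm, fitted = solution$fitted_signal)
  evals <- solution$kernel_evals
  for (round in seq_len(config$nm)) {
    pert_all <- perturb_stacked(cur$components, config$sigma_scheme,
                                config$mut_reps, config$bounds,
                                config$sigma_ladder)
    evals <- evals + config$mut_reps
    K <- cbind(cur$kernels, kernel_matrix(p, pert_all))
    comps <- rbind(cur$components, pert_all)
    trial <- fit_prune_cap(comps, K, s_b, plan_row, config$nc,
                           init_cols = seq_len(nrow(cur$components)))
    if (trial$residual <= cur$residual && !is.null(trial$components))
      cur <- trial
  }
  new_solution(cur$components, cur$weights, cur$residual, cur$fitted,
               kernel_evals = evals)
}

#' Monte Carlo inversion of one voxel
#'
#' For each bootstrap row of the plan: proliferation followed by mutation.
#' Deterministic given `config$seed` (per-bootstrap RNG substreams are drawn
#' from it), and restores the caller's RNG state on exit.
#'
#' @param signal Signal vector (length M).
#' @param p Protocol.
#' @param plan Bootstrap plan from [draw_bootstrap_plan()]; its row count
#'   caps the number of bootstraps at `config$nb`.
#' @param config An [mc_config()].
#' @return List of `idmc_solution`, one per bootstrap row.
#' @export
mc_invert_voxel <- function(signal, p, plan, config = mc_config()) {
  nb <- min(nrow(plan), config$nb)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max, nb)
  lapply(seq_len(nb), function(b) {
    set.seed(sub_seeds[b])
    sol <- proliferate(signal, p, plan[b, ], config)
    mutate_mc(sol, signal, p, plan[b, ], config)
  })
}
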