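# Informed dictionary-guided MC (ID-MC) refinement: starting from the
# matched-and-projected dictionary solution, a small number of mutation
# rounds locally perturb the retained parameter sets, expand the kernel set
# with the perturbed candidates, and refit the weights by NNLS.

#' Default per-field mutation scales
#'
#' Diffusivities, transition frequencies and relaxation rates are perturbed
#' multiplicatively (log-normal, `value * exp(sigma * z)` with `z ~ N(0,1)`),
#' which respects positivity across the order-of-magnitude parameter ranges;
#' angles are perturbed additively in radians. Default sigma 0.1 for every
#' field. All perturbed values are clipped to the parameter bounds.
#'
#' @return Named numeric vector over [component_fields()].
#' @export
default_sigma_scheme <- function() {
  setNames(rep(0.1, 9L), component_fields())
}

#' ID-MC inversion configuration
#'
#' @param nm Mutation rounds; `nm = 0` reduces ID-MC to pure dictionary
#'   matching (DM). Default 1.
#' @param r Perturbed replicate sets per mutation round (default 200).
#' @param nc Component cap (default 10).
#' @param sigma_scheme Per-field perturbation scales
#'   ([default_sigma_scheme()]).
#' @param sigma_ladder Per-replicate multipliers of the scheme, cycled over
#'   the replicate sets of a round (default `c(0.5, 1, 2, 4)`).
#' @param bounds Parameter bounds.
#' @param seed Integer seed for the per-bootstrap mutation streams.
#' @return List of class `idmc_config`.
#' @export
idmc_config <- function(nm = 1L, r = 200L, nc = 10L,
                        sigma_scheme = default_sigma_scheme(),
                        sigma_ladder = c(0.5, 1, 2, 4),
                        bounds = default_bounds(), seed = 1L) {
  if (nm < 0L) stop("nm must be >= 0")
  if (r < 1L) stop("r must be >= 1")
  validate_bounds(bounds)
  structure(list(nm = as.integer(nm), r = as.integer(r), nc = as.integer(nc),
                 sigma_scheme = sigma_scheme, sigma_ladder = sigma_ladder,
                 bounds = bounds, seed = as.integer(seed)),
            class = "idmc_config")
}

#' Perturb a component set
#'
#' Generates `R` perturbed copies of a component set by independent
#' zero-mean Gaussian offsets per field: multiplicative in log-space for the
#' positive fields, additive for the angles (see [default_sigma_scheme()]).
#' Results are clipped to `bounds`; the original set is untouched. Uses the
#' current RNG state.
#'
#' @param comps Component matrix (n x 9).
#' @param sigma_scheme Named per-field scales.
#' @param R Number of perturbed replicate sets.
#' @param bounds Parameter bounds.
#' @param scales Optional per-replicate multipliers of the whole scheme
#'   (recycled to length `R`); used by the mutation steps to mix exploration
#'   radii within one round. Default 1.
#' @return List of `R` component matrices, each n x 9 and within `bounds`.
#' @export
perturb_components <- function(comps, sigma_scheme = default_sigma_scheme(),
                               R = 200L, bounds = default_bounds(),
                               scales = 1) {
  stacked <- perturb_stacked(comps, sigma_scheme, R, bounds, scales)
  n <- nrow(comps)
  lapply(seq_len(R), function(r)
    stacked[((r - 1L) * n + 1L):(r * n), , drop = FALSE])
}

# all R replicates stacked into one (R*n) x 9 matrix (fast path used by the
# mutation loops)
perturb_stacked <- function(comps, sigma_scheme, R, bounds, scales = 1) {
  if (is.null(dim(comps)) || nrow(comps) == 0L)
    stop("perturb_components needs a non-empty component set")
  n <- nrow(comps)
  total <- R * n
  scale_rows <- rep(rep_len(scales, R), each = n)
  out <- comps[rep(seq_len(n), R), , drop = FALSE]
  mult_fields <- c("d_par", "d_perp", "d0", "gamma_par", "gamma_perp",
                   "r1", "r2")
  for (f in mult_fields)
    out[, f] <- out[, f] *
      exp(rnorm(total, 0, 1) * (sigma_scheme[[f]] * scale_rows))
  for (f in c("theta", "phi"))
    out[, f] <- out[, f] + rnorm(total, 0, 1) * (sigma_scheme[[f]] * scale_rows)
  clip_components(out, bounds)
}

#' Expand a matched kernel set with perturbed candidates
#'
#' Columns are the matched solution's kernels followed by the kernels of all
#' perturbed component sets; the roster maps every column back to its
#' component.
#'
#' @param p Protocol.
#' @param matched Non-empty `idmc_solution` (the matched/projected entry).
#' @param perturbed List of perturbed component matrices
#'   (from [perturb_components()]); may be empty.
#' @return List with `kernels` (M x (n * (1 + R)) matrix) and `roster`
#'   (component matrix whose rows parallel the kernel columns).
#' @export
expand_kernels <- function(p, matched, perturbed = list()) {
  if (is_empty_solution(matched)) stop("matched solution is empty")
  roster <- matched$components
  if (length(perturbed))
    roster <- rbind(roster, do.call(rbind, perturbed))
  list(kernels = kernel_matrix(p, roster), roster = roster)
}

#' ID-MC local mutation refinement
#'
#' `nm` iterations of {perturb the retained set; expand the kernel set;
#' NNLS on the bootstrap-resampled measurements; keep nonzero weights; cap
#' at `nc` by weight and refit}. The matched kernels are part of the first
#' expanded set, so the refined residual never exceeds the matched (DM)
#' residual; rounds that would increase the residual are rejected.
#' `nm = 0` returns the matched solution unchanged. Uses the current RNG
#' state.
#'
#' @param signal Full signal vector.
#' @param p Protocol.
#' @param plan_row Bootstrap resampling indices.
#' @param matched Non-empty `idmc_solution` from the projection step.
#' @param config An [idmc_config()].
#' @return Refined `idmc_solution`.
#' @export
idmc_refine <- function(signal, p, plan_row, matched, config = idmc_config()) {
  if (is_empty_solution(matched)) stop("matched solution is empty")
  if (config$nm == 0L) return(matched)
  s_b <- signal[plan_row]
  cur <- list(components = matched$components, weights = matched$weights,
              kernels = kernel_matrix(p, matched$components),
              residual = matched$residual_norm,
              fitted = matched$fitted_signal)
  evals <- matched$kernel_evals
  for (round in seq_len(config$nm)) {
    pert_all <- perturb_stacked(cur$components, config$sigma_scheme,
                                config$r, config$bounds, config$sigma_ladder)
    evals <- evals + config$r
    ek <- list(kernels = cbind(cur$kernels, kernel_matrix(p, pert_all)),
               roster = rbind(cur$components, pert_all))
    trial <- fit_prune_cap(ek$roster, ek$kernels, s_b, plan_row, config$nc,
                           init_cols = seq_len(nrow(cur$components)))
    if (trial$residual <= cur$residual && !is.null(trial$components))
      cur <- trial
  }
  new_solution(cur$components, cur$weights, cur$residual, cur$fitted,
               kernel_evals = evals,
               match_index = matched$match_index,
               match_similarity = matched$match_similarity)
}

#' ID-MC inversion of one voxel
#'
#' Per bootstrap row: match the resampled signal against the informed
#' dictionary, project onto the matched kernels by NNLS, then refine by
#' local mutation ([idmc_refine()]). Deterministic given `config$seed`;
#' requires the plan to be the one the dictionary was built with.
#'
#' @param signal Signal vector (length M).
#' @param p Protocol.
#' @param plan Bootstrap plan (must match `dictionary$plan`).
#' @param dictionary An `informed_dictionary` (see [build_dictionary()]).
#' @param config An [idmc_config()].
#' @return List of `idmc_solution`, one per bootstrap row.
#' @export
idmc_invert_voxel <- function(signal, p, plan, dictionary,
                              config = idmc_config()) {
  check_dictionary_compat(dictionary, p, plan)
  nb <- nrow(plan)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max, nb)
  lapply(seq_len(nb), function(b) {
    matched <- dm_project(signal, p, plan[b, ], dictionary, b)
    if (is_empty_solution(matched)) return(matched)
    set.seed(sub_seeds[b])
    idmc_refine(signal, p, plan[b, ], matched, config)
  })
}
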