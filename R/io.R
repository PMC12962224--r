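# Volume I/O and run provenance: 4D NIfTI signal volumes in, 3D descriptor
# maps out, plus self-describing output directories (seed + config hash +
# package version).

#' Read a 4D signal volume into a voxel-by-measurement matrix
#'
#' @param path 4D NIfTI file (x, y, z, M) or an object coercible by
#'   `RNifti::asNifti`.
#' @param mask Optional logical 3D array or 3D NIfTI mask (nonzero = keep);
#'   default keeps every voxel.
#' @param p Optional protocol; when given, the 4th dimension must equal
#'   `n_meas(p)`.
#' @return List with `signals` (V x M matrix), `mask` (logical array), and
#'   `reference` (the image, for writing maps back with the input geometry).
#' @export
read_signals <- function(path, mask = NULL, p = NULL) {
  img <- RNifti::asNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D volume (x, y, z, measurements)")
  M <- dim(arr)[4]
  if (!is.null(p) && M != n_meas(p))
    stop("volume has ", M, " measurements but the protocol has ", n_meas(p))
  if (is.null(mask)) {
    mask <- array(TRUE, dim = dim(arr)[1:3])
  } else {
    mask <- as.array(RNifti::asNifti(mask)) != 0
    # a trailing singleton dimension may be dropped on a NIfTI round trip
    dm <- dim(mask)
    if (length(dm) < 3L) dim(mask) <- c(dm, rep(1L, 3L - length(dm)))
    if (!identical(dim(mask), dim(arr)[1:3]))
      stop("mask dimensions do not match the volume")
  }
  flat <- matrix(arr, ncol = M)   # voxels in raster (column-major) order
  list(signals = flat[which(mask), , drop = FALSE],
       mask = mask, reference = img)
}

#' Write descriptor maps as NIfTI volumes
#'
#' One 3D NIfTI per map, named `<name>.nii.gz`, carrying the reference
#' image's geometry when supplied.
#'
#' @param maps Named list of 3D arrays (see [voxel_maps()]).
#' @param out_dir Output directory (created if needed).
#' @param reference Optional reference NIfTI for the affine/geometry.
#' @return Character vector of written paths, invisibly.
#' @export
write_maps <- function(maps, out_dir, reference = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(maps), function(nm) {
    f <- file.path(out_dir, paste0(nm, ".nii.gz"))
    img <- if (is.null(reference)) RNifti::asNifti(maps[[nm]])
           else RNifti::asNifti(maps[[nm]], reference = reference)
    RNifti::writeNifti(img, f)
    f
  }, character(1))
  invisible(paths)
}

#' Write per-voxel solutions and provenance
#'
#' Solutions are serialized to an R-native binary container
#' (`solutions.rds`), the pooled components of each voxel to
#' `components.csv`, and a provenance record (seed, config hash, package
#' version) to `provenance.json` so the output directory is
#' self-describing.
#'
#' @param solutions List over voxels of per-bootstrap solution lists.
#' @param out_dir Output directory.
#' @param seed The seed the run used.
#' @param config The inversion config (hashed into the provenance record).
#' @return `out_dir`, invisibly.
#' @export
write_solutions <- function(solutions, out_dir, seed, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(solutions, file.path(out_dir, "solutions.rds"))
  pooled <- do.call(rbind, lapply(seq_along(solutions), function(v) {
    d <- aggregate_solutions(solutions[[v]])
    if (is_empty_distribution(d)) return(NULL)
    data.frame(voxel = v, d$components, weight = d$weights)
  }))
  if (!is.null(pooled))
    write.csv(pooled, file.path(out_dir, "components.csv"), row.names = FALSE)
  prov <- list(seed = seed,
               config_hash = config_hash(config),
               package = "idmc",
               version = as.character(utils::packageVersion("idmc")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Read back a solutions container
#' @param out_dir Directory written by [write_solutions()].
#' @return The per-voxel solution lists.
#' @export
read_solutions <- function(out_dir) {
  readRDS(file.path(out_dir, "solutions.rds"))
}

config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  v <- unlist(config, use.names = TRUE)
  v <- v[vapply(v, is.numeric, logical(1))]
  paste0("c", format(sum(as.numeric(v) * seq_along(v)) %% 1e9, digits = 12))
}

#' Per-voxel RNG seed derivation
#'
#' Derives a voxel-specific seed from the global seed and the voxel's raster
#' index, so serial and parallel voxel traversals produce identical
#' results.
#'
#' @param global_seed Integer run seed.
#' @param voxel_index 1-based raster index of the voxel.
#' @return Integer seed below 2^31.
#' @export
voxel_seed <- function(global_seed, voxel_index) {
  as.integer((as.numeric(global_seed) * 48271 + voxel_index * 16807) %%
               2147483647)
}

#' Invert every voxel of a masked volume
#'
#' Raster-order traversal of the masked voxels with per-voxel RNG streams
#' derived by [voxel_seed()], so results are independent of traversal order.
#'
#' @param signals V x M signal matrix (rows aligned to `which(mask)`).
#' @param p Protocol.
#' @param plan Bootstrap plan.
#' @param method `"mc"`, `"dm"` or `"idmc"`.
#' @param mc_cfg,idmc_cfg,dictionary Passed to [invert_voxel()].
#' @param seed Global run seed.
#' @return List over voxels of per-bootstrap solution lists.
#' @export
invert_volume <- function(signals, p, plan, method = c("mc", "dm", "idmc"),
                          mc_cfg = mc_config(), idmc_cfg = idmc_config(),
                          dictionary = NULL, seed = 1L) {
  method <- match.arg(method)
  lapply(seq_len(nrow(signals)), function(v) {
    vc_mc <- mc_cfg; vc_mc$seed <- voxel_seed(seed, v)
    vc_id <- idmc_cfg; vc_id$seed <- voxel_seed(seed, v)
    invert_voxel(signals[v, ], p, plan, method,
                 mc_cfg = vc_mc, idmc_cfg = vc_id, dictionary = dictionary)
  })
}
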