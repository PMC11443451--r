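#' Study configuration
#'
#' One object collecting everything a run needs: the phantom cohort
#' specification, the distance binning, the laminar scheme, vessel
#' segmentation settings and the stochastic statistics options. Every random
#' procedure draws from a named sub-seed derived deterministically from the
#' single master `seed`, so a run is replayable from its provenance record.
#'
#' @param phantom a [phantom_spec()].
#' @param bin_edges strictly increasing distance bin edges in mm, first 0.
#' @param min_voxels_per_bin minimum voxels per cell for a defined value.
#' @param n_depths number of cortical depth bins (the compartment scheme is
#'   defined for 21).
#' @param depth_mode `"equivolume"` or `"equidistant"` laminar coordinate.
#' @param vessel_scales_mm Hessian vesselness filter scales in mm.
#' @param otsu_bins histogram bins for the 3-class Otsu threshold search.
#' @param B_perm Monte-Carlo permutations for permutation Welch tests.
#' @param B_boot bootstrap resamples for effect-size confidence intervals.
#' @param m_imputations completed datasets for monotone multiple imputation.
#' @param seed master seed.
#' @param save_volumes write per-subject NIfTI volumes during [run_study()].
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(phantom = phantom_spec(),
                         bin_edges = c(0, 2, 4, 6, 8, 10),
                         min_voxels_per_bin = 4L,
                         n_depths = 21L,
                         depth_mode = c("equivolume", "equidistant"),
                         vessel_scales_mm = c(0.5, 1.0),
                         otsu_bins = 256L,
                         B_perm = 100000L,
                         B_boot = 2000L,
                         m_imputations = 5L,
                         seed = 1L,
                         save_volumes = FALSE) {
  depth_mode <- match.arg(depth_mode)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing")
  if (bin_edges[1] != 0) stop("first bin edge must be 0")
  if (min_voxels_per_bin < 1L) stop("min_voxels_per_bin must be >= 1")
  if (n_depths != 21L)
    stop("the compartment scheme is defined for 21 depths")
  seed <- as.integer(seed)
  cfg <- list(phantom = phantom, bin_edges = bin_edges,
              min_voxels_per_bin = as.integer(min_voxels_per_bin),
              n_depths = as.integer(n_depths), depth_mode = depth_mode,
              vessel_scales_mm = vessel_scales_mm,
              otsu_bins = as.integer(otsu_bins),
              B_perm = as.integer(B_perm), B_boot = as.integer(B_boot),
              m_imputations = as.integer(m_imputations), seed = seed,
              save_volumes = isTRUE(save_volumes),
              seeds = derive_seeds(seed))
  class(cfg) <- "study_config"
  cfg
}

#' Derive named sub-seeds from a master seed
#'
#' Deterministic (seed, name) mapping so that independent stochastic stages
#' (cohort generation, permutation, bootstrap, imputation) never share a
#' random stream. All sub-seeds stay below 2^31.
#'
#' @param seed integer master seed.
#' @return Named integer vector.
#' @export
derive_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("cohort", "permutation", "bootstrap", "imputation")
  s
}

#' Read a study configuration from YAML
#'
#' Unknown keys are fatal; the `phantom:` sub-map is forwarded to
#' [phantom_spec()]. Missing keys take the package defaults.
#'
#' @param path YAML file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(study_config)), "phantom")
  bad <- setdiff(names(y), c(known, "phantom"))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- y[intersect(names(y), known)]
  if (!is.null(y$phantom)) {
    pk <- names(formals(phantom_spec))
    badp <- setdiff(names(y$phantom), pk)
    if (length(badp)) stop("unknown phantom keys: ", paste(badp, collapse = ", "))
    args$phantom <- do.call(phantom_spec, y$phantom)
  }
  do.call(study_config, args)
}
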