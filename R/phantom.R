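#' Phantom cohort specification
#'
#' Parameters of the synthetic two-group cohort: a folded cortical ribbon
#' (sinusoidal outer surface, inner surface offset by the cortical thickness
#' along the normal) pierced by near-vertical tubular veins, with qT1 (ms) and
#' QSM (ppm) fields carrying an areal baseline, a laminar depth gradient,
#' per-group linear and quadratic vein-distance effects, a group offset,
#' between-subject intercepts and voxel noise. Effect defaults are calibrated
#' to the cell means and SEMs of the source study's qT1 and pQSM tables
#' (young/old distance slopes -13.5/+1.6 ms per mm; pQSM U-shape curvature
#' 1.3e-4 ppm per mm^2; subject SDs chosen so simulated cell SEMs land in the
#' printed 11-24 ms and 3e-4 - 1.2e-3 ppm ranges).
#'
#' Distance effects are centred at 5 mm and depth effects at mid-depth, so
#' ANOVA main and interaction effects map one-to-one onto generator
#' parameters.
#'
#' @param n_young,n_old cohort sizes (defaults 18 and 17).
#' @param grid_shape voxels per axis.
#' @param spacing mm per voxel edge (scalar or length 3).
#' @param fold_amplitude,fold_wavelength outer-surface sinusoid (mm).
#' @param thickness cortical thickness (mm); must be >= 4 x spacing.
#' @param outer_level mean height of the outer surface (mm); default centres
#'   the ribbon in the grid.
#' @param n_areas coronal-split area count (2 emulates M1/S1).
#' @param n_veins,vein_radius,vein_min_sep,vein_tilt_sd,vein_margin vein
#'   count, radius (mm, >= spacing), minimum pairwise axis separation (mm),
#'   SD of the axis tilt components, and in-plane placement margin (mm).
#' @param qt1_baseline per-area qT1 at mid-depth / 5 mm (ms), recycled.
#' @param qt1_depth_slope qT1 change from superficial to deep (ms per unit
#'   depth fraction).
#' @param qt1_dist_slope_young,qt1_dist_slope_old qT1 change per mm of vein
#'   distance; their difference is the programmed age x distance interaction.
#' @param qt1_dist_curv quadratic distance term (ms per mm^2).
#' @param qt1_group_offset additive old-group offset (ms).
#' @param qt1_subject_sd,qt1_voxel_sd between-subject and voxel noise SD (ms).
#' @param qt1_wm,qt1_csf,qt1_vein background values outside the ribbon (ms).
#' @param qsm_p_pos per-voxel probability of a positive susceptibility sign.
#' @param qsm_baseline per-area positive-QSM magnitude at centre (ppm).
#' @param qsm_depth_slope,qsm_group_offset,qsm_dist_slope_young,
#'   qsm_dist_slope_old,qsm_dist_curv analogous QSM effect parameters (ppm).
#' @param qsm_subject_sd,qsm_voxel_sd QSM noise SDs (ppm).
#' @param qsm_floor minimum magnitude a signed QSM draw is clamped to (ppm).
#' @param vein_qsm susceptibility of vein voxels (ppm); veins are bright on
#'   QSM, which is what the vesselness filter detects.
#' @param risk_prevalence vascular-risk probability in the old group (9/17).
#' @param seed master seed for cohort generation.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(n_young = 18L, n_old = 17L,
                         grid_shape = c(96L, 96L, 64L),
                         spacing = c(0.5, 0.5, 0.5),
                         fold_amplitude = 3, fold_wavelength = 24,
                         thickness = 3, outer_level = NULL,
                         n_areas = 2L,
                         n_veins = 6L, vein_radius = 1.0, vein_min_sep = 10,
                         vein_tilt_sd = 0.05, vein_margin = 4,
                         qt1_baseline = c(1692, 1736),
                         qt1_depth_slope = -650,
                         qt1_dist_slope_young = -13.5,
                         qt1_dist_slope_old = 1.6,
                         qt1_dist_curv = 0,
                         qt1_group_offset = -24,
                         qt1_subject_sd = 55, qt1_voxel_sd = 80,
                         qt1_wm = 1250, qt1_csf = 2900, qt1_vein = 1600,
                         qsm_p_pos = 0.6,
                         qsm_baseline = c(0.0130, 0.0102),
                         qsm_depth_slope = -0.0074,
                         qsm_group_offset = 0.0047,
                         qsm_dist_slope_young = 0,
                         qsm_dist_slope_old = 0,
                         qsm_dist_curv = 1.3e-4,
                         qsm_subject_sd = 0.0019, qsm_voxel_sd = 0.004,
                         qsm_floor = 1e-4, vein_qsm = 0.3,
                         risk_prevalence = 9 / 17,
                         seed = 42L) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spec <- as.list(environment())
  spec$grid_shape <- as.integer(grid_shape)
  spec$n_areas <- as.integer(n_areas)
  spec$qt1_baseline <- rep_len(qt1_baseline, spec$n_areas)
  spec$qsm_baseline <- rep_len(qsm_baseline, spec$n_areas)
  if (is.null(outer_level))
    spec$outer_level <- (grid_shape[3] * spacing[3] + thickness) / 2
  num <- vapply(spec[!vapply(spec, is.null, TRUE)],
                function(x) all(is.finite(unlist(x))), TRUE)
  if (!all(num)) stop("non-finite phantom parameter: ",
                      paste(names(num)[!num], collapse = ", "))
  if (thickness < 4 * max(spacing))
    stop("cortical thickness must be >= 4 x spacing to resolve 21 depths")
  if (vein_radius < max(spacing))
    stop("vein radius must be >= spacing to survive voxelization")
  sds <- c(qt1_subject_sd, qt1_voxel_sd, qsm_subject_sd, qsm_voxel_sd,
           vein_tilt_sd)
  if (any(sds < 0)) stop("all sd parameters must be >= 0")
  if (n_veins < 0L) stop("vein count must be >= 0")
  if (risk_prevalence < 0 || risk_prevalence > 1)
    stop("risk_prevalence must be in [0, 1]")
  class(spec) <- "phantom_spec"
  spec
}

#' Build the folded ribbon's signed-distance surfaces
#'
#' The outer (GM/CSF) surface is the graph `z = z0 + A sin(2 pi x / lambda)`;
#' the inner (WM/GM) surface is its parallel offset at the cortical thickness
#' along the surface normal. Signed distances are positive toward the cortex
#' interior from each boundary, so the ribbon is where both are positive.
#' Distances are computed through an exact Euclidean transform of the
#' rasterized surface shell, accurate to within one voxel diagonal of the
#' true point-to-surface distance.
#'
#' @param spec a [phantom_spec()].
#' @return List with `inner` and `outer` signed-distance volumes (mm) and the
#'   surface height matrix as attribute `"surface_height"`.
#' @export
make_surfaces <- function(spec) {
  d <- spec$grid_shape
  s <- spec$spacing
  ext <- d * s
  cx <- (seq_len(d[1]) - 0.5) * s[1]
  cz <- (seq_len(d[3]) - 0.5) * s[3]
  f <- spec$outer_level +
    spec$fold_amplitude * sin(2 * pi * cx / spec$fold_wavelength)
  if (max(f) + 2 * s[3] > ext[3] ||
      min(f) - spec$thickness - 2 * s[3] < 0)
    stop("ribbon exits grid: enlarge the z extent or lower the amplitude")

  # two-sided exact EDT against the voxelized surface: distance from each
  # voxel center to the nearest center on the other side of the surface,
  # minus half a voxel (the surface runs between the two center sheets)
  zoff <- outer(rep(f, times = d[2]), cz, function(fz, z) z - fz) # (nx*ny) x nz
  below <- array(zoff < 0, dim = d)
  d_up <- .edt3d_cpp(as.logical(!below), d, s)   # below-voxels: to above side
  d_dn <- .edt3d_cpp(as.logical(below), d, s)
  h <- s[3] / 2
  s_out <- ifelse(below, pmax(d_up - h, h / 4), -pmax(d_dn - h, h / 4))
  s_in <- spec$thickness - s_out
  out <- list(inner = as_volume(array(s_in, d), s),
              outer = as_volume(array(s_out, d), s))
  attr(out, "surface_height") <- f
  out
}

.grid_xy <- function(spec) {
  d <- spec$grid_shape
  s <- spec$spacing
  list(x = (seq_len(d[1]) - 0.5) * s[1], y = (seq_len(d[2]) - 0.5) * s[2],
       z = (seq_len(d[3]) - 0.5) * s[3])
}

#' Carve tubular veins through the slab
#'
#' Places `n_veins` near-vertical cylinder axes (unit direction jittered by
#' `vein_tilt_sd`) by rejection sampling under the minimum pairwise
#' separation, measured between the in-plane base points. A voxel belongs to
#' the mask iff its center lies within the vein radius of an axis. Axes run
#' the full grid height, so every vein pierces both surfaces.
#'
#' @param spec a [phantom_spec()].
#' @return List with `mask` (binary volume), `axis_distance` (mm to the
#'   nearest axis, the analytic truth), and the `axes` matrix
#'   (x0, y0, dx, dy, dz per row). Uses the current RNG state.
#' @export
carve_veins <- function(spec) {
  if (spec$n_veins < 1L)
    stop("no veins segmented: phantom vein count must be >= 1")
  d <- spec$grid_shape
  s <- spec$spacing
  ext <- d * s
  m <- spec$vein_margin
  if (2 * m >= min(ext[1:2]))
    stop("vein_margin too large for the grid extent")
  pts <- matrix(NA_real_, 0, 2)
  draws <- 0L
  while (nrow(pts) < spec$n_veins) {
    if (draws >= 1000L)
      stop("could not place ", spec$n_veins, " veins with separation ",
           spec$vein_min_sep, " mm after 1000 draws (achieved ", nrow(pts), ")")
    cand <- c(stats::runif(1, m, ext[1] - m), stats::runif(1, m, ext[2] - m))
    draws <- draws + 1L
    if (nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - cand)^2))) >= spec$vein_min_sep)
      pts <- rbind(pts, cand)
  }
  dirs <- cbind(matrix(stats::rnorm(2 * spec$n_veins, 0, spec$vein_tilt_sd),
                       ncol = 2), 1)
  dirs <- dirs / sqrt(rowSums(dirs^2))

  g <- .grid_xy(spec)
  X <- array(rep(g$x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(g$y, each = d[1]), times = d[3]), d)
  Z <- array(rep(g$z, each = d[1] * d[2]), d)
  zmid <- ext[3] / 2
  axis_dist <- array(Inf, d)
  for (v in seq_len(spec$n_veins)) {
    vx <- X - pts[v, 1]; vy <- Y - pts[v, 2]; vz <- Z - zmid
    proj <- vx * dirs[v, 1] + vy * dirs[v, 2] + vz * dirs[v, 3]
    d2 <- pmax(vx^2 + vy^2 + vz^2 - proj^2, 0)
    axis_dist <- pmin(axis_dist, sqrt(d2))
  }
  list(mask = as_volume(array(axis_dist <= spec$vein_radius, d), s),
       axis_distance = as_volume(axis_dist, s),
       axes = cbind(pts, dirs))
}

#' Synthesize qT1 and QSM metric volumes for one subject
#'
#' Cortex voxels follow the additive effect model (distance centred at 5 mm,
#' depth at 0.5); QSM signs are a per-voxel Bernoulli mixture so that both
#' positive and negative QSM extraction are exercised, with the negative
#' branch mirroring the positive magnitude model. Vein voxels are bright on
#' QSM; WM/CSF backgrounds carry constant qT1 with voxel noise.
#'
#' @param spec a [phantom_spec()].
#' @param group `"young"` or `"old"`.
#' @param surfaces output of [make_surfaces()].
#' @param veins output of [carve_veins()].
#' @param area_labels integer label volume.
#' @param effects subject random intercepts, as drawn by [generate_subject()].
#' @return List with `qt1`, `qsm`, `depth_truth` and `dist_truth` volumes.
#' @export
synthesize_metric_field <- function(spec, group, surfaces, veins, area_labels,
                                    effects) {
  d <- spec$grid_shape
  s_out <- surfaces$outer$data
  s_in <- surfaces$inner$data
  cortex <- s_out > 0 & s_in > 0
  delta <- pmin(pmax(s_out / spec$thickness, 0), 1)
  dist_truth <- pmax(veins$axis_distance$data - spec$vein_radius, 0)
  Dc <- pmin(pmax(dist_truth, 0), 10) - 5
  old <- group == "old"
  area <- area_labels$data
  vein <- veins$mask$data > 0

  n <- sum(cortex)
  qt1 <- array(NA_real_, d)
  qt1[s_in <= 0] <- spec$qt1_wm
  qt1[s_out <= 0] <- spec$qt1_csf
  slope <- if (old) spec$qt1_dist_slope_old else spec$qt1_dist_slope_young
  qt1[cortex] <- spec$qt1_baseline[area[cortex]] +
    spec$qt1_depth_slope * (delta[cortex] - 0.5) +
    slope * Dc[cortex] + spec$qt1_dist_curv * Dc[cortex]^2 +
    (if (old) spec$qt1_group_offset else 0) +
    effects$u_qt1 + stats::rnorm(n, 0, spec$qt1_voxel_sd)

  qsm <- array(stats::rnorm(prod(d), 0, spec$qsm_voxel_sd), d)
  qslope <- if (old) spec$qsm_dist_slope_old else spec$qsm_dist_slope_young
  base_mag <- spec$qsm_baseline[area[cortex]] +
    spec$qsm_depth_slope * (delta[cortex] - 0.5) +
    qslope * Dc[cortex] + spec$qsm_dist_curv * Dc[cortex]^2 +
    (if (old) spec$qsm_group_offset else 0)
  pos <- stats::rbinom(n, 1, spec$qsm_p_pos) == 1
  mag_p <- pmax(base_mag + effects$u_qsm_p +
                  stats::rnorm(n, 0, spec$qsm_voxel_sd), spec$qsm_floor)
  mag_n <- pmax(base_mag + effects$u_qsm_n +
                  stats::rnorm(n, 0, spec$qsm_voxel_sd), spec$qsm_floor)
  qsm[cortex] <- ifelse(pos, mag_p, -mag_n)

  qt1[vein] <- spec$qt1_vein + stats::rnorm(sum(vein), 0, spec$qt1_voxel_sd)
  qsm[vein] <- spec$vein_qsm +
    stats::rnorm(sum(vein), 0, spec$qsm_voxel_sd)

  depth <- array(NA_real_, d)
  depth[cortex] <- delta[cortex]
  list(qt1 = as_volume(qt1, spec$spacing),
       qsm = as_volume(qsm, spec$spacing),
       depth_truth = as_volume(depth, spec$spacing),
       dist_truth = as_volume(dist_truth, spec$spacing))
}

#' Area label volume: equal coronal slabs along x
#' @param spec a [phantom_spec()].
#' @return Integer label volume (1..n_areas everywhere; analysis restricts to
#'   the ribbon downstream).
#' @export
make_area_labels <- function(spec) {
  d <- spec$grid_shape
  lab <- pmin(ceiling(seq_len(d[1]) / (d[1] / spec$n_areas)), spec$n_areas)
  as_volume(array(rep(lab, times = d[2] * d[3]), d), spec$spacing)
}

#' Generate one subject phantom
#'
#' @param spec a [phantom_spec()].
#' @param id participant identifier.
#' @param group `"young"` or `"old"`.
#' @param risk 0/1 vascular-risk flag.
#' @param sub_seed per-subject seed (derived from the master seed by
#'   [generate_cohort()]).
#' @param surfaces shared geometry from [make_surfaces()].
#' @return A `subject_phantom` list: metric volumes, truth surfaces, vein
#'   truth, area labels, truth depth/distance, group, risk and the drawn
#'   subject effects.
#' @export
generate_subject <- function(spec, id, group, risk, sub_seed,
                             surfaces = make_surfaces(spec)) {
  set.seed(sub_seed)
  veins <- carve_veins(spec)
  effects <- list(u_qt1 = stats::rnorm(1, 0, spec$qt1_subject_sd),
                  u_qsm_p = stats::rnorm(1, 0, spec$qsm_subject_sd),
                  u_qsm_n = stats::rnorm(1, 0, spec$qsm_subject_sd))
  areas <- make_area_labels(spec)
  fields <- synthesize_metric_field(spec, group, surfaces, veins, areas,
                                    effects)
  structure(list(id = id, group = group, risk = as.integer(risk),
                 seed = sub_seed,
                 qt1 = fields$qt1, qsm = fields$qsm,
                 inner = surfaces$inner, outer = surfaces$outer,
                 vein_mask = veins$mask,
                 vein_axis_distance = veins$axis_distance,
                 area_labels = areas,
                 depth_truth = fields$depth_truth,
                 dist_truth = fields$dist_truth,
                 effects = effects),
            class = "subject_phantom")
}

#' Generate (or stream) a phantom cohort
#'
#' Derives one sub-seed per subject from the spec's master seed, assigns risk
#' flags in the old group at the configured prevalence, and builds each
#' subject on the shared geometry. With a `callback`, subjects are processed
#' one at a time and only the callback results are kept, so full-size cohorts
#' never need to reside in memory.
#'
#' @param spec a [phantom_spec()].
#' @param callback optional `function(subject)`; its results are returned in
#'   place of the subjects.
#' @return List of `subject_phantom` objects (or callback results), with the
#'   cohort manifest (id, group, risk, seed) as attribute `"manifest"`.
#' @export
generate_cohort <- function(spec, callback = NULL) {
  n <- spec$n_young + spec$n_old
  set.seed(spec$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  risk_old <- stats::rbinom(spec$n_old, 1L, spec$risk_prevalence)
  ids <- c(sprintf("Y%02d", seq_len(spec$n_young)),
           sprintf("O%02d", seq_len(spec$n_old)))
  groups <- rep(c("young", "old"), c(spec$n_young, spec$n_old))
  risk <- c(rep(0L, spec$n_young), risk_old)
  surfaces <- make_surfaces(spec)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- generate_subject(spec, ids[i], groups[i], risk[i], sub_seeds[i],
                             surfaces)
    res[[i]] <- if (is.null(callback)) subj else callback(subj)
  }
  attr(res, "manifest") <- data.frame(participant_id = ids, group = groups,
                                      risk = risk, seed = sub_seeds,
                                      stringsAsFactors = FALSE)
  res
}
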