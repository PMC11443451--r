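# Distance binning, QSM sign splitting, and the long-format condition table.

#' Bin a vein distance into a 2-mm distance condition
#'
#' Half-open bins `(prev, next]` matching the analysis convention that a
#' distance of exactly 2 mm belongs to the closer bin while 2.01 mm starts
#' the next. Distance 0 (a vein voxel) and distances beyond the last edge are
#' excluded (`NA`).
#'
#' @param d nonnegative distances in mm.
#' @param edges bin edges, default `c(0, 2, 4, 6, 8, 10)`.
#' @return Factor with labels `"0-2"` .. `"8-10"`; `NA` for excluded voxels.
#' @export
bin_distance <- function(d, edges = c(0, 2, 4, 6, 8, 10)) {
  if (any(d < 0, na.rm = TRUE))
    stop("negative vein distance: upstream invariant breached")
  cut(d, breaks = edges, labels = bin_labels(edges),
      include.lowest = FALSE, right = TRUE)
}

#' Split QSM values by sign
#'
#' @param values QSM voxel values in ppm (finite).
#' @return List with `pQSM` (values > 0) and `nQSM` (values < 0); exact zeros
#'   are discarded. Either side may be empty.
#' @export
split_qsm <- function(values) {
  if (any(!is.finite(values)))
    stop("split_qsm expects finite values (drop missing voxels first)")
  list(pQSM = values[values > 0], nQSM = values[values < 0])
}

#' Extract the per-subject condition table
#'
#' For every (area, compartment, distance bin) cell, the mean metric value
#' over in-mask, non-vein voxels, with the voxel count recorded; a cell value
#' is missing when fewer than `min_voxels` voxels contribute. qT1 is averaged
#' over all cell voxels; pQSM and nQSM are averaged over the sign-split
#' subsets with their own counts under the same minimum rule (a cell can be
#' present for qT1 but missing for nQSM).
#'
#' @param qt1,qsm metric volumes.
#' @param vdm vessel distance map volume.
#' @param compartments output of [assign_compartments()].
#' @param area_labels integer label volume.
#' @param vein_mask binary vein mask volume.
#' @param participant_id,group,risk identifiers copied into every row.
#' @param bin_edges distance bin edges (mm).
#' @param min_voxels minimum voxels per cell.
#' @param area_names optional names for the integer labels.
#' @return A condition table data.frame (see [validate_condition_table()]).
#' @export
extract_condition_values <- function(qt1, qsm, vdm, compartments, area_labels,
                                     vein_mask, participant_id, group,
                                     risk = 0L,
                                     bin_edges = c(0, 2, 4, 6, 8, 10),
                                     min_voxels = 4L,
                                     area_names = NULL) {
  for (v in list(qsm, vdm, area_labels, vein_mask))
    check_same_grid(qt1, v, "extract_condition_values")
  comp <- compartments$compartment
  keep <- !is.na(comp) & comp != "EXCLUDED" & !(vein_mask$data > 0)
  if (!any(keep)) stop("no retained cortical voxels outside veins")

  labs <- sort(unique(c(area_labels$data[keep])))
  if (is.null(area_names)) area_names <- paste0("area", labs)
  if (length(area_names) < length(labs)) stop("too few area names")
  bins <- bin_distance(vdm$data[keep], bin_edges)
  af <- factor(area_labels$data[keep], levels = labs, labels = area_names)
  cf <- factor(comp[keep], levels = .compartment_levels)
  for (nm in area_names)
    if (!any(af == nm, na.rm = TRUE)) stop("empty area mask: ", nm)
  for (nm in .compartment_levels)
    if (!any(cf == nm, na.rm = TRUE)) stop("empty compartment mask: ", nm)

  inbin <- !is.na(bins)
  key <- interaction(af, cf, bins, drop = FALSE)
  grid <- expand.grid(area = area_names,
                      compartment = .compartment_levels,
                      distance_bin = bin_labels(bin_edges),
                      stringsAsFactors = FALSE)
  grid_key <- interaction(factor(grid$area, levels = area_names),
                          factor(grid$compartment,
                                 levels = .compartment_levels),
                          factor(grid$distance_bin,
                                 levels = bin_labels(bin_edges)),
                          drop = FALSE)

  cell_stats <- function(vals, sel) {
    k <- key[sel & inbin & !is.na(vals)]
    v <- vals[sel & inbin & !is.na(vals)]
    n <- tapply(v, k, length)
    m <- tapply(v, k, mean)
    n[is.na(n)] <- 0L
    idx <- match(as.character(grid_key), names(n))
    list(n = as.integer(n[idx]), mean = as.numeric(m[idx]))
  }

  qv <- qt1$data[keep]
  sv <- qsm$data[keep]
  rows <- list()
  stats_q <- cell_stats(qv, rep(TRUE, length(qv)))
  pv <- ifelse(!is.na(sv) & sv > 0, sv, NA_real_)
  nv <- ifelse(!is.na(sv) & sv < 0, sv, NA_real_)
  stats_p <- cell_stats(pv, rep(TRUE, length(sv)))
  stats_n <- cell_stats(nv, rep(TRUE, length(sv)))

  mk <- function(metric, st) {
    val <- st$mean
    val[st$n < min_voxels] <- NA_real_
    data.frame(participant_id = participant_id, group = group,
               risk = as.integer(risk), area = grid$area,
               compartment = grid$compartment,
               distance_bin = grid$distance_bin, metric = metric,
               value = val, n_voxels = st$n, stringsAsFactors = FALSE)
  }
  out <- rbind(mk("qT1", stats_q), mk("pQSM", stats_p), mk("nQSM", stats_n))
  rownames(out) <- NULL
  out
}

#' Condition table for one subject phantom
#'
#' Convenience wrapper running either the full measurement path (vein
#' segmentation, distance transform, equi-volume depths) or the truth path
#' (the phantom's analytic vein distances and generative depth field), and
#' extracting the condition table. The truth path isolates the statistics
#' from segmentation error and is what the stats-recovery tests use.
#'
#' @param subject a `subject_phantom`.
#' @param config a [study_config()].
#' @param use `"measured"` or `"truth"`.
#' @return Condition table rows for this subject.
#' @export
subject_condition_table <- function(subject, config = study_config(),
                                    use = c("measured", "truth")) {
  use <- match.arg(use)
  ribbon <- as_volume(subject$inner$data > 0 & subject$outer$data > 0,
                      subject$inner$spacing)
  if (use == "measured") {
    seg <- segment_veins(subject$qsm, mask = ribbon,
                         scales_mm = config$vessel_scales_mm,
                         n_bins = config$otsu_bins)
    vein <- seg$mask
    if (!any(vein$data > 0)) stop("no veins segmented for ", subject$id)
    vdm <- euclidean_distance_map(vein)
    depth <- compute_depth_field(subject$inner, subject$outer,
                                 mode = config$depth_mode)
  } else {
    vein <- subject$vein_mask
    vdm <- subject$dist_truth
    depth <- subject$depth_truth
  }
  comp <- assign_compartments(depth)
  seg_info <- if (use == "measured")
    list(otsu_lower = seg$thresholds$lower,
         otsu_upper = seg$thresholds$upper,
         n_vein_voxels = sum(vein$data > 0))
  else list(n_vein_voxels = sum(vein$data > 0))
  out <- extract_condition_values(subject$qt1, subject$qsm, vdm, comp,
                           subject$area_labels, vein,
                           participant_id = subject$id,
                           group = subject$group, risk = subject$risk,
                           bin_edges = config$bin_edges,
                           min_voxels = config$min_voxels_per_bin,
                           area_names = paste0("A", seq_len(
                             config$phantom$n_areas)))
  attr(out, "segmentation") <- seg_info
  out
}
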