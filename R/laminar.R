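# Equi-volume cortical depth sampling: per-voxel depth fraction, 21 depth
# bins, four analysis compartments.

#' Equidistant depth fraction
#'
#' Baseline laminar coordinate: the Euclidean fraction
#' `d_outer / (d_outer + d_inner)`, 0 at the GM/CSF (superficial) boundary
#' and 1 at the WM/GM (deep) boundary.
#'
#' @param d_outer,d_inner unsigned distances (mm) to the outer and inner
#'   boundary; nonnegative, not both zero.
#' @return Depth fraction in \[0, 1\].
#' @export
equidistant_depth <- function(d_outer, d_inner) {
  if (any(d_outer < 0 | d_inner < 0)) stop("distances must be nonnegative")
  tot <- d_outer + d_inner
  if (any(tot == 0)) stop("degenerate voxel: both boundary distances are 0")
  d_outer / tot
}

#' Equi-volume model: volume fraction to Euclidean fraction
#'
#' In a wedge whose local cross-sectional area interpolates linearly from
#' `A_o` at the outer boundary to `A_i` at the inner boundary, the Euclidean
#' position `rho` (from the outer boundary) enclosing the volume fraction
#' `alpha` is
#' `rho = (-A_i + sqrt(alpha A_o^2 + (1 - alpha) A_i^2)) / (A_o - A_i)`,
#' continuously extended to `rho = alpha` when `A_o = A_i` (flat cortex).
#' Monotone increasing bijection of \[0, 1\] for fixed valid areas.
#'
#' Both `rho` and `alpha` are measured from the boundary whose local area is
#' `A_i` (the convention of the equi-volume literature, where the wedge's
#' cross-section grows linearly from `A_i` at `rho = 0` to `A_o` at
#' `rho = 1`); [compute_depth_field()] converts to the superficial-origin
#' depth convention.
#'
#' @param alpha volume fraction in \[0, 1\].
#' @param A_i,A_o inner and outer local areas (> 0).
#' @return Euclidean fraction in \[0, 1\].
#' @export
equivolume_fraction <- function(alpha, A_i, A_o) {
  if (any(!is.finite(A_i)) || any(!is.finite(A_o)) ||
      any(A_i <= 0) || any(A_o <= 0))
    stop("local areas must be finite and positive")
  if (any(alpha < -1e-12 | alpha > 1 + 1e-12)) stop("alpha must be in [0, 1]")
  n <- max(length(alpha), length(A_i), length(A_o))
  alpha <- pmin(pmax(rep_len(alpha, n), 0), 1)
  A_i <- rep_len(A_i, n); A_o <- rep_len(A_o, n)
  flat <- abs(A_o - A_i) < 1e-12 * pmax(A_o, A_i)
  out <- alpha
  out[!flat] <- (sqrt(alpha[!flat] * A_o[!flat]^2 +
                        (1 - alpha[!flat]) * A_i[!flat]^2) - A_i[!flat]) /
    (A_o[!flat] - A_i[!flat])
  pmin(pmax(out, 0), 1)
}

#' Inverse equi-volume model: Euclidean fraction to volume fraction
#'
#' Closed-form inverse of [equivolume_fraction()] (the defining relation is
#' quadratic in the square root), used as the per-voxel equi-volume depth:
#' `alpha = ((rho (A_o - A_i) + A_i)^2 - A_i^2) / (A_o^2 - A_i^2)`.
#'
#' @param rho Euclidean fraction in \[0, 1\].
#' @param A_i,A_o local areas (> 0).
#' @return Volume fraction in \[0, 1\].
#' @export
equivolume_alpha <- function(rho, A_i, A_o) {
  if (any(A_i <= 0) || any(A_o <= 0)) stop("local areas must be positive")
  n <- max(length(rho), length(A_i), length(A_o))
  rho <- rep_len(rho, n); A_i <- rep_len(A_i, n); A_o <- rep_len(A_o, n)
  flat <- abs(A_o - A_i) < 1e-12 * pmax(A_o, A_i)
  out <- rho
  r <- rho[!flat] * (A_o[!flat] - A_i[!flat]) + A_i[!flat]
  out[!flat] <- (r^2 - A_i[!flat]^2) / (A_o[!flat]^2 - A_i[!flat]^2)
  pmin(pmax(out, 0), 1)
}

# Mean-curvature field of the outer boundary's level sets: sum of principal
# curvatures kappa = -div(grad s_out / |grad s_out|), positive where the
# outer surface is convex toward CSF (gyral crown, outer area > inner).
.level_set_curvature <- function(s_out, spacing) {
  gx <- .diff_axis(s_out, 1, spacing[1])
  gy <- .diff_axis(s_out, 2, spacing[2])
  gz <- .diff_axis(s_out, 3, spacing[3])
  gn <- sqrt(gx^2 + gy^2 + gz^2)
  gn[gn < 1e-9] <- 1e-9
  -( .diff_axis(gx / gn, 1, spacing[1]) +
     .diff_axis(gy / gn, 2, spacing[2]) +
     .diff_axis(gz / gn, 3, spacing[3]) )
}

#' Per-voxel cortical depth field
#'
#' For every ribbon voxel (both signed distances positive), the unsigned
#' boundary distances give the Euclidean fraction; `"equidistant"` mode
#' returns it directly. `"equivolume"` mode estimates the local outer/inner
#' area ratio from the mean curvature `H` of the outer boundary's level set
#' through the voxel under a wedge model (`A_o = 1 + H t`,
#' `A_i = 1 - H (T - t)` for a voxel at depth `t` of local thickness `T`) and
#' returns the volume fraction at the voxel's Euclidean position. Voxels
#' where the wedge degenerates (a nonpositive area) fall back to the
#' equidistant fraction; their count is reported as attribute `"n_fallback"`.
#'
#' @param inner_sd,outer_sd signed-distance volumes (positive toward the
#'   cortex interior from each boundary).
#' @param mode `"equivolume"` or `"equidistant"`.
#' @return Depth-fraction volume (`NA` off-ribbon), 0 = superficial.
#' @export
compute_depth_field <- function(inner_sd, outer_sd,
                                mode = c("equivolume", "equidistant")) {
  mode <- match.arg(mode)
  check_same_grid(inner_sd, outer_sd, "compute_depth_field")
  s_in <- inner_sd$data
  s_out <- outer_sd$data
  cortex <- is.finite(s_in) & is.finite(s_out) & s_in > 0 & s_out > 0
  if (!any(cortex)) stop("empty cortical ribbon")
  d_o <- s_out[cortex]
  d_i <- s_in[cortex]
  rho <- equidistant_depth(d_o, d_i)
  n_fallback <- 0L
  if (mode == "equivolume") {
    H <- .level_set_curvature(s_out, outer_sd$spacing)[cortex]
    A_o <- 1 + H * d_o
    A_i <- 1 - H * d_i
    ok <- A_o > 1e-6 & A_i > 1e-6
    n_fallback <- sum(!ok)
    alpha <- rho
    # depth runs from the outer boundary, so the wedge is entered on its
    # A_o side: apply the model with the outer area in the reference role
    alpha[ok] <- equivolume_alpha(rho[ok], A_i = A_o[ok], A_o = A_i[ok])
    rho <- alpha
  }
  depth <- array(NA_real_, dim(s_out))
  depth[cortex] <- rho
  out <- as_volume(depth, outer_sd$spacing)
  attr(out, "n_fallback") <- n_fallback
  attr(out, "mode") <- mode
  out
}

.compartment_of_depth_index <- function(j) {
  lab <- rep("EXCLUDED", 21L)
  lab[4:7] <- "SF"; lab[8:11] <- "OM"; lab[12:15] <- "IM"; lab[16:19] <- "DP"
  lab[j]
}

#' Assign 21 depth bins and the four analysis compartments
#'
#' Uniform partition of the depth fraction into 21 bins
#' (`j = 1 + floor(21 delta)`, capped at 21; 1 = most superficial). The three
#' most superficial and the two deepest bins are excluded to reduce partial
#' volume effects; the remaining 16 form four compartments of four
#' consecutive depths each: SF (4-7), OM (8-11), IM (12-15), DP (16-19).
#'
#' @param depth depth-fraction volume from [compute_depth_field()].
#' @return List: `depth_index` volume (1..21, `NA` off-ribbon) and
#'   `compartment` character array with levels SF/OM/IM/DP/EXCLUDED.
#' @export
assign_compartments <- function(depth) {
  stopifnot(is_volume(depth))
  delta <- depth$data
  j <- array(NA_integer_, dim(delta))
  ok <- is.finite(delta)
  j[ok] <- pmin(1L + as.integer(floor(delta[ok] * 21)), 21L)
  comp <- array(NA_character_, dim(delta))
  comp[ok] <- .compartment_of_depth_index(j[ok])
  list(depth_index = as_volume(array(as.numeric(j), dim(delta)),
                               depth$spacing),
       compartment = comp)
}
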