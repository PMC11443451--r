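#' 3-D scalar volume
#'
#' The carrier type for every gridded quantity in the pipeline: metric maps
#' (qT1 in ms, QSM in ppm), probability maps in \[0, 1\], binary masks,
#' integer label maps and distance maps in mm. A volume is a 3-D array plus
#' per-axis voxel spacing in mm; voxels outside any mask carry `NA`.
#'
#' @param data 3-D numeric (or logical) array.
#' @param spacing numeric length-3, mm per voxel edge; strictly positive.
#' @return An object of class `"volume"`.
#' @export
as_volume <- function(data, spacing = c(0.5, 0.5, 0.5)) {
  if (is.logical(data)) data <- array(as.numeric(data), dim = dim(data))
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3-D array, got ", length(dim(data)), " dims")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values")
  structure(list(data = data, spacing = spacing), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d voxels, spacing %s mm, %d non-missing\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              sum(!is.na(x$data))))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "volume")

#' Assert that two volumes share one grid
#'
#' Every voxelwise combination in the pipeline goes through this check first:
#' identical shape and spacing, else a fatal error naming the operands.
#'
#' @param a,b volumes.
#' @param what label used in the error message.
#' @return Invisibly `TRUE`.
#' @export
check_same_grid <- function(a, b, what = "volumes") {
  stopifnot(is_volume(a), is_volume(b))
  if (!identical(dim(a$data), dim(b$data)))
    stop(what, ": shape mismatch (", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"), ")")
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop(what, ": spacing mismatch")
  invisible(TRUE)
}

#' Voxel center coordinates of a volume grid
#'
#' Centers at `(i - 0.5) * spacing` along each axis, so the grid origin is the
#' corner of the first voxel.
#'
#' @param vol a volume (or anything with `dim` and `$spacing`).
#' @return List of three numeric vectors `x`, `y`, `z` (mm).
#' @keywords internal
voxel_centers <- function(vol) {
  d <- dim(vol$data)
  s <- vol$spacing
  list(x = (seq_len(d[1]) - 0.5) * s[1],
       y = (seq_len(d[2]) - 0.5) * s[2],
       z = (seq_len(d[3]) - 0.5) * s[3])
}
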