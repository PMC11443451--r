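# Minimal NIfTI-1 I/O.
#
# No NIfTI package is available in the target environment, so the subset of
# the format the pipeline needs is implemented here: single-file .nii or
# .nii.gz, 3-D (or trailing-singleton) grids, the common datatypes, pixdim
# spacing, scl_slope/scl_inter rescaling, and both endiannesses on read.
# Orientation metadata beyond spacing is deliberately ignored: all volumes of
# a run live on one RAS grid and the pipeline never mixes native spaces.

.nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

.nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3-D scalar volume from a `.nii` or `.nii.gz` file. A 4th (or
#' higher) singleton dimension is squeezed with a warning; a non-singleton 4th
#' dimension is fatal. Voxel spacing is taken from `pixdim`.
#'
#' @param path file path.
#' @return A [as_volume()] object.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  con <- .nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  sz <- readBin(hdr[1:4], "integer", size = 4L)
  endian <- .Platform$endian
  if (sz != 348L) {
    endian <- if (endian == "little") "big" else "little"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  rd <- function(off, what, n, size)
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  dims <- rd(40L, "integer", 8L, 2L)
  datatype <- rd(70L, "integer", 1L, 2L)
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic '", magic, "' in ", path)

  ndim <- dims[1]
  shape <- dims[1 + seq_len(max(ndim, 3L))]
  shape[shape == 0L] <- 1L
  if (ndim > 3L) {
    extra <- dims[1 + 4:ndim]
    if (any(extra > 1L))
      stop("volume in ", path, " is ", ndim, "-D with non-singleton extra dims")
    warning("squeezing ", ndim, "-D volume with singleton trailing dims: ",
            basename(path))
    shape <- shape[1:3]
  }
  if (length(shape) < 3L) shape <- c(shape, rep(1L, 3L - length(shape)))
  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-positive voxel spacing in NIfTI header of ", path)

  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype, " in ", path)
  nvox <- prod(shape)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < nvox) stop("truncated voxel data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  as_volume(array(vals, dim = shape), spacing = spacing)
}

#' Write a NIfTI-1 volume
#'
#' Writes float64 voxel data (lossless for the pipeline's doubles) with the
#' grid spacing in `pixdim`; `NA` values are stored as NaN. `.gz` suffixes
#' are honoured.
#'
#' @param vol a volume.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  d <- dim(vol$data)
  con <- .nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size)
  wf <- function(x, size) writeBin(as.double(x), con, size = size)
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L, 4L)                               # sizeof_hdr
  wraw(36L)                                  # data_type..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)           # dim[8]
  wf(c(0, 0, 0), 4L); wi(0L, 2L)             # intent_p1..3, intent_code
  wi(64L, 2L); wi(64L, 2L); wi(0L, 2L)       # datatype, bitpix, slice_start
  wf(c(1, vol$spacing, 0, 0, 0, 0), 4L)      # pixdim[8]
  wf(352, 4L)                                # vox_offset
  wf(1, 4L); wf(0, 4L)                       # scl_slope, scl_inter
  wi(0L, 2L); wraw(1L)                       # slice_end, slice_code
  writeBin(as.raw(2L), con)                  # xyzt_units = mm
  wf(c(0, 0, 0, 0), 4L)                      # cal_max..toffset
  wi(c(0L, 0L), 4L)                          # glmax, glmin
  wraw(104L)                                 # descrip, aux_file
  wi(c(0L, 0L), 2L)                          # qform_code, sform_code
  wf(rep(0, 6), 4L)                          # quatern, qoffset
  wf(rep(0, 12), 4L)                         # srow
  wraw(16L)                                  # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  wraw(4L)                                   # extension flag
  writeBin(as.double(vol$data), con, size = 8L)
  invisible(path)
}
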