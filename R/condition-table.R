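# Long-format statistics input: one row per
# (participant, area, compartment, distance bin, metric) cell.

.ct_columns <- c("participant_id", "group", "risk", "area", "compartment",
                 "distance_bin", "metric", "value", "n_voxels")

.compartment_levels <- c("SF", "OM", "IM", "DP")
.metric_levels <- c("qT1", "pQSM", "nQSM")

#' Distance bin labels for a set of bin edges
#' @param edges strictly increasing numeric vector of edges in mm.
#' @return Character labels, e.g. `"0-2"`.
#' @export
bin_labels <- function(edges = c(0, 2, 4, 6, 8, 10)) {
  paste0(edges[-length(edges)], "-", edges[-1])
}

#' Validate a condition table
#'
#' Checks the cell-structure invariants: required columns, no duplicate
#' condition rows, `value` missing exactly when `n_voxels` is below the
#' minimum voxel rule, positive qT1, sign-correct pQSM/nQSM.
#'
#' @param tab data.frame in long condition format.
#' @param min_voxels minimum voxels per cell for a value to be defined.
#' @return `tab`, invisibly, or a fatal error.
#' @export
validate_condition_table <- function(tab, min_voxels = 4L) {
  miss <- setdiff(.ct_columns, names(tab))
  if (length(miss)) stop("condition table misses columns: ",
                         paste(miss, collapse = ", "))
  key <- interaction(tab$participant_id, tab$area, tab$compartment,
                     tab$distance_bin, tab$metric, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate condition rows in table (first: ",
         as.character(key[duplicated(key)][1]), ")")
  low <- tab$n_voxels < min_voxels
  if (any(low & !is.na(tab$value)))
    stop("cells below the minimum voxel rule must have NA values")
  if (any(!low & is.na(tab$value)))
    stop("cells satisfying the minimum voxel rule must carry a value")
  ok <- !is.na(tab$value)
  if (any(ok & tab$metric == "qT1" & tab$value <= 0))
    stop("qT1 values must be positive")
  if (any(ok & tab$metric == "pQSM" & tab$value <= 0))
    stop("pQSM values must be positive")
  if (any(ok & tab$metric == "nQSM" & tab$value >= 0))
    stop("nQSM values must be negative")
  invisible(tab)
}

#' Write / read a condition table as TSV
#'
#' Tab-separated text with one header row; missing values encoded as `"NA"`.
#' The round trip preserves text columns exactly and values to at least 12
#' significant digits (doubles are written at full precision).
#'
#' @param tab condition table (validated before writing).
#' @param path file path.
#' @param min_voxels minimum voxel rule used for validation.
#' @return `write_condition_table`: invisibly `path`;
#'   `read_condition_table`: the table.
#' @export
write_condition_table <- function(tab, path, min_voxels = 4L) {
  validate_condition_table(tab, min_voxels)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_condition_table
#' @export
read_condition_table <- function(path) {
  if (!file.exists(path)) stop("no such condition table: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c(participant_id = "character",
                                          group = "character",
                                          risk = "integer",
                                          area = "character",
                                          compartment = "character",
                                          distance_bin = "character",
                                          metric = "character",
                                          value = "numeric",
                                          n_voxels = "integer"))
  tab
}
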