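#' Construct a voxel-wise statistic map
#'
#' A scalar field on the mask grid; `NA` marks voxels where the statistic is
#' not computed (outside coverage, below threshold, ...).
#'
#' @param values 3-D numeric array (NA = absent).
#' @param affine 4x4 voxel-to-world transform.
#' @param kind one of `"overlap_pct"`, `"subtraction_pct"`, `"bf10"`,
#'   `"category"`.
#' @return object of class `stat_map`.
#' @export
stat_map <- function(values, affine,
                     kind = c("overlap_pct", "subtraction_pct", "bf10",
                              "category")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(values)) == 3L)
  v <- values[!is.na(values)]
  if (kind == "overlap_pct" && length(v) && (min(v) < 0 || max(v) > 100))
    stop("overlap percentages must lie in [0, 100]", call. = FALSE)
  if (kind == "subtraction_pct" && length(v) &&
      (min(v) < -100 || max(v) > 100))
    stop("subtraction percentages must lie in [-100, 100]", call. = FALSE)
  structure(list(values = values, affine = affine, kind = kind),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("stat_map [%s]: grid %s, %d computed voxels%s\n", x$kind,
              paste(dim(x$values), collapse = "x"), length(v),
              if (length(v)) sprintf(", range [%.3g, %.3g]", min(v), max(v))
              else ""))
  invisible(x)
}

#' Write a stat map to NIfTI (float32; NA stored as NaN)
#' @param map a [stat_map()].
#' @param path output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_stat_map <- function(map, path) {
  vals <- map$values
  vals[is.na(vals)] <- NaN
  write_nifti(vals, map$affine, path, datatype = "float32")
}

values_to_grid <- function(values, vm) {
  arr <- array(NA_real_, dim = vm$grid_shape)
  flat <- vm$voxel_index[, 1L] + 1L +
    vm$voxel_index[, 2L] * vm$grid_shape[1L] +
    vm$voxel_index[, 3L] * vm$grid_shape[1L] * vm$grid_shape[2L]
  arr[flat] <- values
  arr
}

#' Group lesion-overlap percentage map
#'
#' Per voxel, 100 x (number of group members lesioned) / (group size) — the
#' percentage colour bar of an overlay lesion plot.
#'
#' @param vm a [build_voxel_matrix()] result (filtered or not).
#' @param member_ids patient ids forming the group (subset of
#'   `vm$patient_ids`).
#' @return a [stat_map()] of kind `"overlap_pct"` (computed on every column
#'   of `vm`).
#' @export
group_overlap_pct <- function(vm, member_ids) {
  stopifnot(inherits(vm, "voxel_matrix"))
  if (length(member_ids) == 0L) stop("empty group", call. = FALSE)
  missing <- setdiff(member_ids, vm$patient_ids)
  if (length(missing))
    stop("unknown patient ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- vm$patient_ids %in% member_ids
  pct <- 100 * colSums(vm$matrix[rows, , drop = FALSE]) / sum(rows)
  stat_map(values_to_grid(pct, vm), vm$affine, "overlap_pct")
}

#' Lesion subtraction map
#'
#' Voxel-wise difference of overlap percentages, deficit group minus
#' no-deficit group, in percentage points. Using percentages (not raw
#' counts) keeps unequal group sizes comparable.
#'
#' @param abnormal_pct,normal_pct [stat_map()]s of kind `"overlap_pct"` on
#'   the same grid/affine.
#' @return a [stat_map()] of kind `"subtraction_pct"`.
#' @export
subtraction_map <- function(abnormal_pct, normal_pct) {
  stopifnot(inherits(abnormal_pct, "stat_map"),
            inherits(normal_pct, "stat_map"))
  if (!identical(dim(abnormal_pct$values), dim(normal_pct$values)) ||
      max(abs(abnormal_pct$affine - normal_pct$affine)) > 1e-6)
    stop("grid/affine mismatch between overlap maps", call. = FALSE)
  stat_map(abnormal_pct$values - normal_pct$values, abnormal_pct$affine,
           "subtraction_pct")
}

#' Display-threshold a map
#'
#' Keeps voxels with value strictly greater than `min_value`; all others
#' become absent (`NA`). The conventional display cut for subtraction maps
#' is 40 (percentage points).
#'
#' @param map a [stat_map()].
#' @param min_value strict lower threshold.
#' @return thresholded [stat_map()] of the same kind.
#' @export
threshold_map <- function(map, min_value = 40) {
  stopifnot(inherits(map, "stat_map"))
  vals <- map$values
  vals[!is.na(vals) & vals <= min_value] <- NA_real_
  stat_map(vals, map$affine, map$kind)
}

#' Peak voxel of a map
#'
#' The computed voxel with the maximum value; ties are broken by the lowest
#' lexicographic 0-based voxel index (i, then j, then k) so the peak is
#' reproducible. The coordinate is reported in world (affine) space at the
#' voxel centre.
#'
#' @param map a [stat_map()].
#' @return list with `value`, `voxel_index` (0-based i,j,k) and `world_xyz`.
#' @export
peak_voxel <- function(map) {
  stopifnot(inherits(map, "stat_map"))
  vals <- map$values
  if (all(is.na(vals))) stop("map has no computed voxels", call. = FALSE)
  mx <- max(vals, na.rm = TRUE)
  flat <- which(!is.na(vals) & vals == mx)
  shape <- dim(vals)
  f0 <- flat - 1L
  idx <- cbind(i = f0 %% shape[1L],
               j = (f0 %/% shape[1L]) %% shape[2L],
               k = f0 %/% (shape[1L] * shape[2L]))
  ord <- order(idx[, 1L], idx[, 2L], idx[, 3L])
  ijk <- idx[ord[1L], ]
  list(value = mx, voxel_index = unname(ijk),
       world_xyz = voxel_to_world(unname(ijk), map$affine))
}
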