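#' Construct a lesion volume
#'
#' @param data 3-D array of 0/1 (1 = lesioned voxel).
#' @param affine 4x4 voxel-to-world transform.
#' @param participant_id patient identifier.
#' @param space_label free-text label of the reference space.
#' @return object of class `lesion_volume`.
#' @export
lesion_volume <- function(data, affine, participant_id,
                          space_label = "unknown") {
  stopifnot(length(dim(data)) == 3L)
  if (!all(data %in% c(0, 1)))
    stop("lesion volume must be binary (0/1)", call. = FALSE)
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible", call. = FALSE)
  structure(list(data = data, affine = affine,
                 participant_id = as.character(participant_id),
                 space_label = space_label),
            class = "lesion_volume")
}

#' @export
print.lesion_volume <- function(x, ...) {
  cat(sprintf("lesion_volume '%s': %s grid, %d lesioned voxels (%s)\n",
              x$participant_id, paste(dim(x$data), collapse = "x"),
              sum(x$data), x$space_label))
  invisible(x)
}

#' Load a binary lesion mask from NIfTI
#'
#' Values are binarized by `value > 0`; the grid and affine are preserved.
#' 4-D volumes and non-finite values are rejected.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param participant_id patient identifier; defaults to the file stem.
#' @param space_label reference-space label stored on the volume.
#' @return a [lesion_volume()].
#' @export
load_mask <- function(path, participant_id = NULL, space_label = "MNI152") {
  if (is.null(participant_id))
    participant_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  vol <- read_nifti(path)
  if (any(!is.finite(vol$data)))
    stop("non-finite values in lesion mask ", path, call. = FALSE)
  lesion_volume((vol$data > 0) + 0, vol$affine, participant_id, space_label)
}

#' Write a lesion volume to NIfTI (uint8)
#'
#' @param volume a [lesion_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(volume, path) {
  write_nifti(volume$data, volume$affine, path, datatype = "uint8")
}

#' Stack lesion volumes into a patient-by-voxel damage matrix
#'
#' Rows are patients, columns voxels in lexicographic 0-based voxel-index
#' order (i fastest, matching R's column-major array order). All volumes
#' must share grid shape and affine (affine entries compared to `tol`).
#'
#' @param volumes list of [lesion_volume()] objects.
#' @param tol absolute tolerance on affine entries.
#' @return object of class `voxel_matrix`: fields `matrix` (patients x
#'   voxels, 0/1), `patient_ids`, `grid_shape`, `affine`, `voxel_index`
#'   (columns' 0-based (i,j,k), an n_voxel x 3 matrix).
#' @export
build_voxel_matrix <- function(volumes, tol = 1e-4) {
  if (length(volumes) == 0L) stop("no lesion volumes supplied", call. = FALSE)
  ids <- vapply(volumes, function(v) v$participant_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate patient ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  ref <- volumes[[1L]]
  shape <- dim(ref$data)
  for (v in volumes) {
    if (!identical(dim(v$data), shape))
      stop("grid shape mismatch for patient ", v$participant_id,
           call. = FALSE)
    if (max(abs(v$affine - ref$affine)) > tol)
      stop("affine mismatch for patient ", v$participant_id, call. = FALSE)
  }
  mat <- do.call(rbind, lapply(volumes, function(v) as.vector(v$data)))
  rownames(mat) <- ids
  idx <- as.matrix(expand.grid(i = 0:(shape[1L] - 1L),
                               j = 0:(shape[2L] - 1L),
                               k = 0:(shape[3L] - 1L)))
  structure(list(matrix = mat, patient_ids = ids, grid_shape = shape,
                 affine = ref$affine, voxel_index = idx),
            class = "voxel_matrix")
}

#' @export
print.voxel_matrix <- function(x, ...) {
  cat(sprintf("voxel_matrix: %d patients x %d voxels (grid %s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

#' Voxel coverage filter
#'
#' Retains voxels damaged in at least `min_lesioned` patients and intact in
#' at least `min_intact` patients — the minimum-coverage rule applied before
#' voxel-wise inference (the reference analysis used at-least-3 lesioned).
#'
#' @param vm a [build_voxel_matrix()] result.
#' @param min_lesioned minimum number of lesioned patients per voxel (>= 1).
#' @param min_intact minimum number of intact patients per voxel.
#' @return a `voxel_matrix` restricted to retained columns, with attribute
#'   `n_retained`.
#' @export
coverage_filter <- function(vm, min_lesioned = 3L, min_intact = 1L) {
  stopifnot(inherits(vm, "voxel_matrix"))
  if (min_lesioned < 1L) stop("min_lesioned must be >= 1", call. = FALSE)
  lesioned <- colSums(vm$matrix)
  keep <- lesioned >= min_lesioned &
    (nrow(vm$matrix) - lesioned) >= min_intact
  vm$matrix <- vm$matrix[, keep, drop = FALSE]
  vm$voxel_index <- vm$voxel_index[keep, , drop = FALSE]
  attr(vm, "n_retained") <- sum(keep)
  vm
}
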