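# Minimal single-file NIfTI-1 I/O (.nii / .nii.gz). Only what lesion masks
# and scalar stat maps need: 3-D volumes, common datatypes, sform affine
# (qform quaternion decoded on read). Written against the nifti1.h layout;
# no R NIfTI package is available in the supported environment.

NIFTI_DT <- list(`2`  = list(what = "integer", size = 1L, signed = FALSE),
                 `4`  = list(what = "integer", size = 2L, signed = TRUE),
                 `8`  = list(what = "integer", size = 4L, signed = TRUE),
                 `16` = list(what = "double",  size = 4L, signed = TRUE),
                 `64` = list(what = "double",  size = 8L, signed = TRUE),
                 `256` = list(what = "integer", size = 1L, signed = TRUE),
                 `512` = list(what = "integer", size = 2L, signed = FALSE))

read_all_bytes <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  chunks <- list()
  repeat {
    b <- readBin(con, "raw", n = 1048576L)
    if (length(b) == 0L) break
    chunks[[length(chunks) + 1L]] <- b
  }
  do.call(c, chunks)
}

quaternion_affine <- function(b, c_, d, qoffset, pixdim, qfac) {
  a2 <- 1 - b^2 - c_^2 - d^2
  a <- sqrt(max(a2, 0))
  R <- rbind(c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_)),
             c(2 * (b * c_ + a * d), a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b)),
             c(2 * (b * d - a * c_), 2 * (c_ * d + a * b), a^2 + d^2 - b^2 - c_^2))
  if (qfac == 0) qfac <- 1
  S <- diag(c(pixdim[1L], pixdim[2L], qfac * pixdim[3L]))
  aff <- diag(4)
  aff[1:3, 1:3] <- R %*% S
  aff[1:3, 4L] <- qoffset
  aff
}

#' Read a NIfTI-1 volume
#'
#' Minimal reader for single-file NIfTI-1 (`.nii`, `.nii.gz`): 3-D volumes,
#' datatypes uint8/int8/int16/uint16/int32/float32/float64, either byte
#' order, scl_slope/scl_inter scaling. The voxel-to-world affine is taken
#' from the sform when `sform_code > 0`, else decoded from the qform
#' quaternion, else a diagonal pixdim fallback (with a warning). Voxel
#' indices are 0-based throughout the package; world coordinates are
#' obtained only through the affine.
#'
#' @param path file path.
#' @return list with `data` (3-D array), `affine` (4x4), `dims`, `pixdim`.
#' @export
read_nifti <- function(path) {
  bytes <- read_all_bytes(path)
  if (length(bytes) < 352L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  rd <- function(off, what, n, size, signed = TRUE, endian = "little")
    readBin(bytes[(off + 1L):length(bytes)], what, n = n, size = size,
            signed = signed, endian = endian)
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L) != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, endian = "big") != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
  }
  rd2 <- function(off, what, n, size, signed = TRUE)
    rd(off, what, n, size, signed, endian)
  magic <- rawToChar(bytes[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic '", magic, "' in ", path, call. = FALSE)
  dim <- rd2(40L, "integer", 8L, 2L)
  ndim <- dim[1L]
  extra <- if (ndim > 3L) dim[5:(ndim + 1L)] else integer(0)
  if (ndim > 3L && any(extra > 1L))
    stop("4-D (or higher) NIfTI not supported: ", path, call. = FALSE)
  if (ndim < 3L) dim[(ndim + 2L):4L] <- 1L
  shape <- dim[2:4]
  datatype <- rd2(70L, "integer", 1L, 2L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE)
  pixdim <- rd2(76L, "double", 8L, 4L)
  vox_offset <- rd2(108L, "double", 1L, 4L)
  scl_slope <- rd2(112L, "double", 1L, 4L)
  scl_inter <- rd2(116L, "double", 1L, 4L)
  qform_code <- rd2(252L, "integer", 1L, 2L)
  sform_code <- rd2(254L, "integer", 1L, 2L)
  quatern <- rd2(256L, "double", 6L, 4L)   # b, c, d, qoffset x/y/z
  srow <- rd2(280L, "double", 12L, 4L)
  nvox <- prod(shape)
  # unsigned 16-bit needs a widening read (readBin signed=FALSE only for size 1/2... size 2 ok)
  vals <- readBin(bytes[(vox_offset + 1L):length(bytes)], dt$what, n = nvox,
                  size = dt$size, signed = dt$signed, endian = endian)
  if (length(vals) < nvox)
    stop("truncated NIfTI data in ", path, call. = FALSE)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  if (any(!is.finite(vals)) && datatype %in% c(2L, 4L, 8L, 256L, 512L))
    stop("non-finite values in integer NIfTI volume: ", path, call. = FALSE)
  affine <- if (sform_code > 0L) {
    rbind(matrix(srow, nrow = 3L, byrow = TRUE), c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    quaternion_affine(quatern[1L], quatern[2L], quatern[3L], quatern[4:6],
                      pixdim[2:4], pixdim[1L])
  } else {
    warning("no sform/qform in ", path, "; using diagonal pixdim affine",
            call. = FALSE)
    diag(c(pixdim[2:4], 1))
  }
  list(data = array(vals, dim = shape), affine = affine, dims = shape,
       pixdim = pixdim[2:4])
}

#' Write a NIfTI-1 volume
#'
#' Minimal single-file NIfTI-1 writer. The affine is stored as the sform
#' (code 2, "aligned") and mirrored into pixdim; the qform is left unset.
#' `datatype` may be `"uint8"` (lesion masks) or `"float32"` (stat maps;
#' `NA` is stored as NaN). Files ending in `.gz` are gzip-compressed.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype `"uint8"`, `"int16"`, `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, affine, path, datatype = "float32") {
  stopifnot(length(dim(data)) == 3L, is.matrix(affine),
            all(dim(affine) == c(4L, 4L)))
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("unsupported datatype: ", datatype, call. = FALSE))
  size <- switch(datatype, uint8 = 1L, int16 = 2L, int32 = 4L,
                 float32 = 4L, float64 = 8L)
  if (code %in% c(2L, 4L, 8L) && any(!is.finite(data)))
    stop("integer datatypes cannot store non-finite values", call. = FALSE)
  pixdim <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi(348L, 4L)                       # sizeof_hdr
  wraw(36L)                          # data_type, db_name, extents, session_error, regular, dim_info
  wi(c(3L, dim(data), 1L, 1L, 1L, 1L), 2L)   # dim[8]
  wraw(14L)                          # intent_p1..3, intent_code
  wi(code, 2L)                       # datatype
  wi(8L * size, 2L)                  # bitpix
  wi(0L, 2L)                         # slice_start
  wf(c(1, pixdim, 0, 0, 0, 0))       # pixdim[8] (qfac = 1)
  wf(352)                            # vox_offset
  wf(c(1, 0))                        # scl_slope, scl_inter
  wraw(4L)                           # slice_end (int16), slice_code, xyzt_units
  wf(c(0, 0, 0))                     # cal_max, cal_min, slice_duration
  wf(0)                              # toffset
  wi(c(0L, 0L), 4L)                  # glmax, glmin
  desc <- charToRaw("tiltmap")
  wraw_pad <- function(r, n) writeBin(c(r, raw(n - length(r))), con)
  wraw_pad(desc, 80L)                # descrip
  wraw(24L)                          # aux_file
  wi(c(0L, 2L), 2L)                  # qform_code = 0, sform_code = 2
  wf(rep(0, 6))                      # quatern b,c,d + qoffset x,y,z
  wf(t(affine[1:3, ]))               # srow_x, srow_y, srow_z
  wraw(16L)                          # intent_name
  writeBin(c(charToRaw("n+1"), raw(5L)), con)  # magic + padding to 352
  if (code %in% c(2L, 4L, 8L)) {
    writeBin(as.integer(round(data)), con, size = size, endian = "little")
  } else {
    writeBin(as.double(data), con, size = size, endian = "little")
  }
  invisible(path)
}

#' Map 0-based voxel indices to world coordinates
#'
#' @param ijk integer vector of length 3 (or n x 3 matrix) of 0-based voxel
#'   indices.
#' @param affine 4x4 voxel-to-world transform.
#' @return numeric world coordinates (length 3, or n x 3 matrix).
#' @export
voxel_to_world <- function(ijk, affine) {
  if (is.matrix(ijk)) {
    h <- cbind(ijk, 1)
    out <- h %*% t(affine[1:3, , drop = FALSE])
    colnames(out) <- c("x", "y", "z")
    out
  } else {
    as.numeric(affine[1:3, ] %*% c(ijk, 1))
  }
}
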