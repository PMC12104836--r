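# Minimal NIfTI-1 volume I/O.
#
# Only what the localisation pipeline needs: single 3-D volumes, sform affine,
# integer or float data, optional gzip (.nii / .nii.gz). No NIfTI R package is
# assumed; the format is written field-by-field against the NIfTI-1 layout
# (348-byte header + 4-byte extender, data at offset 352, little endian).

NIFTI_DTYPES <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3-D volume as NIfTI-1
#'
#' @param data 3-D array (integer or double).
#' @param affine 4x4 voxel-to-world (mm) matrix, applied to 0-based voxel
#'   indices (the NIfTI sform convention).
#' @param path output path; `.nii` or `.nii.gz`.
#' @param dtype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, affine, path, dtype = "int32") {
  assert_that(length(dim(data)) == 3L, "data must be a 3-D array")
  assert_that(is.matrix(affine) && all(dim(affine) == c(4L, 4L)),
              "affine must be a 4x4 matrix")
  dt <- NIFTI_DTYPES[[dtype]]
  assert_that(!is.null(dt), sprintf("unsupported dtype '%s'", dtype))

  dims <- dim(data)
  pixdim <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wb_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wb_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wb_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wb_raw <- function(n) writeBin(raw(n), con)

  wb_i32(348L)                       # sizeof_hdr
  wb_raw(10L); wb_raw(18L)           # data_type, db_name (unused)
  wb_i32(0L); wb_i16(0L); wb_raw(2L) # extents, session_error, regular+dim_info
  wb_i16(c(3L, dims, 1L, 1L, 1L, 1L))        # dim[8]
  wb_f32(c(0, 0, 0)); wb_i16(0L)             # intent_p1-3, intent_code
  wb_i16(dt$code); wb_i16(dt$bitpix); wb_i16(0L) # datatype, bitpix, slice_start
  wb_f32(c(1, pixdim, 1, 1, 1, 1))           # pixdim[8] (qfac 1)
  wb_f32(352); wb_f32(1); wb_f32(0)          # vox_offset, scl_slope, scl_inter
  wb_i16(0L); wb_raw(2L)                     # slice_end, slice_code+xyzt_units
  wb_f32(c(0, 0, 0, 0)); wb_i32(c(0L, 0L))   # cal_max/min, slice_dur, toffset, glmax/min
  wb_raw(80L); wb_raw(24L)                   # descrip, aux_file
  wb_i16(0L); wb_i16(1L)                     # qform_code, sform_code = 1
  wb_f32(rep(0, 6))                          # quaternion + qoffset
  wb_f32(affine[1, ]); wb_f32(affine[2, ]); wb_f32(affine[3, ]) # srow_x/y/z
  wb_raw(16L)                                # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  wb_raw(4L)                                 # extender

  vec <- as.vector(data)
  if (dt$what == "integer") vec <- as.integer(round(vec)) else vec <- as.double(vec)
  writeBin(vec, con, size = dt$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (3-D array), `affine` (4x4 sform matrix) and
#'   `dtype`.
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  assert_that(length(hdr) == 348L, "truncated NIfTI header")
  rd_i32 <- function(off, n = 1L) readBin(hdr[(off + 1L):(off + 4L * n)],
                                          "integer", n = n, size = 4L, endian = "little")
  rd_i16 <- function(off, n = 1L) readBin(hdr[(off + 1L):(off + 2L * n)],
                                          "integer", n = n, size = 2L, endian = "little")
  rd_f32 <- function(off, n = 1L) readBin(hdr[(off + 1L):(off + 4L * n)],
                                          "double", n = n, size = 4L, endian = "little")
  assert_that(rd_i32(0L) == 348L, "not a NIfTI-1 file (bad sizeof_hdr)")
  dims <- rd_i16(40L, 8L)
  ndim <- dims[1]
  assert_that(ndim >= 3L, "expected a 3-D volume")
  shape <- dims[2:4]
  dtcode <- rd_i16(70L)
  dt_name <- names(NIFTI_DTYPES)[vapply(NIFTI_DTYPES, function(d) d$code,
                                        integer(1)) == dtcode]
  assert_that(length(dt_name) == 1L, sprintf("unsupported NIfTI datatype %d", dtcode))
  dt <- NIFTI_DTYPES[[dt_name]]
  vox_offset <- rd_f32(108L)
  sform_code <- rd_i16(254L)
  if (sform_code > 0L) {
    affine <- rbind(matrix(c(rd_f32(280L, 4L), rd_f32(296L, 4L), rd_f32(312L, 4L)),
                           nrow = 3L, byrow = TRUE), c(0, 0, 0, 1))
  } else {
    pixdim <- rd_f32(76L, 8L)[2:4]
    affine <- diag(c(pixdim, 1))
  }
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(shape)
  vec <- readBin(con, dt$what, n = n, size = dt$size, endian = "little",
                 signed = dt$signed)
  assert_that(length(vec) == n, "truncated NIfTI data section")
  list(data = array(vec, dim = shape), affine = affine, dtype = dt_name)
}
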