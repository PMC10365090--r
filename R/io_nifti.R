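# Minimal NIfTI-1 reader/writer.
#
# The offline toolchain this package targets ships no NIfTI package, so the
# subset of NIfTI-1 the pipeline needs is implemented here: single-file .nii
# (optionally gzipped), 3-D grids, datatypes uint8/int16/int32/float32/float64,
# scl_slope/scl_inter rescaling, spacing from pixdim and origin from the sform
# row offsets. Little-endian files are written; both endiannesses are read.

nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

pad_char <- function(s, n) {
  r <- charToRaw(s)
  if (length(r) > n) r <- r[seq_len(n)]
  c(r, raw(n - length(r)))
}

#' Write a 3-D array as a NIfTI-1 file
#'
#' @param data numeric or integer 3-D array
#' @param path output path; `.nii` or `.nii.gz`
#' @param spacing voxel spacing in mm, length 3
#' @param origin world coordinate of voxel (1,1,1), length 3
#' @param datatype NIfTI datatype code: 2 (uint8), 4 (int16), 16 (float32),
#'   64 (float64)
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        datatype = 16L) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stopf("unsupported NIfTI datatype code %s", datatype)
  con <- open_maybe_gz(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(348L, 4)                        # sizeof_hdr
  writeBin(raw(10 + 18 + 4 + 2 + 1 + 1), con)  # unused through dim_info
  wi(c(3L, dim(data), 1L, 1L, 1L, 1L), 2)      # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)          # intent_p1..3, intent_code
  wi(datatype, 2)
  wi(dt$size * 8L, 2)                # bitpix
  wi(0L, 2)                          # slice_start
  wf(c(1, spacing, 1, 0, 0, 0))      # pixdim[8]
  wf(352)                            # vox_offset
  wf(1); wf(0)                       # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)   # slice_end, slice_code + xyzt_units
  wf(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_dur, toffset
  wi(c(0L, 0L), 4)                   # glmax, glmin
  writeBin(pad_char("radiomix", 80), con)  # descrip
  writeBin(raw(24), con)             # aux_file
  wi(c(0L, 1L), 2)                   # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))            # quaternion b,c,d + qoffset
  wf(c(spacing[1], 0, 0, origin[1])) # srow_x
  wf(c(0, spacing[2], 0, origin[2])) # srow_y
  wf(c(0, 0, spacing[3], origin[3])) # srow_z
  writeBin(raw(16), con)             # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  writeBin(raw(4), con)              # extension flag
  if (dt$what == "integer") {
    v <- as.integer(round(data))
    if (!dt$signed && dt$size == 1L) {
      writeBin(as.raw(pmin(pmax(v, 0L), 255L)), con)
    } else {
      writeBin(v, con, size = dt$size, endian = "little")
    }
  } else {
    writeBin(as.numeric(data), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' @param path `.nii` or `.nii.gz` file
#' @return list with `data` (3-D array, rescaled), `spacing`, `origin`
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  if (length(hdr) < 348) stopf("format error: %s is not a NIfTI-1 file", path)
  endian <- "little"
  gi <- function(off, size, n = 1, signed = TRUE)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = signed)
  gf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = endian)
  if (gi(0, 4) != 348L) {
    endian <- "big"
    if (gi(0, 4) != 348L)
      stopf("format error: %s has an unrecognized NIfTI header", path)
  }
  dims <- gi(40, 2, 8)
  if (dims[1] < 3) dims <- c(3, dims[2:3], 1, dims[5:8])
  nx <- dims[2]; ny <- dims[3]; nz <- dims[4]
  datatype <- gi(70, 2)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stopf("unsupported NIfTI datatype %d in %s", datatype, path)
  pixdim <- gf(76, 8)
  vox_offset <- gf(108)
  scl_slope <- gf(112); scl_inter <- gf(116)
  sform_code <- gi(254, 2)
  srow <- matrix(gf(280, 12), nrow = 3, byrow = TRUE)
  n <- as.numeric(nx) * ny * nz
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- if (dt$what == "integer" && dt$size == 1L) {
    as.integer(readBin(con, "raw", n = n))
  } else {
    readBin(con, dt$what, n = n, size = dt$size, endian = endian,
            signed = dt$signed)
  }
  if (length(vals) < n) stopf("format error: %s truncated pixel data", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  spacing <- abs(pixdim[2:4])
  if (any(spacing <= 0)) stopf("format error: %s missing voxel spacing", path)
  origin <- if (sform_code > 0) srow[, 4] else c(0, 0, 0)
  list(data = array(vals, c(nx, ny, nz)), spacing = spacing, origin = origin)
}
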