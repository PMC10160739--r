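# Minimal NIfTI-1 codec for single 2D float32 slices (.nii / .nii.gz).
# Little-endian only; datatypes float32 (16), int16 (4), uint8 (2) on read.

#' Write a 2D slice as NIfTI-1 float32
#'
#' @param mat numeric matrix (rows x cols)
#' @param path output path ending in .nii or .nii.gz
#' @param pixel_spacing length-2 numeric, mm per pixel (row, col)
#' @return `path`, invisibly
#' @export
write_nifti_2d <- function(mat, path, pixel_spacing = c(1, 1)) {
  if (!is.matrix(mat)) stopf("mat must be a matrix")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size = 4L) writeBin(as.integer(x), con, size = size,
                                        endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wr <- function(n) writeBin(raw(n), con)
  wi(348L)                                   # sizeof_hdr
  wr(36L)                                    # data_type..dim_info
  wi(c(2L, ncol(mat), nrow(mat), 1L, 1L, 1L, 1L, 1L), size = 2L)  # dim[8]
  wf(c(0, 0, 0))                             # intent_p1..p3
  wi(0L, 2L)                                 # intent_code
  wi(16L, 2L)                                # datatype: float32
  wi(32L, 2L)                                # bitpix
  wi(0L, 2L)                                 # slice_start
  wf(c(0, pixel_spacing[2], pixel_spacing[1], 1, 1, 1, 1, 1))  # pixdim[8]
  wf(352)                                    # vox_offset
  wf(c(1, 0))                                # scl_slope, scl_inter
  wi(0L, 2L); wr(1L); wr(1L)                 # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                             # cal_max, cal_min, slice_duration
  wf(0)                                      # toffset
  wi(c(0L, 0L))                              # glmax, glmin
  wr(80L); wr(24L)                           # descrip, aux_file
  wi(0L, 2L); wi(0L, 2L)                     # qform_code, sform_code
  wf(rep(0, 18))                             # quatern/qoffset + srow x,y,z
  wr(16L)                                    # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con) # magic
  wr(4L)                                     # extension flag
  # data in column-major x-fastest order: x = image column
  wf(as.numeric(t(mat)))
  invisible(path)
}

#' Read a 2D slice from a NIfTI-1 file
#'
#' @param path .nii or .nii.gz path
#' @return numeric matrix; pixel spacing in attribute `pixel_spacing`
#' @export
read_nifti_2d <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  ri <- function(off, size, n = 1L)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4L,
            endian = "little")
  if (ri(0, 4) != 348L) stopf("unsupported NIfTI header (not little-endian NIfTI-1)")
  dims <- ri(40, 2, 8)
  if (dims[1] < 2 || any(dims[4:8] > 1) && dims[1] > 2)
    stopf("only single 2D slices supported (dim = %s)", paste(dims, collapse = ","))
  nx <- dims[2]; ny <- dims[3]
  datatype <- ri(70, 2)
  vox_offset <- rf(108)
  pixdim <- rf(76, 8)
  scl_slope <- rf(112); scl_inter <- rf(116)
  if (scl_slope == 0) scl_slope <- 1
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- nx * ny
  vals <- switch(as.character(datatype),
    "16" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    "64" = readBin(con, "numeric", n = n, size = 8L, endian = "little"),
    "4"  = readBin(con, "integer", n = n, size = 2L, endian = "little"),
    "2"  = readBin(con, "integer", n = n, size = 1L, signed = FALSE,
                   endian = "little"),
    stopf("unsupported NIfTI datatype %d", datatype))
  mat <- matrix(vals * scl_slope + scl_inter, nrow = ny, ncol = nx,
                byrow = TRUE)
  attr(mat, "pixel_spacing") <- c(pixdim[3], pixdim[2])
  mat
}
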