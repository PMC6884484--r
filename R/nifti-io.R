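# Minimal NIfTI-1 I/O for 3D scalar volumes, base R only.
# Covers single-file .nii / .nii.gz, datatypes uint8(2) int16(4) int32(8)
# float32(16) float64(64) uint16(512), both endiannesses, scl_slope/inter.

.nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

.read_nifti_header <- function(con, endian) {
  hdr <- list()
  hdr$sizeof_hdr <- readBin(con, "integer", 1, 4, endian = endian)
  readBin(con, "raw", 35)                                   # unused legacy fields
  readBin(con, "raw", 1)                                    # dim_info
  hdr$dim <- readBin(con, "integer", 8, 2, endian = endian)
  readBin(con, "double", 3, 4, endian = endian)             # intent_p1..p3
  readBin(con, "integer", 1, 2, endian = endian)            # intent_code
  hdr$datatype <- readBin(con, "integer", 1, 2, endian = endian)
  hdr$bitpix <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "integer", 1, 2, endian = endian)            # slice_start
  hdr$pixdim <- readBin(con, "double", 8, 4, endian = endian)
  hdr$vox_offset <- readBin(con, "double", 1, 4, endian = endian)
  hdr$scl_slope <- readBin(con, "double", 1, 4, endian = endian)
  hdr$scl_inter <- readBin(con, "double", 1, 4, endian = endian)
  readBin(con, "raw", 348 - 120)                            # remainder incl. magic
  hdr
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Reads single-file NIfTI-1 (`.nii` or `.nii.gz`). Voxel spacing is taken
#' from the header `pixdim`; slice axial positions follow as
#' `slice_index * spacing[3]` (see [axial_positions()]).
#'
#' @param path file path.
#' @param as_label logical; if `TRUE` return a [label_volume()] (values must
#'   be in {0,1}), otherwise an [intensity_volume()].
#' @return An `intensity_volume` or `label_volume`.
#' @export
read_volume <- function(path, as_label = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "integer", 1, 4, endian = "little")
  endian <- if (identical(first, 348L)) "little" else "big"
  close(con); on.exit()
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- .read_nifti_header(con, endian)
  if (hdr$sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  ndim <- hdr$dim[1]
  if (ndim != 3L && !(ndim > 3L && all(hdr$dim[5:8] <= 1)))
    stop("expected a 3D image, header declares ", ndim, " dims: ", path)
  dims <- hdr$dim[2:4]
  if (any(dims < 1)) stop("invalid image dimensions in header: ", path)
  dt <- .nifti_datatypes[[as.character(hdr$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", hdr$datatype)
  skip <- hdr$vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(hdr$scl_slope) && hdr$scl_slope != 0 &&
      !(hdr$scl_slope == 1 && hdr$scl_inter == 0))
    vals <- vals * hdr$scl_slope + hdr$scl_inter
  spacing <- hdr$pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- c(1, 1, 1)
  arr <- array(vals, dim = dims)
  if (as_label) label_volume(arr, spacing) else intensity_volume(arr, spacing)
}

#' Write a volume to a NIfTI-1 file
#'
#' Intensity volumes are stored as float32, label volumes as uint8 (so binary
#' labels round-trip exactly). `.nii.gz` paths are gzip-compressed.
#'
#' @param vol an [intensity_volume()] or [label_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  is_label <- inherits(vol, "label_volume")
  if (!is_label && !inherits(vol, "intensity_volume"))
    stop("vol must be an intensity_volume or label_volume")
  dims <- dim(vol$data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wraw <- function(k) writeBin(raw(k), con)
  wb(348L, 4)                                  # sizeof_hdr
  wraw(36)                                     # data_type, db_name, extents, ...
  wb(as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), 2)   # dim[8]
  wb(c(0, 0, 0), 4)                            # intent_p1..p3
  wb(0L, 2)                                    # intent_code
  wb(if (is_label) 2L else 16L, 2)             # datatype
  wb(if (is_label) 8L else 32L, 2)             # bitpix
  wb(0L, 2)                                    # slice_start
  wb(c(1, vol$spacing, 0, 0, 0, 0), 4)         # pixdim[8]
  wb(352, 4)                                   # vox_offset
  wb(c(0, 0), 4)                               # scl_slope, scl_inter
  wb(0L, 2); wraw(2)                           # slice_end, slice_code, xyzt_units
  wb(c(0, 0, 0, 0), 4)                         # cal_max, cal_min, slice_duration, toffset
  wb(c(0L, 0L), 4)                             # glmax, glmin
  wraw(80 + 24)                                # descrip, aux_file
  wb(c(0L, 0L), 2)                             # qform_code, sform_code
  wb(rep(0, 6), 4)                             # quatern, qoffset
  wb(c(vol$spacing[1], 0, 0, 0), 4)            # srow_x
  wb(c(0, vol$spacing[2], 0, 0), 4)            # srow_y
  wb(c(0, 0, vol$spacing[3], 0), 4)            # srow_z
  wraw(16)                                     # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  wraw(4)                                      # extension flag
  if (is_label) {
    writeBin(as.raw(vol$data), con)
  } else {
    writeBin(as.double(vol$data), con, size = 4, endian = "little")
  }
  invisible(path)
}
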