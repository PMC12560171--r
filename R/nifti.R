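# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# No NIfTI package ships with the supported toolchain, so the subset of the
# format this pipeline needs (3D scalar volumes, float/int datatypes,
# pixdim-encoded voxel size) is implemented directly against the NIfTI-1
# header layout. Orientation metadata beyond voxel size is not interpreted.

NIFTI_HDR_SIZE <- 348L

#' Write a volume as NIfTI-1
#'
#' Writes a single-file NIfTI-1 image (`.nii`, gzipped when the path ends in
#' `.gz`) with float32 data and the voxel size recorded in `pixdim`.
#'
#' @param volume a [gm_volume()] or a 3D numeric array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size voxel edge lengths in mm (taken from the volume when it
#'   is a `gm_volume`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path, voxel_size = c(1.5, 1.5, 1.5)) {
  arr <- as_volume_array(volume)
  if (inherits(volume, "gm_volume")) voxel_size <- volume$voxel_size
  if (length(dim(arr)) != 3L) stop("write_nifti expects a 3D array", call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))

  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wpad <- function(n) writeBin(raw(n), con)

  wi(NIFTI_HDR_SIZE, 4L)            # sizeof_hdr
  wpad(36L)                         # data_type, db_name, extents, session_error, regular, dim_info
  wi(c(3L, dim(arr), 1L, 1L, 1L, 1L), 2L)  # dim[8]
  wf(c(0, 0, 0))                    # intent_p1..p3
  wi(0L, 2L)                        # intent_code
  wi(16L, 2L)                       # datatype = float32
  wi(32L, 2L)                       # bitpix
  wi(0L, 2L)                        # slice_start
  wf(c(1, voxel_size, 1, 1, 1, 1))  # pixdim[8] (qfac = 1)
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2L); wpad(2L)              # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4L)                 # glmax, glmin
  wpad(104L)                        # descrip[80] + aux_file[24]
  wi(c(0L, 1L), 2L)                 # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))           # quatern/qoffset
  wf(c(voxel_size[1], 0, 0, 0))     # srow_x
  wf(c(0, voxel_size[2], 0, 0))     # srow_y
  wf(c(0, 0, voxel_size[3], 0))     # srow_z
  wpad(16L)                         # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  wpad(4L)                          # extension flag
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports 3D single-file NIfTI-1 images with uint8, int16, int32, float32 or
#' float64 data, either endianness, optional gzip compression, and
#' `scl_slope`/`scl_inter` rescaling.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param subject_id,session_id identifiers attached to the returned volume.
#' @return A [gm_volume()].
#' @export
read_nifti <- function(path, subject_id = NA_character_, session_id = NA_character_) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  chunks <- list()
  repeat {
    b <- readBin(con, "raw", n = 1048576L)
    if (length(b) == 0L) break
    chunks[[length(chunks) + 1L]] <- b
  }
  bytes <- do.call(c, chunks)
  if (length(bytes) < NIFTI_HDR_SIZE) stop("truncated NIfTI header: ", path, call. = FALSE)

  endian <- "little"
  rd <- function(off, what, n, size) {
    readBin(bytes[(off + 1L):length(bytes)], what, n = n, size = size, endian = endian)
  }
  if (rd(0L, "integer", 1L, 4L) != NIFTI_HDR_SIZE) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L) != NIFTI_HDR_SIZE) {
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
    }
  }
  dim_field <- rd(40L, "integer", 8L, 2L)
  ndim <- dim_field[1L]
  if (ndim < 3L) stop("expected a 3D NIfTI volume, got ndim = ", ndim, call. = FALSE)
  dims <- dim_field[2:4]
  extra <- if (ndim > 3L) dim_field[5:(1L + ndim)] else integer(0)
  if (any(extra > 1L)) {
    stop("expected a 3D NIfTI volume, got dims ",
         paste(dim_field[2:(1 + ndim)], collapse = "x"), call. = FALSE)
  }
  datatype <- rd(70L, "integer", 1L, 2L)
  pixdim <- rd(76L, "numeric", 8L, 4L)
  vox_offset <- rd(108L, "numeric", 1L, 4L)
  scl_slope <- rd(112L, "numeric", 1L, 4L)
  scl_inter <- rd(116L, "numeric", 1L, 4L)

  n <- prod(dims)
  off <- as.integer(round(vox_offset))
  payload <- bytes[(off + 1L):length(bytes)]
  dat <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(payload, "integer", n = n, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(payload, "integer", n = n, size = 2L, endian = endian)),
    "8"  = as.numeric(readBin(payload, "integer", n = n, size = 4L, endian = endian)),
    "16" = readBin(payload, "numeric", n = n, size = 4L, endian = endian),
    "64" = readBin(payload, "numeric", n = n, size = 8L, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype, " in ", path, call. = FALSE)
  )
  if (length(dat) < n) stop("truncated NIfTI data in ", path, call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    dat <- dat * scl_slope + scl_inter
  }
  gm_volume(array(dat, dim = dims), voxel_size = pixdim[2:4],
            subject_id = subject_id, session_id = session_id)
}
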