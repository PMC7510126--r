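# Minimal NIfTI-1 single-file (.nii / .nii.gz) volume I/O.
#
# Only the subset of the format the pipeline needs: 3-D volumes, scalar
# datatypes (uint8, int16, int32, uint16, float32, float64), pixdim voxel
# sizes, scl_slope/scl_inter scaling, either endianness on read,
# little-endian canonical sform on write. Orientation handling beyond the
# diagonal voxel-size affine is out of scope: inputs are assumed already
# aligned on one grid.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L, uint16 = 512L)
NIFTI_BITPIX <- c(uint8 = 8L, int16 = 16L, int32 = 32L, float32 = 32L,
                  float64 = 64L, uint16 = 16L)

read_all_raw <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  chunks <- list()
  repeat {
    x <- readBin(con, raw(), 1048576L)
    if (length(x) == 0L) break
    chunks[[length(chunks) + 1L]] <- x
  }
  do.call(c, chunks)
}

#' Read a NIfTI-1 volume
#'
#' Minimal single-file NIfTI-1 reader for aligned analysis-grid volumes.
#' Applies `scl_slope`/`scl_inter` when set. Orientation metadata beyond the
#' voxel size is ignored (inputs must already share one grid).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return numeric array (3-D) with attribute `voxel_size_mm` (length 3).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  buf <- read_all_raw(path)
  if (length(buf) < 352L) stop("not a NIfTI-1 file (too short): ", path, call. = FALSE)
  endian <- "little"
  if (readBin(buf[1:4], integer(), 1L, endian = endian) != 348L) {
    endian <- "big"
    if (readBin(buf[1:4], integer(), 1L, endian = endian) != 348L) {
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
    }
  }
  at <- function(off, what, n, size) {
    readBin(buf[(off + 1L):(off + n * size)], what, n, size = size,
            endian = endian)
  }
  magic <- rawToChar(buf[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("unsupported NIfTI magic '", magic, "' in ", path, call. = FALSE)
  }
  dim_field <- at(40L, integer(), 8L, 2L)
  ndim <- dim_field[1L]
  if (ndim < 1L || ndim > 7L) stop("corrupt dim field in ", path, call. = FALSE)
  dims <- pmax(dim_field[2L:(1L + ndim)], 1L)
  datatype <- at(70L, integer(), 1L, 2L)
  pixdim <- at(76L, numeric(), 8L, 4L)
  vox_offset <- at(108L, numeric(), 1L, 4L)
  scl_slope <- at(112L, numeric(), 1L, 4L)
  scl_inter <- at(116L, numeric(), 1L, 4L)

  n <- prod(dims)
  start <- as.integer(vox_offset)
  dt_name <- names(NIFTI_DT)[match(datatype, unlist(NIFTI_DT))]
  if (is.na(dt_name)) {
    stop(sprintf("unsupported NIfTI datatype code %d in %s", datatype, path),
         call. = FALSE)
  }
  size <- NIFTI_BITPIX[[dt_name]] / 8L
  slice <- buf[(start + 1L):(start + n * size)]
  vals <- switch(dt_name,
    uint8 = readBin(slice, integer(), n, size = 1L, signed = FALSE, endian = endian),
    int16 = readBin(slice, integer(), n, size = 2L, signed = TRUE, endian = endian),
    uint16 = readBin(slice, integer(), n, size = 2L, signed = FALSE, endian = endian),
    int32 = readBin(slice, integer(), n, size = 4L, endian = endian),
    float32 = readBin(slice, numeric(), n, size = 4L, endian = endian),
    float64 = readBin(slice, numeric(), n, size = 8L, endian = endian))
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  img <- array(vals, dims)
  attr(img, "voxel_size_mm") <- abs(pixdim[2:4])
  img
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3-D array as a little-endian single-file NIfTI-1 volume with a
#' diagonal sform affine built from the voxel size. NA values are stored as
#' NaN for float datatypes and rejected for integer datatypes.
#'
#' @param img 3-D numeric array.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param voxel_size_mm voxel edge lengths, mm (length 3).
#' @param datatype one of `"float32"` (default), `"float64"`, `"int16"`,
#'   `"uint8"`.
#' @param descrip up to 79 characters stored in the header description.
#' @return the path, invisibly.
#' @export
write_nifti <- function(img, path, voxel_size_mm = c(1, 1, 1),
                        datatype = "float32", descrip = "cpasl") {
  if (length(dim(img)) != 3L) stop("img must be a 3-D array", call. = FALSE)
  if (!datatype %in% c("float32", "float64", "int16", "uint8")) {
    stop("unsupported write datatype: ", datatype, call. = FALSE)
  }
  if (datatype %in% c("int16", "uint8")) {
    if (anyNA(img)) stop("NA values cannot be stored in integer datatypes",
                         call. = FALSE)
    rng <- if (datatype == "int16") c(-32768, 32767) else c(0, 255)
    if (min(img) < rng[1L] || max(img) > rng[2L]) {
      stop("values out of range for ", datatype, call. = FALSE)
    }
  }
  dims <- dim(img)
  dt_code <- NIFTI_DT[[datatype]]
  bitpix <- NIFTI_BITPIX[[datatype]]

  rc <- rawConnection(raw(0L), "wb")
  rc_open <- TRUE
  on.exit(if (rc_open) close(rc), add = TRUE)
  wi32 <- function(x) writeBin(as.integer(x), rc, size = 4L, endian = "little")
  wi16 <- function(x) writeBin(as.integer(x), rc, size = 2L, endian = "little")
  wf32 <- function(x) writeBin(as.numeric(x), rc, size = 4L, endian = "little")
  wpad <- function(n) writeBin(raw(n), rc)
  wstr <- function(s, n) {
    b <- charToRaw(substr(s, 1L, n - 1L))
    writeBin(c(b, raw(n - length(b))), rc)
  }

  wi32(348L)                      # sizeof_hdr
  wpad(10L + 18L + 4L + 2L + 1L)  # data_type, db_name, extents, session_error, regular
  wpad(1L)                        # dim_info
  wi16(c(3L, dims, 1L, 1L, 1L, 1L))          # dim[8]
  wf32(c(0, 0, 0)); wi16(0L)      # intent_p1..p3, intent_code
  wi16(dt_code); wi16(bitpix); wi16(0L)      # datatype, bitpix, slice_start
  wf32(c(1, voxel_size_mm, rep(0, 4)))       # pixdim[8] (qfac = 1)
  wf32(352)                       # vox_offset
  wf32(1); wf32(0)                # scl_slope, scl_inter
  wi16(0L); wpad(1L)              # slice_end, slice_code
  writeBin(as.raw(2L), rc)        # xyzt_units: mm
  wf32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  wi32(c(0L, 0L))                 # glmax, glmin
  wstr(descrip, 80L); wstr("", 24L)          # descrip, aux_file
  wi16(0L); wi16(1L)              # qform_code, sform_code
  wf32(rep(0, 6))                 # quatern_b/c/d, qoffset_x/y/z
  wf32(c(voxel_size_mm[1L], 0, 0, 0))        # srow_x
  wf32(c(0, voxel_size_mm[2L], 0, 0))        # srow_y
  wf32(c(0, 0, voxel_size_mm[3L], 0))        # srow_z
  wstr("", 16L)                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), rc) # magic
  wpad(4L)                        # no header extensions

  vals <- as.vector(img)
  switch(datatype,
    float32 = writeBin(as.numeric(vals), rc, size = 4L, endian = "little"),
    float64 = writeBin(as.numeric(vals), rc, size = 8L, endian = "little"),
    int16 = writeBin(as.integer(round(vals)), rc, size = 2L, endian = "little"),
    uint8 = writeBin(as.integer(round(vals)), rc, size = 1L, endian = "little"))

  payload <- rawConnectionValue(rc)
  close(rc); rc_open <- FALSE
  out <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  writeBin(payload, out)
  close(out)
  invisible(path)
}
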