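# Minimal NIfTI-1 I/O.  No NIfTI package is assumed; this writer/reader
# covers the subset the pipeline produces: single-file .nii / .nii.gz,
# little-endian, 3D/4D, float32/float64/int32/int16/uint8, sform affine.

NIFTI_DTYPES <- list(
  uint8   = list(code = 2L,   bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,   bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,   bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L,  bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L,  bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

#' Volume record: array data plus spatial metadata
#'
#' Thin container pairing a 3D/4D array with its voxel-to-world affine,
#' a units string and an optional validity mask (voxels where the value is
#' defined; fitted maps use NA outside it).
#'
#' @param data numeric or logical array, 3 or 4 dimensions.
#' @param affine 4x4 voxel-to-world matrix (mm); must be invertible.
#' @param units free-text units tag (e.g. "ms", "fraction", "percent").
#' @param modality modality tag (e.g. "mwf_g", "qt1").
#' @param validity optional logical array matching the spatial grid.
#' @return an object of class `qm_volume`.
#' @export
volume_record <- function(data, affine = diag(4), units = "", modality = "",
                          validity = NULL) {
  stopifnot(is.array(data), length(dim(data)) %in% c(3L, 4L))
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  if (!is.null(validity))
    stopifnot(identical(dim(validity)[1:3], dim(data)[1:3]))
  structure(list(data = data, affine = affine, units = units,
                 modality = modality, validity = validity),
            class = "qm_volume")
}

#' @export
print.qm_volume <- function(x, ...) {
  cat("<qm_volume>", x$modality, paste(dim(x$data), collapse = "x"),
      if (nzchar(x$units)) paste0("[", x$units, "]") else "", "\n")
  invisible(x)
}

diag_affine <- function(voxel_size) {
  a <- diag(4)
  a[1, 1] <- voxel_size[1]; a[2, 2] <- voxel_size[2]; a[3, 3] <- voxel_size[3]
  a
}

raw_to_string <- function(r) {
  z <- which(r == as.raw(0))
  rawToChar(r[seq_len(if (length(z)) z[1] - 1L else length(r))])
}

pad_char <- function(s, n) {
  r <- charToRaw(substr(s, 1L, n))
  c(r, raw(n - length(r)))
}

#' Write a volume to a NIfTI-1 file
#'
#' @param record a `qm_volume`, or a bare array (paired with `affine`).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param affine affine used when `record` is a bare array.
#' @param dtype on-disk type, one of `"float32"`, `"float64"`, `"uint8"`,
#'   `"int16"`, `"int32"`. Masks/labels default to `uint8`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(record, path, affine = diag(4), dtype = NULL) {
  if (!inherits(record, "qm_volume"))
    record <- volume_record(if (is.logical(record)) record else record,
                            affine = affine)
  x <- record$data
  if (is.null(dtype))
    dtype <- if (is.logical(x) || (is.integer(x) && max(abs(x), 0L, na.rm = TRUE) < 256))
      "uint8" else "float32"
  dt <- NIFTI_DTYPES[[dtype]]
  if (is.null(dt)) stop("unsupported dtype: ", dtype)
  dims <- dim(x)
  ndim <- length(dims)
  dim8 <- rep(1L, 8); dim8[1] <- ndim; dim8[1 + seq_len(ndim)] <- dims
  vox <- sqrt(colSums(record$affine[1:3, 1:3]^2))
  pixdim <- rep(0, 8); pixdim[1] <- 1; pixdim[2:4] <- vox
  if (ndim == 4L) pixdim[5] <- 1

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(v, size) writeBin(v, con, size = size, endian = "little")
  wb(348L, 4L)
  writeBin(raw(36), con)                       # unused legacy fields
  wb(as.integer(dim8), 2L)                     # dim
  wb(c(0, 0, 0), 4L)                           # intent_p1..p3 (float)
  wb(c(0L, dt$code, dt$bitpix, 0L), 2L)        # intent_code, datatype, bitpix, slice_start
  wb(as.numeric(pixdim), 4L)
  wb(352, 4L)                                  # vox_offset (float)
  wb(c(1, 0), 4L)                              # scl_slope, scl_inter
  wb(0L, 2L); writeBin(raw(2), con)            # slice_end, slice_code+xyzt_units
  wb(c(0, 0, 0, 0), 4L)                        # cal_max/min, slice_dur, toffset
  wb(c(0L, 0L), 4L)                            # glmax, glmin
  writeBin(pad_char(paste0("units=", record$units), 80L), con)
  writeBin(raw(24), con)                       # aux_file
  wb(c(0L, 1L), 2L)                            # qform_code=0, sform_code=1
  wb(rep(0, 6), 4L)                            # quaternion + qoffset
  wb(as.numeric(t(record$affine[1:3, ])), 4L)  # srow_x/y/z
  writeBin(pad_char(substr(record$modality, 1L, 15L), 16L), con)
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  writeBin(raw(4), con)                        # no extensions
  vals <- as.vector(x)
  if (dtype %in% c("uint8", "int16", "int32")) {
    vals[is.na(vals)] <- 0
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Accepts plain and gzip-compressed single-file NIfTI-1.
#'
#' @param path file path.
#' @return a [volume_record()] (`qm_volume`); the units tag round-trips via
#'   the header description field and the modality via `intent_name`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rb")                    # transparently handles plain files
  on.exit(close(con))
  rb <- function(what, n, size, signed = TRUE)
    readBin(con, what, n = n, size = size, endian = "little", signed = signed)
  hdr_size <- rb("integer", 1L, 4L)
  if (!identical(hdr_size, 348L))
    stop("malformed NIfTI header in ", path, " (sizeof_hdr = ", hdr_size,
         "; big-endian or NIfTI-2 files are not supported)")
  invisible(rb("raw", 36L, 1L))
  dim8 <- rb("integer", 8L, 2L)
  invisible(rb("double", 3L, 4L))
  invisible(rb("integer", 1L, 2L))             # intent_code
  datatype <- rb("integer", 1L, 2L)
  invisible(rb("integer", 2L, 2L))             # bitpix, slice_start
  pixdim <- rb("double", 8L, 4L)
  vox_offset <- rb("double", 1L, 4L)
  scl_slope <- rb("double", 1L, 4L)
  scl_inter <- rb("double", 1L, 4L)
  invisible(rb("integer", 1L, 2L)); invisible(rb("raw", 2L, 1L))
  invisible(rb("double", 4L, 4L))
  invisible(rb("integer", 2L, 4L))
  descrip <- raw_to_string(rb("raw", 80L, 1L))
  invisible(rb("raw", 24L, 1L))
  qform_code <- rb("integer", 1L, 2L)
  sform_code <- rb("integer", 1L, 2L)
  invisible(rb("double", 6L, 4L))
  srow <- matrix(rb("double", 12L, 4L), nrow = 3, byrow = TRUE)
  intent_name <- raw_to_string(rb("raw", 16L, 1L))
  magic <- raw_to_string(rb("raw", 4L, 1L))
  if (!magic %in% c("n+1", "ni1"))
    stop("malformed NIfTI header in ", path, " (bad magic '", magic, "')")

  ndim <- dim8[1]
  if (!ndim %in% c(3L, 4L)) stop("only 3D/4D volumes supported, got ndim=", ndim)
  dims <- dim8[1 + seq_len(ndim)]
  n <- prod(dims)
  seek(con, vox_offset)
  key <- names(NIFTI_DTYPES)[vapply(NIFTI_DTYPES, function(d) d$code == datatype,
                                    logical(1))]
  if (length(key) != 1L) stop("unsupported NIfTI datatype code ", datatype)
  dt <- NIFTI_DTYPES[[key]]
  vals <- rb(dt$what, n, dt$size, signed = dt$signed)
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  data <- array(vals, dim = dims)
  affine <- diag(4)
  if (sform_code > 0) affine[1:3, ] <- srow
  else { affine[1, 1] <- pixdim[2]; affine[2, 2] <- pixdim[3]; affine[3, 3] <- pixdim[4] }
  units <- if (startsWith(descrip, "units=")) sub("^units=", "", descrip) else ""
  volume_record(data, affine, units = units, modality = intent_name)
}

#' Check that two volumes share a grid
#' @param a,b `qm_volume` objects or arrays.
#' @param tol affine tolerance (mm).
#' @return TRUE invisibly; errors on mismatch.
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  da <- if (inherits(a, "qm_volume")) dim(a$data) else dim(a)
  db <- if (inherits(b, "qm_volume")) dim(b$data) else dim(b)
  if (!identical(da[1:3], db[1:3]))
    stop("grid mismatch: ", paste(da[1:3], collapse = "x"), " vs ",
         paste(db[1:3], collapse = "x"))
  if (inherits(a, "qm_volume") && inherits(b, "qm_volume") &&
      max(abs(a$affine - b$affine)) > tol)
    stop("affine mismatch between volumes")
  invisible(TRUE)
}
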