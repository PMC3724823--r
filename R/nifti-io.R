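# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is available in the supported dependency set, so the
# format is handled directly. Scope: single-file .nii / .nii.gz, 3D or 4D,
# datatypes uint8 / int16 / int32 / float32 / float64, little- or big-endian
# on read, little-endian float32 (data) or int16 (labels) on write, sform
# affine (code >= 1) preferred with pixdim fallback. Everything the pipeline
# writes is re-readable by this reader (closure property, tested).

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE, bitpix = 8),
  `4`  = list(what = "integer", size = 2, signed = TRUE,  bitpix = 16),
  `8`  = list(what = "integer", size = 4, signed = TRUE,  bitpix = 32),
  `16` = list(what = "numeric", size = 4, signed = TRUE,  bitpix = 32),
  `64` = list(what = "numeric", size = 8, signed = TRUE,  bitpix = 64)
)

nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (3D or 4D array), `affine` (4x4
#'   voxel-to-world matrix, RAS), and `voxel_size` (mm per voxel along the
#'   three spatial axes).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348)
  if (length(hdr_raw) < 348) stop("truncated NIfTI header in ", path)
  sizeof <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = "little")
  endian <- "little"
  if (sizeof != 348) {
    sizeof_b <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = "big")
    if (sizeof_b != 348) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
    endian <- "big"
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (magic != "n+1") stop("unsupported NIfTI magic '", magic, "' in ", path)
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                     "integer", n, 2, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "numeric", n, 4, endian = endian)
  dim0 <- rd_i16(40, 8)
  ndim <- dim0[1]
  if (!ndim %in% c(3, 4)) {
    stop("only 3D/4D NIfTI supported, got ", ndim, "D in ", path)
  }
  dims <- dim0[2:(1 + ndim)]
  datatype <- rd_i16(70, 1)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  sform_code <- rd_i16(254, 1)
  srow <- matrix(rd_f32(280, 12), 3, 4, byrow = TRUE)

  n <- prod(dims)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(vals, dim = dims)

  affine <- diag(4)
  if (sform_code >= 1) {
    affine[1:3, ] <- srow
  } else {
    affine[1, 1] <- pixdim[2]
    affine[2, 2] <- pixdim[3]
    affine[3, 3] <- pixdim[4]
  }
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  list(data = data, affine = affine, voxel_size = voxel_size)
}

#' Write a NIfTI-1 volume
#'
#' @param data 3D or 4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-world matrix (RAS); stored as the sform.
#' @param datatype `"float32"` (default) or `"int16"` for label/mask volumes.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4),
                        datatype = c("float32", "int16")) {
  datatype <- match.arg(datatype)
  ndim <- length(dim(data))
  if (!ndim %in% c(3, 4)) stop("data must be a 3D or 4D array")
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4x4")
  code <- if (datatype == "float32") 16L else 4L
  dt <- NIFTI_DTYPES[[as.character(code)]]
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))

  hdr <- raw(348)
  put <- function(off, bytes) {
    hdr[(off + 1):(off + length(bytes))] <<- bytes
  }
  w_i32 <- function(x) writeBin(as.integer(x), raw(), 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), raw(), 2, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), raw(), 4, endian = "little")
  put(0, w_i32(348))
  dim8 <- c(ndim, dim(data), rep(1L, 7 - ndim))
  put(40, w_i16(dim8))
  put(70, w_i16(code))
  put(72, w_i16(dt$bitpix))
  put(76, w_f32(c(1, voxel_size, rep(1, 4))))
  put(108, w_f32(352))            # vox_offset
  put(112, w_f32(1))              # scl_slope
  put(123, as.raw(10L))           # xyzt_units: mm
  put(252, w_i16(1))              # qform_code (identity quaternion)
  put(254, w_i16(1))              # sform_code
  put(280, w_f32(t(affine[1:3, ])))
  put(344, c(charToRaw("n+1"), as.raw(0L)))

  con <- nii_connection(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)           # extension flag
  if (datatype == "float32") {
    writeBin(as.numeric(data), con, 4, endian = "little")
  } else {
    v <- as.integer(round(data))
    if (any(v < -32768 | v > 32767)) stop("values out of int16 range")
    writeBin(v, con, 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary mask volume
#'
#' @param path NIfTI path.
#' @param any_nonzero If `FALSE` (strict, default) values other than 0/1 are
#'   rejected; if `TRUE` any nonzero voxel is treated as inside.
#' @return List with logical-valued `data` (0/1 array), `affine`,
#'   `voxel_size`.
#' @export
read_mask <- function(path, any_nonzero = FALSE) {
  v <- read_nifti(path)
  u <- unique(as.vector(v$data))
  if (!any_nonzero && !all(u %in% c(0, 1))) {
    stop("mask ", path, " contains values other than 0/1 (",
         paste(utils::head(setdiff(u, c(0, 1)), 5), collapse = ", "),
         "); pass any_nonzero = TRUE to accept")
  }
  v$data <- (v$data != 0) * 1
  v
}
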