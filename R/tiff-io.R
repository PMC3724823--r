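# Minimal multi-page TIFF I/O (little-endian, uncompressed, 32-bit float,
# single strip per page) and a small PNG writer for the HSV orientation
# export. No TIFF/PNG package exists in the supported dependency set; the
# subset written here is exactly the subset read back (round-trip tested)
# and opens in standard viewers.

w_u16 <- function(x) writeBin(as.integer(x), raw(), 2, endian = "little")
w_u32 <- function(x) writeBin(as.integer(x), raw(), 4, endian = "little")

tiff_ifd_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits inline (count 1)
  val <- if (type == 3) c(w_u16(value), w_u16(0)) else w_u32(value)
  c(w_u16(tag), w_u16(type), w_u32(count), val)
}

#' Write a multi-page TIFF stack
#'
#' Grayscale 32-bit float, uncompressed, one page per matrix.
#'
#' @param images List of numeric matrices (identical shapes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(images, path) {
  if (!length(images)) stop("no images to write")
  shp <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), shp), logical(1)))) {
    stop("all pages must have the same shape")
  }
  h <- shp[1]; w <- shp[2]
  n_entries <- 10L
  ifd_size <- 2 + n_entries * 12 + 4
  data_size <- 4 * h * w

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), w_u16(42), w_u32(8)), con)
  offset <- 8
  for (p in seq_along(images)) {
    data_off <- offset + ifd_size
    next_ifd <- if (p < length(images)) data_off + data_size else 0
    entries <- c(
      tiff_ifd_entry(256, 4, 1, w),          # ImageWidth
      tiff_ifd_entry(257, 4, 1, h),          # ImageLength
      tiff_ifd_entry(258, 3, 1, 32),         # BitsPerSample
      tiff_ifd_entry(259, 3, 1, 1),          # Compression: none
      tiff_ifd_entry(262, 3, 1, 1),          # Photometric: BlackIsZero
      tiff_ifd_entry(273, 4, 1, data_off),   # StripOffsets
      tiff_ifd_entry(277, 3, 1, 1),          # SamplesPerPixel
      tiff_ifd_entry(278, 4, 1, h),          # RowsPerStrip
      tiff_ifd_entry(279, 4, 1, data_size),  # StripByteCounts
      tiff_ifd_entry(339, 3, 1, 3)           # SampleFormat: IEEE float
    )
    writeBin(c(w_u16(n_entries), entries, w_u32(next_ifd)), con)
    writeBin(as.numeric(t(images[[p]])), con, 4, endian = "little")
    offset <- data_off + data_size
  }
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_tiff_stack()]
#'
#' @param path TIFF path.
#' @return List of numeric matrices.
#' @export
read_tiff_stack <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw_all[1:2]) != "II") {
    stop("only little-endian TIFF supported: ", path)
  }
  rd_u16 <- function(off) readBin(raw_all[(off + 1):(off + 2)], "integer",
                                  1, 2, signed = FALSE, endian = "little")
  rd_u32 <- function(off) {
    v <- readBin(raw_all[(off + 1):(off + 4)], "integer", 1, 4,
                 endian = "little")
    if (v < 0) v <- v + 2^32
    v
  }
  ifd_off <- rd_u32(4)
  images <- list()
  while (ifd_off != 0) {
    n <- rd_u16(ifd_off)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- rd_u16(base)
      type <- rd_u16(base + 2)
      val <- if (type == 3) rd_u16(base + 8) else rd_u32(base + 8)
      tags[[as.character(tag)]] <- val
    }
    g <- function(t, default = NULL) tags[[as.character(t)]] %||% default
    if (g(259, 1) != 1) stop("compressed TIFF not supported")
    if (g(258, 32) != 32 || g(339, 3) != 3) {
      stop("only 32-bit float TIFF supported")
    }
    w <- g(256); h <- g(257); so <- g(273)
    vals <- readBin(raw_all[(so + 1):(so + 4 * w * h)], "numeric",
                    w * h, 4, endian = "little")
    images[[length(images) + 1]] <- t(matrix(vals, w, h))
    ifd_off <- rd_u32(ifd_off + 2 + n * 12)
  }
  images
}

#' Write a PLI stack as multi-page TIFF with a JSON protocol sidecar
#'
#' @param stack A `pli_stack`.
#' @param path TIFF output path; the protocol goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_pli_stack <- function(stack, path) {
  stopifnot(inherits(stack, "pli_stack"))
  write_tiff_stack(stack$images, path)
  jsonlite::write_json(unclass(stack$protocol), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PLI stack written by [write_pli_stack()]
#'
#' @param path TIFF path with `<path>.json` protocol sidecar.
#' @return A `pli_stack`.
#' @export
read_pli_stack <- function(path) {
  images <- read_tiff_stack(path)
  pj <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  proto <- pli_protocol(mode = pj$mode, rotation_angles = pj$rotation_angles,
                        pixel_size = pj$pixel_size,
                        section_thickness = pj$section_thickness,
                        delta_max = pj$delta_max)
  if (length(images) != length(proto$rotation_angles)) {
    stop("page count (", length(images), ") does not match protocol (",
         length(proto$rotation_angles), " angles)")
  }
  structure(list(images = images, protocol = proto), class = "pli_stack")
}

# --- PNG (8-bit RGB, for the HSV-coded orientation export) ---------------

adler32 <- function(bytes) {
  MOD <- 65521
  a <- 1; b <- 0
  v <- as.integer(bytes)
  # chunked to keep cumulative sums inside double precision
  step <- 3000
  for (i in seq(1, length(v), by = step)) {
    j <- min(length(v), i + step - 1)
    seg <- v[i:j]
    ca <- cumsum(seg)
    b <- (b + length(seg) * a + sum(ca %% MOD)) %% MOD
    a <- (a + ca[length(seg)]) %% MOD
  }
  as.raw(c(bitwAnd(bitwShiftR(b, 8), 255L), bitwAnd(b, 255L),
           bitwAnd(bitwShiftR(a, 8), 255L), bitwAnd(a, 255L)))
}

crc32_png <- function(bytes) {
  # R exposes CRC-32 through memCompress's gzip trailer
  gz <- memCompress(bytes, "gzip")
  n <- length(gz)
  rev(gz[(n - 7):(n - 4)])   # gzip stores CRC32 little-endian; PNG wants big
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  len <- writeBin(length(data), raw(), 4, endian = "big")
  c(len, body, crc32_png(body))
}

#' Write an 8-bit RGB PNG
#'
#' @param rgb Array h x w x 3 with values in [0, 1].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_png_rgb <- function(rgb, path) {
  d <- dim(rgb)
  if (length(d) != 3 || d[3] != 3) stop("rgb must be h x w x 3")
  h <- d[1]; w <- d[2]
  px <- array(as.raw(pmin(255, pmax(0, round(rgb * 255)))), dim = d)
  # scanlines: filter byte 0 + RGB triples, row-major
  rows <- lapply(seq_len(h), function(r) {
    c(as.raw(0), as.vector(t(matrix(c(px[r, , 1], px[r, , 2], px[r, , 3]),
                                    w, 3))))
  })
  payload <- do.call(c, rows)
  gz <- memCompress(payload, "gzip")
  zlib <- c(as.raw(c(0x78, 0x01)), gz[11:(length(gz) - 8)], adler32(payload))
  ihdr <- c(writeBin(as.integer(w), raw(), 4, endian = "big"),
            writeBin(as.integer(h), raw(), 4, endian = "big"),
            as.raw(c(8, 2, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' HSV-coded orientation image
#'
#' Direction maps to hue over the 180-degree color circle, inclination to
#' saturation (in-plane fibers saturated, steep fibers washed out), and the
#' maximum-intensity map to value; invalid pixels are black.
#'
#' @param orient A `pli_orientation`.
#' @param path Optional PNG output path.
#' @return RGB array h x w x 3 in [0, 1], invisibly if `path` given.
#' @export
orientation_hsv_map <- function(orient, path = NULL) {
  stopifnot(inherits(orient, "pli_orientation"))
  h <- orient$direction / 180
  s <- 1 - orient$inclination / 90
  v <- orient$max_intensity
  v <- v / max(v, na.rm = TRUE)
  bad <- !orient$valid | is.na(h) | is.na(s)
  h[bad] <- 0; s[bad] <- 0; v[bad] <- 0
  cols <- grDevices::hsv(pmin(1, pmax(0, h)), pmin(1, pmax(0, s)),
                         pmin(1, pmax(0, v)))
  rgbm <- t(grDevices::col2rgb(cols)) / 255
  out <- array(rgbm, dim = c(dim(orient$direction), 3))
  if (!is.null(path)) {
    write_png_rgb(out, path)
    return(invisible(out))
  }
  out
}
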