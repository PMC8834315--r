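# Minimal baseline TIFF codec for single-sample grayscale images.
#
# Scope: uncompressed (compression tag 1), one sample per pixel, 8- or
# 16-bit unsigned integer or 32-bit IEEE float, strip-organised, either
# byte order.  This covers the plain grayscale exports of the common
# microscopy tool chains; anything fancier (LZW, tiles, RGB, palettes)
# is rejected with a clear error rather than mis-read.

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

read_uint <- function(con, size, endian) {
  v <- readBin(con, "integer", n = 1L, size = size,
               signed = size >= 4L, endian = endian)
  if (size == 4L && v < 0) v <- v + 2^32
  v
}

# Read the value list of one IFD entry.
tiff_entry_values <- function(con, entry, endian) {
  size <- TIFF_TYPE_SIZES[entry$type]
  total <- size * entry$count
  if (total > 4L) seek(con, entry$offset)
  if (entry$type %in% c(3L, 4L)) {
    vapply(seq_len(entry$count), function(i) read_uint(con, size, endian),
           numeric(1))
  } else if (entry$type == 1L) {
    as.numeric(readBin(con, "integer", n = entry$count, size = 1L,
                       signed = FALSE, endian = endian))
  } else {
    # types we never need (rationals, ascii); caller ignores them
    NULL
  }
}

#' Read a grayscale TIFF image
#'
#' Reads an uncompressed single-channel TIFF (8/16-bit unsigned integer
#' or 32-bit float, little- or big-endian) into a numeric matrix,
#' row-major with origin at the top-left.  Multi-page files are rejected
#' unless \code{page} selects one plane explicitly.
#'
#' @param path file path.
#' @param page plane index (1-based) for multi-page files; \code{NULL}
#'   (default) requires a single-page file.
#' @return numeric matrix of pixel intensities (rows = image rows).
#' @export
read_tiff_gray <- function(path, page = NULL) {
  if (!file.exists(path))
    abort_validation(sprintf("TIFF not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  order_mark <- readChar(con, 2L, useBytes = TRUE)
  endian <- switch(order_mark, II = "little", MM = "big",
                   abort_parse(sprintf("not a TIFF (byte-order mark '%s'): %s",
                                       order_mark, path)))
  if (read_uint(con, 2L, endian) != 42L)
    abort_parse(sprintf("not a TIFF (bad magic): %s", path))
  ifd_offset <- read_uint(con, 4L, endian)

  # walk the IFD chain
  offsets <- numeric(0)
  while (ifd_offset != 0) {
    offsets <- c(offsets, ifd_offset)
    seek(con, ifd_offset)
    n <- read_uint(con, 2L, endian)
    seek(con, ifd_offset + 2 + 12 * n)
    ifd_offset <- read_uint(con, 4L, endian)
    if (length(offsets) > 4096L) abort_parse("corrupt TIFF: IFD chain loop")
  }
  if (is.null(page)) {
    if (length(offsets) > 1L)
      abort_validation(sprintf(
        "multi-page TIFF (%d pages): pass 'page' to select a plane: %s",
        length(offsets), path))
    page <- 1L
  }
  if (page < 1L || page > length(offsets))
    abort_validation(sprintf("page %d out of range (1..%d): %s",
                             page, length(offsets), path))

  seek(con, offsets[page])
  n <- read_uint(con, 2L, endian)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    seek(con, offsets[page] + 2 + 12 * (i - 1))
    tag   <- read_uint(con, 2L, endian)
    type  <- read_uint(con, 2L, endian)
    count <- read_uint(con, 4L, endian)
    off   <- seek(con)  # value field position
    entries[[i]] <- list(tag = tag, type = type, count = count,
                         value_pos = off)
  }
  get_tag <- function(tag, default = NULL) {
    for (e in entries) {
      if (e$tag == tag) {
        seek(con, e$value_pos)
        if (TIFF_TYPE_SIZES[e$type] * e$count > 4L)
          e$offset <- read_uint(con, 4L, endian)  # value stored out of line
        return(tiff_entry_values(con, e, endian))
      }
    }
    default
  }

  width  <- get_tag(256L); height <- get_tag(257L)
  if (is.null(width) || is.null(height))
    abort_parse(sprintf("TIFF lacks image dimensions: %s", path))
  bits   <- get_tag(258L, 1)
  compression <- get_tag(259L, 1)
  if (compression != 1)
    abort_validation(sprintf("unsupported TIFF compression %d (only 1): %s",
                             compression, path))
  spp <- get_tag(277L, 1)
  if (any(spp != 1))
    abort_validation(sprintf("not single-channel grayscale (%d samples): %s",
                             spp[1], path))
  photometric <- get_tag(262L, 1)
  if (!photometric %in% c(0, 1))
    abort_validation(sprintf("unsupported photometric %d: %s",
                             photometric, path))
  sample_format <- get_tag(339L, 1)
  strip_offsets <- get_tag(273L)
  if (is.null(strip_offsets)) abort_parse("TIFF lacks strip offsets")
  rows_per_strip <- get_tag(278L, height)
  byte_counts <- get_tag(279L)
  bytes_px <- bits / 8
  if (is.null(byte_counts))
    byte_counts <- pmin(rows_per_strip, height) * width * bytes_px

  if (!(bits == 8 && sample_format == 1) &&
      !(bits == 16 && sample_format == 1) &&
      !(bits == 32 && sample_format == 3))
    abort_validation(sprintf(
      "unsupported pixel type (%d-bit, sample format %d): %s",
      bits, sample_format, path))

  vals <- numeric(0)
  for (s in seq_along(strip_offsets)) {
    seek(con, strip_offsets[s])
    n_px <- byte_counts[s] / bytes_px
    chunk <- if (bits == 32) {
      readBin(con, "numeric", n = n_px, size = 4L, endian = endian)
    } else {
      readBin(con, "integer", n = n_px, size = bytes_px, signed = FALSE,
              endian = endian)
    }
    vals <- c(vals, as.numeric(chunk))
  }
  if (length(vals) < width * height)
    abort_parse(sprintf("truncated TIFF pixel data: %s", path))
  matrix(vals[seq_len(width * height)], nrow = height, ncol = width,
         byrow = TRUE)
}

#' Write a grayscale TIFF image
#'
#' Writes a numeric matrix as an uncompressed single-strip grayscale
#' TIFF (little-endian).  With \code{type = "auto"} integral data in
#' [0, 255] or [0, 65535] is stored as 8- or 16-bit unsigned integers,
#' anything else as 32-bit float.
#'
#' @param pixels numeric matrix (rows = image rows).
#' @param path output path.
#' @param type \code{"auto"}, \code{"uint8"}, \code{"uint16"} or
#'   \code{"float"}.
#' @return \code{path}, invisibly.
#' @export
write_tiff_gray <- function(pixels, path, type = c("auto", "uint8",
                                                   "uint16", "float")) {
  type <- match.arg(type)
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(!is.finite(pixels)))
    abort_validation("'pixels' must be a finite numeric matrix")
  v <- as.vector(t(pixels))  # row-major
  if (type == "auto") {
    type <- if (all(v == round(v)) && all(v >= 0)) {
      if (max(v) <= 255) "uint8" else if (max(v) <= 65535) "uint16"
      else "float"
    } else "float"
  }
  bits <- switch(type, uint8 = 8L, uint16 = 16L, float = 32L)
  fmt  <- if (type == "float") 3L else 1L
  if (type %in% c("uint8", "uint16") &&
      (any(v < 0) || any(v != round(v)) || max(v) > 2^bits - 1))
    abort_validation(sprintf("pixel values do not fit %s", type))

  h <- nrow(pixels); w <- ncol(pixels)
  bytes_px <- bits / 8
  data_bytes <- h * w * bytes_px
  data_offset <- 8L
  ifd_offset <- data_offset + data_bytes + (data_bytes %% 2L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(data_offset + data_bytes + (data_bytes %% 2L)), con,
           size = 4L, endian = "little")
  # pixel data (single strip)
  if (type == "uint8") {
    writeBin(as.integer(ifelse(v > 127, v - 256, v)), con, size = 1L,
             endian = "little")
  } else if (type == "uint16") {
    writeBin(as.integer(ifelse(v > 32767, v - 65536, v)), con, size = 2L,
             endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  }
  if (data_bytes %% 2L) writeBin(as.raw(0L), con)

  entry <- function(tag, type_id, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type_id), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type_id == 3L) {  # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  tags <- list(
    list(256L, 4L, w), list(257L, 4L, h), list(258L, 3L, bits),
    list(259L, 3L, 1L), list(262L, 3L, 1L), list(273L, 4L, data_offset),
    list(277L, 3L, 1L), list(278L, 4L, h), list(279L, 4L, data_bytes),
    list(339L, 3L, fmt))
  writeBin(length(tags), con, size = 2L, endian = "little")
  for (tg in tags) entry(tg[[1]], tg[[2]], 1L, tg[[3]])
  writeBin(0L, con, size = 4L, endian = "little")  # no next IFD
  invisible(path)
}
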