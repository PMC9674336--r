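# Minimal baseline-TIFF reader/writer.
#
# No TIFF package ships with this R installation, so the package carries a
# deliberately small implementation covering exactly what the pipeline
# exchanges: uncompressed, little-endian, single-sample-per-pixel grayscale
# rasters, 8/16-bit unsigned or 32-bit float, one strip per page, multi-page.
# Anything else (RGB, compression, tiles) is rejected with an explicit error.

TAG_WIDTH <- 256L; TAG_LENGTH <- 257L; TAG_BITS <- 258L; TAG_COMPRESSION <- 259L
TAG_PHOTOMETRIC <- 262L; TAG_STRIP_OFFSETS <- 273L; TAG_SPP <- 277L
TAG_ROWS_PER_STRIP <- 278L; TAG_STRIP_BYTES <- 279L; TAG_SAMPLE_FORMAT <- 339L

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

tiff_ifd_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits in the 4-byte field here
  val <- if (type == 3L) c(u16le(value), as.raw(c(0, 0))) else u32le(value)
  c(u16le(tag), u16le(type), u32le(count), val)
}

#' Write grayscale matrices as an uncompressed multi-page TIFF
#'
#' @param images a numeric matrix or a list of matrices (pages, in order).
#' @param path output file path.
#' @param bits 16 (unsigned integer, values rounded and clamped to 0..65535)
#'   or 32 (IEEE float, values written as-is).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(images, path, bits = 16) {
  if (is.matrix(images)) images <- list(images)
  if (!length(images)) stopf("no images to write")
  if (!bits %in% c(16, 32)) stopf("bits must be 16 or 32")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16le(42L)), con)
  # first IFD offset filled after layout: header(8) + all pixel data
  sizes <- vapply(images, function(m) length(m) * (bits / 8), 0)
  data_off <- 8 + c(0, cumsum(sizes))[seq_along(images)]
  ifd_bytes <- 2 + 10 * 12 + 4                     # entry count + entries + next ptr
  ifd_off <- 8 + sum(sizes) + (seq_along(images) - 1) * ifd_bytes
  writeBin(u32le(ifd_off[1]), con)
  for (m in images) {
    v <- t(m)                                      # TIFF stores rows consecutively
    if (bits == 16) {
      iv <- as.integer(pmin(pmax(round(v), 0), 65535))
      writeBin(iv, con, size = 2, endian = "little")
    } else {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    }
  }
  for (i in seq_along(images)) {
    m <- images[[i]]
    entries <- c(
      tiff_ifd_entry(TAG_WIDTH, 4L, 1L, ncol(m)),
      tiff_ifd_entry(TAG_LENGTH, 4L, 1L, nrow(m)),
      tiff_ifd_entry(TAG_BITS, 3L, 1L, bits),
      tiff_ifd_entry(TAG_COMPRESSION, 3L, 1L, 1L),
      tiff_ifd_entry(TAG_PHOTOMETRIC, 3L, 1L, 1L),
      tiff_ifd_entry(TAG_STRIP_OFFSETS, 4L, 1L, data_off[i]),
      tiff_ifd_entry(TAG_SPP, 3L, 1L, 1L),
      tiff_ifd_entry(TAG_ROWS_PER_STRIP, 4L, 1L, nrow(m)),
      tiff_ifd_entry(TAG_STRIP_BYTES, 4L, 1L, sizes[i]),
      tiff_ifd_entry(TAG_SAMPLE_FORMAT, 3L, 1L, if (bits == 32) 3L else 1L))
    nxt <- if (i < length(images)) ifd_off[i + 1] else 0L
    writeBin(c(u16le(10L), entries, u32le(nxt)), con)
  }
  invisible(path)
}

read_u16 <- function(raw, off, n = 1) {
  readBin(raw[(off + 1):(off + 2 * n)], "integer", n = n, size = 2,
          signed = FALSE, endian = "little")
}
read_u32 <- function(raw, off, n = 1) {
  v <- readBin(raw[(off + 1):(off + 4 * n)], "integer", n = n, size = 4,
               endian = "little")
  ifelse(v < 0, v + 2^32, v)
}

#' Read a grayscale (multi-page) TIFF
#'
#' Supports the subset written by [write_tiff()] plus uncompressed 8-bit
#' grayscale: little-endian, one sample per pixel, strip-based.
#'
#' @param path TIFF file path.
#' @return a list of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stopf("truncated TIFF: %s", path)
  if (rawToChar(raw[1:2]) != "II" || read_u16(raw, 2) != 42L)
    stopf("not a little-endian TIFF: %s", path)
  off <- read_u32(raw, 4)
  pages <- list()
  while (off != 0) {
    if (off + 2 > length(raw)) stopf("truncated TIFF (bad IFD offset): %s", path)
    n_entries <- read_u16(raw, off)
    tags <- list()
    for (k in seq_len(n_entries)) {
      e <- off + 2 + (k - 1) * 12
      tag <- read_u16(raw, e); type <- read_u16(raw, e + 2)
      count <- read_u32(raw, e + 4)
      val <- if (type == 3L) read_u16(raw, e + 8, min(count, 2))[1]
             else read_u32(raw, e + 8)
      # multi-valued strip arrays live at an offset; only single-strip files
      # are produced here, but tolerate count>1 by dereferencing
      if (count > 1 && tag %in% c(TAG_STRIP_OFFSETS, TAG_STRIP_BYTES)) {
        ptr <- read_u32(raw, e + 8)
        val <- if (type == 3L) read_u16(raw, ptr, count) else read_u32(raw, ptr, count)
      }
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    if (is.null(g(TAG_WIDTH)) || is.null(g(TAG_LENGTH)))
      stopf("TIFF page missing dimensions: %s", path)
    if (g(TAG_COMPRESSION, 1L) != 1L) stopf("compressed TIFF not supported: %s", path)
    if (g(TAG_SPP, 1L) != 1L)
      stopf("multi-sample (RGB) TIFF not supported, expected grayscale: %s", path)
    bits <- g(TAG_BITS, 8L)
    fmt <- g(TAG_SAMPLE_FORMAT, 1L)
    w <- g(TAG_WIDTH); h <- g(TAG_LENGTH)
    offs <- g(TAG_STRIP_OFFSETS); cnts <- g(TAG_STRIP_BYTES, w * h * bits / 8)
    if (is.null(offs)) stopf("TIFF page missing strip offsets: %s", path)
    buf <- unlist(lapply(seq_along(offs), function(i) {
      if (offs[i] + cnts[i] > length(raw)) stopf("truncated TIFF data: %s", path)
      raw[(offs[i] + 1):(offs[i] + cnts[i])]
    }))
    v <- if (fmt == 3L && bits == 32L) {
      readBin(buf, "numeric", n = w * h, size = 4, endian = "little")
    } else if (bits == 16L) {
      readBin(buf, "integer", n = w * h, size = 2, signed = FALSE, endian = "little")
    } else if (bits == 8L) {
      as.integer(buf[seq_len(w * h)])
    } else stopf("unsupported TIFF bit depth %d: %s", bits, path)
    pages[[length(pages) + 1]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    off <- read_u32(raw, off + 2 + n_entries * 12)
  }
  pages
}
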