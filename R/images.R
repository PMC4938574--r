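#' Calibrated greyscale image
#'
#' Container for a single-channel raster plus its physical pixel size. All
#' intensity and area computations in the package run on this object. Pixels
#' are stored as a numeric matrix indexed `[row, col]`; coordinates elsewhere
#' in the package are 0-based pixel-centre `(x = col - 1, y = row - 1)`.
#'
#' @param pixels numeric matrix of grey intensities. Integer images must lie in
#'   `[0, 255]` (8-bit) or `[0, 65535]` (16-bit); floating-point images must
#'   lie in the unit interval.
#' @param nm_per_px physical calibration, nanometres per pixel edge (> 0).
#' @param channel_label free-text channel tag, e.g. `"TEM"`, `"microspheres"`,
#'   `"CD31"`.
#' @param bits bit depth used when the image is written to disk: 8 or 16.
#' @return An object of class `CalibratedImage`.
#' @export
calibrated_image <- function(pixels, nm_per_px, channel_label = "TEM",
                             bits = NULL) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop_capmorph("pixels must be a non-empty matrix")
  if (!is.numeric(pixels) || anyNA(pixels))
    stop_capmorph("pixels must be numeric with no missing values")
  if (!is.numeric(nm_per_px) || length(nm_per_px) != 1L ||
      !is.finite(nm_per_px) || nm_per_px <= 0)
    stop_capmorph("nm_per_px must be a single finite positive number")
  rng <- range(pixels)
  if (is.null(bits)) bits <- if (rng[2] > 255) 16L else 8L
  if (!bits %in% c(8L, 16L)) stop_capmorph("bits must be 8 or 16")
  if (rng[1] < 0) stop_capmorph("negative pixel intensities are not allowed")
  if (rng[2] > 2^bits - 1 && rng[2] > 1)
    stop_capmorph("pixel intensities exceed the %d-bit range", bits)
  structure(
    list(pixels = pixels, nm_per_px = as.numeric(nm_per_px),
         channel_label = as.character(channel_label), bits = as.integer(bits)),
    class = "CalibratedImage")
}

#' @export
print.CalibratedImage <- function(x, ...) {
  cat(sprintf("CalibratedImage [%s]: %d x %d px, %.4g nm/px, %d-bit\n",
              x$channel_label, nrow(x$pixels), ncol(x$pixels),
              x$nm_per_px, x$bits))
  invisible(x)
}

#' @export
dim.CalibratedImage <- function(x) dim(x$pixels)

#' Read a single-channel TIFF or PNG image
#'
#' Supports baseline uncompressed greyscale TIFF (8/16-bit, strip layout) and
#' non-interlaced greyscale PNG (8/16-bit). Pixels are loaded without any
#' rescaling. The calibration is always supplied by the caller and never taken
#' from file tags, because acquisition magnification varies and embedded
#' resolution tags are unreliable.
#'
#' @param path file to read.
#' @param nm_per_px physical pixel size in nanometres.
#' @param channel_label channel tag attached to the result.
#' @return A [calibrated_image()].
#' @export
read_image <- function(path, nm_per_px, channel_label = "TEM") {
  if (!file.exists(path)) stop_capmorph("image file not found: %s", path)
  magic <- readBin(path, "raw", n = 8L)
  px <- if (length(magic) >= 8 &&
            identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))) {
    read_png_gray(path)
  } else if (length(magic) >= 4 &&
             (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
              identical(magic[1:2], as.raw(c(0x4d, 0x4d))))) {
    read_tiff_gray(path)
  } else {
    stop_capmorph("unsupported image format (expected TIFF or PNG): %s", path)
  }
  calibrated_image(px$pixels, nm_per_px, channel_label, bits = px$bits)
}

#' Write a calibrated image to TIFF or PNG
#'
#' Format is chosen from the file extension (`.tif`/`.tiff` or `.png`). The
#' raster is written verbatim at the image's declared bit depth; calibration is
#' not embedded (it travels in the annotation sidecar).
#'
#' @param img a [calibrated_image()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "CalibratedImage"))
  px <- round(img$pixels)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) write_tiff_gray(px, path, img$bits)
  else if (ext == "png") write_png_gray(px, path, img$bits)
  else stop_capmorph("unsupported output extension '.%s' (use .tif or .png)", ext)
  invisible(path)
}

## ---- TIFF codec (baseline greyscale, uncompressed) -------------------------

write_tiff_gray <- function(pixels, path, bits = 8L) {
  h <- nrow(pixels); w <- ncol(pixels)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)          # "II", 42
  nbytes <- w * h * (bits / 8L)
  ifd_off <- 8L + nbytes
  writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
  vals <- as.integer(t(pixels))                              # row-major
  if (bits == 8L) writeBin(as.raw(vals), con)
  else writeBin(vals, con, size = 2, endian = "little")
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {                                        # SHORT padded
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  writeBin(9L, con, size = 2, endian = "little")             # 9 IFD entries
  tag(256, 4, 1, w); tag(257, 4, 1, h); tag(258, 3, 1, bits)
  tag(259, 3, 1, 1); tag(262, 3, 1, 1)                       # none, BlackIsZero
  tag(273, 4, 1, 8); tag(277, 3, 1, 1); tag(278, 4, 1, h)
  tag(279, 4, 1, nbytes)
  writeBin(0L, con, size = 4, endian = "little")             # no next IFD
  invisible(path)
}

read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  endian <- if (identical(raw[1:2], as.raw(c(0x49, 0x49)))) "little" else "big"
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
    if (v < 0) v + 2^32 else v
  }
  if (u16(2) != 42L) stop_capmorph("not a valid TIFF file: %s", path)
  ifd <- u32(4)
  n <- u16(ifd)
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd + 2 + (i - 1) * 12
    id <- u16(e); type <- u16(e + 2); count <- u32(e + 4)
    size <- c(`1` = 1L, `3` = 2L, `4` = 4L)[as.character(type)]
    if (is.na(size)) next                                    # skip exotic types
    off <- if (size * count <= 4) e + 8 else u32(e + 8)
    rd <- if (size == 2L) u16 else if (size == 4L) u32 else
      function(o) as.integer(raw[o + 1])
    tags[[as.character(id)]] <- vapply(seq_len(count) - 1L,
                                       function(k) rd(off + k * size), numeric(1))
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) {
      if (is.null(default)) stop_capmorph("TIFF tag %d missing in %s", id, path)
      default
    } else v
  }
  if (!is.null(tags[["322"]])) stop_capmorph("tiled TIFF not supported: %s", path)
  if (need(259, 1)[1] != 1) stop_capmorph("compressed TIFF not supported: %s", path)
  spp <- need(277, 1)[1]
  if (spp != 1) stop_capmorph("expected single-channel image, got %d samples/pixel: %s",
                              spp, path)
  photometric <- need(262, 1)[1]
  if (!photometric %in% c(0, 1))
    stop_capmorph("expected single-channel greyscale image (photometric %d): %s",
                  photometric, path)
  bits <- need(258)[1]
  if (!bits %in% c(8, 16))
    stop_capmorph("unsupported bit depth %d (expected 8 or 16): %s", bits, path)
  w <- need(256)[1]; h <- need(257)[1]
  offs <- need(273); counts <- need(279, w * h * bits / 8)
  dat <- raw[unlist(mapply(function(o, cc) (o + 1):(o + cc), offs, counts,
                           SIMPLIFY = FALSE))]
  vals <- if (bits == 8) as.integer(dat)
  else readBin(dat, "integer", n = w * h, size = 2, signed = FALSE,
               endian = endian)
  px <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  if (photometric == 0) px <- (2^bits - 1) - px              # WhiteIsZero
  list(pixels = px, bits = as.integer(bits))
}

## ---- PNG codec (greyscale, non-interlaced) ---------------------------------

crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))  # 0xEDB88320
      else bitwShiftR(bitwAnd(c, -2L), 1)
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  v <- as.integer(bytes)
  for (b in v) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(crc32_table[idx + 1L], bitwShiftR(bitwAnd(crc, -256L), 8))
  }
  bitwXor(crc, -1L)
}

u32be <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(body)))
}

write_png_gray <- function(pixels, path, bits = 8L) {
  h <- nrow(pixels); w <- ncol(pixels)
  vals <- as.integer(t(pixels))
  scan <- if (bits == 8L) as.raw(vals)
  else as.raw(as.vector(rbind(vals %/% 256L, vals %% 256L)))  # big-endian
  bpr <- w * (bits / 8L)
  rows <- matrix(scan, nrow = bpr)
  filtered <- as.raw(rbind(raw(ncol(rows)), rows))            # filter 0 per row
  ihdr <- c(u32be(w), u32be(h), as.raw(c(bits, 0, 0, 0, 0)))
  idat <- memCompress(as.raw(filtered), "gzip")               # RFC1950 stream
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

read_png_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  be32 <- function(off) sum(as.integer(raw[(off + 1):(off + 4)]) * c(2^24, 2^16, 256, 1))
  pos <- 8
  ihdr <- NULL; idat <- list()
  while (pos + 8 <= length(raw)) {
    len <- be32(pos); type <- rawToChar(raw[(pos + 5):(pos + 8)])
    data_off <- pos + 8
    if (type == "IHDR") ihdr <- raw[(data_off + 1):(data_off + len)]
    if (type == "IDAT") idat[[length(idat) + 1]] <- raw[(data_off + 1):(data_off + len)]
    if (type == "IEND") break
    pos <- data_off + len + 4
  }
  if (is.null(ihdr)) stop_capmorph("malformed PNG (no IHDR): %s", path)
  w <- sum(as.integer(ihdr[1:4]) * c(2^24, 2^16, 256, 1))
  h <- sum(as.integer(ihdr[5:8]) * c(2^24, 2^16, 256, 1))
  bits <- as.integer(ihdr[9]); colortype <- as.integer(ihdr[10])
  interlace <- as.integer(ihdr[13])
  if (colortype != 0L)
    stop_capmorph("expected single-channel greyscale PNG (colour type %d): %s",
                  colortype, path)
  if (!bits %in% c(8L, 16L))
    stop_capmorph("unsupported PNG bit depth %d (expected 8 or 16): %s", bits, path)
  if (interlace != 0L) stop_capmorph("interlaced PNG not supported: %s", path)
  stream <- memDecompress(do.call(c, idat), "gzip")
  bpp <- bits / 8L; bpr <- w * bpp
  mat <- matrix(as.integer(stream), nrow = bpr + 1L, ncol = h)
  recon <- matrix(0L, nrow = bpr, ncol = h)
  for (r in seq_len(h)) {
    f <- mat[1, r]; line <- mat[-1, r]
    prev <- if (r > 1) recon[, r - 1] else integer(bpr)
    recon[, r] <- png_unfilter_row(f, line, prev, bpp)
  }
  vals <- if (bits == 8L) as.vector(recon)
  else {
    v <- matrix(as.vector(recon), nrow = 2)
    as.vector(v[1, ] * 256L + v[2, ])
  }
  list(pixels = matrix(vals, nrow = h, ncol = w, byrow = TRUE),
       bits = bits)
}

png_unfilter_row <- function(filter, line, prev, bpp) {
  n <- length(line)
  if (filter == 0L) return(line)
  if (filter == 2L) return((line + prev) %% 256L)
  if (filter == 1L) {
    out <- line
    if (n > bpp)
      for (i in (bpp + 1):n) out[i] <- (out[i] + out[i - bpp]) %% 256L
    return(out)
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    a <- if (i > bpp) out[i - bpp] else 0L
    b <- prev[i]
    if (filter == 3L) out[i] <- (line[i] + (a + b) %/% 2L) %% 256L
    else if (filter == 4L) {                                 # Paeth
      cc <- if (i > bpp) prev[i - bpp] else 0L
      p <- a + b - cc
      pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - cc)
      pred <- if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
      out[i] <- (line[i] + pred) %% 256L
    } else stop_capmorph("unsupported PNG filter type %d", filter)
  }
  out
}
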