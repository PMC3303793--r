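# Minimal baseline TIFF codec (little-endian, uncompressed, one sample per
# pixel).  Pages are 2D planes written in (t, c, z) order; the first page
# carries a JSON ImageDescription with the 5D shape, channel roles and pixel
# sizes so that stacks round-trip losslessly.  Only what the pipeline needs
# is implemented: bits 8/16/32, unsigned-integer and IEEE-float samples,
# strip-organised data, no compression.

TIFF_TAG <- list(width = 256L, length = 257L, bits = 258L, compression = 259L,
                 photometric = 262L, description = 270L, strip_offsets = 273L,
                 samples_per_pixel = 277L, rows_per_strip = 278L,
                 strip_byte_counts = 279L, sample_format = 339L)

# ---- writer ----------------------------------------------------------------

# pages: list of numeric/integer matrices (y, x); sample_format "float"|"uint"
pl_tiff_write <- function(path, pages, sample_format = "float",
                          bits = if (sample_format == "float") 32L else 32L,
                          description = NULL) {
  stopifnot(length(pages) >= 1L, sample_format %in% c("float", "uint"))
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  for (p in pages) {
    if (nrow(p) != h || ncol(p) != w) pl_stop("tiff", "pages differ in shape")
  }
  bpp <- bits %/% 8L
  data_size <- as.numeric(h) * w * bpp
  n_pages <- length(pages)
  desc_raw <- NULL
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(description), as.raw(0L))
    if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))
  }
  data_offsets <- 8 + (seq_len(n_pages) - 1) * data_size
  ifd_start <- 8 + n_pages * data_size
  n_tags <- function(i) if (i == 1L && !is.null(desc_raw)) 11L else 10L
  ifd_size <- function(i) 2 + 12 * n_tags(i) + 4
  ifd_offsets <- numeric(n_pages)
  off <- ifd_start
  for (i in seq_len(n_pages)) {
    ifd_offsets[i] <- off
    off <- off + ifd_size(i)
    if (i == 1L && !is.null(desc_raw)) off <- off + length(desc_raw)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  w2(42L)
  w4(ifd_offsets[1L])
  # pixel data, row-major within each page
  for (p in pages) {
    v <- as.vector(t(p))
    if (sample_format == "float") {
      writeBin(as.numeric(v), con, size = bpp, endian = "little")
    } else {
      writeBin(as.integer(v), con, size = bpp, endian = "little")
    }
  }
  tag <- function(id, type, count, value) {
    w2(id); w2(type); w4(count)
    if (type == 3L && count == 1L) { w2(value); w2(0L) } else w4(value)
  }
  for (i in seq_len(n_pages)) {
    with_desc <- i == 1L && !is.null(desc_raw)
    w2(n_tags(i))
    tag(TIFF_TAG$width, 4L, 1L, w)
    tag(TIFF_TAG$length, 4L, 1L, h)
    tag(TIFF_TAG$bits, 3L, 1L, bits)
    tag(TIFF_TAG$compression, 3L, 1L, 1L)
    tag(TIFF_TAG$photometric, 3L, 1L, 1L)
    if (with_desc)
      tag(TIFF_TAG$description, 2L, length(desc_raw),
          ifd_offsets[i] + ifd_size(i))
    tag(TIFF_TAG$strip_offsets, 4L, 1L, data_offsets[i])
    tag(TIFF_TAG$samples_per_pixel, 3L, 1L, 1L)
    tag(TIFF_TAG$rows_per_strip, 4L, 1L, h)
    tag(TIFF_TAG$strip_byte_counts, 4L, 1L, data_size)
    tag(TIFF_TAG$sample_format, 3L, 1L,
        if (sample_format == "float") 3L else 1L)
    w4(if (i < n_pages) ifd_offsets[i + 1L] else 0L)
    if (with_desc) writeBin(desc_raw, con)
  }
  invisible(path)
}

# ---- reader ----------------------------------------------------------------

pl_tiff_read <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 8L) pl_stop("tiff", "file too short to be a TIFF: ", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    pl_stop("tiff", "not a TIFF file (bad byte-order mark): ", path)
  rd <- function(at, size, n = 1L, what = "integer", signed = TRUE)
    readBin(raw[(at + 1):(at + size * n)], what = what, n = n, size = size,
            endian = endian, signed = signed)
  if (rd(2, 2, signed = FALSE) != 42L)
    pl_stop("tiff", "not a TIFF file (magic != 42): ", path)

  type_size <- c(1L, 1L, 2L, 4L, 8L)  # BYTE ASCII SHORT LONG RATIONAL
  read_values <- function(at, type, count) {
    sz <- type_size[type]
    total <- sz * count
    src <- if (total <= 4L) at else rd(at, 4)
    if (type == 2L) {
      v <- rd(src, 1, total, what = "raw")
      return(rawToChar(v[v != as.raw(0)]))
    }
    if (type == 3L) return(rd(src, 2, count, signed = FALSE))
    rd(src, 4, count)
  }

  pages <- list()
  description <- NULL
  ifd <- rd(4, 4)
  while (ifd != 0L) {
    n_tags <- rd(ifd, 2, signed = FALSE)
    tags <- list()
    for (k in seq_len(n_tags)) {
      at <- ifd + 2 + (k - 1) * 12
      id <- rd(at, 2, signed = FALSE)
      type <- rd(at + 2, 2, signed = FALSE)
      count <- rd(at + 4, 4)
      tags[[as.character(id)]] <- read_values(at + 8, type, count)
    }
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    w <- g(TIFF_TAG$width); h <- g(TIFF_TAG$length)
    if (is.null(w) || is.null(h)) pl_stop("tiff", "IFD missing image size")
    if (g(TIFF_TAG$compression, 1L) != 1L)
      pl_stop("tiff", "compressed TIFF not supported")
    if (g(TIFF_TAG$samples_per_pixel, 1L) != 1L)
      pl_stop("tiff", "multi-sample TIFF not supported; one sample per pixel")
    bits <- g(TIFF_TAG$bits, 1L)
    fmt <- g(TIFF_TAG$sample_format, 1L)
    offs <- g(TIFF_TAG$strip_offsets)
    cnts <- g(TIFF_TAG$strip_byte_counts, as.numeric(h) * w * bits / 8)
    if (is.null(description)) description <- g(TIFF_TAG$description)
    bpp <- bits %/% 8L
    vals <- unlist(lapply(seq_along(offs), function(i) {
      n <- cnts[i] %/% bpp
      if (fmt == 3L) rd(offs[i], bpp, n, what = "numeric")
      else if (bpp == 4L) rd(offs[i], bpp, n)
      else rd(offs[i], bpp, n, signed = FALSE)
    }))
    if (length(vals) != as.numeric(h) * w)
      pl_stop("tiff", "strip data does not cover the page")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
    ifd <- rd(ifd + 2 + 12 * n_tags, 4)
  }
  list(pages = pages, description = description)
}
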