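# ChannelStack: the canonical image container.  Axis order is fixed to
# (t, c, z, y, x) with singleton axes allowed; centroids and distances are
# physical (micrometres), pixel indices 0-based.

CHANNEL_ROLES <- c("membrane", "nuclear_unconverted", "nuclear_converted")

#' Construct a multi-channel image stack
#'
#' Wraps a nonnegative intensity array in the package's canonical container.
#' Axis order is fixed to `(t, c, z, y, x)`; arrays of lower dimensionality
#' are padded with leading singleton axes at the positions given by `axes`.
#'
#' @param pixels numeric array, up to 5D, all values finite and `>= 0`.
#' @param channel_roles character vector naming each channel, drawn from
#'   `"membrane"`, `"nuclear_unconverted"`, `"nuclear_converted"`; must be
#'   unique and match the channel-axis length.
#' @param pixel_size_um physical voxel spacing, `(z, y, x)` in micrometres,
#'   strictly positive.
#' @param time_step_min frame interval in minutes, or `NULL` for single
#'   frames.
#' @param axes character string naming the axes of `pixels` when it has
#'   fewer than 5 dimensions, e.g. `"cyx"`; defaults to the trailing axes
#'   of `"tczyx"`.
#' @return an object of class `channel_stack` with fields `pixels` (5D
#'   array), `channel_roles`, `pixel_size_um`, `time_step_min`.
#' @export
channel_stack <- function(pixels, channel_roles, pixel_size_um = c(1, 1, 1),
                          time_step_min = NULL, axes = NULL) {
  pixels <- as_5d(pixels, axes)
  x <- structure(list(pixels = pixels,
                      channel_roles = as.character(channel_roles),
                      pixel_size_um = as.numeric(pixel_size_um),
                      time_step_min = time_step_min),
                 class = "channel_stack")
  validate_channel_stack(x)
}

as_5d <- function(pixels, axes = NULL) {
  d <- dim(pixels) %||% length(pixels)
  if (length(d) > 5L) pl_stop("core_io", "arrays beyond 5D are not supported")
  if (is.null(axes)) {
    # pad with leading singleton axes: a (y, x) matrix becomes (1,1,1,y,x)
    d <- c(rep(1L, 5L - length(d)), d)
    return(array(pixels, dim = d))
  }
  axes <- strsplit(tolower(axes), "")[[1L]]
  canon <- c("t", "c", "z", "y", "x")
  if (length(axes) != length(d) || anyDuplicated(axes) ||
      !all(axes %in% canon))
    pl_stop("core_io", "axes must be distinct characters from 'tczyx'")
  full <- stats::setNames(rep(1L, 5L), canon)
  full[axes] <- d
  # permute present axes into canonical order; singleton insertion does not
  # change the column-major flattening
  perm <- order(match(axes, canon))
  array(as.vector(aperm(array(pixels, dim = d), perm)), dim = unname(full))
}

validate_channel_stack <- function(x, stage = "core_io") {
  p <- x$pixels
  if (!is.array(p) || length(dim(p)) != 5L)
    pl_stop(stage, "pixels must be a 5D (t,c,z,y,x) array")
  if (anyNA(p) || any(!is.finite(p)) || any(p < 0))
    pl_stop(stage, "intensities must be finite and >= 0")
  if (length(x$channel_roles) != dim(p)[2L])
    pl_stop(stage, "channel_roles length (", length(x$channel_roles),
            ") != channel axis length (", dim(p)[2L], ")")
  if (anyDuplicated(x$channel_roles))
    pl_stop(stage, "channel roles must be unique")
  if (!all(x$channel_roles %in% CHANNEL_ROLES))
    pl_stop(stage, "unknown channel role; allowed: ",
            paste(CHANNEL_ROLES, collapse = ", "))
  if (length(x$pixel_size_um) != 3L || any(x$pixel_size_um <= 0))
    pl_stop(stage, "pixel_size_um must be 3 strictly positive values (z,y,x)")
  x
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<channel_stack> t=%d c=%d z=%d y=%d x=%d\n", d[1], d[2], d[3],
              d[4], d[5]))
  cat("  roles:", paste(x$channel_roles, collapse = ", "), "\n")
  cat("  pixel size (z,y,x) um:", paste(x$pixel_size_um, collapse = ", "),
      "\n")
  if (!is.null(x$time_step_min))
    cat("  time step:", x$time_step_min, "min\n")
  invisible(x)
}

# Extract one 2D (y, x) plane.
stack_plane <- function(stack, t = 1L, role = NULL, c = NULL, z = 1L) {
  ci <- c %||% match(role, stack$channel_roles)
  if (is.na(ci)) pl_stop("core_io", "no channel with role '", role, "'")
  stack$pixels[t, ci, z, , ]
}

# Extract the (z, y, x) volume of one channel at one frame.
stack_volume <- function(stack, t = 1L, role = NULL, c = NULL) {
  ci <- c %||% match(role, stack$channel_roles)
  if (is.na(ci)) pl_stop("core_io", "no channel with role '", role, "'")
  d <- dim(stack$pixels)
  array(stack$pixels[t, ci, , , ], dim = d[3:5])
}

#' Maximum intensity projection over z
#'
#' Collapses the depth axis by the per-pixel maximum, the standard MIP used
#' to flatten confocal volumes before 2D analysis.  All other axes and the
#' metadata are preserved; the projection is idempotent.
#'
#' @param stack a [channel_stack()].
#' @return a `channel_stack` with singleton z axis.
#' @export
project_mip <- function(stack) {
  stack <- validate_channel_stack(stack)
  d <- dim(stack$pixels)
  out <- array(0, dim = c(d[1:2], 1L, d[4:5]))
  for (z in seq_len(d[3L])) {
    out[, , 1L, , ] <- pmax(out[, , 1L, , ], stack$pixels[, , z, , ,
                                                          drop = FALSE])
  }
  stack$pixels <- out
  stack
}

# ---- stack/mask TIFF I/O ---------------------------------------------------

#' Write a stack to (OME-style) multi-page TIFF
#'
#' Pages are 2D planes in `(t, c, z)` order; shape, channel roles and pixel
#' sizes are stored as JSON in the first page's ImageDescription so
#' [read_stack()] reconstructs an equal object.  Data are 32-bit floats.
#'
#' @param stack a [channel_stack()].
#' @param path output file path.
#' @export
write_stack <- function(stack, path) {
  stack <- validate_channel_stack(stack)
  d <- dim(stack$pixels)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- matrix(stack$pixels[t, ch, z, , ], d[4], d[5])
  }
  desc <- jsonlite::toJSON(list(axes = "TCZYX", shape = unname(d),
                                channel_roles = stack$channel_roles,
                                pixel_size_um = stack$pixel_size_um,
                                time_step_min = stack$time_step_min),
                           auto_unbox = TRUE, digits = NA, null = "null")
  pl_tiff_write(path, pages, sample_format = "float", bits = 32L,
                description = as.character(desc))
  invisible(path)
}

#' Read a TIFF image into a channel stack
#'
#' Reads an uncompressed single-sample TIFF/OME-TIFF.  If the file carries
#' this package's JSON ImageDescription, the full `(t, c, z, y, x)` geometry
#' and metadata are restored; otherwise the pages are interpreted as
#' `(t, c, z)`-ordered planes with `t = pages / length(roles)`, `z = 1`.
#'
#' @param path TIFF file path.
#' @param roles channel roles; required for files without embedded metadata,
#'   checked against it otherwise.
#' @param pixel_size_um voxel spacing override for bare files.
#' @return a [channel_stack()].
#' @export
read_stack <- function(path, roles = NULL, pixel_size_um = c(1, 1, 1)) {
  tf <- pl_tiff_read(path)
  meta <- NULL
  if (!is.null(tf$description)) {
    meta <- tryCatch(jsonlite::fromJSON(tf$description), error = function(e)
      NULL)
    if (!is.null(meta) && !identical(meta$axes, "TCZYX")) meta <- NULL
  }
  n_pages <- length(tf$pages)
  if (!is.null(meta)) {
    d <- as.integer(meta$shape)
    if (prod(d[1:3]) != n_pages)
      pl_stop("core_io", "page count does not match embedded shape")
    if (!is.null(roles) && length(roles) != d[2L])
      pl_stop("core_io", "roles length (", length(roles),
              ") does not match channel count (", d[2L], ")")
    roles <- roles %||% meta$channel_roles
    pixel_size_um <- meta$pixel_size_um
    tstep <- meta$time_step_min
  } else {
    if (is.null(roles))
      pl_stop("core_io", "roles required for TIFFs without embedded metadata")
    nc <- length(roles)
    if (n_pages %% nc != 0L)
      pl_stop("core_io", "page count (", n_pages,
              ") not divisible by roles length (", nc, ")")
    d <- c(n_pages %/% nc, nc, 1L, nrow(tf$pages[[1]]), ncol(tf$pages[[1]]))
    tstep <- NULL
  }
  px <- array(0, dim = d)
  i <- 0L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    px[t, ch, z, , ] <- tf$pages[[i]]
  }
  if (any(px < 0))
    pl_stop("core_io", "negative intensities after decoding: ", path)
  channel_stack(px, roles, pixel_size_um, if (is.null(tstep)) NULL else tstep)
}

#' Write a label mask as an unsigned 32-bit integer TIFF
#' @param mask integer matrix (y, x) or array (z, y, x); 0 = background.
#' @param path output path.
#' @export
write_label_mask <- function(mask, path) {
  mask <- as_mask3d(mask)
  pages <- lapply(seq_len(dim(mask)[1L]), function(z) matrix(mask[z, , ],
                  dim(mask)[2L], dim(mask)[3L]))
  desc <- jsonlite::toJSON(list(axes = "ZYX", shape = unname(dim(mask))),
                           auto_unbox = TRUE, digits = NA)
  pl_tiff_write(path, pages, sample_format = "uint", bits = 32L,
                description = as.character(desc))
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#' @param path TIFF path.
#' @return integer array (z, y, x).
#' @export
read_label_mask <- function(path) {
  tf <- pl_tiff_read(path)
  nz <- length(tf$pages)
  out <- array(0L, dim = c(nz, nrow(tf$pages[[1]]), ncol(tf$pages[[1]])))
  for (z in seq_len(nz)) out[z, , ] <- as.integer(tf$pages[[z]])
  validate_label_mask(out)
}

# label mask helpers: labels must be 0..N contiguous
as_mask3d <- function(mask) {
  d <- dim(mask) %||% length(mask)
  if (length(d) == 2L) mask <- array(mask, dim = c(1L, d))
  else if (length(d) != 3L) pl_stop("core_io", "mask must be 2D or 3D")
  mask
}

validate_label_mask <- function(mask, stage = "core_io") {
  mask <- as_mask3d(mask)
  v <- as.integer(mask)
  if (any(v < 0L)) pl_stop(stage, "labels must be nonnegative")
  n <- max(v)
  if (n > 0L && !all(seq_len(n) %in% v))
    pl_stop(stage, "positive labels must form the contiguous set 1..N")
  array(v, dim = dim(mask))
}
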