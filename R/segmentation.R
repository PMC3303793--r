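# Nucleus segmentation: robust global background, threshold + connected
# components, optional membrane-guided watershed splitting of touching
# nuclei.

#' Estimate image background
#'
#' Robust global estimate: `level` is the median and `spread` the
#' MAD-based robust standard deviation (1.4826 * MAD) of the pixels outside
#' the exclusion mask.  Deterministic.
#'
#' @param frame numeric matrix `(y, x)` or array `(z, y, x)`.
#' @param exclude optional logical mask of the same shape; `TRUE` pixels are
#'   left out of the estimate.
#' @return list of class `background_estimate` with `level`, `spread`,
#'   `method`.
#' @export
estimate_background <- function(frame, exclude = NULL) {
  v <- as.numeric(frame)
  if (!length(v)) pl_stop("segmentation", "empty frame")
  if (!is.null(exclude)) {
    if (length(exclude) != length(v))
      pl_stop("segmentation", "exclude mask shape differs from frame")
    v <- v[!exclude]
    if (!length(v)) pl_stop("segmentation", "all pixels excluded")
  }
  structure(list(level = stats::median(v),
                 spread = stats::mad(v, constant = 1.4826),
                 method = "median_mad"),
            class = "background_estimate")
}

#' Segment nuclei above background
#'
#' Thresholds at `T = level + k_bg * spread`, labels the connected
#' components of pixels strictly above `T` (8-connectivity in 2D,
#' 26-connectivity in 3D), removes components smaller than `min_size_px`
#' and relabels the survivors 1..N in scan order.
#'
#' @param frame numeric matrix `(y, x)` or array `(z, y, x)`.
#' @param bg a [estimate_background()] result (or any list with `level` and
#'   `spread`).
#' @param k_bg threshold factor (> 0); default 3.
#' @param min_size_px minimum component size in pixels; default 20.
#' @return integer label array shaped like `frame` (returned 3D as
#'   `(z, y, x)`); 0 is background.  An empty mask is a valid result.
#' @export
segment_nuclei <- function(frame, bg, k_bg = 3, min_size_px = 20L) {
  if (k_bg <= 0) pl_stop("segmentation", "k_bg must be > 0")
  if (min_size_px < 1L) pl_stop("segmentation", "min_size_px must be >= 1")
  vol <- as_mask3d(frame)
  thr <- bg$level + k_bg * bg$spread
  mask <- vol > thr
  lab <- array(.cc_label(as.logical(aperm(mask, c(1L, 2L, 3L))),
                         dim(vol)), dim = dim(vol))
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(sizes >= min_size_px)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  validate_label_mask(lab, "segmentation")
}

#' Split touching nuclei using the membrane channel
#'
#' Within each labelled region, runs a seeded watershed with the (1-pixel
#' Gaussian smoothed) membrane intensity as elevation.  Seeds are the
#' regional minima of the smoothed membrane inside the region; regions are
#' split wherever a membrane ridge crosses them.  The union of foreground
#' pixels is unchanged and labels are renumbered 1..N.
#'
#' @param mask integer label array from [segment_nuclei()].
#' @param membrane membrane-channel image of the same shape.
#' @return relabelled integer array.
#' @export
membrane_guided_split <- function(mask, membrane) {
  mask <- as_mask3d(mask)
  mem <- as_mask3d(membrane)
  if (!identical(dim(mask), dim(mem)))
    pl_stop("segmentation", "mask and membrane shapes differ")
  if (max(mask) == 0L) return(mask)
  smooth <- mem
  for (z in seq_len(dim(mem)[1L]))
    smooth[z, , ] <- gauss_blur2d(matrix(mem[z, , ], dim(mem)[2L],
                                         dim(mem)[3L]), 1)
  minima <- regional_minima(smooth, mask)
  # connected plateaus of minima become seeds, kept separate across regions
  seed_cc <- array(.cc_label(as.logical(minima), dim(mask)), dim = dim(mask))
  pair <- seed_cc
  pair[minima] <- match(paste(seed_cc[minima], mask[minima]),
                        unique(paste(seed_cc[minima], mask[minima])))
  out <- array(.ws_flood(as.numeric(smooth), as.integer(pair),
                         as.integer(mask), dim(mask)), dim = dim(mask))
  # renumber 1..N in scan order
  relabel_scan(out)
}

relabel_scan <- function(lab) {
  pos <- lab > 0L
  u <- unique(lab[pos])
  lab[pos] <- match(lab[pos], u)
  validate_label_mask(lab, "segmentation")
}

# pixels <= every in-region 26-neighbour of the same region
regional_minima <- function(vol, region) {
  d <- dim(vol)
  is_min <- region > 0L
  big <- max(vol) + 1
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (!dz && !dy && !dx) next
    nb <- shift3d(vol, dz, dy, dx, fill = big)
    nb_reg <- shift3d(region, dz, dy, dx, fill = 0L)
    other <- nb_reg != region  # out-of-region neighbours do not count
    nb[other] <- big
    is_min <- is_min & (vol <= nb)
  }
  is_min
}

shift3d <- function(a, dz, dy, dx, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src_z <- seq_len(d[1]) + dz; src_y <- seq_len(d[2]) + dy
  src_x <- seq_len(d[3]) + dx
  okz <- src_z >= 1 & src_z <= d[1]
  oky <- src_y >= 1 & src_y <= d[2]
  okx <- src_x >= 1 & src_x <= d[3]
  out[which(okz), which(oky), which(okx)] <-
    a[src_z[okz], src_y[oky], src_x[okx]]
  out
}

#' Score a segmentation against ground truth
#'
#' Greedy nearest-first one-to-one matching of predicted to true centroids
#' within `match_radius_um`, then standard object-level precision, recall
#' and F1.
#'
#' @param pred_centroids matrix of predicted centroids, columns `(y, x)` in
#'   micrometres (use [measure_nuclei()] output).
#' @param true_centroids matrix of true centroids, same convention.
#' @param match_radius_um maximum centroid distance for a match.
#' @return list with `precision`, `recall`, `f1`, `n_matched`.
#' @export
evaluate_segmentation <- function(pred_centroids, true_centroids,
                                  match_radius_um) {
  np <- NROW(pred_centroids); nt <- NROW(true_centroids)
  if (np == 0L || nt == 0L) {
    return(list(precision = if (np == 0L && nt == 0L) 1 else 0,
                recall = if (nt == 0L) 1 else 0,
                f1 = 0, n_matched = 0L))
  }
  dmat <- sqrt(outer(pred_centroids[, 1], true_centroids[, 1], "-")^2 +
                 outer(pred_centroids[, 2], true_centroids[, 2], "-")^2)
  matched <- greedy_match(dmat, match_radius_um)
  m <- nrow(matched)
  precision <- m / np
  recall <- m / nt
  f1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1, n_matched = m)
}

# globally-shortest-first one-to-one matching under a distance gate;
# ties broken by (row, column) order
greedy_match <- function(dmat, gate) {
  cand <- which(dmat <= gate, arr.ind = TRUE)
  if (!nrow(cand)) return(matrix(integer(0), 0L, 2L))
  ord <- order(dmat[cand], cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  used_r <- logical(nrow(dmat)); used_c <- logical(ncol(dmat))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1L]; cc <- cand[i, 2L]
    if (!used_r[r] && !used_c[cc]) {
      keep[i] <- TRUE
      used_r[r] <- TRUE
      used_c[cc] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}
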