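# Independent brute-force oracles and small scenario builders shared across
# the suite.  Oracles deliberately reimplement the quantities they check
# with the most literal algorithm available.

options(photolineage.verbose = FALSE)

# per-pixel maximum over z by an explicit triple loop
oracle_mip <- function(vol) {
  d <- dim(vol)
  out <- matrix(-Inf, d[2], d[3])
  for (z in seq_len(d[1]))
    for (y in seq_len(d[2]))
      for (x in seq_len(d[3]))
        out[y, x] <- max(out[y, x], vol[z, y, x])
  out
}

# even-odd point-in-polygon via explicit upward ray crossing count, with an
# on-edge check; one point at a time
oracle_pip <- function(py, px, verts, eps = 1e-9) {
  n <- nrow(verts)
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    y1 <- verts[i, 1]; x1 <- verts[i, 2]
    y2 <- verts[j, 1]; x2 <- verts[j, 2]
    # on-segment?
    if (abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)) <= eps &&
        px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
        py >= min(y1, y2) - eps && py <= max(y1, y2) + eps)
      return(TRUE)
    if ((y1 > py) != (y2 > py)) {
      x_at <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < x_at) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# per-label mean intensities by explicit accumulation
oracle_label_means <- function(mask, img) {
  labs <- sort(unique(mask[mask > 0]))
  sapply(labs, function(l) mean(img[mask == l]))
}

# exhaustive optimal one-to-one matching under a gate: maximum cardinality,
# then minimum total distance, by recursion over rows
oracle_best_matching <- function(dmat, gate) {
  nr <- nrow(dmat); nc <- ncol(dmat)
  best <- list(card = -1L, dist = Inf)
  recurse <- function(r, used, card, dist) {
    if (r > nr) {
      if (card > best$card ||
          (card == best$card && dist < best$dist - 1e-12))
        best <<- list(card = card, dist = dist)
      return(invisible(NULL))
    }
    recurse(r + 1L, used, card, dist)  # leave row r unmatched
    for (cc in seq_len(nc)) {
      if (!used[cc] && dmat[r, cc] <= gate) {
        used[cc] <- TRUE
        recurse(r + 1L, used, card + 1L, dist + dmat[r, cc])
        used[cc] <- FALSE
      }
    }
  }
  recurse(1L, logical(nc), 0L, 0)
  best
}

# closed-form leading eigenvector of a symmetric 2x2 matrix
oracle_eig2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; d <- m[2, 2]
  tr <- a + d
  det <- a * d - b * b
  l1 <- tr / 2 + sqrt(tr^2 / 4 - det)
  v <- if (abs(b) > 1e-12) c(b, l1 - a) else if (a >= d) c(1, 0) else c(0, 1)
  v / sqrt(sum(v^2))
}

# small endpoint world reused by several module tests (same physics as the
# default, fewer cells: keeps module tests inside the time budget)
small_regen_overrides <- function(...) {
  utils::modifyList(
    list(field_um = c(500, 800), n_converted = 300, n_bystander = 80,
         n_stump = 60),
    list(...))
}

small_regen_scenario <- function(seed = 1, ...)
  do.call(photo_scenario,
          c(list(name = "regeneration_7dpa", seed = seed),
            small_regen_overrides(...)))

# per-frame record tables straight from generator truth (no imaging), for
# tracking tests; labels are the within-frame rank of the cell id
truth_frames <- function(truth) {
  lapply(split(truth$cells, truth$cells$frame), function(f) {
    f <- f[order(f$id), , drop = FALSE]
    data.frame(frame = f$frame, label = seq_len(nrow(f)), id = f$id,
               centroid_y_um = f$y_um, centroid_x_um = f$x_um)
  })
}

# map forest edges to (parent id, child id) pairs using truth_frames tables
edges_as_ids <- function(edges, frames) {
  if (!nrow(edges)) return(edges)
  look <- do.call(rbind, frames)
  id_of <- function(fr, lb)
    look$id[look$frame == fr & look$label == lb]
  data.frame(parent = vapply(seq_len(nrow(edges)), function(i)
    id_of(edges$frame_a[i], edges$label_a[i]), numeric(1)),
    child = vapply(seq_len(nrow(edges)), function(i)
      id_of(edges$frame_b[i], edges$label_b[i]), numeric(1)),
    frame = edges$frame_b)
}

# converted-channel segmentation + measurement for every frame of a stack
segment_stack_frames <- function(stack, k_bg = 3, min_size = 20) {
  lapply(seq_len(dim(stack$pixels)[1]), function(t) {
    conv <- stack$pixels[t, match("nuclear_converted", stack$channel_roles),
                         1, , ]
    bg <- estimate_background(conv)
    mask <- segment_nuclei(conv, bg, k_bg, min_size)
    measure_nuclei(mask, stack, bg = list(nuclear_converted = bg), t = t)
  })
}
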