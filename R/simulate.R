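# Synthetic tissue generator: forward model from cell states to image
# stacks, plus the ground truth used as the oracle for every downstream
# stage.  Cell state is vectorised as a data frame (one row per cell).

CELL_COLUMNS <- c("id", "y_um", "x_um", "radius_um", "converted_pool",
                  "unconverted_pool", "synth", "membrane_pool",
                  "division_count", "parent", "alive", "converted",
                  "partition_product")

new_cells <- function(id, y_um, x_um, radius_um, converted_pool = 0,
                      unconverted_pool, synth = unconverted_pool,
                      membrane_pool, division_count = 0L,
                      parent = NA_integer_, alive = TRUE, converted = FALSE,
                      partition_product = 1) {
  df <- data.frame(id = as.integer(id), y_um = y_um, x_um = x_um,
                   radius_um = radius_um, converted_pool = converted_pool,
                   unconverted_pool = unconverted_pool, synth = synth,
                   membrane_pool = membrane_pool,
                   division_count = as.integer(division_count),
                   parent = as.integer(parent), alive = alive,
                   converted = converted,
                   partition_product = partition_product)
  validate_cells(df)
}

validate_cells <- function(df) {
  stopifnot(all(CELL_COLUMNS %in% names(df)))
  if (any(df$converted_pool < 0) || any(df$unconverted_pool < 0) ||
      any(df$membrane_pool < 0))
    pl_stop("synthetic_data", "fluorophore pools must be >= 0")
  if (any(df$division_count < 0L))
    pl_stop("synthetic_data", "division_count must be >= 0")
  df
}

#' Photoconvert cells inside a region
#'
#' Moves a fraction `p_conv` of each in-region cell's unconverted pool into
#' its converted pool; the per-cell total pool is conserved exactly and
#' cells outside the region are untouched.
#'
#' @param cells cell-state data frame (see [simulate_tissue()]).
#' @param region `list(type = "stripe", x_min, x_max)` (micrometres) or
#'   `list(type = "sphere", center = c(y, x), radius)`.
#' @param p_conv photoconversion efficiency in `[0, 1]`.
#' @return the updated cell-state data frame; gains a logical `converted`
#'   membership flag.
#' @export
apply_photoconversion <- function(cells, region, p_conv) {
  if (!(p_conv >= 0 && p_conv <= 1))
    pl_stop("synthetic_data", "p_conv must be in [0, 1]")
  inside <- region_contains(region, cells$y_um, cells$x_um)
  moved <- p_conv * cells$unconverted_pool[inside]
  cells$converted_pool[inside] <- cells$converted_pool[inside] + moved
  cells$unconverted_pool[inside] <- cells$unconverted_pool[inside] - moved
  cells$converted <- cells$converted | (inside & p_conv > 0)
  cells
}

region_contains <- function(region, y_um, x_um) {
  if (identical(region$type, "stripe"))
    return(x_um >= region$x_min & x_um <= region$x_max)
  if (identical(region$type, "sphere"))
    return((y_um - region$center[1])^2 + (x_um - region$center[2])^2 <=
             region$radius^2)
  pl_stop("synthetic_data", "region type must be 'stripe' or 'sphere'")
}

#' Divide one cell into two daughters
#'
#' The converted pool is partitioned between the daughters with fraction
#' `f ~ Normal(0.5, 0.5 * partition_cv)` truncated to (0, 1); the two
#' shares sum exactly to the parent's pool (dilution, no synthesis).  The
#' unconverted pool of each daughter is reset to the steady-state synthesis
#' level (constitutive expression replenishes the unconverted label).
#' Draws come from the current RNG stream.
#'
#' @param parent single-row cell-state data frame.
#' @param partition_cv coefficient of variation of the split; 0 gives exact
#'   halves.
#' @param steady_state unconverted pool assigned to each daughter.
#' @param ids integer ids for the two daughters.
#' @param offset_um optional 2-column matrix of (y, x) offsets placing the
#'   daughters; defaults to zero displacement.
#' @return two-row cell-state data frame (parent id recorded).
#' @export
advance_division <- function(parent, partition_cv = 0.05,
                             steady_state = 800,
                             ids = parent$id * 2L + c(0L, 1L),
                             offset_um = NULL) {
  stopifnot(nrow(parent) == 1L)
  if (!isTRUE(parent$alive))
    pl_stop("synthetic_data", "cannot divide a dead cell")
  if (partition_cv < 0)
    pl_stop("synthetic_data", "partition_cv must be >= 0")
  f <- rtrunc_norm(1L, 0.5, 0.5 * partition_cv, 0, 1)
  shares <- c(f, 1 - f) * parent$converted_pool
  if (is.null(offset_um)) offset_um <- matrix(0, 2L, 2L)
  new_cells(id = ids,
            y_um = parent$y_um + offset_um[, 1L],
            x_um = parent$x_um + offset_um[, 2L],
            radius_um = parent$radius_um,
            converted_pool = shares,
            unconverted_pool = steady_state, synth = steady_state,
            membrane_pool = parent$membrane_pool,
            division_count = parent$division_count + 1L,
            parent = parent$id,
            converted = parent$converted,
            partition_product = parent$partition_product * c(f, 1 - f) * 2)
}

#' Render one image frame from cell states
#'
#' Forward imaging model: nuclei are Gaussian blobs (sd = nuclear radius)
#' scaled by the matching pool in each nuclear channel; membranes are ridges
#' along the boundaries of the nearest-nucleus (Voronoi) partition scaled by
#' the local `membrane_pool`; the frame is then blurred by a Gaussian PSF,
#' subjected to Poisson shot noise at the stated gain, offset Gaussian read
#' noise, and clipped at zero.
#'
#' @param cells cell-state data frame; dead cells are skipped, positions
#'   outside the field are clipped to it.
#' @param scenario a [photo_scenario()]; supplies field geometry, optics and
#'   noise parameters.
#' @param noise override for `scenario$noise$enabled`.
#' @return `channel_stack` with one frame and channels
#'   (membrane, nuclear_unconverted, nuclear_converted).
#' @export
render_frame <- function(cells, scenario, noise = NULL) {
  px <- scenario$pixel_size_um
  ny <- as.integer(round(scenario$field_um[1] / px))
  nx <- as.integer(round(scenario$field_um[2] / px))
  cells <- cells[cells$alive, , drop = FALSE]
  chan <- list(membrane = matrix(0, ny, nx),
               nuclear_unconverted = matrix(0, ny, nx),
               nuclear_converted = matrix(0, ny, nx))
  if (nrow(cells)) {
    cy <- pmin(pmax(cells$y_um / px, 0), ny - 1)
    cx <- pmin(pmax(cells$x_um / px, 0), nx - 1)
    sig <- cells$radius_um / px
    for (i in seq_len(nrow(cells))) {
      r <- ceiling(4 * sig[i])
      ys <- max(1L, floor(cy[i] + 1 - r)):min(ny, ceiling(cy[i] + 1 + r))
      xs <- max(1L, floor(cx[i] + 1 - r)):min(nx, ceiling(cx[i] + 1 + r))
      blob <- outer(exp(-((ys - 1 - cy[i])^2) / (2 * sig[i]^2)),
                    exp(-((xs - 1 - cx[i])^2) / (2 * sig[i]^2)))
      if (cells$unconverted_pool[i] > 0)
        chan$nuclear_unconverted[ys, xs] <-
          chan$nuclear_unconverted[ys, xs] + cells$unconverted_pool[i] * blob
      if (cells$converted_pool[i] > 0)
        chan$nuclear_converted[ys, xs] <-
          chan$nuclear_converted[ys, xs] + cells$converted_pool[i] * blob
    }
    if (isTRUE(scenario$render_membrane) && nrow(cells) >= 2L)
      chan$membrane <- membrane_ridges(cbind(cy, cx), cells$membrane_pool,
                                       ny, nx)
  }
  psf <- scenario$psf_sigma_um / px
  chan <- lapply(chan, gauss_blur2d, sigma = psf)
  use_noise <- noise %||% isTRUE(scenario$noise$enabled)
  nz <- scenario$noise
  chan <- lapply(chan, function(m) {
    if (use_noise && nz$gain > 0)
      m[] <- stats::rpois(length(m), nz$gain * m) / nz$gain
    # detector baseline is a deterministic camera property, applied even
    # when stochastic noise is disabled (it anchors the background level)
    m <- m + nz$offset
    if (use_noise && nz$read_sd > 0)
      m <- m + stats::rnorm(length(m), 0, nz$read_sd)
    # integer ADU quantization, like the offset a deterministic detector
    # property; sub-half-count blob tails vanish instead of percolating
    if (isTRUE(nz$quantize %||% TRUE)) m <- round(m)
    pmax(m, 0)
  })
  arr <- array(0, dim = c(1L, 3L, 1L, ny, nx))
  for (i in 1:3) arr[1, i, 1, , ] <- chan[[i]]
  channel_stack(arr, names(chan), pixel_size_um = c(px, px, px),
                time_step_min = scenario$time_step_min)
}

# Voronoi boundary ridges: pixels whose nearest cell centroid differs from a
# 4-neighbour's nearest centroid, at the membrane_pool of the nearest cell.
membrane_ridges <- function(centers_px, membrane_pool, ny, nx) {
  grid <- cbind(rep(seq_len(ny) - 1, times = nx),
                rep(seq_len(nx) - 1, each = ny))
  nn <- FNN::get.knnx(centers_px, grid, k = 1L)$nn.index[, 1L]
  lab <- matrix(nn, ny, nx)
  edge <- matrix(FALSE, ny, nx)
  edge[-ny, ] <- edge[-ny, ] | (lab[-ny, ] != lab[-1L, ])
  edge[-1L, ] <- edge[-1L, ] | (lab[-1L, ] != lab[-ny, ])
  edge[, -nx] <- edge[, -nx] | (lab[, -nx] != lab[, -1L])
  edge[, -1L] <- edge[, -1L] | (lab[, -1L] != lab[, -nx])
  out <- matrix(0, ny, nx)
  out[edge] <- membrane_pool[lab[edge]]
  out
}

#' Simulate a tissue scenario
#'
#' Runs the full generator for a scenario preset: places cells, applies
#' photoconversion and the division schedule, moves cells, and renders every
#' frame.  Deterministic given `scenario$seed` (a single RNG stream drives
#' every draw; the caller's RNG state is left untouched).
#'
#' @param scenario a [photo_scenario()].
#' @return `list(stack, truth)` where `stack` is a [channel_stack()] time
#'   series and `truth` is a `ground_truth` object: `$cells` (per frame, per
#'   cell: true centroid, pre-noise pools, division count, photoconversion
#'   flag), `$lineage` (parent/child/frame edges) and the resolved
#'   `$scenario`.
#' @export
simulate_tissue <- function(scenario) {
  stopifnot(inherits(scenario, "photo_scenario"))
  pl_log("simulate", "scenario=", scenario$name, " seed=", scenario$seed)
  with_seed(scenario$seed, {
    if (scenario$type == "endpoint_classes") sim_endpoint(scenario)
    else sim_timelapse(scenario)
  })
}

# -- endpoint preset: 7 dpa regenerate, class-structured division counts ----

sim_endpoint <- function(sc) {
  m <- 12  # border margin, um: keeps blobs inside the field
  fy <- sc$field_um[1]; fx <- sc$field_um[2]
  # photoconverted contributors in the regenerate
  d_class <- sample(sc$division_classes, sc$n_converted, replace = TRUE,
                    prob = sc$class_proportions)
  guide_on <- isTRUE(sc$guide$enabled)
  guide_idx <- if (guide_on) which(d_class == 0L) else integer(0)
  n_scatter <- sc$n_converted - length(guide_idx)
  guide_pts <- NULL
  if (length(guide_idx)) {
    gx <- seq(sc$plane_x_um + 3 * m, fx - 3 * m,
              length.out = length(guide_idx))
    guide_pts <- cbind(fy / 2 + stats::rnorm(length(gx), 0,
                                             sc$guide$jitter_um), gx)
  }
  regen <- place_hardcore(n_scatter + sc$n_bystander, c(m, fy - m),
                          c(sc$plane_x_um + m, fx - m), sc$min_spacing_um,
                          existing = guide_pts)
  pos <- matrix(NA_real_, sc$n_converted + sc$n_bystander, 2L)
  conv_rows <- seq_len(sc$n_converted)
  if (length(guide_idx)) pos[guide_idx, ] <- guide_pts
  pos[setdiff(conv_rows, guide_idx), ] <-
    regen[seq_len(n_scatter), , drop = FALSE]
  by_rows <- sc$n_converted + seq_len(sc$n_bystander)
  pos[by_rows, ] <- regen[n_scatter + seq_len(sc$n_bystander), , drop = FALSE]
  # stump cells rostral to the amputation plane
  stump <- place_hardcore(sc$n_stump, c(m, fy - m), c(m, sc$plane_x_um - m),
                          sc$min_spacing_um)
  n_all <- nrow(pos) + nrow(stump)
  # cell-to-cell expression variability, identical for both reporters
  # (1:1 stoichiometry from the 2A construct)
  p0 <- sc$pool0 * rexpr_cv(n_all, sc$expression_cv)
  cells <- new_cells(id = seq_len(n_all),
                     y_um = c(pos[, 1], stump[, 1]),
                     x_um = c(pos[, 2], stump[, 2]),
                     radius_um = sc$nuclear_radius_um,
                     converted_pool = 0,
                     unconverted_pool = p0,
                     membrane_pool = sc$membrane_pool)
  # conversion happened at amputation time inside the stripe; regenerate
  # contributors are descendants of stripe cells, so they are converted by
  # construction rather than by present-day position
  stripe <- list(type = "stripe", x_min = sc$stripe_um[1],
                 x_max = sc$stripe_um[2])
  cells <- apply_photoconversion(cells, stripe, sc$p_conv)
  cells$converted[conv_rows] <- TRUE
  cells$converted_pool[conv_rows] <- sc$p_conv * p0[conv_rows]
  cells$unconverted_pool[conv_rows] <- (1 - sc$p_conv) * p0[conv_rows]
  # dilute the converted pool through d divisions with noisy partitioning;
  # unconverted pool resets to the cell's steady state at any division
  cells$division_count[conv_rows] <- d_class
  for (i in conv_rows) {
    d <- d_class[i]
    if (d > 0L) {
      f <- rtrunc_norm(d, 0.5, 0.5 * sc$partition_cv, 0, 1)
      cells$partition_product[i] <- prod(2 * f)
      cells$converted_pool[i] <- cells$converted_pool[i] * prod(f)
      cells$unconverted_pool[i] <- cells$synth[i]
    }
  }
  truth_cells <- cbind(frame = 1L, cells)
  truth <- structure(list(cells = truth_cells,
                          lineage = empty_lineage(),
                          scenario = sc),
                     class = "ground_truth")
  stack <- render_frame(cells, sc)
  list(stack = stack, truth = truth)
}

# -- timelapse preset: founders divide once at fixture-defined frames -------

sim_timelapse <- function(sc) {
  nf <- nrow(sc$founder_yx_um)
  founders <- new_cells(id = seq_len(nf),
                        y_um = sc$founder_yx_um[, 1],
                        x_um = sc$founder_yx_um[, 2],
                        radius_um = sc$nuclear_radius_um,
                        converted_pool = 0,
                        unconverted_pool = sc$pool0 *
                          rexpr_cv(nf, sc$expression_cv),
                        membrane_pool = sc$membrane_pool)
  for (i in seq_len(nf)) {
    founders <- apply_photoconversion(
      founders, list(type = "sphere",
                     center = c(founders$y_um[i], founders$x_um[i]),
                     radius = sc$nuclear_radius_um), sc$p_conv)
  }
  m <- 12
  nb_pos <- place_hardcore(sc$n_neighbors, c(m, sc$field_um[1] - m),
                           c(m, sc$field_um[2] - m), sc$min_spacing_um,
                           existing = sc$founder_yx_um)
  neighbors <- new_cells(id = nf + seq_len(sc$n_neighbors),
                         y_um = nb_pos[, 1], x_um = nb_pos[, 2],
                         radius_um = sc$nuclear_radius_um,
                         converted_pool = 0,
                         unconverted_pool = sc$pool0 *
                           rexpr_cv(sc$n_neighbors, sc$expression_cv),
                         membrane_pool = sc$membrane_pool)
  cells <- rbind(founders, neighbors)
  next_id <- max(cells$id) + 1L
  lineage <- empty_lineage()
  frames_truth <- list()
  stack_px <- NULL
  decay <- exp(-sc$decay_rate_per_min * (sc$time_step_min %||% 0))
  for (fr in seq_len(sc$n_frames)) {
    if (fr > 1L) {
      alive <- which(cells$alive)
      step <- matrix(stats::rnorm(2L * length(alive), 0,
                                  sc$motion$diffusion_sd_um),
                     ncol = 2L)
      cells$y_um[alive] <- cells$y_um[alive] + step[, 1] + sc$motion$drift_um[1]
      cells$x_um[alive] <- cells$x_um[alive] + step[, 2] + sc$motion$drift_um[2]
      # nuclei volume-exclude: relax overlapping pairs back to the
      # hard-core distance (deterministic, no RNG draws)
      pos <- repel_pairs(cbind(cells$y_um[alive], cells$x_um[alive]),
                         sc$min_spacing_um)
      cells$y_um[alive] <- pos[, 1]
      cells$x_um[alive] <- pos[, 2]
      cells$converted_pool[alive] <- cells$converted_pool[alive] * decay
      # fixture-defined divisions: founder k divides so that its daughters
      # first exist at frame division_frames[k]
      for (k in seq_len(nf)) {
        if (sc$division_frames[k] == fr) {
          p_row <- which(cells$id == k)
          theta <- stats::runif(1, 0, 2 * pi)
          off <- (sc$daughter_sep_um / 2) *
            rbind(c(sin(theta), cos(theta)), -c(sin(theta), cos(theta)))
          kids <- advance_division(cells[p_row, ],
                                   partition_cv = sc$partition_cv,
                                   steady_state = cells$synth[p_row],
                                   ids = next_id + 0:1, offset_um = off)
          next_id <- next_id + 2L
          cells$alive[p_row] <- FALSE
          cells <- rbind(cells, kids)
          lineage <- rbind(lineage,
                           data.frame(parent = k, child = kids$id,
                                      frame = fr))
        }
      }
    }
    live <- cells[cells$alive, , drop = FALSE]
    frames_truth[[fr]] <- cbind(frame = fr, live)
    fr_stack <- render_frame(live, sc)
    if (is.null(stack_px)) {
      d <- dim(fr_stack$pixels)
      stack_px <- array(0, dim = c(sc$n_frames, d[2:5]))
    }
    stack_px[fr, , , , ] <- fr_stack$pixels[1, , , , ]
  }
  stack <- channel_stack(stack_px, CHANNEL_ROLES,
                         pixel_size_um = rep(sc$pixel_size_um, 3L),
                         time_step_min = sc$time_step_min)
  truth <- structure(list(cells = do.call(rbind, frames_truth),
                          lineage = lineage, scenario = sc),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

empty_lineage <- function()
  data.frame(parent = integer(0), child = integer(0), frame = integer(0))

# Random sequential adsorption with a hard-core minimum distance, using a
# grid of bin width min_dist so each proposal checks at most 9 bins.
place_hardcore <- function(n, y_range, x_range, min_dist, existing = NULL) {
  n_exist <- if (is.null(existing)) 0L else nrow(existing)
  pts <- matrix(NA_real_, n + n_exist, 2L)
  if (n_exist) pts[seq_len(n_exist), ] <- existing
  bins <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(by, bx) paste0(by, ",", bx)
  add <- function(i) {
    k <- key(floor(pts[i, 1] / min_dist), floor(pts[i, 2] / min_dist))
    bins[[k]] <- c(bins[[k]], i)
  }
  clear <- function(y, x) {
    by <- floor(y / min_dist); bx <- floor(x / min_dist)
    for (dy in -1:1) for (dx in -1:1) {
      js <- bins[[key(by + dy, bx + dx)]]
      if (!is.null(js) &&
          any((pts[js, 1] - y)^2 + (pts[js, 2] - x)^2 < min_dist^2))
        return(FALSE)
    }
    TRUE
  }
  for (i in seq_len(n_exist)) add(i)
  placed <- 0L
  tries <- 0L
  max_tries <- 4000L * n
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    y <- stats::runif(1, y_range[1], y_range[2])
    x <- stats::runif(1, x_range[1], x_range[2])
    if (clear(y, x)) {
      placed <- placed + 1L
      pts[n_exist + placed, ] <- c(y, x)
      add(n_exist + placed)
    }
  }
  if (placed < n)
    pl_stop("synthetic_data", "could not place ", n, " cells at spacing ",
            min_dist, " um; field too crowded")
  pts[n_exist + seq_len(n), , drop = FALSE]
}

# Push apart any pair of points closer than d_min, splitting the correction
# evenly; a few sweeps suffice at the simulated densities.
repel_pairs <- function(pts, d_min, sweeps = 5L) {
  n <- nrow(pts)
  if (n < 2L) return(pts)
  for (s in seq_len(sweeps)) {
    moved <- FALSE
    d2 <- as.matrix(stats::dist(pts))
    idx <- which(d2 < d_min & upper.tri(d2), arr.ind = TRUE)
    if (!nrow(idx)) break
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1L]; j <- idx[r, 2L]
      v <- pts[j, ] - pts[i, ]
      d <- sqrt(sum(v^2))
      if (d >= d_min) next
      u <- if (d > 1e-9) v / d else c(1, 0)
      shift <- (d_min - d) / 2
      pts[i, ] <- pts[i, ] - u * shift
      pts[j, ] <- pts[j, ] + u * shift
      moved <- TRUE
    }
    if (!moved) break
  }
  pts
}
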