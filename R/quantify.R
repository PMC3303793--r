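# Per-nucleus quantification: one record per label with per-channel mean and
# integrated intensity, physical centroid, and the colocalization call used
# as the divided / non-divided readout.

#' Measure per-nucleus intensities
#'
#' One record per label: unweighted pixel-centre centroid (converted to
#' micrometres), voxel count, and per-channel arithmetic mean, integrated
#' intensity and background-subtracted mean (clamped at 0).
#'
#' @param mask integer label array `(z, y, x)` (2D input allowed) aligned to
#'   one frame of `stack`.
#' @param stack a [channel_stack()].
#' @param bg named list of [estimate_background()] results, one per channel
#'   role; missing channels get level 0.
#' @param t frame index of `stack` that `mask` belongs to.
#' @return data frame of class `nucleus_records` with columns `frame`,
#'   `label`, `centroid_z_um`, `centroid_y_um`, `centroid_x_um`, `voxels`,
#'   then `mean_<role>`, `integrated_<role>`, `bgsub_mean_<role>` for each
#'   channel, sorted by label.
#' @export
measure_nuclei <- function(mask, stack, bg = list(), t = 1L) {
  stack <- validate_channel_stack(stack, "quantification")
  mask <- as_mask3d(mask)
  d <- dim(stack$pixels)
  if (!identical(dim(mask), d[3:5]))
    pl_stop("quantification", "mask shape does not match the stack frame")
  lab <- as.integer(mask)
  fg <- lab > 0L
  n <- if (any(fg)) max(lab) else 0L
  px <- stack$pixel_size_um
  if (n == 0L) {
    rec <- empty_records(stack$channel_roles)
    return(rec)
  }
  labs <- lab[fg]
  voxels <- as.vector(tabulate(labs, nbins = n))
  dz <- dim(mask)
  zi <- (seq_along(lab) - 1L) %% dz[1L]
  yi <- ((seq_along(lab) - 1L) %/% dz[1L]) %% dz[2L]
  xi <- (seq_along(lab) - 1L) %/% (dz[1L] * dz[2L])
  cz <- rowsum_vec(zi[fg], labs, n) / voxels * px[1L]
  cy <- rowsum_vec(yi[fg], labs, n) / voxels * px[2L]
  cx <- rowsum_vec(xi[fg], labs, n) / voxels * px[3L]
  rec <- data.frame(frame = t, label = seq_len(n), centroid_z_um = cz,
                    centroid_y_um = cy, centroid_x_um = cx, voxels = voxels)
  for (role in stack$channel_roles) {
    v <- as.numeric(stack_volume(stack, t = t, role = role))
    tot <- rowsum_vec(v[fg], labs, n)
    level <- if (!is.null(bg[[role]])) bg[[role]]$level else 0
    rec[[paste0("mean_", role)]] <- tot / voxels
    rec[[paste0("integrated_", role)]] <- tot
    rec[[paste0("bgsub_mean_", role)]] <- pmax(tot / voxels - level, 0)
  }
  class(rec) <- c("nucleus_records", "data.frame")
  rec
}

rowsum_vec <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

empty_records <- function(roles) {
  rec <- data.frame(frame = integer(0), label = integer(0),
                    centroid_z_um = numeric(0), centroid_y_um = numeric(0),
                    centroid_x_um = numeric(0), voxels = integer(0))
  for (role in roles) {
    rec[[paste0("mean_", role)]] <- numeric(0)
    rec[[paste0("integrated_", role)]] <- numeric(0)
    rec[[paste0("bgsub_mean_", role)]] <- numeric(0)
  }
  class(rec) <- c("nucleus_records", "data.frame")
  rec
}

#' Classify colocalization state of nuclei
#'
#' Reduces the visual "does the photoconverted nucleus colocalize with
#' unconverted signal?" judgement to the scalar ratio
#' `r = u / (u + c)` of background-subtracted means (u = unconverted,
#' c = converted).  Bright nuclei (`c >= bright_floor`) with `r < r_low`
#' are called `non_divided` (the unconverted label was converted away and
#' never replenished because the cell did not divide); nuclei with
#' `r >= r_low` are `divided_or_renewed`; dim nuclei below the floor with
#' low `r` are `indeterminate`.
#'
#' @param records a [measure_nuclei()] table containing
#'   `bgsub_mean_nuclear_unconverted` and `bgsub_mean_nuclear_converted`.
#' @param r_low ratio threshold in (0, 1); default 0.2.
#' @param bright_floor minimum background-subtracted converted mean for a
#'   confident `non_divided` call.
#' @return the records with added columns `coloc_ratio` and `coloc_call`.
#' @export
classify_colocalization <- function(records, r_low = 0.2, bright_floor = 0) {
  if (!(r_low > 0 && r_low < 1))
    pl_stop("quantification", "r_low must be in (0, 1)")
  u <- records$bgsub_mean_nuclear_unconverted
  cv <- records$bgsub_mean_nuclear_converted
  if (is.null(u) || is.null(cv))
    pl_stop("quantification",
            "records lack background-subtracted nuclear channels")
  denom <- u + cv
  r <- ifelse(denom > 0, u / denom, NA_real_)
  call <- ifelse(!is.na(r) & r >= r_low, "divided_or_renewed",
                 ifelse(!is.na(r) & cv >= bright_floor, "non_divided",
                        "indeterminate"))
  records$coloc_ratio <- r
  records$coloc_call <- call
  records
}
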