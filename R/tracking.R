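# Frame-to-frame linking into lineage forests.  Greedy globally
# shortest-first matching with a physical gate; a parent may acquire one
# extra child per frame step (mitosis is binary), detected when an otherwise
# unmatched next-frame nucleus sits within the gate of an already-matched
# parent.

#' Link nucleus records across one frame step
#'
#' Greedy shortest-first one-to-one matching of centroids within `gate_um`
#' (ties broken by label order).  Afterwards, any unmatched record of frame
#' t+1 whose nearest frame-t record within the gate already has exactly one
#' child is attached as a second child (a division); remaining unmatched
#' t+1 records are left to become roots (cells entering the field) and
#' unmatched frame-t records terminate.
#'
#' @param a,b [measure_nuclei()]-style tables for frames t and t+1 (need
#'   `label`, `centroid_y_um`, `centroid_x_um`, `frame`).
#' @param gate_um maximum centroid displacement per frame step (> 0).
#' @return data frame with columns `frame_a`, `label_a`, `frame_b`,
#'   `label_b`, `type` (`"link"` or `"division"`).
#' @export
link_frames <- function(a, b, gate_um) {
  if (gate_um <= 0) pl_stop("tracking", "gate_um must be > 0")
  empty <- data.frame(frame_a = integer(0), label_a = integer(0),
                      frame_b = integer(0), label_b = integer(0),
                      type = character(0))
  if (!nrow(a) || !nrow(b)) return(empty)
  dmat <- sqrt(outer(a$centroid_y_um, b$centroid_y_um, "-")^2 +
                 outer(a$centroid_x_um, b$centroid_x_um, "-")^2)
  m <- greedy_match(dmat, gate_um)
  edges <- data.frame(frame_a = a$frame[m[, 1L]], label_a = a$label[m[, 1L]],
                      frame_b = b$frame[m[, 2L]], label_b = b$label[m[, 2L]],
                      type = rep("link", nrow(m)))
  n_child <- tabulate(m[, 1L], nbins = nrow(a))
  unmatched_b <- setdiff(seq_len(nrow(b)), m[, 2L])
  for (j in unmatched_b) {
    cand <- which(dmat[, j] <= gate_um & n_child == 1L)
    if (!length(cand)) next
    i <- cand[which.min(dmat[cand, j])]
    n_child[i] <- 2L
    edges <- rbind(edges,
                   data.frame(frame_a = a$frame[i], label_a = a$label[i],
                              frame_b = b$frame[j], label_b = b$label[j],
                              type = "division"))
  }
  edges
}

#' Build a lineage forest from per-frame records
#'
#' Applies [link_frames()] to every adjacent frame pair.  `direction`
#' controls the processing order: backward mode walks the pairs starting
#' from the final frame (the per-pair matching is symmetric, so both
#' directions agree on unambiguous data); edges always point forward in
#' time in the result.
#'
#' @param frames list of per-frame record tables, in time order.
#' @param gate_um matching gate.
#' @param direction `"forward"` or `"backward"`.
#' @return object of class `lineage_forest` with `$nodes` (frame, label,
#'   centroid) and `$edges` (parent/child across consecutive frames).
#' @export
build_forest <- function(frames, gate_um,
                         direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (length(frames) < 2L) pl_stop("tracking", "need at least 2 frames")
  pairs <- seq_len(length(frames) - 1L)
  if (direction == "backward") pairs <- rev(pairs)
  edges <- do.call(rbind, lapply(pairs, function(t)
    link_frames(frames[[t]], frames[[t + 1L]], gate_um)))
  nodes <- do.call(rbind, lapply(frames, function(f)
    f[, intersect(c("frame", "label", "centroid_z_um", "centroid_y_um",
                    "centroid_x_um"), names(f)), drop = FALSE]))
  edges <- edges[order(edges$frame_a, edges$label_a, edges$label_b), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  forest <- structure(list(nodes = nodes, edges = edges,
                           n_frames = length(frames)),
                      class = "lineage_forest")
  validate_forest(forest)
}

validate_forest <- function(forest) {
  e <- forest$edges
  if (nrow(e)) {
    if (any(e$frame_b != e$frame_a + 1L))
      pl_stop("tracking", "edges must connect consecutive frames")
    outd <- table(paste(e$frame_a, e$label_a))
    if (any(outd > 2L)) pl_stop("tracking", "out-degree above 2")
    ind <- table(paste(e$frame_b, e$label_b))
    if (any(ind > 1L)) pl_stop("tracking", "in-degree above 1")
  }
  forest
}

#' Summarise a lineage forest
#'
#' @param forest a [build_forest()] result.
#' @return list with `n_lineages` (roots present in the first frame),
#'   `n_divisions` (nodes of out-degree 2), `n_terminal` (leaves in the
#'   final frame), `n_entering` (roots appearing after the first frame).
#' @export
summarize_forest <- function(forest) {
  n <- forest$nodes
  e <- forest$edges
  if (!nrow(n))
    return(list(n_lineages = 0L, n_divisions = 0L, n_terminal = 0L,
                n_entering = 0L))
  key <- function(f, l) paste(f, l)
  has_parent <- key(n$frame, n$label) %in% key(e$frame_b, e$label_b)
  has_child <- key(n$frame, n$label) %in% key(e$frame_a, e$label_a)
  first_f <- min(n$frame)
  last_f <- max(n$frame)
  outd <- table(key(e$frame_a, e$label_a))
  list(n_lineages = sum(!has_parent & n$frame == first_f),
       n_divisions = sum(outd == 2L),
       n_terminal = sum(!has_child & n$frame == last_f),
       n_entering = sum(!has_parent & n$frame > first_f))
}

#' @export
print.lineage_forest <- function(x, ...) {
  s <- summarize_forest(x)
  cat(sprintf(paste0("<lineage_forest> %d nodes, %d edges, %d frames; ",
                     "%d first-frame lineages, %d divisions\n"),
              nrow(x$nodes), nrow(x$edges), x$n_frames, s$n_lineages,
              s$n_divisions))
  invisible(x)
}
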