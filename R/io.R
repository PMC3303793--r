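# Artifact writers/readers.  Nucleus tables travel as CSV with fixed,
# versioned column names; lineage forests, mixture models and spatial
# results as JSON; label masks and stacks as integer/float TIFF.  Write
# then read is the identity for every artifact type (up to storage
# precision).

#' Write a pipeline artifact to disk
#'
#' Dispatches on the artifact class: `nucleus_records` tables go to CSV,
#' `lineage_forest` / `mixture_model` / `spatial_result` to JSON,
#' `channel_stack` to float TIFF and bare integer arrays (label masks) to
#' unsigned-integer TIFF.
#'
#' @param x artifact object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_outputs <- function(x, path) UseMethod("write_outputs")

#' @export
write_outputs.nucleus_records <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @export
write_outputs.lineage_forest <- function(x, path) {
  jsonlite::write_json(list(artifact = "lineage_forest", nodes = x$nodes,
                            edges = x$edges, n_frames = x$n_frames),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
write_outputs.mixture_model <- function(x, path) {
  jsonlite::write_json(c(list(artifact = "mixture_model"), unclass(x)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
write_outputs.spatial_result <- function(x, path) {
  jsonlite::write_json(c(list(artifact = "spatial_result"), unclass(x)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
write_outputs.channel_stack <- function(x, path) write_stack(x, path)

#' @export
write_outputs.default <- function(x, path) {
  if (is.array(x) || is.matrix(x)) return(write_label_mask(x, path))
  pl_stop("core_io", "no writer for class ", paste(class(x), collapse = "/"))
}

#' Read a nucleus-record CSV written by [write_outputs()]
#' @param path CSV path.
#' @return `nucleus_records` data frame.
#' @export
read_nuclei <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(rec) <- c("nucleus_records", "data.frame")
  rec
}

#' Read a lineage-forest JSON written by [write_outputs()]
#' @param path JSON path.
#' @return `lineage_forest` object.
#' @export
read_forest <- function(path) {
  j <- jsonlite::fromJSON(path)
  if (!identical(j$artifact, "lineage_forest"))
    pl_stop("core_io", "not a lineage_forest artifact: ", path)
  edges <- as.data.frame(j$edges)
  if (!nrow(edges))
    edges <- data.frame(frame_a = integer(0), label_a = integer(0),
                        frame_b = integer(0), label_b = integer(0),
                        type = character(0))
  validate_forest(structure(list(nodes = as.data.frame(j$nodes),
                                 edges = edges,
                                 n_frames = j$n_frames),
                            class = "lineage_forest"))
}

#' Read a mixture-model JSON written by [write_outputs()]
#' @param path JSON path.
#' @return `mixture_model` object.
#' @export
read_mixture <- function(path) {
  j <- jsonlite::fromJSON(path)
  if (!identical(j$artifact, "mixture_model"))
    pl_stop("core_io", "not a mixture_model artifact: ", path)
  j$artifact <- NULL
  j$K <- as.integer(j$K)
  j$n <- as.integer(j$n)
  structure(j, class = "mixture_model")
}

#' Read a spatial-result JSON written by [write_outputs()]
#' @param path JSON path.
#' @return `spatial_result` object.
#' @export
read_spatial <- function(path) {
  j <- jsonlite::fromJSON(path)
  if (!identical(j$artifact, "spatial_result"))
    pl_stop("core_io", "not a spatial_result artifact: ", path)
  j$artifact <- NULL
  structure(j, class = "spatial_result")
}
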