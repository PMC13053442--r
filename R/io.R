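# File formats: multi-page TIFF stacks with a JSON voxel-size sidecar,
# graph JSON, SWC-like text for visualisation tools.

#' Write a voxel volume as a multi-page TIFF with JSON sidecar
#'
#' One TIFF page per z-slice (8-bit), plus `<path>.json` recording voxel
#' size and axial calibration, which plain TIFF does not carry reliably.
#' @param volume a `voxel_volume`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  d <- dim(volume$data)
  mx <- max(volume$data, 1)
  pages <- lapply(seq_len(d[3]), function(k)
    t(volume$data[, , k]) / mx)           # writeTIFF wants row = y
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(voxel_size_um = volume$voxel_size,
         z_calibration = volume$z_calibration,
         dims = d, intensity_max = mx),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_volume_tiff()]
#' @param path TIFF path; the `<path>.json` sidecar must exist.
#' @return a `voxel_volume`.
#' @export
read_volume_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- vapply(pages, function(p) t(p), matrix(0, meta$dims[1],
                                                meta$dims[2]))
  vol <- array(round(arr * meta$intensity_max), dim = meta$dims)
  voxel_volume(vol, meta$voxel_size_um, meta$z_calibration)
}

#' Serialise a capillary graph to JSON
#' @param graph a `capillary_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(
    list(nodes = graph$nodes,
         edges = lapply(graph$edges, function(e)
           list(from = e$from, to = e$to,
                coords = unname(as.matrix(e$coords))))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a capillary graph from JSON
#' @param path JSON path written by [write_graph_json()].
#' @return a `capillary_graph`.
#' @export
read_graph_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- lapply(seq_len(nrow(j$edges)), function(i)
    list(from = j$edges$from[i], to = j$edges$to[i],
         coords = j$edges$coords[[i]]))
  capillary_graph(j$nodes, edges, validate = FALSE)
}

#' Write a graph as SWC-like text
#'
#' Node-per-line format (id, structure type 0, x, y, z, radius, parent)
#' readable by common neurite/vessel viewers. Each edge polyline becomes a
#' chain of sample points; branch points appear once and are referenced as
#' parents. Cycles make SWC ill-defined as a tree, so the second visit of a
#' node starts a new root (parent -1) and the file is a forest covering
#' every polyline point.
#' @param graph a `capillary_graph`.
#' @param path output path.
#' @param radius constant radius column value, µm.
#' @return `path`, invisibly.
#' @export
write_graph_swc <- function(graph, path, radius = 2.5) {
  lines <- character(0)
  counter <- 0L
  node_swc <- new.env()
  for (e in graph$edges) {
    prev <- -1L
    kf <- as.character(e$from)
    if (!is.null(node_swc[[kf]])) prev <- node_swc[[kf]]
    for (i in seq_len(nrow(e$coords))) {
      counter <- counter + 1L
      lines[length(lines) + 1L] <- sprintf(
        "%d 0 %.4f %.4f %.4f %.3f %d", counter,
        e$coords[i, 1], e$coords[i, 2], e$coords[i, 3], radius, prev)
      prev <- counter
      if (i == 1 && is.null(node_swc[[kf]])) node_swc[[kf]] <- counter
    }
    kt <- as.character(e$to)
    if (is.null(node_swc[[kt]])) node_swc[[kt]] <- counter
  }
  writeLines(c("# SWC-like capillary centrelines (um)", lines), path)
  invisible(path)
}
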