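#' Spatial capillary graph
#'
#' A `capillary_graph` is the vector model of a capillary network: nodes are
#' endpoints and branch points in world coordinates (micrometres), edges carry
#' an ordered polyline of 3D points whose first and last vertices coincide
#' with the node coordinates. All network morphometry (length densities,
#' branching density, tortuosity, anisotropy) is computed on this object.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z` (µm).
#' @param edges list of edges; each edge is a list with elements `from`, `to`
#'   (node ids) and `coords`, an n x 3 matrix of polyline vertices in µm.
#' @param validate check structural invariants (endpoint coincidence, no
#'   zero-length edges).
#' @return An object of class `capillary_graph`.
#' @export
capillary_graph <- function(nodes, edges, validate = TRUE) {
  nodes <- as.data.frame(nodes)
  stopifnot(all(c("id", "x", "y", "z") %in% names(nodes)))
  edges <- lapply(edges, function(e) {
    e$coords <- matrix(as.numeric(e$coords), ncol = 3,
                       dimnames = list(NULL, c("x", "y", "z")))
    e
  })
  g <- structure(list(nodes = nodes, edges = edges),
                 class = "capillary_graph")
  if (validate && length(edges)) {
    pos <- as.matrix(nodes[, c("x", "y", "z")])
    rownames(pos) <- as.character(nodes$id)
    for (i in seq_along(edges)) {
      e <- edges[[i]]
      if (nrow(e$coords) < 2)
        stop("edge ", i, ": polyline needs at least 2 points")
      if (polyline_length(e$coords) <= 0)
        stop("edge ", i, ": zero-length edge")
      a <- pos[as.character(e$from), ]
      b <- pos[as.character(e$to), ]
      if (max(abs(e$coords[1, ] - a)) > 1e-6 ||
          max(abs(e$coords[nrow(e$coords), ] - b)) > 1e-6)
        stop("edge ", i, ": polyline endpoints do not coincide with nodes")
    }
  }
  g
}

#' @export
print.capillary_graph <- function(x, ...) {
  L <- total_length(x)
  cat(sprintf("<capillary_graph> %d nodes, %d edges, total length %.1f um\n",
              nrow(x$nodes), length(x$edges), L))
  invisible(x)
}

#' Arc length of a polyline
#' @param coords n x 3 (or n x 2) matrix of vertices.
#' @return total chord-sum length.
#' @export
polyline_length <- function(coords) {
  if (is.null(dim(coords)) || nrow(coords) < 2) return(0)
  d <- diff(coords)
  sum(sqrt(rowSums(d^2)))
}

#' Node degrees of a capillary graph
#'
#' Degree counts edge incidences; a self-loop edge contributes 2.
#' @param graph a `capillary_graph`.
#' @return named integer vector over node ids.
#' @export
node_degrees <- function(graph) {
  ids <- graph$nodes$id
  deg <- integer(length(ids))
  names(deg) <- as.character(ids)
  for (e in graph$edges) {
    deg[as.character(e$from)] <- deg[as.character(e$from)] + 1L
    deg[as.character(e$to)]   <- deg[as.character(e$to)] + 1L
  }
  deg
}

#' Per-edge segment decomposition
#'
#' Unit directions and lengths of every polyline segment in the graph,
#' used by the orientation tensor and length sums.
#' @param graph a `capillary_graph`.
#' @return list with `dir` (m x 3 unit rows) and `len` (m lengths, µm).
#' @export
graph_segments <- function(graph) {
  dirs <- list(); lens <- list()
  for (e in graph$edges) {
    d <- diff(e$coords)
    l <- sqrt(rowSums(d^2))
    keep <- l > 1e-9
    if (!any(keep)) next
    dirs[[length(dirs) + 1L]] <- d[keep, , drop = FALSE] / l[keep]
    lens[[length(lens) + 1L]] <- l[keep]
  }
  if (!length(lens)) return(list(dir = matrix(0, 0, 3), len = numeric(0)))
  list(dir = do.call(rbind, dirs), len = unlist(lens))
}

#' Apply an affine map to every coordinate of a graph
#' @param graph a `capillary_graph`.
#' @param f function taking and returning an n x 3 coordinate matrix.
#' @return transformed `capillary_graph`.
#' @export
transform_graph <- function(graph, f) {
  graph$nodes[, c("x", "y", "z")] <-
    f(as.matrix(graph$nodes[, c("x", "y", "z")]))
  graph$edges <- lapply(graph$edges, function(e) {
    e$coords <- f(e$coords)
    colnames(e$coords) <- c("x", "y", "z")
    e
  })
  graph
}
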