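#' Voxel volume with anisotropic voxel size
#'
#' 3D scalar or label grid in x-fastest array order, with voxel size in µm
#' and a multiplicative axial calibration factor applied to z world
#' coordinates when the volume is vectorised. Voxel (i, j, k) (1-based) has
#' its centre at world ((i - 0.5) dx, (j - 0.5) dy, (k - 0.5) dz * z_cal).
#' @param data 3D numeric/integer array.
#' @param voxel_size c(dx, dy, dz) in µm, all > 0.
#' @param z_calibration axial calibration factor (> 0).
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size, z_calibration = 1) {
  stopifnot(length(dim(data)) == 3, all(dim(data) >= 1),
            length(voxel_size) == 3, all(voxel_size > 0),
            is.numeric(z_calibration), z_calibration > 0)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 z_calibration = as.numeric(z_calibration)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g um, z-cal %.3g\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$z_calibration))
  invisible(x)
}

# global Otsu threshold on a 256-bin histogram of the volume intensities
otsu_threshold_volume <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  h <- tabulate(pmin(256L, 1L + as.integer(
    255 * (x - rng[1]) / diff(rng))), nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (1:256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + (k - 0.5) / 255 * diff(rng)
}

#' Segment capillaries from an intensity volume
#'
#' Global threshold (Otsu on the volume histogram, or fixed), morphological
#' closing with a 1-voxel ball, then removal of connected components
#' (26-connectivity) smaller than `min_object_volume`. An all-background
#' result raises an error of class `myocap3d_empty_segmentation`.
#' @param volume a scalar `voxel_volume`.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold intensity threshold when `method = "fixed"`.
#' @param min_object_volume smallest retained component, in µm^3.
#' @param closing apply the 1-voxel closing (default TRUE).
#' @return binary `voxel_volume` (0/1).
#' @export
segment_capillaries <- function(volume, method = c("otsu", "fixed"),
                                threshold = NULL, min_object_volume = 100,
                                closing = TRUE) {
  method <- match.arg(method)
  x <- volume$data
  thr <- if (method == "otsu") otsu_threshold_volume(x) else threshold
  if (is.null(thr) || is.na(thr))
    stop("no usable threshold (constant volume?)")
  bin <- array(as.integer(x > thr), dim = dim(x))
  dims <- as.integer(dim(bin))
  if (closing) {
    bin <- cpp_closing_ball1(bin, dims)
    dim(bin) <- dims
  }
  if (min_object_volume > 0 && any(bin > 0)) {
    lab <- cpp_label_components(bin, dims, 26L)
    vox_vol <- prod(volume$voxel_size)
    small <- which(lab$sizes * vox_vol < min_object_volume)
    if (length(small)) {
      drop <- lab$labels %in% small
      bin[drop] <- 0L
      dim(bin) <- dims
    }
  }
  if (!any(bin > 0)) {
    cond <- structure(
      class = c("myocap3d_empty_segmentation", "error", "condition"),
      list(message = "segmentation is empty", call = sys.call()))
    stop(cond)
  }
  voxel_volume(bin, volume$voxel_size, volume$z_calibration)
}

#' Topology-preserving curve skeletonisation
#'
#' Thins a binary volume to a unit-width, 26-connected curve skeleton by
#' directional subiteration thinning: in each of six passes (one per face
#' direction) border voxels that are simple points in the (26, 6) digital
#' topology and are not curve endpoints are deleted, with simplicity
#' re-checked sequentially at deletion time. The skeleton is a subset of
#' the input foreground and preserves its connected components and loops.
#' @param binary a binary `voxel_volume`.
#' @return binary `voxel_volume` containing the skeleton.
#' @export
skeletonise <- function(binary) {
  dims <- as.integer(dim(binary$data))
  sk <- cpp_thin3d(array(as.integer(binary$data > 0), dims), dims)
  dim(sk) <- dims
  voxel_volume(sk, binary$voxel_size, binary$z_calibration)
}

# 26-neighbourhood offsets as integer (di, dj, dk) rows
.off26 <- local({
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  as.matrix(g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ])
})

# adjacency list among skeleton voxels; coords = m x 3 (1-based i, j, k)
skeleton_adjacency <- function(coords, dims) {
  m <- nrow(coords)
  key <- function(ijk)
    ijk[, 1] + dims[1] * (ijk[, 2] - 1) + dims[1] * dims[2] * (ijk[, 3] - 1)
  keys <- key(coords)
  ord <- order(keys)
  adj <- vector("list", m)
  for (o in seq_len(nrow(.off26))) {
    nb <- coords
    nb[, 1] <- nb[, 1] + .off26[o, 1]
    nb[, 2] <- nb[, 2] + .off26[o, 2]
    nb[, 3] <- nb[, 3] + .off26[o, 3]
    inb <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nk <- rep(NA_real_, m)
    nk[inb] <- key(nb[inb, , drop = FALSE])
    hit <- match(nk, keys)
    for (v in which(!is.na(hit))) adj[[v]] <- c(adj[[v]], hit[v])
  }
  adj
}

#' Extract a vector graph from a voxel skeleton
#'
#' Nodes are placed at skeleton voxels with a neighbour count different
#' from 2 (endpoints and junctions); clusters of mutually 26-adjacent
#' junction voxels are merged into a single node at their centroid. Edges
#' are the voxel-centre chains between nodes, converted to µm with the
#' volume's voxel size and axial calibration. Isolated voxel loops (all
#' neighbour counts 2) become self-loop edges anchored at an arbitrary
#' vertex of the loop.
#' @param skeleton a binary `voxel_volume` holding a unit-width skeleton.
#' @return a `capillary_graph` in µm.
#' @export
skeleton_to_graph <- function(skeleton) {
  dims <- dim(skeleton$data)
  coords <- which(skeleton$data > 0, arr.ind = TRUE)
  vs <- skeleton$voxel_size
  zc <- skeleton$z_calibration
  to_world <- function(ijk) {
    cbind(x = (ijk[, 1] - 0.5) * vs[1],
          y = (ijk[, 2] - 0.5) * vs[2],
          z = (ijk[, 3] - 0.5) * vs[3] * zc)
  }
  if (!nrow(coords))
    return(capillary_graph(
      data.frame(id = integer(), x = numeric(), y = numeric(),
                 z = numeric()), list()))
  adj <- skeleton_adjacency(coords, dims)
  deg <- lengths(adj)
  m <- nrow(coords)

  # cluster junction voxels (neighbour count >= 3) into nodes; other
  # non-regular voxels (endpoints, isolated) are singleton nodes
  node_of <- integer(m)                      # 0 = regular chain voxel
  nid <- 0L
  junction <- which(deg >= 3)
  visited <- logical(m)
  for (v in junction) {
    if (visited[v]) next
    nid <- nid + 1L
    stack <- v; members <- integer()
    while (length(stack)) {
      a <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (visited[a]) next
      visited[a] <- TRUE
      members <- c(members, a)
      for (b in adj[[a]]) if (deg[b] >= 3 && !visited[b]) stack <- c(stack, b)
    }
    node_of[members] <- nid
  }
  for (v in which(deg <= 1)) { nid <- nid + 1L; node_of[v] <- nid }

  world <- to_world(coords)
  node_xyz <- matrix(NA_real_, nid, 3)
  for (n in seq_len(nid)) {
    mem <- which(node_of == n)
    node_xyz[n, ] <- colMeans(world[mem, , drop = FALSE])
  }

  edges <- list()
  used <- logical(m)                        # regular voxels consumed by a walk
  seen_pair <- character(0)                 # dedupe direct node-node contacts
  add_edge <- function(from, to, chain) {
    poly <- rbind(node_xyz[from, , drop = FALSE],
                  world[chain, , drop = FALSE],
                  node_xyz[to, , drop = FALSE])
    if (polyline_length(poly) <= 0) return(invisible(NULL))
    edges[[length(edges) + 1L]] <<- list(from = from, to = to, coords = poly)
    invisible(NULL)
  }
  for (v in seq_len(m)) {
    if (node_of[v] == 0L) next
    for (b in adj[[v]]) {
      if (node_of[b] != 0L) {
        if (node_of[b] == node_of[v]) next           # intra-cluster contact
        pk <- paste(sort(c(v, b)), collapse = "-")
        if (pk %in% seen_pair) next
        seen_pair <- c(seen_pair, pk)
        add_edge(node_of[v], node_of[b], integer(0))
      } else if (!used[b]) {
        chain <- integer(0)
        prev <- v; cur <- b
        repeat {
          if (node_of[cur] != 0L) break
          used[cur] <- TRUE
          chain <- c(chain, cur)
          nxt <- setdiff(adj[[cur]], prev)
          # prefer regular continuation; at a fork into a cluster, take it
          if (!length(nxt)) { cur <- NA_integer_; break }
          # skip neighbours already in this chain (tight turns)
          nxt <- nxt[!(nxt %in% chain)]
          if (!length(nxt)) { cur <- NA_integer_; break }
          prev <- cur
          cur <- nxt[[1]]
        }
        if (is.na(cur)) {
          # chain died without reaching a node (shouldn't happen on a
          # unit-width skeleton); make its tip a node
          nid <- nid + 1L
          node_xyz <- rbind(node_xyz, world[chain[length(chain)], ])
          node_of[chain[length(chain)]] <- nid
          add_edge(node_of[v], nid, chain[-length(chain)])
        } else {
          add_edge(node_of[v], node_of[cur], chain)
        }
      }
    }
  }
  # isolated loops: regular voxels never consumed
  for (v in seq_len(m)) {
    if (node_of[v] != 0L || used[v]) next
    nid <- nid + 1L
    node_xyz <- rbind(node_xyz, world[v, ])
    node_of[v] <- nid
    used[v] <- TRUE
    nbrs <- adj[[v]]
    if (length(nbrs) < 2) next
    chain <- integer(0)
    prev <- v; cur <- nbrs[[1]]
    while (!is.na(cur) && node_of[cur] == 0L && !used[cur]) {
      used[cur] <- TRUE
      chain <- c(chain, cur)
      nxt <- setdiff(adj[[cur]], prev)
      nxt <- nxt[!(nxt %in% chain)]
      prev <- cur
      cur <- if (length(nxt)) nxt[[1]] else NA_integer_
    }
    if (!is.na(cur) && node_of[cur] == nid)
      add_edge(nid, nid, chain)
  }

  nodes <- data.frame(id = seq_len(nid), x = node_xyz[, 1],
                      y = node_xyz[, 2], z = node_xyz[, 3])
  keep <- nodes$id %in% unlist(lapply(edges, function(e) c(e$from, e$to))) |
    tabulate(node_of[node_of > 0], nid) == 1  # keep isolated single voxels
  capillary_graph(nodes[keep | TRUE, ], edges, validate = FALSE)
}

#' Smooth a polyline by local averaging
#'
#' Moving-average smoothing of the vertex chain over a fixed arc-length
#' window, endpoints held fixed. Voxel centrelines carry sub-voxel jitter
#' that, left untreated, dominates the exterior-angle tortuosity even
#' after fixed-step vectorisation; a window of a few voxel diagonals
#' suppresses the jitter while leaving undulations at tissue scale
#' (tens of µm) essentially untouched.
#' @param coords n x 3 polyline matrix.
#' @param window full smoothing window in µm.
#' @return smoothed polyline (same number of vertices).
#' @export
smooth_polyline <- function(coords, window = 3) {
  n <- nrow(coords)
  if (n < 3 || window <= 0) return(coords)
  step <- polyline_length(coords) / (n - 1)
  k <- max(1L, round(window / (2 * step)))
  out <- coords
  for (i in 2:(n - 1)) {
    lo <- max(1, i - k); hi <- min(n, i + k)
    out[i, ] <- colMeans(coords[lo:hi, , drop = FALSE])
  }
  out
}

#' Smooth every edge polyline of a graph
#' @param graph a `capillary_graph`.
#' @param window full smoothing window in µm (see [smooth_polyline()]).
#' @return graph with smoothed edges (node coordinates unchanged).
#' @export
smooth_graph <- function(graph, window = 3) {
  graph$edges <- lapply(graph$edges, function(e) {
    e$coords <- smooth_polyline(e$coords, window)
    e
  })
  graph
}

#' Arc-length resampling of a polyline
#'
#' Places interior vertices at multiples of `step` along the original
#' curve's arc length, preserving both endpoints; the final segment may be
#' shorter than `step`. The resampled (chord-sum) length never exceeds the
#' original length.
#' @param coords n x 3 matrix of vertices.
#' @param step resampling step in µm (> 0); the conventional vectorisation
#'   step for capillary networks is 5 µm.
#' @return resampled polyline matrix.
#' @export
resample_polyline <- function(coords, step = 5) {
  stopifnot(step > 0, nrow(coords) >= 2)
  d <- sqrt(rowSums(diff(coords)^2))
  L <- sum(d)
  if (L <= 0) stop("degenerate polyline (all points identical)")
  s <- c(0, cumsum(d))
  targets <- seq(0, L, by = step)
  if (targets[length(targets)] < L) targets <- c(targets, L)
  out <- matrix(NA_real_, length(targets), 3)
  for (c3 in 1:3)
    out[, c3] <- stats::approx(s, coords[, c3], xout = targets,
                               ties = "ordered")$y
  colnames(out) <- c("x", "y", "z")
  out
}

#' Resample every edge of a graph into fixed-length segments
#' @param graph a `capillary_graph`.
#' @param step segment length in µm (default 5).
#' @return graph with resampled edge polylines.
#' @export
resample_graph <- function(graph, step = 5) {
  graph$edges <- lapply(graph$edges, function(e) {
    e$coords <- resample_polyline(e$coords, step)
    e
  })
  graph
}

# concatenate the two edges of a degree-2 node into one
dissolve_degree2 <- function(graph) {
  repeat {
    deg <- node_degrees(graph)
    # self-loops make their node degree 2 but cannot be dissolved
    loops <- vapply(graph$edges, function(e) e$from == e$to, TRUE)
    loop_nodes <- unique(unlist(lapply(graph$edges[loops],
                                       function(e) e$from)))
    cand <- graph$nodes$id[deg[as.character(graph$nodes$id)] == 2 &
                             !(graph$nodes$id %in% loop_nodes)]
    if (!length(cand)) break
    nd <- cand[[1]]
    inc <- which(vapply(graph$edges, function(e)
      e$from == nd || e$to == nd, TRUE))
    if (length(inc) != 2) break
    e1 <- graph$edges[[inc[1]]]; e2 <- graph$edges[[inc[2]]]
    # orient both so they meet at nd: e1 ends at nd, e2 starts at nd
    if (e1$from == nd) {
      e1$coords <- e1$coords[nrow(e1$coords):1, , drop = FALSE]
      e1 <- list(from = e1$to, to = nd, coords = e1$coords)
    }
    if (e2$to == nd) {
      e2$coords <- e2$coords[nrow(e2$coords):1, , drop = FALSE]
      e2 <- list(from = nd, to = e2$from, coords = e2$coords)
    }
    merged <- list(from = e1$from, to = e2$to,
                   coords = rbind(e1$coords,
                                  e2$coords[-1, , drop = FALSE]))
    graph$edges <- c(graph$edges[-inc], list(merged))
    graph$nodes <- graph$nodes[graph$nodes$id != nd, , drop = FALSE]
  }
  graph
}

#' Prune short terminal spurs
#'
#' Iteratively removes terminal edges (leaf endpoint of degree 1, other
#' endpoint of degree >= 2) shorter than `min_spur_length`, then dissolves
#' junction nodes reduced to degree 2 by concatenating their two edges.
#' This automated cleanup removes the short whiskers that voxel thinning
#' leaves at junctions and tube ends. Isolated short fragments (both
#' endpoints of degree 1) are retained.
#' @param graph a `capillary_graph`.
#' @param min_spur_length spur threshold in µm (default 5, one segment).
#' @return pruned `capillary_graph`.
#' @export
prune_spurs <- function(graph, min_spur_length = 5) {
  repeat {
    deg <- node_degrees(graph)
    lens <- vapply(graph$edges, function(e) polyline_length(e$coords), 0)
    is_spur <- vapply(seq_along(graph$edges), function(i) {
      e <- graph$edges[[i]]
      df <- deg[as.character(e$from)]; dt <- deg[as.character(e$to)]
      lens[i] < min_spur_length && xor(df == 1, dt == 1)
    }, TRUE)
    if (!any(is_spur)) break
    graph$edges <- graph$edges[!is_spur]
    keep_ids <- unique(unlist(lapply(graph$edges,
                                     function(e) c(e$from, e$to))))
    graph$nodes <- graph$nodes[graph$nodes$id %in% keep_ids, , drop = FALSE]
    graph <- dissolve_degree2(graph)
  }
  dissolve_degree2(graph)
}

#' Merge junction pairs closer than the resolution limit
#'
#' Voxel thinning can leave a junction blob as two degree->=3 nodes a
#' voxel or two apart instead of one cluster. Two genuine branch points
#' closer than about a tube diameter are not resolvable in the image
#' anyway, so edges shorter than `max_len` whose both endpoints are
#' junctions are contracted into a single node at their midpoint. This
#' is part of the automated graph cleanup that stands in for manual
#' editing of reconstructions.
#' @param graph a `capillary_graph`.
#' @param max_len contraction threshold in µm (default 3, below a
#'   typical capillary diameter).
#' @return cleaned `capillary_graph`.
#' @export
merge_close_junctions <- function(graph, max_len = 3) {
  repeat {
    deg <- node_degrees(graph)
    lens <- vapply(graph$edges, function(e) polyline_length(e$coords), 0)
    cand <- which(vapply(seq_along(graph$edges), function(i) {
      e <- graph$edges[[i]]
      e$from != e$to && lens[i] < max_len &&
        deg[as.character(e$from)] >= 3 && deg[as.character(e$to)] >= 3
    }, TRUE))
    if (!length(cand)) break
    e0 <- graph$edges[[cand[1]]]
    keep <- e0$from
    drop <- e0$to
    mid <- (graph$nodes[graph$nodes$id == keep, c("x", "y", "z")] +
              graph$nodes[graph$nodes$id == drop, c("x", "y", "z")]) / 2
    graph$nodes[graph$nodes$id == keep, c("x", "y", "z")] <- mid
    graph$nodes <- graph$nodes[graph$nodes$id != drop, , drop = FALSE]
    newpos <- as.numeric(mid)
    graph$edges <- graph$edges[-cand[1]]
    graph$edges <- lapply(graph$edges, function(e) {
      if (e$from %in% c(keep, drop)) {
        e$from <- keep
        e$coords[1, ] <- newpos
      }
      if (e$to %in% c(keep, drop)) {
        e$to <- keep
        e$coords[nrow(e$coords), ] <- newpos
      }
      e
    })
    # contraction can leave degenerate self-loops from parallel contacts
    graph$edges <- Filter(function(e)
      !(e$from == e$to && polyline_length(e$coords) < max_len),
      graph$edges)
  }
  graph
}

#' Apply axial (z) calibration
#'
#' Multiplies all z world coordinates by `factor`, leaving x and y
#' unchanged: the standard correction for axial shrinkage of thick
#' sections before 3D measurement. For a `voxel_volume` the factor is
#' composed into its `z_calibration` (applied when vectorising); for a
#' `capillary_graph` the node and polyline z coordinates are rescaled.
#' @param x a `capillary_graph` or `voxel_volume`.
#' @param factor multiplicative axial factor (> 0).
#' @return object of the same type.
#' @export
apply_axial_calibration <- function(x, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("calibration factor must be a positive scalar")
  if (inherits(x, "voxel_volume")) {
    x$z_calibration <- x$z_calibration * factor
    x
  } else if (inherits(x, "capillary_graph")) {
    transform_graph(x, function(p) { p[, 3] <- p[, 3] * factor; p })
  } else stop("unsupported type")
}

#' Full image-to-graph reconstruction
#'
#' The standard reconstruction chain: segmentation, curve skeletonisation,
#' graph extraction with junction-cluster merging, spur pruning at voxel
#' resolution, and fixed-step vectorisation. Axial calibration is taken
#' from the volume's `z_calibration` (compose with
#' [apply_axial_calibration()] beforehand to correct shrinkage).
#' @param volume an intensity `voxel_volume`.
#' @param step vectorisation segment length, µm (default 5).
#' @param spur spur-pruning threshold, µm (default 5).
#' @param smooth centreline smoothing window, µm (default 8; 0 disables).
#' @param junction_merge contraction threshold for sub-resolution
#'   junction pairs, µm (see [merge_close_junctions()]; 0 disables).
#' @param method,threshold,min_object_volume passed to
#'   [segment_capillaries()].
#' @return a resampled `capillary_graph`.
#' @export
reconstruct_capillaries <- function(volume, step = 5, spur = 5, smooth = 8,
                                    junction_merge = 3,
                                    method = "otsu", threshold = NULL,
                                    min_object_volume = 100) {
  bin <- segment_capillaries(volume, method = method, threshold = threshold,
                             min_object_volume = min_object_volume)
  sk <- skeletonise(bin)
  g <- skeleton_to_graph(sk)
  g <- prune_spurs(g, spur)
  g <- merge_close_junctions(g, junction_merge)
  g <- smooth_graph(g, smooth)
  resample_graph(g, step)
}
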