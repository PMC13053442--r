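# Shared fixtures, built in code. Expensive objects are memoised per test
# run so several test files can reuse one reconstruction.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# a small field spec that keeps voxel counts low for unit tests
small_spec <- function(...) {
  args <- list(field_size = c(120, 120, 60),
               target_LVm = 6e-4,
               target_NV = 10 / (120 * 120 * 60),
               seed = 42)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_spec, args)
}

# straight polyline graph along a given direction
line_graph <- function(p1, p2, n = 2) {
  tt <- seq(0, 1, length.out = n)
  coords <- cbind(p1[1] + tt * (p2[1] - p1[1]),
                  p1[2] + tt * (p2[2] - p1[2]),
                  p1[3] + tt * (p2[3] - p1[3]))
  nodes <- data.frame(id = 1:2,
                      x = c(p1[1], p2[1]), y = c(p1[2], p2[2]),
                      z = c(p1[3], p2[3]))
  capillary_graph(nodes, list(list(from = 1L, to = 2L, coords = coords)))
}

# graph from a list of polylines (each its own edge, endpoints as nodes)
polyline_graph <- function(polys) {
  nodes <- list(); edges <- list(); id <- 0L
  for (p in polys) {
    id <- id + 1L; a <- id
    nodes[[a]] <- c(a, p[1, ])
    id <- id + 1L; b <- id
    nodes[[b]] <- c(b, p[nrow(p), ])
    edges[[length(edges) + 1L]] <- list(from = a, to = b, coords = p)
  }
  nd <- as.data.frame(do.call(rbind, nodes))
  names(nd) <- c("id", "x", "y", "z")
  capillary_graph(nd, edges)
}

# Y-shaped graph: three arms meeting at the origin-offset centre
y_graph <- function(centre = c(50, 50, 30), arm = 20,
                    arm_lengths = c(arm, arm, arm)) {
  dirs <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
                c(-0.5, -sqrt(3) / 2, 0))
  nodes <- data.frame(id = 1:4,
                      x = c(centre[1], centre[1] + arm_lengths * dirs[, 1]),
                      y = c(centre[2], centre[2] + arm_lengths * dirs[, 2]),
                      z = c(centre[3], centre[3] + arm_lengths * dirs[, 3]))
  edges <- lapply(1:3, function(i)
    list(from = 1L, to = i + 1L,
         coords = rbind(as.numeric(nodes[1, c("x", "y", "z")]),
                        as.numeric(nodes[i + 1, c("x", "y", "z")]))))
  capillary_graph(nodes, edges)
}

# binary voxel volume containing an axis-aligned solid cylinder along z
cylinder_volume <- function(dims = c(21, 21, 30), radius = 3,
                            voxel = c(1, 1, 1)) {
  arr <- array(0L, dims)
  cx <- (dims[1] + 1) / 2; cy <- (dims[2] + 1) / 2
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    if ((i - cx)^2 + (j - cy)^2 <= radius^2) arr[i, j, ] <- 1L
  voxel_volume(arr, voxel)
}

# regular n-gon polygon (closed implicitly), centred at c0
ngon <- function(n, R, c0 = c(0, 0), phase = 0) {
  th <- phase + 2 * pi * (0:(n - 1)) / n
  cbind(c0[1] + R * cos(th), c0[2] + R * sin(th))
}

rotate2 <- function(p, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  p %*% R
}

# cycle count of a voxel skeleton: E - V + C on the 26-adjacency graph
skeleton_cycles <- function(skvol) {
  coords <- which(skvol$data > 0, arr.ind = TRUE)
  V <- nrow(coords)
  if (!V) return(0L)
  d2 <- as.matrix(dist(coords))
  E <- sum(d2 > 0 & d2 < 1.8) / 2   # 26-adjacency: max step sqrt(3)
  lab <- myocap3d:::cpp_label_components(array(as.integer(skvol$data > 0),
                                    dim(skvol$data)),
                              as.integer(dim(skvol$data)), 26L)
  E - V + lab$n
}
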