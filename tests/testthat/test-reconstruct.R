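test_that("noiseless segmentation reproduces the rasterised tube set", {
  spec <- small_spec(seed = 21)
  net <- generate_capillary_network(spec)
  vol <- rasterise_network(net$graph, spec)
  bin <- segment_capillaries(vol, min_object_volume = 0, closing = FALSE)
  expect_identical(bin$data > 0, vol$data > 0)
})

test_that("all-background input signals an empty segmentation", {
  arr <- array(0L, c(20, 20, 10)); arr[3, 3, 3] <- 255L  # sub-threshold dot
  vol <- voxel_volume(arr, c(1, 1, 1))
  expect_error(segment_capillaries(vol, min_object_volume = 50),
               class = "myocap3d_empty_segmentation")
})

test_that("size filtering removes speckles but keeps tubes", {
  spec <- phantom_spec(field_size = c(50, 50, 40), voxel_size = c(1, 1, 1),
                       capillary_radius = 2.5, seed = 1)
  g <- line_graph(c(25, 25, 0), c(25, 25, 40))
  vol <- rasterise_network(g, spec)
  # inject a 10-voxel speckle away from the tube
  vol$data[5:9, 5, 5] <- 255L
  vol$data[5:9, 6, 5] <- 255L
  n_before <- myocap3d:::cpp_label_components(
    array(as.integer(vol$data > 0), dim(vol$data)),
    as.integer(dim(vol$data)), 26L)$n
  bin <- segment_capillaries(vol, min_object_volume = 50)
  n_after <- myocap3d:::cpp_label_components(
    array(as.integer(bin$data > 0), dim(bin$data)),
    as.integer(dim(bin$data)), 26L)$n
  expect_equal(n_before, 2)
  expect_equal(n_after, 1)
  expect_false(any(bin$data[5:9, 5:6, 5] > 0))
})

test_that("skeleton of a solid cylinder is a unit-width axial path", {
  vol <- cylinder_volume(dims = c(21, 21, 30), radius = 3)
  sk <- skeletonise(vol)
  coords <- which(sk$data > 0, arr.ind = TRUE)
  # subset of the input foreground
  expect_true(all(vol$data[sk$data > 0] > 0))
  # single component spanning the full z extent
  lab <- myocap3d:::cpp_label_components(
    array(as.integer(sk$data), dim(sk$data)), as.integer(dim(sk$data)), 26L)
  expect_equal(lab$n, 1)
  # thinning erodes tube ends by about one tube radius
  zr <- range(coords[, 3])
  expect_lte(zr[1], 1 + 3 + 1)
  expect_gte(zr[2], 30 - 3 - 1)
  # unit width: at most one voxel per slice away from the ends
  slice_counts <- table(coords[, 3])
  expect_true(all(slice_counts == 1))
})

test_that("disjoint tubes keep their component count through thinning", {
  arr <- array(0L, c(30, 30, 25))
  vol <- voxel_volume(arr, c(1, 1, 1))
  spec <- phantom_spec(field_size = c(30, 30, 25), voxel_size = c(1, 1, 1),
                       capillary_radius = 2, seed = 1)
  g <- polyline_graph(list(rbind(c(8, 8, 0), c(8, 8, 25)),
                           rbind(c(22, 22, 0), c(22, 22, 25))))
  vol <- rasterise_network(g, spec)
  sk <- skeletonise(segment_capillaries(vol, min_object_volume = 0))
  lab <- myocap3d:::cpp_label_components(
    array(as.integer(sk$data), dim(sk$data)), as.integer(dim(sk$data)), 26L)
  expect_equal(lab$n, 2)
})

test_that("a rasterised loop thins to a skeleton with exactly one cycle", {
  spec <- phantom_spec(field_size = c(60, 60, 20), voxel_size = c(1, 1, 1),
                       capillary_radius = 2.5, seed = 1)
  th <- seq(0, 2 * pi, length.out = 73)
  ring <- cbind(30 + 18 * cos(th), 30 + 18 * sin(th), 10)
  nodes <- data.frame(id = 1L, x = ring[1, 1], y = ring[1, 2], z = 10)
  g <- capillary_graph(nodes, list(list(from = 1L, to = 1L, coords = ring)),
                       validate = FALSE)
  vol <- rasterise_network(g, spec)
  sk <- skeletonise(segment_capillaries(vol, min_object_volume = 0))
  expect_equal(skeleton_cycles(sk), 1)
})

test_that("skeleton graphs have the expected nodes, edges and lengths", {
  # straight path of 11 collinear voxels at 1 um spacing
  arr <- array(0L, c(15, 5, 5))
  arr[3:13, 3, 3] <- 1L
  g <- skeleton_to_graph(voxel_volume(arr, c(1, 1, 1)))
  expect_equal(nrow(g$nodes), 2)
  expect_length(g$edges, 1)
  expect_equal(total_length(g), 10)

  # Y: three arms meeting at one voxel
  arr <- array(0L, c(21, 21, 5))
  arr[11, 11, 3] <- 1L
  arr[12:18, 11, 3] <- 1L          # +x arm
  arr[4:10, 11, 3] <- 1L           # -x arm
  arr[11, 12:18, 3] <- 1L          # +y arm
  gy <- skeleton_to_graph(voxel_volume(arr, c(1, 1, 1)))
  deg <- node_degrees(gy)
  expect_equal(sum(deg == 3), 1)
  expect_equal(sum(deg == 1), 3)
  expect_length(gy$edges, 3)
})

test_that("polyline resampling respects step, endpoints and length bounds", {
  seg <- rbind(c(0, 0, 0), c(20, 0, 0))
  rs <- resample_polyline(seg, 5)
  expect_equal(nrow(rs), 5)
  expect_equal(diff(rs[, 1]), rep(5, 4))
  expect_equal(rs[1, ], c(x = 0, y = 0, z = 0))
  expect_equal(rs[5, ], c(x = 20, y = 0, z = 0))

  # quarter circle, radius 10: chord sum below arc, above straight distance
  th <- seq(0, pi / 2, length.out = 200)
  qc <- cbind(10 * cos(th), 10 * sin(th), 0)
  rs5 <- resample_polyline(qc, 5)
  len5 <- polyline_length(rs5)
  expect_lt(len5, pi / 2 * 10)
  expect_gte(len5, sqrt(200))

  # step larger than the curve: endpoints only
  rs_big <- resample_polyline(seg, 50)
  expect_equal(nrow(rs_big), 2)
  expect_error(resample_polyline(rbind(c(1, 1, 1), c(1, 1, 1)), 5),
               "degenerate")
})

test_that("resampled length increases monotonically as the step shrinks", {
  th <- seq(0, 3 * pi, length.out = 400)
  curve <- cbind(th * 3, 4 * sin(th), 0.5 * th)
  lens <- vapply(c(20, 10, 5, 2, 1, 0.5), function(s)
    polyline_length(resample_polyline(curve, s)), 0)
  expect_true(all(diff(lens) > 0))
  expect_lte(max(lens), polyline_length(curve))
  expect_gt(max(lens) / polyline_length(curve), 0.999)
})

test_that("spur pruning removes short arms and dissolves their junctions", {
  gy <- y_graph(arm_lengths = c(20, 20, 2))
  pruned <- prune_spurs(gy, min_spur_length = 4)
  expect_length(pruned$edges, 1)
  expect_equal(max(node_degrees(pruned)), 1)
  expect_equal(total_length(pruned), 40)
  # nothing below threshold: identity
  gy2 <- y_graph(arm_lengths = c(20, 20, 10))
  expect_equal(total_length(prune_spurs(gy2, 4)), 50)
  expect_equal(sum(node_degrees(prune_spurs(gy2, 4)) == 3), 1)
})

test_that("axial calibration rescales z and only z", {
  g <- line_graph(c(5, 5, 0), c(5, 5, 50), n = 6)
  expect_identical(apply_axial_calibration(g, 1), g)
  g2 <- apply_axial_calibration(g, 2)
  expect_equal(total_length(g2), 100)
  expect_equal(g2$nodes$x, g$nodes$x)
  expect_error(apply_axial_calibration(g, -1), "positive")
})

test_that("pipeline length fidelity and calibration equivariance hold", {
  spec <- small_spec(seed = 31)
  net <- generate_capillary_network(spec)
  vol <- rasterise_network(net$graph, spec)
  g <- reconstruct_capillaries(vol)
  expect_lt(abs(total_length(g) - net$truth$total_length) /
              net$truth$total_length, 0.05)
  # scaling all z by f with z_calibration 1/f leaves the metrics put
  V <- prod(spec$field_size)
  f <- 0.5
  gz <- transform_graph(net$graph, function(p) {
    p[, 3] <- p[, 3] * f; p
  })
  gz <- apply_axial_calibration(gz, 1 / f)
  for (metric in list(tortuosity,
                      function(x) length_density_LVm(x, V),
                      function(x) branching_density(x, V),
                      anisotropy)) {
    expect_equal(metric(gz), metric(net$graph), tolerance = 0.01)
  }
})
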