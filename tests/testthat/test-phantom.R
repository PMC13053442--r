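test_that("generated networks hit the length-density setpoint", {
  # the generator fills length exactly; assert well inside the 2% contract
  for (seed in 1:5) {
    spec <- small_spec(seed = seed)
    net <- generate_capillary_network(spec)
    V <- prod(spec$field_size)
    expect_lt(abs(net$truth$total_length / V - spec$target_LVm) /
                spec$target_LVm, 0.02)
  }
})

test_that("branch-point count equals the rounded setpoint", {
  spec <- small_spec(seed = 9)
  net <- generate_capillary_network(spec)
  V <- prod(spec$field_size)
  expect_equal(net$truth$n_branch, round(spec$target_NV * V))
  # ground truth is the oracle metric on the vector graph, bit-identical
  expect_identical(net$truth$NV, branching_density(net$graph, V))
  expect_identical(net$truth$LVm, length_density_LVm(net$graph, V))
  expect_identical(net$truth$tortuosity, tortuosity(net$graph))
})

test_that("zero amplitude yields perfectly straight polylines", {
  spec <- small_spec(tortuosity_amplitude = 0, seed = 2)
  net <- generate_capillary_network(spec)
  expect_lt(net$truth$tortuosity, 1e-10)
})

test_that("generation is deterministic in the seed", {
  n1 <- generate_capillary_network(small_spec(seed = 5))
  n2 <- generate_capillary_network(small_spec(seed = 5))
  expect_identical(n1$graph, n2$graph)
  n3 <- generate_capillary_network(small_spec(seed = 6))
  expect_false(isTRUE(all.equal(n1$graph$nodes, n3$graph$nodes)))
})

test_that("infeasible branch requests raise an explicit error", {
  spec <- small_spec(target_NV = 0.4 / prod(c(120, 120, 60)))
  expect_error(generate_capillary_network(spec), "infeasible")
})

test_that("exact tortuosity is monotone in the perturbation amplitude", {
  vals <- vapply(c(0, 2, 4), function(a)
    generate_capillary_network(small_spec(tortuosity_amplitude = a,
                                          seed = 3))$truth$tortuosity, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("anisotropy increases with the orientation concentration", {
  # single layouts fluctuate; the property holds for the seed-averaged value
  mean_aniso <- function(k) mean(vapply(3:5, function(s)
    generate_capillary_network(small_spec(orientation_kappa = k,
                                          seed = s))$truth$anisotropy, 0))
  vals <- vapply(c(0.5, 4, 20), mean_aniso, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("tortuosity setpoint calibration hits the target exactly", {
  spec <- small_spec(target_tortuosity = 0.030, seed = 8)
  net <- generate_capillary_network(spec)
  # exact up to layout rearrangement between candidate amplitudes
  expect_equal(net$truth$tortuosity, 0.030, tolerance = 0.03)
})

test_that("rasterised straight tube has the analytic disc cross-section", {
  spec <- phantom_spec(field_size = c(40, 40, 30), voxel_size = c(1, 1, 1),
                       capillary_radius = 2.5, seed = 1)
  g <- line_graph(c(20.3, 19.6, 0), c(20.3, 19.6, 30))
  vol <- rasterise_network(g, spec)
  # brute-force oracle: test every voxel centre against the disc
  centres <- expand.grid(x = (1:40) - 0.5, y = (1:40) - 0.5)
  disc <- sum((centres$x - 20.3)^2 + (centres$y - 19.6)^2 <= 2.5^2)
  per_slice <- apply(vol$data > 0, 3, sum)
  expect_true(all(per_slice == disc))
  expect_equal(disc, pi * 2.5^2, tolerance = 0.15)
})

test_that("empty graphs rasterise to all-background volumes", {
  spec <- phantom_spec(field_size = c(30, 30, 20), voxel_size = c(1, 1, 1))
  empty <- capillary_graph(data.frame(id = integer(), x = numeric(),
                                      y = numeric(), z = numeric()), list())
  vol <- rasterise_network(empty, spec)
  expect_true(all(vol$data == 0))
})

test_that("sub-voxel radii trigger the thin-structure warning", {
  spec <- phantom_spec(field_size = c(30, 30, 20), voxel_size = c(1, 1, 1),
                       capillary_radius = 0.5)
  g <- line_graph(c(15, 15, 0), c(15, 15, 20))
  expect_warning(rasterise_network(g, spec), "connectivity")
})

test_that("axial shrinkage is undone by the matching calibration", {
  spec_ref <- small_spec(seed = 12)
  spec_shr <- small_spec(seed = 12, z_shrinkage = 0.5)
  ref <- run_capillary_field(spec_ref)
  shr <- run_capillary_field(spec_shr)   # z-calibration 2 applied internally
  expect_lt(abs(shr$measured$LVm - ref$measured$LVm) / ref$measured$LVm,
            0.05)
  # the shrunk stack has half the axial sampling, so truth recovery is a
  # little looser than in the unshrunk run
  expect_lt(abs(shr$measured$LVm - shr$truth$LVm) / shr$truth$LVm, 0.08)
})

test_that("fibre phantoms produce the requested labelled population", {
  spec <- phantom_spec(field_size = c(250, 250, 40), voxel_size = c(1, 1, 1),
                       n_fibres = 40, fibre_diameter_mean = 30,
                       fibre_diameter_sd = 6, seed = 4)
  fp <- generate_fibre_phantom(spec)
  labs <- setdiff(unique(as.vector(fp$labels$data)), 0L)
  expect_length(labs, 40)
  expect_length(fp$fibres$fibres, 40)
  expect_true(all(vapply(fp$fibres$fibres, `[[`, 0, "volume") > 0))
  expect_equal(fp$fibres$total_axial_length, 40 * 40)
})

test_that("single-fibre ground truth follows the cylinder formulae", {
  spec <- phantom_spec(field_size = c(100, 100, 100),
                       voxel_size = c(1, 1, 1), n_fibres = 1,
                       fibre_diameter_mean = 60, fibre_diameter_sd = 1e-6,
                       seed = 2)
  fp <- generate_fibre_phantom(spec)
  f <- fp$fibres$fibres[[1]]
  # hexagonal prism with across-flats ~60 um through a 100 um stack
  A_hex <- (sqrt(3) / 2) * (60 / sqrt(3))^2 * 3
  expect_equal(f$volume, A_hex * 100, tolerance = 0.1)
  expect_equal(f$diameter, 60, tolerance = 0.05)
})

test_that("mean fibre diameter setpoints order the generated samples", {
  spec_small <- phantom_spec(field_size = c(400, 400, 40),
                             voxel_size = c(1, 1, 1), n_fibres = 50,
                             fibre_diameter_mean = 25,
                             fibre_diameter_sd = 5, seed = 6)
  spec_large <- phantom_spec(field_size = c(700, 700, 40),
                             voxel_size = c(1, 1, 1), n_fibres = 50,
                             fibre_diameter_mean = 60,
                             fibre_diameter_sd = 5, seed = 6)
  d_small <- mean(vapply(generate_fibre_phantom(spec_small)$fibres$fibres,
                         `[[`, 0, "diameter"))
  d_large <- mean(vapply(generate_fibre_phantom(spec_large)$fibres$fibres,
                         `[[`, 0, "diameter"))
  expect_gt(d_large, d_small)
})

test_that("impossible fibre diameters raise an infeasibility error", {
  spec <- phantom_spec(field_size = c(100, 100, 40), voxel_size = c(1, 1, 1),
                       n_fibres = 50, fibre_diameter_mean = 80)
  expect_error(generate_fibre_phantom(spec), "infeasible")
})

test_that("serial sections encode the typing convention and exact IMCL", {
  spec <- phantom_spec(field_size = c(220, 220, 40), voxel_size = c(1, 1, 1),
                       n_fibres = 30, fibre_diameter_mean = 30,
                       fibre_diameter_sd = 5, seed = 3)
  # pure type 1 population: BA-D5 positive, others negative
  ss1 <- generate_serial_sections(spec, c("1" = 1),
                                  c("1" = 5), pixel_size = 1)
  expect_true(all(ss1$truth$bad5))
  expect_false(any(ss1$truth$sc71))
  expect_false(any(ss1$truth$h6h1))
  # zero IMCL everywhere leaves the lipid mask empty
  ss0 <- generate_serial_sections(spec, c("1" = 0.5, "2a" = 0.5),
                                  c("1" = 0, "2a" = 0), pixel_size = 1)
  expect_false(any(ss0$lipid))
  # drawn fractions are realised exactly (block + single-pixel top-up)
  ss <- generate_serial_sections(spec, c("1" = 0.5, "2x" = 0.5),
                                 c("1" = 10, "2x" = 3), pixel_size = 1,
                                 jitter_px = 0)
  base <- ss$labels[[1]]
  for (i in ss$truth$fibre) {
    npix <- sum(base == i)
    placed <- 100 * sum(ss$lipid & base == i) / npix
    expect_lt(abs(placed - ss$truth$imcl_target[i]), 100 * 1 / npix + 1e-9)
  }
})
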