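test_that("total length is additive and zero on empty graphs", {
  g1 <- line_graph(c(0, 0, 0), c(0, 0, 5))
  expect_equal(total_length(g1), 5)
  g2 <- polyline_graph(list(rbind(c(0, 0, 0), c(7, 0, 0)),
                            rbind(c(0, 10, 0), c(0, 10, 3))))
  expect_equal(total_length(g2), 10)
  empty <- capillary_graph(data.frame(id = integer(), x = numeric(),
                                      y = numeric(), z = numeric()), list())
  expect_equal(total_length(empty), 0)
})

test_that("length density is length over volume and homogeneous", {
  # 9000 um of straight capillary in a standard field volume
  segs <- lapply(1:90, function(i)
    rbind(c(4 * i, 4 * i, 0), c(4 * i, 4 * i, 100)))
  g <- polyline_graph(segs)
  V <- 387.5^2 * 100
  expect_equal(length_density_LVm(g, V), 9000 / V)
  expect_equal(length_density_LVm(g, 2 * V), length_density_LVm(g, V) / 2)
  expect_error(length_density_LVm(g, 0), "positive")
})

test_that("branching density counts degree >= 3 nodes", {
  expect_equal(branching_density(y_graph(), 1000), 1 / 1000)
  path <- line_graph(c(0, 0, 0), c(0, 0, 40), n = 10)
  expect_equal(branching_density(path, 1000), 0)
})

test_that("mean capillary length follows the two-thirds ratio", {
  expect_equal(mean_capillary_length(3, 2), 1)
  expect_equal(mean_capillary_length(6e-4, 1.37e-6),
               (2 / 3) * 6e-4 / 1.37e-6)
  # volume cancels: scaling LV and NV together leaves MeanCap unchanged
  expect_equal(mean_capillary_length(10 * 6e-4, 10 * 1.37e-6),
               mean_capillary_length(6e-4, 1.37e-6))
  expect_warning(res <- mean_capillary_length(1, 0), "undefined")
  expect_true(is.na(res))
})

test_that("MeanCap from field totals equals MeanCap from densities", {
  net <- fixture("net_small", function()
    generate_capillary_network(small_spec()))
  V <- prod(small_spec()$field_size)
  L <- total_length(net$graph)
  nb <- sum(node_degrees(net$graph) >= 3)
  expect_identical(mean_capillary_length(L / V, nb / V),
                   (2 / 3) * L / nb)
  expect_identical(net$truth$MeanCap,
                   mean_capillary_length(net$truth$LVm, net$truth$NV))
})

test_that("tortuosity matches hand-computed turning angles", {
  straight <- line_graph(c(0, 0, 0), c(0, 0, 100), n = 21)
  expect_equal(tortuosity(straight), 0, tolerance = 1e-12)
  # one 90 degree bend on a 100 um polyline
  bend <- polyline_graph(list(rbind(c(0, 0, 0), c(50, 0, 0), c(50, 50, 0))))
  expect_equal(tortuosity(bend), (pi / 2) / 100)
  # planar zigzag: n interior vertices each turning by theta
  theta <- 0.4
  nseg <- 13
  step <- 5
  dirs <- t(vapply(seq_len(nseg), function(i) {
    a <- ifelse(i %% 2 == 0, theta / 2, -theta / 2)
    c(cos(a), sin(a), 0)
  }, numeric(3)))
  pts <- rbind(c(0, 0, 0), apply(dirs * step, 2, cumsum))
  zig <- polyline_graph(list(pts))
  # brute-force oracle: accumulate acos of consecutive direction dots
  oracle <- 0
  for (i in 2:(nrow(pts) - 1)) {
    u <- pts[i, ] - pts[i - 1, ]; v <- pts[i + 1, ] - pts[i, ]
    oracle <- oracle +
      acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  expect_equal(tortuosity(zig), oracle / (nseg * step), tolerance = 1e-10)
  expect_equal(tortuosity(zig), (nseg - 1) * theta / (nseg * step),
               tolerance = 1e-10)
})

test_that("tortuosity and companion metrics obey the scale laws", {
  net <- fixture("net_small", function()
    generate_capillary_network(small_spec()))
  g <- net$graph
  V <- prod(small_spec()$field_size)
  s <- 2.5
  gs <- transform_graph(g, function(p) p * s)
  expect_equal(tortuosity(gs), tortuosity(g) / s, tolerance = 1e-9)
  expect_equal(anisotropy(gs), anisotropy(g), tolerance = 1e-9)
  expect_equal(length_density_LVm(gs, V * s^3),
               length_density_LVm(g, V) / s^2, tolerance = 1e-9)
  expect_equal(branching_density(gs, V * s^3),
               branching_density(g, V) / s^3, tolerance = 1e-12)
})

test_that("tortuosity is invariant under rotation and translation", {
  net <- fixture("net_small", function()
    generate_capillary_network(small_spec()))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  gr <- transform_graph(net$graph, function(p)
    sweep(p %*% R, 2, c(11, -4, 30), "+"))
  expect_equal(tortuosity(gr), tortuosity(net$graph), tolerance = 1e-9)
  expect_equal(anisotropy(gr), anisotropy(net$graph), tolerance = 1e-6)
})

test_that("anisotropy is 1 for an orthogonal triad and flags parallel sets", {
  triad <- polyline_graph(list(rbind(c(0, 0, 0), c(10, 0, 0)),
                               rbind(c(0, 0, 0), c(0, 10, 0)),
                               rbind(c(0, 0, 0), c(0, 0, 10))))
  expect_equal(anisotropy(triad), 1, tolerance = 1e-12)
  par <- polyline_graph(list(rbind(c(0, 0, 0), c(0, 0, 10)),
                             rbind(c(5, 5, 0), c(5, 5, 10))))
  expect_warning(a <- anisotropy(par), "degenerate")
  expect_identical(a, Inf)
})

test_that("anisotropy matches an explicit-summation Monte Carlo oracle", {
  set.seed(99)
  n <- 10000
  kappa <- 5
  # draw axial directions (same model as the generator, sampled here)
  u <- runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  dirs <- cbind(s * cos(phi), s * sin(phi), w)
  lens <- runif(n, 4, 6)
  polys <- lapply(seq_len(n), function(i)
    rbind(c(0, 0, 0), dirs[i, ] * lens[i]))
  g <- polyline_graph(polys)
  # oracle: accumulate the tensor by explicit per-segment summation
  T <- matrix(0, 3, 3)
  for (i in seq_len(n)) T <- T + lens[i] * tcrossprod(dirs[i, ])
  T <- T / sum(lens)
  ev <- sort(eigen(T, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(anisotropy(g), ev[1] / mean(ev[2:3]), tolerance = 0.01)
  expect_gte(anisotropy(g), 1)
  # alternative eigenvalue-ratio conventions stay ordered
  expect_gte(anisotropy(g, "max_over_min"), anisotropy(g, "max_over_mid"))
})

test_that("fibre geometry recovers cylinder, frustum and square", {
  n <- 96; R <- 15
  circle <- ngon(n, R)
  A_exact <- 0.5 * n * R^2 * sin(2 * pi / n)
  P_exact <- 2 * n * R * sin(pi / n)
  fg <- fibre_geometry(rep(list(circle), 4), c(12.5, 37.5, 62.5, 87.5),
                       z_range = c(0, 100))
  expect_equal(fg$volume, A_exact * 100, tolerance = 1e-9)
  expect_equal(fg$surface, P_exact * 100, tolerance = 1e-9)
  expect_equal(fg$diameter, 2 * R * cos(pi / n), tolerance = 1e-9)
  expect_equal(fg$volume, pi * R^2 * 100, tolerance = 0.01)

  # cone-like taper 20 -> 10 um radius: trapezoid of quadratic areas
  zz <- seq(0, 100, length.out = 5)
  rr <- seq(20, 10, length.out = 5)
  cone <- lapply(rr, function(r) ngon(256, r))
  fgc <- fibre_geometry(cone, zz)
  frustum <- pi * 100 / 3 * (20^2 + 20 * 10 + 10^2)
  # trapezoid overestimates a convex quadratic by at most h^2/12 * max|f''|
  bound <- length(zz) * diff(zz)[1]^3 / 12 * 2 * pi / 100^0  # loose bound
  expect_lt(abs(fgc$volume - frustum), 0.01 * frustum)

  square <- rbind(c(0, 0), c(8, 0), c(8, 8), c(0, 8))
  fgs <- fibre_geometry(list(square, square), c(10, 90), z_range = c(0, 100))
  expect_equal(fgs$diameter, 8)
  expect_error(
    fibre_geometry(list(rbind(c(0, 0), c(4, 4), c(4, 0), c(0, 4)),
                        square), c(10, 90), fibre_id = 7),
    "self-intersecting")
})

test_that("fibre-normalised densities match hand-computed values", {
  g <- line_graph(c(10, 10, 0), c(10, 10, 100), n = 8)  # not used for length
  g350 <- polyline_graph(list(rbind(c(5, 5, 0), c(5, 5, 100)),
                              rbind(c(20, 5, 0), c(20, 5, 100)),
                              rbind(c(35, 5, 0), c(35, 5, 100)),
                              rbind(c(50, 5, 0), c(50, 5, 50))))
  fib1 <- list(total_axial_length = 100, total_surface = 2e4,
               total_volume = 9e4)
  fn <- fibre_normalised_densities(g350, fib1)
  expect_equal(fn$LL, 350 / 100)
  expect_equal(fn$LSf, 350 / 2e4)
  expect_equal(fn$LVf, 350 / 9e4)
  fib2 <- fib1; fib2$total_volume <- fib1$total_volume / 2
  expect_equal(fibre_normalised_densities(g350, fib2)$LVf, 2 * fn$LVf)
  expect_error(fibre_normalised_densities(
    g350, list(total_axial_length = 0, total_surface = 1,
               total_volume = 1)), "positive")
})

test_that("reporting-scale table applies conventional factors", {
  net <- fixture("net_small", function()
    generate_capillary_network(small_spec()))
  V <- prod(small_spec()$field_size)
  m <- compute_morphometry(net$graph, V)
  tab <- format_morphometry(m)
  expect_equal(tab$LVm, m$LVm * 1e6)
  expect_equal(tab$tortuosity, m$tortuosity * 1e3)
  expect_equal(tab$Br_dens, m$Br_dens * 1e6)
  expect_equal(tab$MeanCap, m$MeanCap)
  expect_named(tab, c("LVm", "tortuosity", "anisotropy", "MeanCap",
                      "Br_dens", "LVf", "LSf", "LL"))
})
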