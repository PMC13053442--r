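# Synthetic phantoms: capillary networks, fibre territories and serial
# sections with exactly known vector ground truth.

# run code with a private RNG stream, restoring the caller's state
with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Phantom specification
#'
#' Parameters of the synthetic field: geometry of the imaged volume,
#' capillary network setpoints (length density, branch-point density,
#' tortuosity, orientation concentration), tube radius, axial shrinkage
#' and the fibre population. Defaults emulate a confocal field of view of
#' 387.5 x 387.5 x 100 µm sampled at 0.76 µm pixels and 1 µm optical
#' steps, with network setpoints in the range reported for human limb and
#' trunk muscles (length density about 6e-4 µm^-2, branch-point density
#' about 1.4e-6 µm^-3).
#'
#' @param field_size c(x, y, z) extent in µm.
#' @param voxel_size c(dx, dy, dz) in µm.
#' @param target_LVm capillary length per tissue volume, µm^-2.
#' @param target_NV branch points per tissue volume, µm^-3.
#' @param tortuosity_amplitude transverse sinusoidal perturbation amplitude
#'   in µm; 0 gives perfectly straight polylines.
#' @param target_tortuosity optional exact-tortuosity setpoint
#'   (rad µm^-1); when given, the amplitude is calibrated by root-finding
#'   so the generated graph's exterior-angle tortuosity hits the setpoint.
#' @param wavelength undulation wavelength of the perturbation, µm.
#' @param orientation_kappa concentration (>= 0) of trunk orientations
#'   about the fibre (z) axis; larger is more axial.
#' @param capillary_radius tube radius in µm.
#' @param z_shrinkage axial compression factor in (0, 1] applied at
#'   rasterisation, emulating shrinkage of thick sections.
#' @param fibre_diameter_mean,fibre_diameter_sd lognormal fibre minimal
#'   Feret diameter distribution, µm.
#' @param n_fibres number of fibres in the field.
#' @param noise_sd additive Gaussian intensity noise SD (8-bit scale),
#'   default 0 (off).
#' @param seed integer RNG seed; the phantom is a deterministic function
#'   of the spec including the seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(field_size = c(387.5, 387.5, 100),
                         voxel_size = c(0.76, 0.76, 1),
                         target_LVm = 598.75e-6,
                         target_NV = 1.37e-6,
                         tortuosity_amplitude = 2,
                         target_tortuosity = NULL,
                         wavelength = 50,
                         orientation_kappa = 6,
                         capillary_radius = 2.5,
                         z_shrinkage = 1,
                         fibre_diameter_mean = 55,
                         fibre_diameter_sd = 11,
                         n_fibres = 100,
                         noise_sd = 0,
                         seed = 1L) {
  spec <- list(field_size = as.numeric(field_size),
               voxel_size = as.numeric(voxel_size),
               target_LVm = target_LVm, target_NV = target_NV,
               tortuosity_amplitude = tortuosity_amplitude,
               target_tortuosity = target_tortuosity,
               wavelength = wavelength,
               orientation_kappa = orientation_kappa,
               capillary_radius = capillary_radius,
               z_shrinkage = z_shrinkage,
               fibre_diameter_mean = fibre_diameter_mean,
               fibre_diameter_sd = fibre_diameter_sd,
               n_fibres = n_fibres, noise_sd = noise_sd,
               seed = as.integer(seed))
  with(spec, stopifnot(
    length(field_size) == 3, all(field_size > 0),
    length(voxel_size) == 3, all(voxel_size > 0),
    target_LVm > 0, target_NV >= 0,
    tortuosity_amplitude >= 0, wavelength > 0,
    orientation_kappa >= 0, capillary_radius > 0,
    z_shrinkage > 0, z_shrinkage <= 1,
    fibre_diameter_mean > 0, fibre_diameter_sd >= 0, n_fibres >= 1,
    noise_sd >= 0))
  structure(spec, class = "phantom_spec")
}

# axially symmetric von Mises-Fisher draw about +z; kappa = 0 is isotropic
rvmf_axis <- function(kappa) {
  u <- stats::runif(1)
  w <- if (kappa <= 0) stats::runif(1, -1, 1)
  else 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(max(0, 1 - w^2))
  d <- c(s * cos(phi), s * sin(phi), w)
  if (d[3] < 0) d <- -d          # orientation-symmetric: fold to upper half
  d
}

# one trunk polyline: straight axis from a vMF direction plus a transverse
# sinusoid of given amplitude, vertices at ~1 µm arc steps, confined to the
# field box with a safety margin, truncated to at most max_len (the final
# vertex interpolated so the arc length is exact)
make_trunk <- function(spec, amplitude, max_len) {
  box <- spec$field_size
  mrg <- min(spec$capillary_radius + amplitude + 0.5, min(box) / 4)
  u0 <- rvmf_axis(spec$orientation_kappa)
  start <- stats::runif(3, mrg, box - mrg)
  # orthonormal transverse basis
  ref <- if (abs(u0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u0) * u0; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u0[2] * e1[3] - u0[3] * e1[2],
          u0[3] * e1[1] - u0[1] * e1[3],
          u0[1] * e1[2] - u0[2] * e1[1])
  # parameter range keeping the axis inside the margin box
  tlim <- c(-Inf, Inf)
  for (a in 1:3) if (abs(u0[a]) > 1e-9) {
    b <- sort(c((mrg - start[a]) / u0[a], (box[a] - mrg - start[a]) / u0[a]))
    tlim <- c(max(tlim[1], b[1]), min(tlim[2], b[2]))
  }
  tt <- seq(tlim[1], tlim[2], by = 1)
  if (length(tt) < 3) return(NULL)
  ph <- stats::runif(2, 0, 2 * pi)
  wob1 <- amplitude * sin(2 * pi * tt / spec$wavelength + ph[1])
  wob2 <- amplitude * sin(2 * pi * tt / spec$wavelength + ph[2])
  pts <- cbind(start[1] + tt * u0[1] + wob1 * e1[1] + wob2 * e2[1],
               start[2] + tt * u0[2] + wob1 * e1[2] + wob2 * e2[2],
               start[3] + tt * u0[3] + wob1 * e1[3] + wob2 * e2[3])
  # truncate to max_len exactly
  d <- sqrt(rowSums(diff(pts)^2))
  cs <- c(0, cumsum(d))
  if (cs[length(cs)] > max_len) {
    i <- max(2, findInterval(max_len, cs))
    if (cs[i] >= max_len) i <- i - 1
    frac <- (max_len - cs[i]) / (cs[i + 1] - cs[i])
    pts <- if (frac < 1e-9) pts[1:i, , drop = FALSE] else
      rbind(pts[1:i, , drop = FALSE],
            pts[i, ] + frac * (pts[i + 1, ] - pts[i, ]))
  }
  if (nrow(pts) < 2 || polyline_length(pts) <= 0) return(NULL)
  pts
}

# The trunk length budget is a fraction of the total; connectors consume
# the rest. In small or branch-dense fields the realised connector length
# can overshoot the reserve, so the fraction is lowered and the build
# retried (deterministically, inside one seeded stream).
build_network <- function(spec, amplitude, trunk_frac = 0.88) {
  for (attempt in 1:6) {
    g <- build_network_once(spec, amplitude, trunk_frac)
    if (!is.numeric(g)) return(g)
    # g = overshoot in µm; shrink the trunk budget and retry
    trunk_frac <- trunk_frac *
      max(0.3, 1 - (g + 5) / (spec$target_LVm * prod(spec$field_size)))
    if (trunk_frac < 0.05) break
  }
  stop("infeasible phantom: connector length for the requested branch ",
       "density exceeds the total length budget")
}

# vertices of a straight connector at ~1 µm spacing
connector_points <- function(pa, pb) {
  len <- sqrt(sum((pb - pa)^2))
  tt <- seq(0, 1, length.out = max(2, ceiling(len) + 1))
  cbind(pa[1] + tt * (pb[1] - pa[1]),
        pa[2] + tt * (pb[2] - pa[2]),
        pa[3] + tt * (pb[3] - pa[3]))
}

# A connector's interior must stay clear of every tube except the two it
# joins, and of those two only near the attachment itself. Exclusion is
# therefore source-aware: only points of trunk `ta` within `end_excl` of
# `pa` (resp. `tb` near `pb`) are removed from the test; a third tube
# crossing mid-connector is always seen, however short the connector.
connector_clear <- function(pa, pb, cloud, cloud_src, ta, tb,
                            min_sep, end_excl = 12) {
  if (is.null(cloud) || !nrow(cloud)) return(TRUE)
  pts <- connector_points(pa, pb)
  d_a <- sqrt(rowSums((pts - matrix(pa, nrow(pts), 3, byrow = TRUE))^2))
  d_b <- sqrt(rowSums((pts - matrix(pb, nrow(pts), 3, byrow = TRUE))^2))
  interior <- pts[d_a > 2 & d_b > 2, , drop = FALSE]
  if (!nrow(interior)) return(TRUE)
  ca <- sqrt(rowSums((cloud - matrix(pa, nrow(cloud), 3, byrow = TRUE))^2))
  cb <- sqrt(rowSums((cloud - matrix(pb, nrow(cloud), 3, byrow = TRUE))^2))
  excl <- (cloud_src == ta & ca <= end_excl) |
    (!is.na(tb) & cloud_src == tb & cb <= end_excl)
  clear_of_cloud(interior, cloud[!excl, , drop = FALSE], min_sep)
}

# minimum distance from each row of pts to the accumulated vertex cloud;
# returns TRUE when all distances exceed min_sep (chunked to bound memory)
clear_of_cloud <- function(pts, cloud, min_sep) {
  if (is.null(cloud) || !nrow(cloud) || !nrow(pts)) return(TRUE)
  ms2 <- min_sep^2
  for (lo in seq(1, nrow(cloud), by = 5000)) {
    hi <- min(lo + 4999, nrow(cloud))
    ch <- cloud[lo:hi, , drop = FALSE]
    d2 <- outer(pts[, 1], ch[, 1], "-")^2 +
      outer(pts[, 2], ch[, 2], "-")^2 +
      outer(pts[, 3], ch[, 3], "-")^2
    if (any(d2 < ms2)) return(FALSE)
  }
  TRUE
}

build_network_once <- function(spec, amplitude, trunk_frac) {
  box <- spec$field_size
  V <- prod(box)
  L_target <- spec$target_LVm * V
  n_branch <- round(spec$target_NV * V)
  if (spec$target_NV > 0 && n_branch < 1)
    stop("infeasible phantom: target_NV * volume < 1 branch point; ",
         "enlarge the field or raise target_NV")

  # capillaries may touch only where a branch is intended: polylines keep a
  # clearance of one tube diameter plus a guard band, so that rasterised
  # tubes never fuse and create branch points absent from the ground
  # truth. The guard covers voxelisation overshoot (~half a voxel
  # diagonal per tube) plus the 1-voxel morphological closing, which
  # bridges surface gaps of up to two voxels.
  min_sep <- 2 * spec$capillary_radius + 3.5
  cloud <- NULL
  cloud_src <- integer(0)                 # trunk index; 0 = connector/filler
  grow_cloud <- function(pts, src = 0L) {
    cloud <<- rbind(cloud, pts)
    cloud_src <<- c(cloud_src, rep.int(src, nrow(pts)))
  }

  trunks <- list()
  cum <- 0
  budget <- trunk_frac * L_target
  guard <- 0
  rejects <- 0
  while (cum < budget && guard < 20000) {
    guard <- guard + 1
    tr <- make_trunk(spec, amplitude, max_len = budget - cum)
    if (is.null(tr)) next
    if (polyline_length(tr) < 10 && budget - cum > 20) next
    if (!clear_of_cloud(tr, cloud, min_sep)) {
      rejects <- rejects + 1
      # dense fields: relax gradually rather than loop forever
      if (rejects %% 200 == 0) min_sep <- 0.8 * min_sep
      next
    }
    trunks[[length(trunks) + 1L]] <- tr
    cum <- cum + polyline_length(tr)
    grow_cloud(tr, length(trunks))
  }
  if (length(trunks) < 2 && n_branch > 0)
    stop("infeasible phantom: too few trunks to place branch points")

  # connectors: transverse links between trunks; each full connector
  # creates two degree-3 attachment nodes, a half connector one
  n_full <- n_branch %/% 2L
  n_half <- n_branch %% 2L
  attach <- lapply(trunks, function(x) integer(0))
  connectors <- list()
  # attachments keep clear of trunk ends (a terminal stub shorter than the
  # spur threshold would be pruned downstream, dissolving the junction) and
  # of each other (junction clusters must stay resolvable)
  end_margin <- 9L
  attach_sep <- 7L
  pick_vertex <- function(ti) {
    n <- nrow(trunks[[ti]])
    if (n < 2 * end_margin + 2) return(NA_integer_)
    used <- attach[[ti]]
    avail <- (end_margin + 1):(n - end_margin)
    if (length(used))
      avail <- avail[vapply(avail, function(v)
        all(abs(v - used) > attach_sep), TRUE)]
    if (length(avail) < 1) return(NA_integer_)
    if (length(avail) == 1) avail else sample(avail, 1)
  }
  conn_len <- 0
  for (cfull in seq_len(n_full)) {
    placed <- FALSE
    conn_sep <- min_sep          # relaxed gradually if placement is hard
    for (try in 1:80) {
      if (try %% 15 == 0) conn_sep <- 0.85 * conn_sep
      ta <- sample(length(trunks), 1)
      va <- pick_vertex(ta)
      if (is.na(va)) next
      pa <- trunks[[ta]][va, ]
      cand <- setdiff(sample(length(trunks), min(8, length(trunks))), ta)
      if (!length(cand)) next
      best <- NULL
      for (tb in cand) {
        nb <- nrow(trunks[[tb]])
        if (nb < 2 * end_margin + 2) next
        d2 <- rowSums((trunks[[tb]] - matrix(pa, nb, 3, byrow = TRUE))^2)
        d2[c(seq_len(end_margin), (nb - end_margin + 1):nb)] <- Inf
        for (u in attach[[tb]])
          d2[max(1, u - attach_sep):min(nb, u + attach_sep)] <- Inf
        vb <- which.min(d2)
        if (!is.finite(d2[vb])) next
        if (is.null(best) || d2[vb] < best$d2)
          best <- list(tb = tb, vb = vb, d2 = d2[vb])
      }
      if (is.null(best) || best$d2 < 1) next
      pb <- trunks[[best$tb]][best$vb, ]
      if (!connector_clear(pa, pb, cloud, cloud_src, ta, best$tb,
                           conn_sep)) next
      attach[[ta]] <- c(attach[[ta]], va)
      attach[[best$tb]] <- c(attach[[best$tb]], best$vb)
      connectors[[length(connectors) + 1L]] <-
        list(type = "full", ta = ta, va = va, tb = best$tb, vb = best$vb)
      conn_len <- conn_len + sqrt(best$d2)
      grow_cloud(connector_points(pa, pb))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("infeasible phantom: could not place requested branch points")
  }
  for (chalf in seq_len(n_half)) {
    conn_sep <- min_sep
    for (try in 1:80) {
      if (try %% 15 == 0) conn_sep <- 0.85 * conn_sep
      ta <- sample(length(trunks), 1)
      va <- pick_vertex(ta)
      if (is.na(va)) next
      pa <- trunks[[ta]][va, ]
      phi <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 10, 25)
      dir <- c(cos(phi), sin(phi), stats::runif(1, -0.2, 0.2))
      dir <- dir / sqrt(sum(dir^2))
      pb <- pa + len * dir
      pb <- pmin(pmax(pb, spec$capillary_radius), box - spec$capillary_radius)
      if (sqrt(sum((pb - pa)^2)) < 2) next
      if (!connector_clear(pa, pb, cloud, cloud_src, ta, NA, conn_sep)) next
      grow_cloud(connector_points(pa, pb))
      attach[[ta]] <- c(attach[[ta]], va)
      connectors[[length(connectors) + 1L]] <-
        list(type = "half", ta = ta, va = va, p_free = pb)
      conn_len <- conn_len + sqrt(sum((pb - pa)^2))
      break
    }
  }

  # straight-through filler trunks (no attachments) to hit L_target exactly
  cum <- sum(vapply(trunks, polyline_length, 0)) + conn_len
  if (cum > L_target) return(cum - L_target)   # overshoot: caller retries
  filler <- list()
  guard <- 0
  rejects <- 0
  while (L_target - cum > 0.01 && guard < 20000) {
    guard <- guard + 1
    tr <- make_trunk(spec, amplitude, max_len = L_target - cum)
    if (is.null(tr)) next
    if (!clear_of_cloud(tr, cloud, min_sep)) {
      rejects <- rejects + 1
      if (rejects %% 200 == 0) min_sep <- 0.8 * min_sep
      next
    }
    filler[[length(filler) + 1L]] <- tr
    cum <- cum + polyline_length(tr)
    grow_cloud(tr)
  }

  # ---- assemble the graph
  nodes <- list(); edges <- list()
  new_node <- function(p) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- c(id = id, x = p[1], y = p[2], z = p[3])
    id
  }
  attach_ids <- lapply(trunks, function(x) integer(0))
  for (ti in seq_along(trunks)) {
    pts <- trunks[[ti]]
    brk <- sort(unique(c(1L, attach[[ti]], nrow(pts))))
    ids <- vapply(brk, function(v) new_node(pts[v, ]), 0L)
    attach_ids[[ti]] <- stats::setNames(ids, brk)
    for (s in seq_len(length(brk) - 1)) {
      seg <- pts[brk[s]:brk[s + 1], , drop = FALSE]
      edges[[length(edges) + 1L]] <-
        list(from = ids[s], to = ids[s + 1], coords = seg)
    }
  }
  for (cn in connectors) {
    ida <- attach_ids[[cn$ta]][[as.character(cn$va)]]
    pa <- trunks[[cn$ta]][cn$va, ]
    if (cn$type == "full") {
      idb <- attach_ids[[cn$tb]][[as.character(cn$vb)]]
      pb <- trunks[[cn$tb]][cn$vb, ]
    } else {
      pb <- cn$p_free
      idb <- new_node(pb)
    }
    edges[[length(edges) + 1L]] <-
      list(from = ida, to = idb, coords = rbind(pa, pb))
  }
  for (tr in filler) {
    ia <- new_node(tr[1, ]); ib <- new_node(tr[nrow(tr), ])
    edges[[length(edges) + 1L]] <- list(from = ia, to = ib, coords = tr)
  }
  nodes <- as.data.frame(do.call(rbind, nodes))
  capillary_graph(nodes, edges, validate = FALSE)
}

#' Generate a synthetic capillary network with exact ground truth
#'
#' Grows a spatial graph of axially dominant trunk polylines (orientations
#' drawn from a von Mises-Fisher distribution about the fibre axis),
#' transverse connectors creating the requested number of degree-3 branch
#' points, and straight filler polylines that bring the total centreline
#' length exactly to `target_LVm * volume`. Trunk paths carry a transverse
#' sinusoidal undulation whose amplitude either is taken from the spec or,
#' when `target_tortuosity` is set, is calibrated by root-finding so the
#' exact exterior-angle tortuosity of the generated graph equals the
#' setpoint. Deterministic for a fixed spec (including seed).
#'
#' @param spec a [phantom_spec()].
#' @return list with `graph` (a `capillary_graph`) and `truth`, the exact
#'   vector-graph metrics (`LVm`, `NV`, `tortuosity`, `anisotropy`,
#'   `MeanCap`, `total_length`, `n_branch`, `volume`, `amplitude`).
#' @export
generate_capillary_network <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  V <- prod(spec$field_size)
  gen <- function(a) with_rng_seed(spec$seed, build_network(spec, a))
  amplitude <- spec$tortuosity_amplitude
  if (!is.null(spec$target_tortuosity)) {
    target <- spec$target_tortuosity
    f <- function(a) tortuosity(gen(a)) - target
    hi <- 4
    while (f(hi) < 0 && hi < 64) hi <- hi * 2
    amplitude <- stats::uniroot(f, c(0, hi), tol = 1e-4)$root
  }
  graph <- gen(amplitude)
  LV <- length_density_LVm(graph, V)
  NV <- branching_density(graph, V)
  truth <- list(
    LVm = LV, NV = NV,
    tortuosity = tortuosity(graph),
    anisotropy = anisotropy(graph),
    MeanCap = if (NV > 0) mean_capillary_length(LV, NV) else NA_real_,
    total_length = total_length(graph),
    n_branch = sum(node_degrees(graph) >= 3),
    volume = V, amplitude = amplitude)
  list(graph = graph, truth = truth)
}

#' Rasterise a capillary graph into an image volume
#'
#' Produces the synthetic stand-in for a confocal stack: voxels whose
#' centre lies within `capillary_radius` of any polyline are foreground
#' (intensity 255 on a 0-255 scale, background 0). When `z_shrinkage < 1`
#' the z world coordinates are compressed by that factor before
#' rasterisation, emulating axial deformation of thick sections; the
#' reconstruction then needs an axial calibration of `1/z_shrinkage`.
#' Optional Gaussian intensity noise (SD `spec$noise_sd`) is added from a
#' seed-derived stream.
#' @param graph a `capillary_graph` inside the field box.
#' @param spec the [phantom_spec()] (geometry, radius, shrinkage, noise).
#' @return an intensity `voxel_volume` (z_calibration = 1).
#' @export
rasterise_network <- function(graph, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$capillary_radius < max(spec$voxel_size))
    warning("capillary radius below voxel size: ",
            "thin structures may lose connectivity")
  dims <- as.integer(round(spec$field_size / spec$voxel_size))
  segs <- list()
  for (e in graph$edges) {
    p <- e$coords
    if (nrow(p) < 2) next
    p[, 3] <- p[, 3] * spec$z_shrinkage
    segs[[length(segs) + 1L]] <- cbind(p[-nrow(p), , drop = FALSE],
                                       p[-1, , drop = FALSE])
  }
  vol <- if (length(segs)) {
    cpp_rasterise_tubes(do.call(rbind, segs), dims, spec$voxel_size,
                        spec$capillary_radius)
  } else integer(prod(dims))
  vol <- vol * 255L
  dim(vol) <- dims
  if (spec$noise_sd > 0) {
    vol <- with_rng_seed(spec$seed + 7919L, {
      noisy <- vol + stats::rnorm(length(vol), 0, spec$noise_sd)
      array(as.integer(pmin(255, pmax(0, round(noisy)))), dims)
    })
  }
  voxel_volume(vol, spec$voxel_size, z_calibration = 1)
}

# ---- fibre phantoms -------------------------------------------------------

point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# jittered hexagonal fibre territories; returns list of convex-ish polygons
make_fibre_polygons <- function(spec) {
  A <- spec$field_size[1] * spec$field_size[2]
  n <- spec$n_fibres
  s <- sqrt(2 * A / (sqrt(3) * n))          # ideal spacing for n cells
  # margins cost perimeter sites; tighten the lattice until n cells fit
  lattice <- function(s) {
    dy <- s * sqrt(3) / 2
    centres <- list()
    row <- 0
    y <- 0.45 * s
    while (y < spec$field_size[2] - 0.45 * s + 1e-9) {
      xoff <- if (row %% 2 == 1) s / 2 else 0
      x <- 0.45 * s + xoff
      while (x < spec$field_size[1] - 0.45 * s + 1e-9) {
        centres[[length(centres) + 1L]] <- c(x, y)
        x <- x + s
      }
      row <- row + 1
      y <- y + dy
    }
    centres
  }
  centres <- lattice(s)
  while (length(centres) < n && s > 1) {
    s <- 0.97 * s
    centres <- lattice(s)
  }
  if (spec$fibre_diameter_mean > 0.88 * s)
    stop("infeasible fibre phantom: requested diameters incompatible ",
         "with the field area")
  centres <- centres[sample(length(centres), n)]
  m <- spec$fibre_diameter_mean; sd <- spec$fibre_diameter_sd
  sig2 <- log(1 + (sd / m)^2)
  D <- stats::rlnorm(n, log(m) - sig2 / 2, sqrt(sig2))
  D <- pmin(D, 0.88 * s)
  polys <- vector("list", n)
  ang <- pi / 6 + (0:5) * pi / 3
  for (i in seq_len(n)) {
    R <- D[i] / sqrt(3)                      # across-flats width = D
    jit <- stats::runif(2, -0.04 * s, 0.04 * s)
    rr <- R * stats::runif(6, 0.97, 1.03)
    polys[[i]] <- cbind(centres[[i]][1] + jit[1] + rr * cos(ang),
                        centres[[i]][2] + jit[2] + rr * sin(ang))
  }
  polys
}

rasterise_polygons <- function(polys, dims2, pixel_size) {
  lab <- matrix(0L, dims2[1], dims2[2])
  for (i in seq_along(polys)) {
    p <- polys[[i]]
    bb <- rbind(floor(apply(p, 2, min) / pixel_size),
                ceiling(apply(p, 2, max) / pixel_size))
    xi <- max(1, bb[1, 1]):min(dims2[1], bb[2, 1])
    yi <- max(1, bb[1, 2]):min(dims2[2], bb[2, 2])
    if (!length(xi) || !length(yi)) next
    g <- expand.grid(x = xi, y = yi)
    cx <- (g$x - 0.5) * pixel_size
    cy <- (g$y - 0.5) * pixel_size
    inside <- point_in_polygon(cx, cy, p)
    lab[cbind(g$x[inside], g$y[inside])] <- i
  }
  lab
}

#' Generate a fibre phantom: label volume plus exact fibre model
#'
#' Fibres are prism-like territories running along z: jittered hexagonal
#' cross-sections with a lognormal minimal-Feret diameter distribution at
#' the spec's mean/sd, extruded through the field depth. Ground truth
#' contours are the exact polygons on four evenly spaced planes; derived
#' diameter, lateral surface and volume come from [fibre_geometry()].
#' @param spec a [phantom_spec()] with `n_fibres >= 1`.
#' @return list with `labels` (a label `voxel_volume`) and `fibres`
#'   (a `fibre_model`: per-fibre geometry plus field totals).
#' @export
generate_fibre_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$n_fibres >= 1)
  polys <- with_rng_seed(spec$seed + 104729L, make_fibre_polygons(spec))
  dims <- as.integer(round(spec$field_size / spec$voxel_size))
  lab2 <- rasterise_polygons(polys, dims[1:2], spec$voxel_size[1])
  lab <- array(lab2, dim = dims)
  Lz <- spec$field_size[3]
  plane_z <- Lz * c(1, 3, 5, 7) / 8
  fibres <- lapply(seq_along(polys), function(i) {
    fg <- fibre_geometry(rep(list(polys[[i]]), 4), plane_z,
                         z_range = c(0, Lz), fibre_id = i)
    c(list(id = i, contour = polys[[i]], plane_z = plane_z), fg)
  })
  model <- structure(list(
    fibres = fibres,
    plane_z = plane_z,
    total_axial_length = length(polys) * Lz,
    total_surface = sum(vapply(fibres, `[[`, 0, "surface")),
    total_volume = sum(vapply(fibres, `[[`, 0, "volume"))),
    class = "fibre_model")
  list(labels = voxel_volume(lab, spec$voxel_size), fibres = model)
}

#' @export
print.fibre_model <- function(x, ...) {
  cat(sprintf(
    "<fibre_model> %d fibres, total volume %.3g um^3, surface %.3g um^2\n",
    length(x$fibres), x$total_volume, x$total_surface))
  invisible(x)
}

shift_image <- function(img, dx, dy, fill = 0L) {
  out <- matrix(fill, nrow(img), ncol(img))
  xs <- seq_len(nrow(img)); ys <- seq_len(ncol(img))
  xs_src <- xs - dx; ys_src <- ys - dy
  okx <- xs_src >= 1 & xs_src <= nrow(img)
  oky <- ys_src >= 1 & ys_src <= ncol(img)
  out[xs[okx], ys[oky]] <- img[xs_src[okx], ys_src[oky]]
  out
}

# place lipid pixels inside one fibre so the positive fraction is exact:
# 2x2 droplet blocks first, then single-pixel top-up
place_lipid <- function(mask, frac) {
  npix <- sum(mask)
  target <- round(frac / 100 * npix)
  lip <- matrix(FALSE, nrow(mask), ncol(mask))
  if (target <= 0) return(lip)
  idx <- which(mask, arr.ind = TRUE)
  ord <- sample(nrow(idx))
  placed <- 0
  for (r in ord) {
    if (placed + 4 > target) break
    i <- idx[r, 1]; j <- idx[r, 2]
    if (i + 1 > nrow(mask) || j + 1 > ncol(mask)) next
    blk_i <- c(i, i + 1, i, i + 1); blk_j <- c(j, j, j + 1, j + 1)
    cells <- cbind(blk_i, blk_j)
    if (all(mask[cells]) && !any(lip[cells])) {
      lip[cells] <- TRUE
      placed <- placed + 4
    }
  }
  if (placed < target) {
    free <- which(mask & !lip)
    k <- min(target - placed, length(free))
    if (k > 0) lip[free[sample.int(length(free), k)]] <- TRUE
  }
  lip
}

#' Generate serial sections for fibre typing and IMCL measurement
#'
#' Emulates four successive transverse sections of one sample: three MyHC
#' pseudo-stains (BA-D5, SC-71, 6H1) and a Sudan-Black lipid section, each
#' with its own fibre label map. Each fibre receives a type drawn from
#' `fibre_type_probs`; channel positivity follows the serial-section
#' convention (type 1: BA-D5+; 1/2a: BA-D5+ SC-71+; 2a: SC-71+; 2a/2x:
#' SC-71+ 6H1+; 2x: 6H1+). Positive fibres render bright (about 180),
#' negative fibres dim (about 60) on a dark background, with Gaussian
#' noise. Lipid droplets are placed so each fibre's Sudan-positive area
#' fraction equals its drawn IMCL value exactly (block droplets plus
#' single-pixel top-up). Sections 2-4 are shifted by a small random integer
#' jitter to exercise cross-section matching.
#' @param spec a [phantom_spec()] (field x/y extent and fibre population).
#' @param fibre_type_probs named probabilities over
#'   `c("1", "1/2a", "2a", "2a/2x", "2x")`, summing to 1.
#' @param imcl_by_type named per-type mean IMCL area percentages.
#' @param pixel_size section pixel size, µm.
#' @param noise_sd intensity noise SD.
#' @param jitter_px maximum inter-section misalignment, pixels.
#' @param imcl_sd per-fibre SD of the drawn IMCL value around its type mean.
#' @return object of class `section_set`: `channels` (3 intensity images),
#'   `labels` (4 label maps, Sudan last), `lipid` mask, `pixel_size`,
#'   `truth` (per-fibre type, positivity, drawn and placed IMCL).
#' @export
generate_serial_sections <- function(spec, fibre_type_probs, imcl_by_type,
                                     pixel_size = 1, noise_sd = 6,
                                     jitter_px = 2, imcl_sd = 1) {
  types <- c("1", "1/2a", "2a", "2a/2x", "2x")
  stopifnot(all(names(fibre_type_probs) %in% types),
            abs(sum(fibre_type_probs) - 1) < 1e-8,
            all(imcl_by_type >= 0), all(imcl_by_type <= 100))
  probs <- stats::setNames(rep(0, 5), types)
  probs[names(fibre_type_probs)] <- fibre_type_probs
  imcl_mean <- stats::setNames(rep(0, 5), types)
  imcl_mean[names(imcl_by_type)] <- imcl_by_type
  pos_table <- rbind("1" = c(TRUE, FALSE, FALSE),
                     "1/2a" = c(TRUE, TRUE, FALSE),
                     "2a" = c(FALSE, TRUE, FALSE),
                     "2a/2x" = c(FALSE, TRUE, TRUE),
                     "2x" = c(FALSE, FALSE, TRUE))
  with_rng_seed(spec$seed + 15485863L, {
    polys <- make_fibre_polygons(spec)
    dims2 <- as.integer(round(spec$field_size[1:2] / pixel_size))
    base <- rasterise_polygons(polys, dims2, pixel_size)
    n <- length(polys)
    ftype <- sample(types, n, replace = TRUE, prob = probs)
    pos <- pos_table[ftype, , drop = FALSE]
    render <- function(positive) {
      img <- matrix(30, dims2[1], dims2[2])
      img[base > 0] <- 60
      for (i in which(positive)) img[base == i] <- 180
      if (noise_sd > 0)
        img[] <- pmax(0, img + stats::rnorm(length(img), 0, noise_sd))
      img
    }
    chans <- list(bad5 = render(pos[, 1]),
                  sc71 = render(pos[, 2]),
                  h6h1 = render(pos[, 3]))
    imcl_drawn <- pmin(100, pmax(0, stats::rnorm(n, imcl_mean[ftype],
                                                 ifelse(imcl_mean[ftype] > 0,
                                                        imcl_sd, 0))))
    lipid <- matrix(FALSE, dims2[1], dims2[2])
    imcl_placed <- numeric(n)
    for (i in seq_len(n)) {
      mk <- base == i
      li <- place_lipid(mk, imcl_drawn[i])
      lipid <- lipid | li
      imcl_placed[i] <- 100 * sum(li) / sum(mk)
    }
    shifts <- matrix(sample(-jitter_px:jitter_px, 6, replace = TRUE), 3, 2)
    labels <- list(
      base,
      shift_image(base, shifts[1, 1], shifts[1, 2]),
      shift_image(base, shifts[2, 1], shifts[2, 2]),
      shift_image(base, shifts[3, 1], shifts[3, 2]))
    chans$sc71 <- shift_image(chans$sc71, shifts[1, 1], shifts[1, 2], 30)
    chans$h6h1 <- shift_image(chans$h6h1, shifts[2, 1], shifts[2, 2], 30)
    lipid_sh <- shift_image(lipid, shifts[3, 1], shifts[3, 2], FALSE)
    truth <- data.frame(fibre = seq_len(n), type = ftype,
                        bad5 = pos[, 1], sc71 = pos[, 2], h6h1 = pos[, 3],
                        imcl_target = imcl_drawn, imcl_placed = imcl_placed)
    structure(list(channels = chans, labels = labels, lipid = lipid_sh,
                   pixel_size = pixel_size, truth = truth,
                   shifts = shifts),
              class = "section_set")
  })
}
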