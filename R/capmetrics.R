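#' Total capillary length
#'
#' Sum of all polyline segment lengths in the graph, in micrometres.
#' Additive over disjoint subgraphs; an empty graph has length 0.
#' @param graph a `capillary_graph`.
#' @return length in µm.
#' @export
total_length <- function(graph) {
  if (!length(graph$edges)) return(0)
  sum(vapply(graph$edges, function(e) polyline_length(e$coords), 0))
}

#' Capillary length density per tissue volume (LVm)
#'
#' Total centreline length divided by the reference tissue volume.
#' Internally in µm^-2; Table-style reporting (x 1e6) is applied only at
#' serialisation (see [format_morphometry()]).
#' @param graph a `capillary_graph`.
#' @param reference_volume tissue volume in µm^3 (> 0).
#' @return length density in µm^-2.
#' @export
length_density_LVm <- function(graph, reference_volume) {
  if (!is.numeric(reference_volume) || reference_volume <= 0)
    stop("reference_volume must be positive")
  total_length(graph) / reference_volume
}

#' Capillary branching density
#'
#' Number of nodes of degree >= 3 per unit tissue volume.
#' @inheritParams length_density_LVm
#' @return branch-point density in µm^-3.
#' @export
branching_density <- function(graph, reference_volume) {
  if (!is.numeric(reference_volume) || reference_volume <= 0)
    stop("reference_volume must be positive")
  sum(node_degrees(graph) >= 3L) / reference_volume
}

#' Mean capillary length
#'
#' `MeanCap = (2/3) * L_V / N_V`: two-thirds of the capillary length per
#' unit volume divided by the branching-point density. The reference volume
#' cancels, so the same value is obtained from raw field totals.
#' @param LV length density (µm^-2).
#' @param NV branching density (µm^-3).
#' @return mean capillary length in µm; `NA` with a warning when `NV` is 0
#'   (the quantity is undefined, not zero or infinite).
#' @export
mean_capillary_length <- function(LV, NV) {
  stopifnot(is.numeric(LV), is.numeric(NV), LV >= 0, NV >= 0)
  if (NV == 0) {
    warning("branching density is zero: MeanCap undefined")
    return(NA_real_)
  }
  (2 / 3) * LV / NV
}

#' Exterior-angle tortuosity
#'
#' At every interior vertex of every edge polyline the exterior (turning)
#' angle between consecutive segments is accumulated; the sum is divided by
#' the total capillary length. Straight polylines contribute zero. The
#' measure is invariant under rotation and translation and scales as 1/s
#' under coordinate scaling by s. Junction vertices are node endpoints of
#' their polylines and therefore contribute no angle.
#' @param graph a resampled `capillary_graph`.
#' @return tortuosity in rad µm^-1; `NA` with a warning for zero total length.
#' @export
tortuosity <- function(graph) {
  L <- total_length(graph)
  if (L <= 0) {
    warning("zero total length: tortuosity undefined")
    return(NA_real_)
  }
  ang <- 0
  for (e in graph$edges) {
    d <- diff(e$coords)
    l <- sqrt(rowSums(d^2))
    keep <- l > 1e-9          # duplicated vertices carry no direction
    d <- d[keep, , drop = FALSE]
    if (nrow(d) < 2) next
    u <- d / sqrt(rowSums(d^2))
    a <- u[-nrow(u), , drop = FALSE]
    b <- u[-1, , drop = FALSE]
    dots <- pmin(1, pmax(-1, rowSums(a * b)))
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    ang <- ang + sum(atan2(sqrt(rowSums(cr^2)), dots))
  }
  ang / L
}

#' Structure-tensor anisotropy of segment orientations
#'
#' Builds the length-weighted second-moment tensor
#' `T = sum_i l_i u_i u_i' / sum_i l_i` over unit segment directions
#' (orientation-symmetric: u and -u are equivalent) and returns a ratio of
#' its eigenvalues. The ratio convention is configurable because several are
#' in use; the default, largest eigenvalue over the mean of the remaining
#' two, equals 1 for isotropic networks.
#' @param graph a resampled `capillary_graph` with at least one segment.
#' @param definition eigenvalue ratio: `"max_over_mean"` (default),
#'   `"max_over_min"` or `"max_over_mid"`.
#' @return anisotropy >= 1, or `Inf` with a warning when the orientation
#'   distribution is degenerate (all segments parallel).
#' @export
anisotropy <- function(graph,
                       definition = c("max_over_mean", "max_over_min",
                                      "max_over_mid")) {
  definition <- match.arg(definition)
  seg <- graph_segments(graph)
  if (!length(seg$len)) stop("graph has no segments")
  w <- seg$len / sum(seg$len)
  u <- seg$dir
  T <- crossprod(u * sqrt(w))        # sum_i w_i u_i u_i'
  ev <- sort(eigen(T, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  denom <- switch(definition,
                  max_over_mean = mean(ev[2:3]),
                  max_over_min  = ev[3],
                  max_over_mid  = ev[2])
  if (denom <= .Machine$double.eps * max(ev)) {
    warning("degenerate orientation distribution: infinite anisotropy")
    return(Inf)
  }
  ev[1] / denom
}

# ---- fibre geometry -------------------------------------------------------

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_perimeter <- function(p) {
  q <- rbind(p, p[1, ])
  sum(sqrt(rowSums(diff(q)^2)))
}

# brute-force simplicity check: no two non-adjacent edges intersect
polygon_is_simple <- function(p) {
  n <- nrow(p)
  if (n < 3) return(FALSE)
  seg_int <- function(a, b, c, d) {
    cross <- function(o, u, v)
      (u[1] - o[1]) * (v[2] - o[2]) - (u[2] - o[2]) * (v[1] - o[1])
    d1 <- cross(c, d, a); d2 <- cross(c, d, b)
    d3 <- cross(a, b, c); d4 <- cross(a, b, d)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  q <- rbind(p, p[1, ])
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(i - j) <= 1 || (i == 1 && j == n)) next
    if (seg_int(q[i, ], q[i + 1, ], q[j, ], q[j + 1, ])) return(FALSE)
  }
  TRUE
}

#' Fibre geometry from multi-plane contours
#'
#' Reconstructs per-fibre size descriptors from closed cross-sectional
#' contours traced on several z-planes: per-plane polygon area and
#' perimeter, volume as trapezoidal integration of areas over z, lateral
#' surface as trapezoidal integration of perimeters, and diameter as the
#' mean minimal Feret width over planes. When `z_range` extends beyond the
#' traced planes, the first/last plane values are extended to the stack
#' bounds (fibres are assumed prismatic through the imaged slab).
#' @param contours list of closed polygons (n x 2 matrices, µm), one per plane.
#' @param plane_z strictly increasing z positions (µm) of the planes.
#' @param z_range optional c(zmin, zmax) of the image stack; defaults to
#'   `range(plane_z)`.
#' @param fibre_id used in error messages.
#' @return list with `diameter`, `surface`, `volume`, `areas`, `perimeters`,
#'   `axial_length`.
#' @export
fibre_geometry <- function(contours, plane_z, z_range = NULL, fibre_id = NA) {
  stopifnot(length(contours) == length(plane_z), length(plane_z) >= 2,
            all(diff(plane_z) > 0))
  if (is.null(z_range)) z_range <- range(plane_z)
  for (i in seq_along(contours)) {
    if (!polygon_is_simple(contours[[i]]))
      stop(sprintf("fibre %s: self-intersecting contour on plane %d",
                   as.character(fibre_id), i))
  }
  A <- vapply(contours, polygon_area, 0)
  P <- vapply(contours, polygon_perimeter, 0)
  Fmin <- vapply(contours, function(p) min_feret_points(p), 0)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  np <- length(plane_z)
  vol <- trapz(plane_z, A) + A[1] * (plane_z[1] - z_range[1]) +
    A[np] * (z_range[2] - plane_z[np])
  surf <- trapz(plane_z, P) + P[1] * (plane_z[1] - z_range[1]) +
    P[np] * (z_range[2] - plane_z[np])
  list(diameter = mean(Fmin), surface = surf, volume = vol,
       areas = A, perimeters = P, axial_length = diff(z_range))
}

#' Fibre-normalised capillary length densities
#'
#' Capillary length per summed fibre axial length (LL, dimensionless),
#' per summed fibre lateral surface (LSf, µm^-1) and per summed fibre
#' volume (LVf, µm^-2). Fibre axial length is the z-extent of each fibre
#' within the field (fibres run through the transverse field).
#' @param graph a `capillary_graph`.
#' @param fibres a `fibre_model` (see [generate_fibre_phantom()]) or any list
#'   with numeric totals `total_axial_length`, `total_surface`, `total_volume`.
#' @return list with `LL`, `LSf`, `LVf`.
#' @export
fibre_normalised_densities <- function(graph, fibres) {
  tl <- fibres$total_axial_length
  ts <- fibres$total_surface
  tv <- fibres$total_volume
  if (is.null(tl) || is.null(ts) || is.null(tv) ||
      tl <= 0 || ts <= 0 || tv <= 0)
    stop("fibre totals must be positive")
  L <- total_length(graph)
  list(LL = L / tl, LSf = L / ts, LVf = L / tv)
}

#' All capillary network parameters for one field
#'
#' Computes the full parameter set on a vector graph: LVm, branching
#' density, MeanCap (from this field's LV and NV), tortuosity, anisotropy,
#' and, when a fibre model is supplied, the fibre-normalised densities LL,
#' LSf and LVf. All values are in base units (µm powers); use
#' [format_morphometry()] for reporting-scale output.
#' @param graph a resampled `capillary_graph`.
#' @param reference_volume field tissue volume in µm^3.
#' @param fibres optional `fibre_model`.
#' @param aniso_definition passed to [anisotropy()].
#' @return list of class `morphometry_result`.
#' @export
compute_morphometry <- function(graph, reference_volume, fibres = NULL,
                                aniso_definition = "max_over_mean") {
  LV <- length_density_LVm(graph, reference_volume)
  NV <- branching_density(graph, reference_volume)
  res <- list(
    LVm = LV,
    Br_dens = NV,
    MeanCap = if (NV > 0) mean_capillary_length(LV, NV) else NA_real_,
    tortuosity = if (total_length(graph) > 0) tortuosity(graph) else NA_real_,
    anisotropy = if (length(graph$edges))
      anisotropy(graph, aniso_definition) else NA_real_,
    LL = NA_real_, LSf = NA_real_, LVf = NA_real_,
    reference_volume = reference_volume
  )
  if (!is.null(fibres)) {
    fn <- fibre_normalised_densities(graph, fibres)
    res[c("LL", "LSf", "LVf")] <- fn[c("LL", "LSf", "LVf")]
  }
  class(res) <- "morphometry_result"
  res
}

#' Reporting-scale morphometry table
#'
#' Applies the conventional reporting scale factors (LVm and Br_dens x 1e6,
#' tortuosity x 1e3, LVf and LSf x 1e4; MeanCap in µm, LL and anisotropy
#' dimensionless) to one or more `morphometry_result`s. Scale factors are
#' applied only here, never inside the computational routines.
#' @param results a `morphometry_result` or list of them.
#' @return data.frame with columns LVm, tortuosity, anisotropy, MeanCap,
#'   Br_dens, LVf, LSf, LL in reporting units.
#' @export
format_morphometry <- function(results) {
  if (inherits(results, "morphometry_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(LVm = r$LVm * 1e6,
               tortuosity = r$tortuosity * 1e3,
               anisotropy = r$anisotropy,
               MeanCap = r$MeanCap,
               Br_dens = r$Br_dens * 1e6,
               LVf = r$LVf * 1e4,
               LSf = r$LSf * 1e4,
               LL = r$LL)
  })
  do.call(rbind, rows)
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("<morphometry_result> (reporting units)\n")
  print(format_morphometry(x), row.names = FALSE)
  invisible(x)
}
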