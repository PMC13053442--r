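#' Minimal Feret diameter of a point set (rotating calipers)
#'
#' Minimum over orientations of the projection width of the convex hull.
#' For a convex polygon the minimum width is attained with one caliper jaw
#' flush against a hull edge, so it suffices to take, for every hull edge,
#' the greatest distance of any hull point from that edge's line, and
#' minimise over edges.
#' @param pts n x 2 matrix of points.
#' @return minimal width (same units as `pts`).
#' @export
min_feret_points <- function(pts) {
  pts <- unique(as.matrix(pts)[, 1:2, drop = FALSE])
  if (nrow(pts) < 2) return(0)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n == 2) return(0)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    a <- hp[i, ]; b <- hp[if (i == n) 1 else i + 1, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) { widths[i] <- Inf; next }
    nrm <- c(-e[2], e[1]) / len
    d <- (hp[, 1] - a[1]) * nrm[1] + (hp[, 2] - a[2]) * nrm[2]
    widths[i] <- max(abs(d))
  }
  min(widths)
}

#' Maximal Feret diameter of a point set
#' @param pts n x 2 matrix of points.
#' @return largest pairwise distance between hull points.
#' @export
max_feret_points <- function(pts) {
  pts <- unique(as.matrix(pts)[, 1:2, drop = FALSE])
  if (nrow(pts) < 2) return(0)
  hp <- pts[grDevices::chull(pts), , drop = FALSE]
  sqrt(max(as.matrix(stats::dist(hp))^2))
}

#' Exhaustive-angle Feret width (oracle)
#'
#' Projection width minimised over a fixed angular grid; used as an
#' independent check of the rotating-calipers result.
#' @param pts n x 2 matrix of points.
#' @param step_deg angular grid spacing in degrees.
#' @return minimal projection width over the grid.
#' @export
min_feret_sweep <- function(pts, step_deg = 0.1) {
  pts <- as.matrix(pts)[, 1:2, drop = FALSE]
  th <- seq(0, pi, by = step_deg * pi / 180)
  w <- vapply(th, function(t) {
    p <- pts[, 1] * cos(t) + pts[, 2] * sin(t)
    max(p) - min(p)
  }, 0)
  min(w)
}

# corner points of a pixel region: each pixel (i, j) contributes its four
# corners so that a w x h pixel rectangle has exact width w * pixel_size
region_corners <- function(mask, pixel_size = 1) {
  ij <- which(mask, arr.ind = TRUE)
  if (!nrow(ij)) return(matrix(0, 0, 2))
  corners <- rbind(cbind(ij[, 1] - 1, ij[, 2] - 1),
                   cbind(ij[, 1],     ij[, 2] - 1),
                   cbind(ij[, 1] - 1, ij[, 2]),
                   cbind(ij[, 1],     ij[, 2]))
  unique(corners) * pixel_size
}

#' Minimal Feret diameter of a fibre cross-section
#'
#' Accepts either a logical pixel mask (pixels are treated as unit squares,
#' so an axis-aligned w x h rectangle of pixels has width exactly
#' `w * pixel_size`) or an explicit polygon in world units. Regions touching
#' the image border are returned with a `border` flag: their width is at
#' risk of being biased low and they are excluded from summaries by default.
#' @param region logical matrix (mask) or n x 2 polygon matrix (µm).
#' @param pixel_size pixel edge length in µm (masks only).
#' @return minimal Feret diameter in µm, with attribute `border` for masks.
#' @export
minimal_feret <- function(region, pixel_size = 1) {
  if (is.logical(region) || (is.matrix(region) && all(region %in% c(0, 1)) &&
                             !is.null(dim(region)) && any(dim(region) > 2))) {
    mask <- region > 0
    if (!any(mask)) stop("empty region")
    pts <- region_corners(mask, pixel_size)
    val <- min_feret_points(pts)
    border <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)])
    attr(val, "border") <- border
    val
  } else {
    min_feret_points(region)
  }
}

#' MyHC fibre-type call from an antibody positivity triple
#'
#' Serial-section typing convention for the antibody panel
#' (BA-D5 = MyHC-1, SC-71 = MyHC-2a, 6H1 = MyHC-2x): pure types are positive
#' on exactly one antibody; hybrids are concomitantly positive on two,
#' BA-D5 + SC-71 for type 1/2a and SC-71 + 6H1 for type 2a/2x. The three
#' remaining patterns (none, BA-D5 + 6H1, all three) fall outside the
#' convention and are flagged `unclassified`. Total function on {pos,neg}^3.
#' @param bad5,sc71,h6h1 logical (TRUE = positive) scalars or vectors.
#' @return character vector over
#'   `c("1", "1/2a", "2a", "2a/2x", "2x", "unclassified")`.
#' @export
classify_fibre_type <- function(bad5, sc71, h6h1) {
  key <- paste0(as.integer(bad5), as.integer(sc71), as.integer(h6h1))
  map <- c("100" = "1", "110" = "1/2a", "010" = "2a",
           "011" = "2a/2x", "001" = "2x")
  out <- unname(map[key])
  out[is.na(out)] <- "unclassified"
  out
}

# Otsu split of a continuous sample: threshold maximising between-class
# variance over all midpoints between consecutive sorted values. Shift- and
# scale-invariant in the resulting two-class partition.
otsu_split <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  if (n < 2 || diff(range(xs)) < 1e-12) return(NA_real_)
  cs <- cumsum(xs)
  tot <- cs[n]
  k <- 1:(n - 1)
  w1 <- k / n
  m1 <- cs[k] / k
  m2 <- (tot - cs[k]) / (n - k)
  bc <- w1 * (1 - w1) * (m1 - m2)^2
  i <- which.max(bc)
  (xs[i] + xs[i + 1]) / 2
}

#' Antibody positivity calls from per-fibre mean intensities
#'
#' Splits each channel's per-fibre mean-intensity distribution into a
#' positive and a negative class. The default policy applies an Otsu-style
#' two-class split directly to the continuous intensity sample of that
#' channel within the section; a fixed threshold can be supplied instead.
#' Degenerate channels (no intensity spread) are called all-negative with
#' a warning. Calls are invariant to adding a constant to every intensity.
#' @param means n x 3 numeric matrix of per-fibre mean intensities, columns
#'   in panel order (BA-D5, SC-71, 6H1).
#' @param policy `"otsu"` or a numeric vector of 3 fixed thresholds.
#' @return n x 3 logical matrix of positivity calls.
#' @export
call_positivity <- function(means, policy = "otsu") {
  means <- as.matrix(means)
  stopifnot(ncol(means) == 3, all(means >= 0))
  out <- matrix(FALSE, nrow(means), 3,
                dimnames = list(NULL, c("bad5", "sc71", "h6h1")))
  for (ch in 1:3) {
    x <- means[, ch]
    if (identical(policy, "otsu")) {
      thr <- otsu_split(x)
      if (is.na(thr)) {
        warning(sprintf("channel %d intensities are degenerate; all-negative",
                        ch))
        next
      }
      out[, ch] <- x > thr
    } else {
      stopifnot(is.numeric(policy), length(policy) == 3)
      out[, ch] <- x > policy[ch]
    }
  }
  out
}

#' Intramyocellular lipid area fraction
#'
#' Percentage of the fibre cross-sectional area covered by lipid-positive
#' pixels: `100 * |lipid AND fibre| / |fibre|`.
#' @param lipid logical matrix, lipid-positive pixels.
#' @param fibre logical matrix, the fibre region (same geometry).
#' @return percentage in \[0, 100\].
#' @export
imcl_index <- function(lipid, fibre) {
  stopifnot(identical(dim(lipid), dim(fibre)))
  nf <- sum(fibre)
  if (nf == 0) stop("empty fibre region")
  100 * sum(lipid & fibre) / nf
}

label_centroids <- function(labels) {
  ij <- which(labels > 0, arr.ind = TRUE)
  l <- labels[labels > 0]
  cx <- tapply(ij[, 1], l, mean)
  cy <- tapply(ij[, 2], l, mean)
  n <- tapply(l, l, length)
  data.frame(label = as.integer(names(cx)), x = as.numeric(cx),
             y = as.numeric(cy), npix = as.numeric(n))
}

match_two_sections <- function(ref, mov, gate) {
  # translation-only registration: align centroid-cloud means
  shift <- colMeans(ref[, c("x", "y")]) - colMeans(mov[, c("x", "y")])
  mx <- mov$x + shift[1]; my <- mov$y + shift[2]
  d2 <- outer(ref$x, mx, "-")^2 + outer(ref$y, my, "-")^2
  fwd <- apply(d2, 1, which.min)
  bwd <- apply(d2, 2, which.min)
  ok <- bwd[fwd] == seq_len(nrow(ref)) &
    sqrt(d2[cbind(seq_len(nrow(ref)), fwd)]) <= gate
  match <- rep(NA_integer_, nrow(ref))
  match[ok] <- mov$label[fwd[ok]]
  match
}

#' Match fibres across serial sections
#'
#' Registers each section's fibre label map to the first (reference) section
#' by translation (centroid-cloud mean alignment) and matches fibres by
#' mutual nearest centroids within a distance gate. Unmatched fibres are
#' reported, never silently dropped.
#' @param label_maps list of >= 2 integer label matrices (0 = background).
#' @param pixel_size µm per pixel.
#' @param gate matching gate in µm; default half the median equivalent
#'   diameter of the reference section's fibres.
#' @return list with `matches` (data.frame: reference label and matched label
#'   per section, NA where unmatched), `matched_fraction`, `gate`.
#'   Signals an error if fewer than half the reference fibres match in any
#'   section (registration failure).
#' @export
match_fibres_across_sections <- function(label_maps, pixel_size = 1,
                                         gate = NULL) {
  stopifnot(length(label_maps) >= 2)
  cents <- lapply(label_maps, label_centroids)
  ref <- cents[[1]]
  if (is.null(gate)) {
    eqd <- 2 * sqrt(ref$npix / pi) * pixel_size
    gate <- 0.5 * stats::median(eqd)
  }
  out <- data.frame(ref_label = ref$label)
  fracs <- numeric(length(label_maps) - 1)
  for (s in 2:length(label_maps)) {
    m <- match_two_sections(ref, cents[[s]], gate / pixel_size)
    out[[paste0("section", s)]] <- m
    fracs[s - 1] <- mean(!is.na(m))
  }
  if (any(fracs < 0.5))
    stop(sprintf("registration failure: only %.0f%% of fibres matched",
                 100 * min(fracs)))
  list(matches = out, matched_fraction = fracs, gate = gate)
}

#' Per-section summary of typed fibres
#'
#' Fibre-type proportions over classified fibres (summing to 100%),
#' per-type and pooled minimal Feret diameters, and fibre counts. Fibres
#' flagged `unclassified` (and, by default, border-touching fibres) are
#' excluded from proportions and diameter summaries. A warning is emitted
#' below 100 analysed fibres, the conventional floor for stable per-muscle
#' estimates.
#' @param records data.frame with columns `type`, `min_feret`, optionally
#'   `imcl_index` and logical `border`.
#' @param drop_border exclude border-touching fibres (default TRUE).
#' @return list with `proportions` (%), `diameter_by_type`, `pooled_diameter`,
#'   `imcl_by_type` (if available), `n_fibres`.
#' @export
section_summary <- function(records, drop_border = TRUE) {
  stopifnot(is.data.frame(records), all(c("type", "min_feret") %in%
                                          names(records)))
  if (drop_border && "border" %in% names(records))
    records <- records[!records$border, , drop = FALSE]
  typed <- records[records$type != "unclassified", , drop = FALSE]
  if (!nrow(typed)) stop("no classified fibres")
  if (nrow(typed) < 100)
    warning(sprintf("only %d analysed fibres (< 100)", nrow(typed)))
  tab <- table(typed$type)
  props <- 100 * as.numeric(tab) / sum(tab)
  names(props) <- names(tab)
  dia <- tapply(typed$min_feret, typed$type, mean)
  dia_sd <- tapply(typed$min_feret, typed$type, stats::sd)
  out <- list(proportions = props,
              diameter_by_type = data.frame(type = names(dia),
                                            mean = as.numeric(dia),
                                            sd = as.numeric(dia_sd)),
              pooled_diameter = mean(typed$min_feret),
              n_fibres = nrow(typed))
  if ("imcl_index" %in% names(typed))
    out$imcl_by_type <- tapply(typed$imcl_index, typed$type, mean)
  out
}

#' Full serial-section fibre analysis
#'
#' Runs the 2D arm end to end on a section set: matches fibres across the
#' three MyHC sections and the lipid section, computes per-fibre mean
#' channel intensities, calls positivity, types each fibre, measures the
#' minimal Feret diameter and the IMCL area fraction on the reference
#' label map.
#' @param sections a `section_set` (see [generate_serial_sections()]).
#' @param policy positivity threshold policy for [call_positivity()].
#' @return data.frame of fibre records (one row per reference fibre).
#' @export
analyse_sections <- function(sections, policy = "otsu") {
  maps <- sections$labels
  mm <- match_fibres_across_sections(maps, sections$pixel_size)
  m <- mm$matches
  chans <- sections$channels
  mean_int <- function(img, labels, labs) {
    mu <- tapply(img[labels > 0], labels[labels > 0], mean)
    as.numeric(mu[as.character(labs)])
  }
  means <- cbind(
    mean_int(chans[[1]], maps[[1]], m$ref_label),
    mean_int(chans[[2]], maps[[2]], m$section2),
    mean_int(chans[[3]], maps[[3]], m$section3))
  keep <- stats::complete.cases(means)
  pos <- matrix(FALSE, nrow(means), 3)
  pos[keep, ] <- call_positivity(means[keep, , drop = FALSE], policy)
  type <- rep("unclassified", nrow(m))
  type[keep] <- classify_fibre_type(pos[keep, 1], pos[keep, 2], pos[keep, 3])
  ref_map <- maps[[1]]
  sudan_col <- if (ncol(m) >= 4) m[[4]] else m$ref_label
  rec <- data.frame(fibre = m$ref_label, type = type,
                    bad5 = pos[, 1], sc71 = pos[, 2], h6h1 = pos[, 3],
                    min_feret = NA_real_, area = NA_real_,
                    imcl_index = NA_real_, border = FALSE)
  for (i in seq_len(nrow(rec))) {
    mask <- ref_map == rec$fibre[i]
    mf <- minimal_feret(mask, sections$pixel_size)
    rec$min_feret[i] <- as.numeric(mf)
    rec$border[i] <- isTRUE(attr(mf, "border"))
    rec$area[i] <- sum(mask) * sections$pixel_size^2
    if (!is.null(sections$lipid) && !is.na(sudan_col[i])) {
      smask <- sections$labels[[length(sections$labels)]] == sudan_col[i]
      if (any(smask))
        rec$imcl_index[i] <- imcl_index(sections$lipid, smask)
    }
  }
  rec
}
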