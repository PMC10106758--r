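#' Two-dimensional shape and motion descriptors of an ROI contour
#'
#' Sixteen descriptors of the cross-sectional lumen contour. Geometric
#' quantities are computed in physical millimeters: pixel area counts pixels,
#' mesh area and perimeter come from the sub-pixel iso-contour of the binary
#' mask (marching-squares polygon), the maximum diameter is the largest
#' distance between pixel corner vertices, and the axis lengths derive from
#' the second central moments of the pixel centers (principal-axis lengths
#' `4 * sqrt(eigenvalue)`, matching the full axis of the equivalent ellipse).
#' Two motion descriptors relate the mask to the reference-frame mask:
#' centroid drift (mm) and fractional area change.
#'
#' @param mask logical matrix, connected and non-empty.
#' @param spacing pixel spacing in mm.
#' @param reference_mask mask of the reference timeframe (defaults to `mask`
#'   itself, giving zero drift and zero area change).
#' @return named numeric vector of 16 shape features.
#' @export
shape2d_features <- function(mask, spacing = 1, reference_mask = mask) {
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  px_area <- n * spacing^2
  xy <- idx * spacing
  cen <- colMeans(xy)

  # marching-squares contour, smoothed to suppress the staircase bias of the
  # pixelation (vessel lumen contours are smooth); perimeter and mesh area
  # come from the same polygon so the isoperimetric bound holds
  poly <- smooth_polygon(mask_contour(mask, spacing))
  perim <- polygon_length(poly)
  mesh_area <- abs(polygon_area(poly))

  # boundary pixels: at least one 4-neighbor outside the mask
  inner <- mask
  inner[] <- FALSE
  nu <- nrow(mask); nv <- ncol(mask)
  pad <- matrix(FALSE, nu + 2, nv + 2)
  pad[2:(nu + 1), 2:(nv + 1)] <- mask
  core <- pad[2:(nu + 1), 2:(nv + 1)] & pad[1:nu, 2:(nv + 1)] &
          pad[3:(nu + 2), 2:(nv + 1)] & pad[2:(nu + 1), 1:nv] &
          pad[2:(nu + 1), 3:(nv + 2)]
  bnd <- which(mask & !core, arr.ind = TRUE)
  if (nrow(bnd) == 0) bnd <- idx
  corners <- rbind(
    (bnd + matrix(c(-0.5, -0.5), nrow(bnd), 2, byrow = TRUE)) * spacing,
    (bnd + matrix(c(0.5, -0.5), nrow(bnd), 2, byrow = TRUE)) * spacing,
    (bnd + matrix(c(-0.5, 0.5), nrow(bnd), 2, byrow = TRUE)) * spacing,
    (bnd + matrix(c(0.5, 0.5), nrow(bnd), 2, byrow = TRUE)) * spacing
  )
  max_diam <- sqrt(max_pairwise_dist2(corners))

  # principal axes from second central moments of pixel centers
  if (n > 1) {
    cv <- stats::cov(xy) * (n - 1) / n
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0

  bbox_area <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1) *
    spacing^2
  hull <- grDevices::chull(corners)
  hull_area <- abs(polygon_area(corners[hull, , drop = FALSE]))

  ref_idx <- which(reference_mask, arr.ind = TRUE)
  ref_cen <- colMeans(ref_idx * spacing)
  ref_area <- nrow(ref_idx) * spacing^2

  c(
    PixelArea = px_area,
    MeshArea = mesh_area,
    Perimeter = perim,
    PerimeterToArea = perim / mesh_area,
    MaximumDiameter = max_diam,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    Elongation = elong,
    Eccentricity = ecc,
    Circularity = 2 * sqrt(pi * mesh_area) / perim,
    Compactness = 4 * pi * mesh_area / perim^2,
    Extent = px_area / bbox_area,
    Solidity = px_area / hull_area,
    EquivalentDiameter = 2 * sqrt(px_area / pi),
    CentroidDrift = sqrt(sum((cen - ref_cen)^2)),
    AreaFractionChange = (px_area - ref_area) / ref_area
  )
}

# marching-squares iso-contour (level 0.5) of the zero-padded mask,
# in physical coordinates where pixel (i, j) is centered at (i, j) * spacing
mask_contour <- function(mask, spacing = 1) {
  nu <- nrow(mask); nv <- ncol(mask)
  z <- matrix(0, nu + 2, nv + 2)
  z[2:(nu + 1), 2:(nv + 1)] <- mask * 1
  cl <- grDevices::contourLines(x = (0:(nu + 1)) * spacing,
                                y = (0:(nv + 1)) * spacing,
                                z = z, levels = 0.5)
  if (!length(cl)) stop("mask contour extraction failed")
  lens <- vapply(cl, function(c) length(c$x), 1L)
  c1 <- cl[[which.max(lens)]]
  cbind(c1$x, c1$y)
}

# circular moving average of the closed-polygon vertices
smooth_polygon <- function(poly, window = 5L) {
  n <- nrow(poly)
  if (n < 2 * window) return(poly)
  k <- (window - 1L) %/% 2L
  idx <- function(i) ((i - 1L) %% n) + 1L
  out <- poly
  for (i in seq_len(n))
    out[i, ] <- colMeans(poly[idx((i - k):(i + k)), , drop = FALSE])
  out
}

polygon_length <- function(poly) {
  p2 <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  sum(sqrt(rowSums((p2 - poly)^2)))
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

max_pairwise_dist2 <- function(pts) {
  # convex hull first: the diameter is attained on the hull
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  d2 <- outer(hp[, 1], hp[, 1], `-`)^2 + outer(hp[, 2], hp[, 2], `-`)^2
  max(d2)
}
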