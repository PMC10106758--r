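#' Vessel centerline with landmark positions
#'
#' Carries an ordered polyline in physical millimeters with cumulative arc
#' length, unit tangents (central differences) and the four standardized
#' aortic landmarks: A1.1 (proximal ascending, distal to the coronary ostia),
#' B1 (proximal to the brachiocephalic trunk), B4.1 (distal to the subclavian
#' artery) and D1.1 (mid-descending, next to the pulmonary artery).
#'
#' @param points numeric matrix (n x 3) of ordered centerline points, mm.
#' @param landmarks named numeric vector of arc-length positions (mm) for
#'   `A1.1`, `B1`, `B4.1`, `D1.1`; must be increasing in that order.
#' @return an object of class `centerline`.
#' @export
centerline <- function(points, landmarks) {
  stopifnot(is.matrix(points), ncol(points) == 3, nrow(points) >= 2)
  need <- c("A1.1", "B1", "B4.1", "D1.1")
  if (!all(need %in% names(landmarks)))
    stop("landmarks must name A1.1, B1, B4.1, D1.1")
  lm <- landmarks[need]
  if (any(diff(lm) <= 0))
    stop("landmarks out of order: require A1.1 < B1 < B4.1 < D1.1 in arc length")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg <= 0)) stop("centerline points must be strictly ordered")
  s <- c(0, cumsum(seg))
  if (any(lm < 0 | lm > s[length(s)]))
    stop("landmark arc lengths outside the centerline range")
  n <- nrow(points)
  tg <- matrix(0, n, 3)
  tg[1, ] <- points[2, ] - points[1, ]
  tg[n, ] <- points[n, ] - points[n - 1, ]
  if (n > 2) tg[2:(n - 1), ] <- points[3:n, ] - points[1:(n - 2), ]
  tg <- tg / sqrt(rowSums(tg^2))
  structure(list(points = points, arc = s, tangents = tg, landmarks = lm),
            class = "centerline")
}

#' Straight-tube centerline helper
#'
#' Centerline along the z axis through the origin, matching the straight
#' phantom, with the four landmarks spread evenly along the axis.
#'
#' @param length_mm total centerline length, mm (centered on z = 0).
#' @param n_points number of polyline points.
#' @return a [centerline()].
#' @export
straight_centerline <- function(length_mm = 80, n_points = 81L) {
  z <- seq(-length_mm / 2, length_mm / 2, length.out = n_points)
  pts <- cbind(0, 0, z)
  lm <- c("A1.1" = 0.1, "B1" = 0.4, "B4.1" = 0.6, "D1.1" = 0.9) * length_mm
  centerline(pts, lm)
}

#' Arched centerline helper
#'
#' Half-circle centerline in the x-z plane matching the arched phantom.
#'
#' @param length_mm arc length, mm.
#' @param n_points number of polyline points.
#' @return a [centerline()].
#' @export
arch_centerline <- function(length_mm = 120, n_points = 121L) {
  Rc <- length_mm / pi
  phi <- seq(0, pi, length.out = n_points)
  pts <- cbind(Rc * cos(phi), 0, Rc * sin(phi))
  lm <- c("A1.1" = 0.1, "B1" = 0.35, "B4.1" = 0.6, "D1.1" = 0.9) * length_mm
  centerline(pts, lm)
}

# interpolate point / tangent at arc position s
centerline_at <- function(cl, s) {
  p <- vapply(1:3, function(k) stats::approx(cl$arc, cl$points[, k], s)$y, 1)
  tg <- vapply(1:3, function(k) stats::approx(cl$arc, cl$tangents[, k], s)$y, 1)
  list(point = p, tangent = tg / sqrt(sum(tg^2)))
}

#' Define an analysis plane
#'
#' Builds the oriented cross-section at one centerline position. The normal
#' is the local centerline tangent (pointing toward increasing arc length).
#' In-plane axes: the first axis is the normalized projection of a fixed
#' global reference direction onto the plane (falling back to the next
#' canonical axis when parallel to the normal); the second is
#' `normal x first`, giving reproducible plane coordinates across runs.
#'
#' @param cl a [centerline()].
#' @param s arc-length position, mm.
#' @param label plane label.
#' @param extent in-plane half-extent of the sampling grid, mm.
#' @return an object of class `plane_definition`.
#' @export
plane_at <- function(cl, s, label = sprintf("s=%.1f", s), extent = 25) {
  at <- centerline_at(cl, s)
  n <- at$tangent
  e1 <- NULL
  for (ref in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    proj <- ref - sum(ref * n) * n
    if (sqrt(sum(proj^2)) > 1e-6) { e1 <- proj / sqrt(sum(proj^2)); break }
  }
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  structure(list(label = label, origin = at$point, normal = n,
                 e1 = e1, e2 = e2, extent = extent, arc = s),
            class = "plane_definition")
}

#' Place the standardized analysis planes
#'
#' Returns the four landmark planes plus equidistantly spaced intermediate
#' planes: `n_ascending` additional planes strictly between A1.1 and B1 and
#' `n_descending` additional planes strictly between B4.1 and D1.1. The
#' default configuration (5 + 3) yields exactly 12 planes. Each plane's
#' normal is the local centerline tangent.
#'
#' @param cl a [centerline()].
#' @param n_ascending additional equidistant planes in the ascending segment.
#' @param n_descending additional equidistant planes in the descending segment.
#' @param extent in-plane half-extent passed to [plane_at()], mm.
#' @return list of `plane_definition` objects, ordered by arc length.
#' @export
place_planes <- function(cl, n_ascending = 5L, n_descending = 3L, extent = 25) {
  lm <- cl$landmarks
  planes <- list()
  add <- function(s, label) planes[[length(planes) + 1]] <<- plane_at(cl, s, label, extent)
  add(lm["A1.1"], "A1.1")
  if (n_ascending > 0) {
    s <- seq(lm["A1.1"], lm["B1"], length.out = n_ascending + 2)
    for (k in seq_len(n_ascending)) add(s[k + 1], sprintf("A+%d", k))
  }
  add(lm["B1"], "B1")
  add(lm["B4.1"], "B4.1")
  if (n_descending > 0) {
    s <- seq(lm["B4.1"], lm["D1.1"], length.out = n_descending + 2)
    for (k in seq_len(n_descending)) add(s[k + 1], sprintf("D+%d", k))
  }
  add(lm["D1.1"], "D1.1")
  planes
}

# pixel grid of a plane: cell-centered 1 mm (default) lattice, origin-centered
plane_grid <- function(plane, spacing = 1) {
  u <- grid_axis(-plane$extent, plane$extent, spacing)
  v <- u
  nu <- length(u); nv <- length(v)
  uu <- rep(u, times = nv); vv <- rep(v, each = nu)
  pts <- cbind(plane$origin[1] + uu * plane$e1[1] + vv * plane$e2[1],
               plane$origin[2] + uu * plane$e1[2] + vv * plane$e2[2],
               plane$origin[3] + uu * plane$e1[3] + vv * plane$e2[3])
  list(u = u, v = v, nu = nu, nv = nv, pts = pts)
}

# vectorized trilinear interpolation of a 3D array at physical points;
# NA outside the grid (no extrapolation)
trilinear <- function(arr, spacing, origin, pts) {
  d <- dim(arr)
  gx <- (pts[, 1] - origin[1]) / spacing[1]
  gy <- (pts[, 2] - origin[2]) / spacing[2]
  gz <- (pts[, 3] - origin[3]) / spacing[3]
  ok <- gx >= 0 & gx <= d[1] - 1 & gy >= 0 & gy <= d[2] - 1 &
        gz >= 0 & gz <= d[3] - 1
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  gx <- gx[ok]; gy <- gy[ok]; gz <- gz[ok]
  x0 <- pmin(floor(gx), d[1] - 2); y0 <- pmin(floor(gy), d[2] - 2)
  z0 <- pmin(floor(gz), d[3] - 2)
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  at <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
       at(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
       at(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
       at(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
       at(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
       at(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
       at(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
       at(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[ok] <- v
  out
}

#' Multiplanar reconstruction of a velocity field onto a plane
#'
#' Resamples the three velocity components onto the plane's cell-centered
#' pixel grid (default 1 mm isotropic) by trilinear interpolation. Pixels
#' outside the source grid are flagged invalid and never extrapolated.
#'
#' @param field a [velocity_field()] or a static 3-component field (list with
#'   `vx`, `vy`, `vz` 3D arrays plus `spacing`, `origin`).
#' @param plane a `plane_definition`.
#' @param t 1-based timeframe index (ignored for static fields).
#' @param spacing plane pixel spacing, mm (the MPR resolution).
#' @return an object of class `plane_sample`: component matrices `vx`, `vy`,
#'   `vz` (m/s), logical `valid`, the plane geometry and pixel coordinates.
#' @export
resample_mpr <- function(field, plane, t = 1L, spacing = 1) {
  g <- plane_grid(plane, spacing)
  is4d <- length(dim(field$vx)) == 4
  pick <- function(a) if (is4d) a[, , , t, drop = TRUE] else a
  vx <- trilinear(pick(field$vx), field$spacing, field$origin, g$pts)
  vy <- trilinear(pick(field$vy), field$spacing, field$origin, g$pts)
  vz <- trilinear(pick(field$vz), field$spacing, field$origin, g$pts)
  valid <- !(is.na(vx) | is.na(vy) | is.na(vz))
  if (!any(valid)) stop("plane lies fully outside the field grid")
  shape <- function(x) matrix(x, g$nu, g$nv)
  structure(list(vx = shape(vx), vy = shape(vy), vz = shape(vz),
                 valid = shape(valid), spacing = spacing,
                 u = g$u, v = g$v, normal = plane$normal,
                 e1 = plane$e1, e2 = plane$e2, origin = plane$origin,
                 label = plane$label, timeframe = t),
            class = "plane_sample")
}

#' Propagate an ROI mask across timeframes by centroid tracking
#'
#' Translates the reference-frame ROI to every timeframe so that it follows
#' the centroid of through-plane speed inside a search window around the
#' reference ROI. The translation is rigid (integer pixels), so the mask area
#' is preserved exactly. With zero flow everywhere in the window the mask is
#' returned untranslated with a warning.
#'
#' @param mask logical matrix: ROI on the reference timeframe.
#' @param samples list of `plane_sample` objects, one per timeframe.
#' @param search_mm half-width of the search window around the reference ROI,
#'   mm.
#' @return list of logical masks, one per timeframe.
#' @export
propagate_roi <- function(mask, samples, search_mm = 5) {
  stopifnot(any(mask))
  idx <- which(mask, arr.ind = TRUE)
  ref_c <- colMeans(idx)
  sp <- samples[[1]]$spacing
  pad <- ceiling(search_mm / sp)
  nu <- nrow(mask); nv <- ncol(mask)
  win <- matrix(FALSE, nu, nv)
  win[max(1, min(idx[, 1]) - pad):min(nu, max(idx[, 1]) + pad),
      max(1, min(idx[, 2]) - pad):min(nv, max(idx[, 2]) + pad)] <- TRUE
  lapply(samples, function(s) {
    u <- s$vx * s$normal[1] + s$vy * s$normal[2] + s$vz * s$normal[3]
    w <- abs(u); w[!s$valid | !win] <- 0
    if (sum(w, na.rm = TRUE) <= 0) {
      warning("zero flow in tracking window; mask left untranslated")
      return(mask)
    }
    wi <- which(w > 0, arr.ind = TRUE)
    ww <- w[wi]
    cen <- c(sum(wi[, 1] * ww), sum(wi[, 2] * ww)) / sum(ww)
    sh <- round(cen - ref_c)
    shift_mask(mask, sh[1], sh[2])
  })
}

# integer-pixel shift preserving area (clipped shifts rejected)
shift_mask <- function(mask, di, dj) {
  nu <- nrow(mask); nv <- ncol(mask)
  out <- matrix(FALSE, nu, nv)
  idx <- which(mask, arr.ind = TRUE)
  ii <- idx[, 1] + di; jj <- idx[, 2] + dj
  if (any(ii < 1 | ii > nu | jj < 1 | jj > nv))
    return(mask)  # shift would clip the ROI: keep in place (area preserved)
  out[cbind(ii, jj)] <- TRUE
  out
}
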