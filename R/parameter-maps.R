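#' Cross-sectional flow parameter maps
#'
#' Five scalar maps summarize the flow profile of an analysis plane at one
#' timeframe:
#'
#' * **throughflow** `u = v . n` (m/s, signed) — velocity component along the
#'   plane normal;
#' * **wpd** `WPD = u / |v|` (dimensionless, the cosine of the deviation from
#'   centerline-parallel flow);
#' * **angle** `alpha = acos(v/|v| . n)` (degrees, 0-180);
#' * **lnh** local normalized helicity `(w . v) / (|w||v|)` with `w` the
#'   vorticity (curl of the velocity field), in `[-1, 1]`, sign encoding
#'   helix handedness;
#' * **vorticity** the plane-normal vorticity component, self-normalized per
#'   plane and timeframe to `[-1, 1]` (or scaled by a fixed reference).
#'
#' Zero-velocity pixels are handled explicitly: WPD and LNH are set to 0,
#' the angle to 90 degrees, each with a low-signal flag; the speed floor
#' defaults to 1e-6 m/s.
#'
#' @name parameter-maps
NULL

new_parameter_map <- function(kind, values, units, sample, flags = NULL,
                              normalized = FALSE) {
  structure(list(kind = kind, values = values, units = units,
                 mask = sample$mask, valid = sample$valid,
                 flags = flags, normalized = normalized,
                 spacing = sample$spacing,
                 plane = sample$label, timeframe = sample$timeframe),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map> %s [%s]%s, plane %s, t=%s\n", x$kind, x$units,
              if (x$normalized) " (normalized)" else "",
              x$plane %||% "?", x$timeframe %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

speed2 <- function(sample) sample$vx^2 + sample$vy^2 + sample$vz^2

#' Throughflow map
#'
#' Signed velocity component along the plane normal, `u = v . n`, per pixel.
#'
#' @param sample a `plane_sample` from [resample_mpr()].
#' @return a `parameter_map` of kind `"throughflow"` (m/s).
#' @export
throughflow_map <- function(sample) {
  n <- sample$normal
  u <- sample$vx * n[1] + sample$vy * n[2] + sample$vz * n[3]
  u[!sample$valid] <- 0
  new_parameter_map("throughflow", u, "m/s", sample)
}

#' Wall parallelity degree map
#'
#' `WPD = u / |v|`: the throughflow divided by the velocity magnitude, i.e.
#' the cosine of the angle between the velocity and the plane normal.
#' Pixels slower than `floor` are set to 0 and flagged low-signal.
#'
#' @param sample a `plane_sample`.
#' @param floor speed floor in m/s below which WPD is undefined.
#' @return a `parameter_map` of kind `"wpd"` (dimensionless, `[-1, 1]`).
#' @export
wpd_map <- function(sample, floor = 1e-6) {
  n <- sample$normal
  u <- sample$vx * n[1] + sample$vy * n[2] + sample$vz * n[3]
  sp <- sqrt(speed2(sample))
  low <- !sample$valid | sp < floor
  w <- ifelse(low, 0, u / sp)
  w <- pmin(pmax(w, -1), 1)
  new_parameter_map("wpd", w, "dimensionless", sample, flags = low)
}

#' Flow angle map
#'
#' Angular deviation of the velocity from the plane normal,
#' `alpha = acos(v/|v| . n)` in degrees. The arccos argument is clamped to
#' `[-1, 1]`; zero-velocity pixels get 90 degrees and a low-signal flag.
#'
#' @inheritParams wpd_map
#' @return a `parameter_map` of kind `"angle"` (degrees, `[0, 180]`).
#' @export
angle_map <- function(sample, floor = 1e-6) {
  n <- sample$normal
  u <- sample$vx * n[1] + sample$vy * n[2] + sample$vz * n[3]
  sp <- sqrt(speed2(sample))
  low <- !sample$valid | sp < floor
  cosa <- ifelse(low, 0, u / pmax(sp, floor))
  cosa <- pmin(pmax(cosa, -1), 1)
  a <- acos(cosa) * 180 / pi
  new_parameter_map("angle", a, "degrees", sample, flags = low)
}

#' Vorticity of a velocity field
#'
#' Curl of the velocity vector field, computed on the 3D source grid by
#' spacing-aware central differences (one-sided at the borders). Computing on
#' the source grid and resampling to the plane afterwards is deliberate:
#' in-plane 2D differences cannot recover all three curl components.
#'
#' @param field a [velocity_field()].
#' @param t 1-based timeframe index.
#' @return a static 3-component field (`vx`, `vy`, `vz` 3D arrays in 1/s,
#'   with `spacing` and `origin`) holding the vorticity vectors.
#' @export
vorticity_field <- function(field, t = 1L) {
  d <- dim(field$vx)
  if (any(d[1:3] < 3)) stop("grid must have at least 3 voxels per axis")
  sp <- field$spacing / 1000  # mm -> m so curl is in 1/s
  vx <- field$vx[, , , t, drop = TRUE]
  vy <- field$vy[, , , t, drop = TRUE]
  vz <- field$vz[, , , t, drop = TRUE]
  wx <- deriv_axis(vz, 2, sp[2]) - deriv_axis(vy, 3, sp[3])
  wy <- deriv_axis(vx, 3, sp[3]) - deriv_axis(vz, 1, sp[1])
  wz <- deriv_axis(vy, 1, sp[1]) - deriv_axis(vx, 2, sp[2])
  list(vx = wx, vy = wy, vz = wz, spacing = field$spacing,
       origin = field$origin)
}

# central differences along one axis, one-sided at the borders
deriv_axis <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  idx <- function(k) {
    i <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    i[[axis]] <- k
    do.call(`[`, c(list(a), i, list(drop = FALSE)))
  }
  out <- array(0, d)
  asn <- function(k, val) {
    i <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    i[[axis]] <- k
    eval(call("<-", as.call(c(list(as.name("["), as.name("out")), i)), val))
  }
  # interior: (a[k+1] - a[k-1]) / 2h
  ctr <- (idx(3:n) - idx(1:(n - 2))) / (2 * h)
  lo <- (idx(2) - idx(1)) / h
  hi <- (idx(n) - idx(n - 1)) / h
  if (axis == 1) {
    out[2:(n - 1), , ] <- ctr; out[1, , ] <- lo; out[n, , ] <- hi
  } else if (axis == 2) {
    out[, 2:(n - 1), ] <- ctr; out[, 1, ] <- lo; out[, n, ] <- hi
  } else {
    out[, , 2:(n - 1)] <- ctr; out[, , 1] <- lo; out[, , n] <- hi
  }
  out
}

#' Local normalized helicity map
#'
#' `LNH = (w . v) / (|w| |v|)` per pixel, where the vorticity `w` has been
#' resampled onto the plane with the same trilinear MPR as the velocity.
#' Pixels where either magnitude falls below the floor are set to 0 and
#' flagged. `absolute = TRUE` returns `|LNH|`.
#'
#' @param sample a `plane_sample` of the velocity.
#' @param vort_sample a `plane_sample` of the vorticity (same plane/grid),
#'   from [resample_mpr()] applied to [vorticity_field()].
#' @param floor magnitude floor (m/s for velocity; 1/s for vorticity).
#' @param absolute return the absolute value.
#' @return a `parameter_map` of kind `"lnh"` (dimensionless, `[-1, 1]`).
#' @export
lnh_map <- function(sample, vort_sample, floor = 1e-6, absolute = FALSE) {
  dot <- sample$vx * vort_sample$vx + sample$vy * vort_sample$vy +
         sample$vz * vort_sample$vz
  sv <- sqrt(speed2(sample))
  sw <- sqrt(speed2(vort_sample))
  low <- !sample$valid | !vort_sample$valid | sv < floor | sw < floor
  h <- ifelse(low, 0, dot / (sv * sw))
  h <- pmin(pmax(h, -1), 1)
  if (absolute) h <- abs(h)
  new_parameter_map("lnh", h, "dimensionless", sample, flags = low)
}

#' Normal-component vorticity map
#'
#' Signed scalar `(w . n) / w_ref` per pixel. By default `w_ref` is the
#' maximum `|w . n|` over the ROI of this plane and timeframe
#' (self-normalized, so the map lies in `[-1, 1]`); alternatively a fixed
#' reference in 1/s can be supplied for cross-plane comparability.
#'
#' @param sample a `plane_sample` of the velocity (carries the ROI and
#'   normal).
#' @param vort_sample a `plane_sample` of the vorticity on the same grid.
#' @param reference `"self"` or a positive number (1/s).
#' @param mask optional ROI used for the self-normalization; defaults to the
#'   valid pixels.
#' @return a `parameter_map` of kind `"vorticity"` (dimensionless).
#' @export
normal_vorticity_map <- function(sample, vort_sample, reference = "self",
                                 mask = NULL) {
  n <- sample$normal
  wn <- vort_sample$vx * n[1] + vort_sample$vy * n[2] + vort_sample$vz * n[3]
  wn[!vort_sample$valid] <- 0
  if (identical(reference, "self")) {
    roi <- if (is.null(mask)) sample$valid else mask & sample$valid
    wref <- max(abs(wn[roi]), 0)
    vals <- if (wref > 0) wn / wref else wn * 0
  } else {
    stopifnot(is.numeric(reference), reference > 0)
    vals <- pmin(pmax(wn / reference, -1), 1)
  }
  new_parameter_map("vorticity", vals, "dimensionless", sample)
}

#' Fixed normalization ranges for the five parameter maps
#'
#' Unsigned maps are normalized to `[0, 4096]`, signed maps to
#' `[-2048, 2047]`: throughflow `[-6, 6]` m/s (signed), angle `[0, 180]`
#' degrees (unsigned), WPD `[0, 1]` (unsigned), LNH `[-1, 1]` (signed),
#' normalized vorticity `[-1, 1]` (signed).
#'
#' @param kind one of `"throughflow"`, `"angle"`, `"wpd"`, `"lnh"`,
#'   `"vorticity"`.
#' @return list with `input_range`, `output_range` and `clip`.
#' @export
normalization_spec <- function(kind) {
  tab <- list(
    throughflow = list(input_range = c(-6, 6), output_range = c(-2048, 2047)),
    angle       = list(input_range = c(0, 180), output_range = c(0, 4096)),
    wpd         = list(input_range = c(0, 1), output_range = c(0, 4096)),
    lnh         = list(input_range = c(-1, 1), output_range = c(-2048, 2047)),
    vorticity   = list(input_range = c(-1, 1), output_range = c(-2048, 2047))
  )
  if (!kind %in% names(tab)) stop("unknown parameter map kind: ", kind)
  c(tab[[kind]], list(kind = kind, clip = TRUE))
}

#' Normalize a parameter map to its fixed intensity range
#'
#' Affine rescaling of the map's native input range onto the fixed output
#' range, with values outside the input range clipped to the range ends.
#' Values remain floating point; rounding to integer gray levels happens only
#' at radiomics discretization, so bin boundaries are controlled in one place.
#'
#' @param map a `parameter_map` (not yet normalized).
#' @param spec a normalization spec from [normalization_spec()]; defaults to
#'   the spec of the map's kind.
#' @return the normalized `parameter_map` (units `"normalized"`).
#' @export
normalize_map <- function(map, spec = normalization_spec(map$kind)) {
  if (isTRUE(map$normalized)) stop("map is already normalized")
  if (!identical(spec$kind, map$kind))
    stop(sprintf("normalization spec for '%s' applied to '%s' map",
                 spec$kind, map$kind))
  lo <- spec$input_range[1]; hi <- spec$input_range[2]
  olo <- spec$output_range[1]; ohi <- spec$output_range[2]
  v <- (map$values - lo) / (hi - lo) * (ohi - olo) + olo
  if (isTRUE(spec$clip)) v <- pmin(pmax(v, olo), ohi)  # order keeps dim()
  out <- map
  out$values <- v
  out$units <- "normalized"
  out$normalized <- TRUE
  out$normalization <- spec
  out
}

#' Invert the fixed-range normalization
#'
#' @param map a normalized `parameter_map` carrying its normalization spec.
#' @return the map in native units (exact on in-range values).
#' @export
denormalize_map <- function(map) {
  if (!isTRUE(map$normalized)) stop("map is not normalized")
  spec <- map$normalization
  lo <- spec$input_range[1]; hi <- spec$input_range[2]
  olo <- spec$output_range[1]; ohi <- spec$output_range[2]
  out <- map
  out$values <- (map$values - olo) / (ohi - olo) * (hi - lo) + lo
  out$units <- switch(map$kind, throughflow = "m/s", angle = "degrees",
                      "dimensionless")
  out$normalized <- FALSE
  out$normalization <- NULL
  out
}

#' Compute the five normalized parameter maps for one plane and timeframe
#'
#' Convenience wrapper: resamples velocity and vorticity onto the plane,
#' computes throughflow, WPD, angle, LNH and normal-component vorticity, and
#' normalizes each to its fixed range.
#'
#' @param field a [velocity_field()].
#' @param plane a `plane_definition`.
#' @param t timeframe index.
#' @param mask optional ROI mask on the plane grid.
#' @param spacing MPR resolution, mm.
#' @param normalized return normalized (`TRUE`, default) or native-unit maps.
#' @return named list of five `parameter_map` objects
#'   (`throughflow`, `wpd`, `angle`, `lnh`, `vorticity`).
#' @export
compute_parameter_maps <- function(field, plane, t = 1L, mask = NULL,
                                   spacing = 1, normalized = TRUE) {
  s <- resample_mpr(field, plane, t, spacing)
  s$mask <- mask
  vor <- vorticity_field(field, t)
  sv <- resample_mpr(vor, plane, t, spacing)
  maps <- list(
    throughflow = throughflow_map(s),
    wpd = wpd_map(s),
    angle = angle_map(s),
    lnh = lnh_map(s, sv),
    vorticity = normal_vorticity_map(s, sv, mask = mask)
  )
  if (normalized) maps <- lapply(maps, normalize_map)
  maps
}
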