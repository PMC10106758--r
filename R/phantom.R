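#' Analytic aortic flow phantom
#'
#' `phantom_spec()` describes a straight or arched tube carrying one of eight
#' canonical cross-sectional flow profiles (parabolic, plug, helical, central /
#' displaced / angulated / multiple jets, vortex), modulated over the cardiac
#' cycle by a systolic waveform. The phantom provides closed-form ground truth
#' for every downstream stage: multiplanar resampling, the five flow parameter
#' maps, radiomics extraction and reproducibility statistics.
#'
#' Lumen membership is decided at voxel centers: a voxel belongs to the lumen
#' iff its center lies within `tube_radius` of the centerline. Jets are
#' modelled as Gaussian axial velocity bumps (width `jet_width_fraction *
#' tube_radius`), displaced by `jet_displacement_fraction * tube_radius` or
#' tilted by `jet_angle` degrees where the profile asks for it.
#'
#' @param tube_radius lumen radius in mm.
#' @param tube_length tube length in mm (extent along the axis).
#' @param centerline_kind `"straight"` (axis along z) or `"arch"` (half circle
#'   in the x-z plane, emulating the aortic arch).
#' @param profile_kind one of `"poiseuille"`, `"plug"`, `"helical"`,
#'   `"central_jet"`, `"displaced_jet"`, `"angulated_jet"`, `"multi_jet"`,
#'   `"vortex"`.
#' @param peak_velocity peak axial velocity in m/s at peak systole.
#' @param jet_displacement_fraction jet center offset as a fraction of the
#'   radius, in `[0, 1)`.
#' @param jet_angle jet axis tilt in degrees (angulated jet).
#' @param jet_width_fraction Gaussian jet sigma as a fraction of the radius.
#' @param helix_rate angular rate of the azimuthal component in rad/s
#'   (helical and vortex profiles).
#' @param waveform per-timeframe scale factors in `[0, 1]` with maximum 1;
#'   defaults to a raised-cosine systolic pulse (see [systolic_waveform()]).
#' @param n_timeframes number of timeframes per cardiac cycle.
#' @param voxel_size isotropic voxel edge length in mm for gridded sampling.
#' @param cycle_ms cardiac cycle duration in ms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(tube_radius = 14,
                         tube_length = 80,
                         centerline_kind = c("straight", "arch"),
                         profile_kind = "poiseuille",
                         peak_velocity = 1.0,
                         jet_displacement_fraction = 0.4,
                         jet_angle = 20,
                         jet_width_fraction = 0.35,
                         helix_rate = 10,
                         waveform = NULL,
                         n_timeframes = 20L,
                         voxel_size = 2.0,
                         cycle_ms = 1000) {
  centerline_kind <- match.arg(centerline_kind)
  profile_kind <- match.arg(profile_kind, c(
    "poiseuille", "plug", "helical", "central_jet",
    "displaced_jet", "angulated_jet", "multi_jet", "vortex"
  ))
  stopifnot(tube_radius > 0, tube_length > 0, peak_velocity > 0,
            n_timeframes >= 1, voxel_size > 0,
            jet_displacement_fraction >= 0, jet_displacement_fraction < 1)
  if (is.null(waveform)) waveform <- systolic_waveform(n_timeframes)
  if (length(waveform) != n_timeframes)
    stop("waveform must have n_timeframes entries")
  if (abs(max(waveform) - 1) > 1e-12)
    stop("waveform maximum must be 1")
  if (any(waveform < 0 | waveform > 1)) stop("waveform entries must lie in [0,1]")
  structure(list(
    tube_radius = tube_radius, tube_length = tube_length,
    centerline_kind = centerline_kind, profile_kind = profile_kind,
    peak_velocity = peak_velocity,
    jet_displacement_fraction = jet_displacement_fraction,
    jet_angle = jet_angle, jet_width_fraction = jet_width_fraction,
    helix_rate = helix_rate, waveform = waveform,
    n_timeframes = as.integer(n_timeframes), voxel_size = voxel_size,
    cycle_ms = cycle_ms
  ), class = "phantom_spec")
}

#' Raised-cosine systolic waveform
#'
#' Systolic pulse over the first 40% of the cycle with a small diastolic tail,
#' normalized to maximum 1.
#'
#' @param n number of timeframes.
#' @param systole_fraction fraction of the cycle occupied by systole.
#' @param diastolic_level residual diastolic flow as a fraction of peak.
#' @return numeric vector of length `n` in `[0, 1]` with `max == 1`.
#' @export
systolic_waveform <- function(n, systole_fraction = 0.4, diastolic_level = 0.05) {
  f <- (seq_len(n) - 1) / n
  w <- ifelse(f < systole_fraction,
              sin(pi * f / systole_fraction)^2, diastolic_level)
  w <- pmax(w, diastolic_level)
  w / max(w)
}

#' Scanner acquisition profile
#'
#' Models the acquisition-dependent differences seen across MR scanners:
#' a multiplicative velocity bias, additive Gaussian velocity noise whose
#' standard deviation scales with the velocity encoding (VENC), and the
#' temporal resolution (frames per cardiac cycle, typically 20-38).
#'
#' @param venc velocity encoding in cm/s.
#' @param noise_sigma_fraction velocity noise standard deviation as a fraction
#'   of VENC.
#' @param velocity_scale_bias multiplicative bias applied to all components.
#' @param n_timeframes frames per cycle for this scanner.
#' @param voxel_size acquisition voxel size in mm.
#' @param seed integer seed for the noise stream.
#' @return an object of class `scanner_profile`.
#' @export
scanner_profile <- function(venc = 150, noise_sigma_fraction = 0.02,
                            velocity_scale_bias = 1.0, n_timeframes = 20L,
                            voxel_size = 2.0, seed = 1L) {
  stopifnot(venc > 0, noise_sigma_fraction >= 0, n_timeframes >= 2)
  structure(list(venc = venc, noise_sigma_fraction = noise_sigma_fraction,
                 velocity_scale_bias = velocity_scale_bias,
                 n_timeframes = as.integer(n_timeframes),
                 voxel_size = voxel_size, seed = as.integer(seed)),
            class = "scanner_profile")
}

#' Observer contouring profile
#'
#' Stands in for manual ROI segmentation differences between observers:
#' smooth random radial jitter of the contour plus a systematic
#' dilation/erosion bias.
#'
#' @param contour_jitter_mm amplitude of the smooth radial boundary jitter, mm.
#' @param dilation_bias_mm signed uniform dilation (+) / erosion (-), mm.
#' @param seed integer seed for the jitter.
#' @return an object of class `observer_profile`.
#' @export
observer_profile <- function(contour_jitter_mm = 0.5, dilation_bias_mm = 0,
                             seed = 1L) {
  stopifnot(contour_jitter_mm >= 0)
  structure(list(contour_jitter_mm = contour_jitter_mm,
                 dilation_bias_mm = dilation_bias_mm, seed = as.integer(seed)),
            class = "observer_profile")
}

# Local tube frame for a set of physical points (mm).
# Returns s (arc position), in-plane offsets (d1, d2, mm), tangent and
# in-plane unit vectors per point. Straight tube: axis z through origin.
# Arch: half circle of radius arch_radius in the x-z plane, centered at origin,
# from (arch_radius,0,0) up over (0,0,arch_radius) to (-arch_radius,0,0).
phantom_frame <- function(spec, pts) {
  n <- nrow(pts)
  if (spec$centerline_kind == "straight") {
    list(s = pts[, 3],
         d1 = pts[, 1], d2 = pts[, 2],
         tx = rep(0, n), ty = rep(0, n), tz = rep(1, n),
         e1x = rep(1, n), e1y = rep(0, n), e1z = rep(0, n),
         e2x = rep(0, n), e2y = rep(1, n), e2z = rep(0, n))
  } else {
    Rc <- spec$tube_length / pi  # arch radius so centerline length = tube_length
    phi <- atan2(pts[, 3], pts[, 1])          # 0 .. pi along the arch
    rho <- sqrt(pts[, 1]^2 + pts[, 3]^2)
    # radial unit vector (in x-z plane) and tangent (direction of increasing phi)
    list(s = Rc * phi,
         d1 = rho - Rc, d2 = pts[, 2],
         tx = -sin(phi), ty = rep(0, n), tz = cos(phi),
         e1x = cos(phi), e1y = rep(0, n), e1z = sin(phi),
         e2x = rep(0, n), e2y = rep(1, n), e2z = rep(0, n))
  }
}

# Cross-sectional profile in local tube coordinates. d1, d2 in mm.
# Returns list(ax, ip1, ip2): axial velocity and in-plane components (m/s)
# along (tangent, e1, e2).
profile_velocity <- function(spec, d1, d2) {
  R <- spec$tube_radius
  vp <- spec$peak_velocity
  r <- sqrt(d1^2 + d2^2)
  inside <- r <= R
  ax <- numeric(length(r)); ip1 <- numeric(length(r)); ip2 <- numeric(length(r))
  sig <- spec$jet_width_fraction * R
  gauss <- function(dd1, dd2) exp(-(dd1^2 + dd2^2) / (2 * sig^2))
  switch(spec$profile_kind,
    poiseuille = { ax <- vp * (1 - (r / R)^2) },
    plug = { ax <- rep(vp, length(r)) },
    helical = {
      ax <- vp * (1 - (r / R)^2)
      # azimuthal speed helix_rate * r (r in m); direction (-d2, d1)/r
      omega <- spec$helix_rate
      ip1 <- -omega * (d2 / 1000)
      ip2 <- omega * (d1 / 1000)
    },
    central_jet = { ax <- vp * gauss(d1, d2) },
    displaced_jet = {
      off <- spec$jet_displacement_fraction * R
      ax <- vp * gauss(d1 - off, d2)
    },
    angulated_jet = {
      a <- spec$jet_angle * pi / 180
      m <- vp * gauss(d1, d2)
      ax <- m * cos(a)
      ip1 <- m * sin(a)
    },
    multi_jet = {
      th <- c(0, 2 * pi / 3, 4 * pi / 3)
      off <- 0.5 * R
      sig3 <- 0.25 * R
      g <- function(dd1, dd2) exp(-(dd1^2 + dd2^2) / (2 * sig3^2))
      m <- g(d1 - off * cos(th[1]), d2 - off * sin(th[1])) +
           g(d1 - off * cos(th[2]), d2 - off * sin(th[2])) +
           g(d1 - off * cos(th[3]), d2 - off * sin(th[3]))
      ax <- vp * m
    },
    vortex = {
      ax <- rep(0.3 * vp, length(r))  # weak plug-like axial component
      omega <- spec$helix_rate
      ip1 <- -omega * (d2 / 1000)
      ip2 <- omega * (d1 / 1000)
    },
    stop("unknown profile_kind: ", spec$profile_kind)
  )
  ax[!inside] <- 0; ip1[!inside] <- 0; ip2[!inside] <- 0
  list(ax = ax, ip1 = ip1, ip2 = ip2)
}

#' Closed-form phantom velocity
#'
#' Evaluates the analytic velocity of a phantom at arbitrary physical points
#' for one timeframe. Zero outside the lumen; scaled by the waveform value of
#' the timeframe.
#'
#' @param spec a [phantom_spec()].
#' @param points numeric matrix (n x 3) of positions in mm, or a length-3
#'   vector for a single point.
#' @param t 1-based timeframe index.
#' @return an n x 3 matrix of velocities in m/s (columns x, y, z).
#' @export
analytic_velocity <- function(spec, points, t = 1L) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3, t >= 1, t <= spec$n_timeframes)
  fr <- phantom_frame(spec, points)
  pv <- profile_velocity(spec, fr$d1, fr$d2)
  w <- spec$waveform[t]
  vx <- w * (pv$ax * fr$tx + pv$ip1 * fr$e1x + pv$ip2 * fr$e2x)
  vy <- w * (pv$ax * fr$ty + pv$ip1 * fr$e1y + pv$ip2 * fr$e2y)
  vz <- w * (pv$ax * fr$tz + pv$ip1 * fr$e1z + pv$ip2 * fr$e2z)
  cbind(x = vx, y = vy, z = vz)
}

#' Construct a velocity field container
#'
#' Time-resolved 3-component vector field on a regular cell-centered grid.
#'
#' @param vx,vy,vz 4D arrays `[nx, ny, nz, nt]` of velocity components (m/s).
#' @param spacing voxel spacing `c(dx, dy, dz)` in mm.
#' @param origin physical position (mm) of the center of voxel `[1,1,1]`.
#' @param times frame times in ms.
#' @param venc velocity encoding in cm/s, or `NA` if unknown.
#' @return an object of class `velocity_field`.
#' @export
velocity_field <- function(vx, vy, vz, spacing, origin, times, venc = NA_real_) {
  stopifnot(length(dim(vx)) == 4, identical(dim(vx), dim(vy)),
            identical(dim(vx), dim(vz)), length(spacing) == 3,
            length(origin) == 3, length(times) == dim(vx)[4])
  structure(list(vx = vx, vy = vy, vz = vz, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), times = as.numeric(times),
                 venc = venc),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$vx)
  cat(sprintf("<velocity_field> %d x %d x %d voxels, %d timeframes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %s mm, venc %s cm/s\n",
              paste(signif(x$spacing, 3), collapse = " x "),
              ifelse(is.na(x$venc), "unknown", format(x$venc))))
  invisible(x)
}

#' Sample a phantom onto a voxel grid under a scanner profile
#'
#' Samples [analytic_velocity()] at voxel centers for every timeframe of the
#' scanner, applies the scanner's multiplicative velocity bias and adds
#' zero-mean Gaussian noise with standard deviation
#' `noise_sigma_fraction * venc`. The scanner's temporal resolution resamples
#' the phantom waveform at its own frame fractions (linear interpolation).
#' Deterministic for a fixed `scanner$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param scanner a [scanner_profile()]; its `n_timeframes` and `voxel_size`
#'   override the phantom defaults.
#' @param margin_mm grid margin beyond the lumen, mm.
#' @param z_extent_mm axial grid extent, mm (kept short: cross-sectional
#'   analysis needs only a neighborhood of the analysis planes).
#' @return a [velocity_field()].
#' @export
generate_velocity_field <- function(spec, scanner = scanner_profile(),
                                    margin_mm = 6, z_extent_mm = NULL) {
  vs <- scanner$voxel_size
  nt <- scanner$n_timeframes
  half <- spec$tube_radius + margin_mm
  if (spec$centerline_kind == "straight") {
    if (is.null(z_extent_mm)) z_extent_mm <- spec$tube_length
    xs <- grid_axis(-half, half, vs)
    ys <- xs
    zs <- grid_axis(-z_extent_mm / 2, z_extent_mm / 2, vs)
  } else {
    Rc <- spec$tube_length / pi
    xs <- grid_axis(-(Rc + half), Rc + half, vs)
    ys <- grid_axis(-half, half, vs)
    zs <- grid_axis(-margin_mm, Rc + half, vs)
  }
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  pts <- cbind(rep(xs, times = ny * nz),
               rep(rep(ys, each = nx), times = nz),
               rep(zs, each = nx * ny))
  # waveform resampled to the scanner's frame grid (cycle fraction)
  f_spec <- (seq_len(spec$n_timeframes) - 1) / spec$n_timeframes
  f_scan <- (seq_len(nt) - 1) / nt
  wf <- stats::approx(c(f_spec, 1), c(spec$waveform, spec$waveform[1]),
                      xout = f_scan, rule = 2)$y
  spec_t <- spec
  spec_t$waveform <- wf / max(wf)
  spec_t$n_timeframes <- nt
  wf <- spec_t$waveform

  base <- analytic_velocity(spec_t, pts, t = which.max(wf))
  base <- base / wf[which.max(wf)]  # unit-waveform field
  vx <- array(0, c(nx, ny, nz, nt)); vy <- vx; vz <- vx
  for (t in seq_len(nt)) {
    vx[, , , t] <- wf[t] * base[, 1]
    vy[, , , t] <- wf[t] * base[, 2]
    vz[, , , t] <- wf[t] * base[, 3]
  }
  b <- scanner$velocity_scale_bias
  vx <- vx * b; vy <- vy * b; vz <- vz * b
  if (scanner$noise_sigma_fraction > 0) {
    sd_ms <- scanner$noise_sigma_fraction * scanner$venc / 100  # cm/s -> m/s
    n <- length(vx)
    rng <- local_rng(scanner$seed)
    vx <- vx + array(rng(n, sd_ms), dim(vx))
    vy <- vy + array(rng(n, sd_ms), dim(vy))
    vz <- vz + array(rng(n, sd_ms), dim(vz))
  }
  velocity_field(vx, vy, vz, spacing = rep(vs, 3),
                 origin = c(xs[1], ys[1], zs[1]),
                 times = (seq_len(nt) - 1) / nt * spec$cycle_ms,
                 venc = scanner$venc)
}

# cell-centered axis covering [lo, hi] with step vs, centered on the range
grid_axis <- function(lo, hi, vs) {
  n <- max(3L, ceiling((hi - lo) / vs))
  (lo + hi) / 2 + (seq_len(n) - (n + 1) / 2) * vs
}

# seeded gaussian stream that does not disturb the global RNG
local_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  function(n, sd) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else assign(".Random.seed", env$state, globalenv())
    out <- stats::rnorm(n, 0, sd)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
}

#' Analytic lumen mask on an analysis plane
#'
#' Pixels of a plane grid whose physical position lies within the phantom
#' lumen (distance to the centerline at most `tube_radius`).
#'
#' @param spec a [phantom_spec()].
#' @param plane a `plane_definition` (see [place_planes()]).
#' @param spacing plane pixel spacing in mm.
#' @return logical matrix; `TRUE` marks lumen pixels.
#' @export
phantom_plane_roi <- function(spec, plane, spacing = 1) {
  g <- plane_grid(plane, spacing)
  fr <- phantom_frame(spec, g$pts)
  m <- matrix(sqrt(fr$d1^2 + fr$d2^2) <= spec$tube_radius, g$nu, g$nv)
  m
}

#' Perturb an ROI contour like a second observer
#'
#' Displaces the mask boundary by smooth random radial jitter (a low-order
#' Fourier series in the polar angle around the mask centroid, amplitude
#' `contour_jitter_mm`) plus a uniform radial dilation/erosion
#' (`dilation_bias_mm`). Assumes a star-shaped mask (true for vessel lumina).
#'
#' @param mask logical matrix (2D ROI).
#' @param observer an [observer_profile()].
#' @param spacing pixel spacing in mm.
#' @return perturbed logical matrix of the same dimensions.
#' @export
perturb_roi <- function(mask, observer, spacing = 1) {
  stopifnot(is.matrix(mask), any(mask))
  if (observer$contour_jitter_mm == 0 && observer$dilation_bias_mm == 0)
    return(mask)
  idx <- which(mask, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  nu <- nrow(mask); nv <- ncol(mask)
  ii <- matrix(rep(seq_len(nu), nv), nu, nv)
  jj <- matrix(rep(seq_len(nv), each = nu), nu, nv)
  dx <- (ii - cx) * spacing; dy <- (jj - cy) * spacing
  r <- sqrt(dx^2 + dy^2); th <- atan2(dy, dx)
  # boundary radius per angle bin from the input mask
  nbin <- 72L
  bin <- pmin(nbin, 1L + floor((th + pi) / (2 * pi) * nbin))
  r0 <- rep(0, nbin)
  rb <- tapply(r[mask], bin[mask], max)
  r0[as.integer(names(rb))] <- rb
  # fill any empty bins by circular interpolation
  if (any(r0 == 0)) {
    good <- which(r0 > 0)
    for (b in which(r0 == 0)) {
      d <- pmin(abs(good - b), nbin - abs(good - b))
      r0[b] <- r0[good[which.min(d)]]
    }
  }
  # smooth Fourier jitter over angle
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(observer$seed)
  a <- stats::rnorm(3); b <- stats::rnorm(3)
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  jit <- function(theta) {
    s <- 0
    for (k in 1:3) s <- s + a[k] * cos(k * theta) + b[k] * sin(k * theta)
    s
  }
  jraw <- jit(th)
  scale <- if (max(abs(jit(seq(0, 2 * pi, length.out = 360)))) > 0)
    observer$contour_jitter_mm / max(abs(jit(seq(0, 2 * pi, length.out = 360)))) else 0
  rlim <- r0[bin] + scale * jraw + observer$dilation_bias_mm
  out <- r <= rlim
  if (!any(out)) stop("ROI perturbation emptied the mask")
  out <- largest_component(out)
  out
}

# keep only the largest 8-connected component (guards contour jitter artifacts)
largest_component <- function(mask) {
  lab <- label_components(mask, connectivity = 8L)
  if (max(lab) <= 1) return(mask)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Cohort specification
#'
#' Describes a group of synthetic subjects: lumen radius distribution,
#' flow-profile mixture, peak-velocity distribution, demographics. The
#' stenosis cohort is biased toward eccentric jets/vortices and higher peak
#' velocities, the control cohort toward parabolic/plug/mildly helical flow,
#' so the two groups differ in flow-profile texture the way valve disease
#' separates from normal valves.
#'
#' @param n_subjects number of subjects.
#' @param label `"no_valve_disease"` or `"aortic_stenosis"`.
#' @param age_range inclusive age range in years.
#' @param sex_ratio_female probability of female sex.
#' @param radius_mean,radius_sd lumen radius distribution, mm.
#' @param peak_velocity_mean,peak_velocity_sd peak velocity distribution, m/s.
#'   Defaults: 1.0 +/- 0.15 (control), 2.8 +/- 0.35 (stenosis).
#' @param profile_mixture named probability vector over profile kinds.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 30L,
                        label = c("no_valve_disease", "aortic_stenosis"),
                        age_range = c(20, 80), sex_ratio_female = 0.5,
                        radius_mean = 14, radius_sd = 1.5,
                        peak_velocity_mean = NULL, peak_velocity_sd = NULL,
                        profile_mixture = NULL, seed = 1L) {
  label <- match.arg(label)
  if (is.null(profile_mixture)) {
    profile_mixture <- if (label == "no_valve_disease")
      c(poiseuille = 0.4, plug = 0.2, helical = 0.3, central_jet = 0.1)
    else
      c(displaced_jet = 0.3, angulated_jet = 0.25, multi_jet = 0.15,
        vortex = 0.15, central_jet = 0.15)
  }
  if (is.null(peak_velocity_mean))
    peak_velocity_mean <- if (label == "no_valve_disease") 1.0 else 2.8
  if (is.null(peak_velocity_sd))
    peak_velocity_sd <- if (label == "no_valve_disease") 0.15 else 0.35
  stopifnot(n_subjects >= 1, abs(sum(profile_mixture) - 1) < 1e-9)
  structure(list(n_subjects = as.integer(n_subjects), label = label,
                 age_range = age_range, sex_ratio_female = sex_ratio_female,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 peak_velocity_mean = peak_velocity_mean,
                 peak_velocity_sd = peak_velocity_sd,
                 profile_mixture = profile_mixture, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw a synthetic cohort
#'
#' Draws per-subject lumen radius, flow profile and peak velocity from the
#' cohort distributions and builds each subject's phantom specification.
#' Velocity fields are not materialized here; call
#' [generate_velocity_field()] per subject (lazily) to keep memory bounded.
#'
#' @param spec a [cohort_spec()].
#' @return a data frame with one row per subject: `subject_id`, `label`,
#'   `age`, `sex`, `radius`, `profile`, `peak_velocity`, plus a list column
#'   `phantom` of [phantom_spec()] objects.
#' @export
generate_cohort <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  n <- spec$n_subjects
  radius <- pmax(8, stats::rnorm(n, spec$radius_mean, spec$radius_sd))
  profile <- sample(names(spec$profile_mixture), n, replace = TRUE,
                    prob = spec$profile_mixture)
  vpeak <- pmax(0.3, stats::rnorm(n, spec$peak_velocity_mean,
                                  spec$peak_velocity_sd))
  age <- round(stats::runif(n, spec$age_range[1], spec$age_range[2]))
  sex <- ifelse(stats::runif(n) < spec$sex_ratio_female, "F", "M")
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  phantoms <- lapply(seq_len(n), function(i) {
    phantom_spec(tube_radius = radius[i], profile_kind = profile[i],
                 peak_velocity = vpeak[i],
                 helix_rate = if (profile[i] %in% c("helical", "vortex")) 12 else 10)
  })
  out <- data.frame(
    subject_id = sprintf("%s_%03d", substr(spec$label, 1, 3), seq_len(n)),
    label = spec$label, age = age, sex = sex, radius = radius,
    profile = profile, peak_velocity = vpeak, stringsAsFactors = FALSE
  )
  out$phantom <- phantoms
  out
}
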