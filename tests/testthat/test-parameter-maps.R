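# The five flow parameter maps and the fixed-range normalization.

test_that("throughflow is the dot product with the plane normal", {
  s <- make_sample(matrix(0, 2, 2), matrix(0, 2, 2), matrix(2, 2, 2))
  expect_equal(throughflow_map(s)$values, matrix(2, 2, 2))
  # v orthogonal to n
  s2 <- make_sample(matrix(1.5, 2, 2), matrix(-0.7, 2, 2), matrix(0, 2, 2))
  expect_equal(throughflow_map(s2)$values, matrix(0, 2, 2))
  # random v and n against a plain dot-product oracle
  set.seed(21)
  for (k in 1:10) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    vx <- matrix(rnorm(9), 3, 3); vy <- matrix(rnorm(9), 3, 3)
    vz <- matrix(rnorm(9), 3, 3)
    s3 <- make_sample(vx, vy, vz, normal = n)
    oracle <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3)
      oracle[i, j] <- sum(c(vx[i, j], vy[i, j], vz[i, j]) * n)
    expect_equal(throughflow_map(s3)$values, oracle, tolerance = 1e-12)
  }
})

test_that("WPD and angle handle oblique and degenerate flow", {
  # v parallel to n
  s <- make_sample(matrix(0, 2, 2), matrix(0, 2, 2), matrix(1.3, 2, 2))
  expect_equal(wpd_map(s)$values, matrix(1, 2, 2))
  expect_equal(angle_map(s)$values, matrix(0, 2, 2), tolerance = 1e-6)
  # v at 60 degrees from n: WPD = cos(60) = 0.5
  s60 <- make_sample(matrix(sin(pi / 3), 2, 2), matrix(0, 2, 2),
                     matrix(cos(pi / 3), 2, 2))
  expect_equal(wpd_map(s60)$values, matrix(0.5, 2, 2), tolerance = 1e-12)
  expect_equal(angle_map(s60)$values, matrix(60, 2, 2), tolerance = 1e-9)
  # antiparallel: angle 180
  s180 <- make_sample(matrix(0, 2, 2), matrix(0, 2, 2), matrix(-1, 2, 2))
  expect_equal(angle_map(s180)$values, matrix(180, 2, 2))
  # 45 degrees
  s45 <- make_sample(matrix(1 / sqrt(2), 1, 1), matrix(0, 1, 1),
                     matrix(1 / sqrt(2), 1, 1))
  expect_equal(angle_map(s45)$values[1, 1], 45, tolerance = 1e-9)
  # zero velocity: WPD 0, angle 90, flags set, never NaN
  s0 <- make_sample(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))
  w0 <- wpd_map(s0); a0 <- angle_map(s0)
  expect_equal(w0$values, matrix(0, 2, 2))
  expect_equal(a0$values, matrix(90, 2, 2))
  expect_true(all(w0$flags) && all(a0$flags))
  expect_false(anyNA(c(w0$values, a0$values)))
})

test_that("WPD equals the cosine of the angle map pixelwise", {
  set.seed(5)
  vx <- matrix(rnorm(100), 10, 10); vy <- matrix(rnorm(100), 10, 10)
  vz <- matrix(rnorm(100), 10, 10)
  n <- c(0.2, -0.4, 0.8); n <- n / sqrt(sum(n^2))
  s <- make_sample(vx, vy, vz, normal = n)
  w <- wpd_map(s)$values
  a <- angle_map(s)$values
  expect_equal(w, cos(a * pi / 180), tolerance = 1e-9)
})

test_that("the discrete curl recovers analytic vorticity", {
  n <- 12; sp_mm <- 2
  ax <- (seq_len(n) - (n + 1) / 2) * sp_mm
  # rigid rotation about z: v = (-Omega y, Omega x, 0), curl = (0, 0, 2 Omega)
  Om <- 3
  vx <- array(0, c(n, n, n, 1)); vy <- vx; vz <- vx
  for (j in seq_len(n)) vx[, j, , 1] <- -Om * ax[j] / 1000
  for (i in seq_len(n)) vy[i, , , 1] <- Om * ax[i] / 1000
  f <- velocity_field(vx, vy, vz, spacing = rep(sp_mm, 3),
                      origin = rep(ax[1], 3), times = 0)
  w <- vorticity_field(f, 1)
  inner <- 2:(n - 1)
  expect_equal(max(abs(w$vz[inner, inner, inner] - 2 * Om)), 0,
               tolerance = 0.02 * 2 * Om)
  expect_lt(max(abs(w$vx[inner, inner, inner])), 1e-9)
  # uniform field: zero curl everywhere
  fu <- velocity_field(array(1, c(5, 5, 5, 1)), array(2, c(5, 5, 5, 1)),
                       array(3, c(5, 5, 5, 1)), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), times = 0)
  wu <- vorticity_field(fu, 1)
  expect_equal(max(abs(c(wu$vx, wu$vy, wu$vz))), 0)
  # Poiseuille: purely azimuthal vorticity, |w| = 2 v r / R^2 (r, R in m)
  sp <- phantom_spec(tube_radius = 14, peak_velocity = 1, n_timeframes = 2L,
                     waveform = c(1, 1))
  fp <- generate_velocity_field(sp,
    scanner_profile(noise_sigma_fraction = 0, n_timeframes = 2L),
    z_extent_mm = 12)
  wp <- vorticity_field(fp, 1)
  d <- dim(wp$vx)
  xs <- fp$origin[1] + (seq_len(d[1]) - 1) * fp$spacing[1]
  ys <- fp$origin[2] + (seq_len(d[2]) - 1) * fp$spacing[2]
  k <- 3
  for (i in c(6, 9, 12)) for (j in c(7, 10)) {
    r_mm <- sqrt(xs[i]^2 + ys[j]^2)
    if (r_mm < 14 - 2.5 * fp$spacing[1] && r_mm > 1) {
      wmag <- sqrt(wp$vx[i, j, k]^2 + wp$vy[i, j, k]^2 + wp$vz[i, j, k]^2)
      # central differences are exact for the parabolic profile
      expect_equal(wmag, 2 * 1 * (r_mm / 1000) / (14 / 1000)^2,
                   tolerance = 1e-6)
      # azimuthal: orthogonal to the radial direction and to z
      expect_lt(abs(wp$vz[i, j, k]), 1e-9)
      expect_lt(abs(wp$vx[i, j, k] * xs[i] + wp$vy[i, j, k] * ys[j]), 1e-6)
    }
  }
  expect_error(vorticity_field(velocity_field(array(0, c(2, 2, 2, 1)),
    array(0, c(2, 2, 2, 1)), array(0, c(2, 2, 2, 1)), c(1, 1, 1),
    c(0, 0, 0), 0), 1), "at least 3")
})

test_that("curl of a discrete gradient field vanishes", {
  set.seed(8)
  n <- 10
  ax <- seq_len(n)
  phi <- array(0, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    phi[i, j, k] <- sin(0.3 * i) * cos(0.4 * j) + 0.05 * k^2
  h <- 0.002
  gx <- flowradiomics:::deriv_axis(phi, 1, h)
  gy <- flowradiomics:::deriv_axis(phi, 2, h)
  gz <- flowradiomics:::deriv_axis(phi, 3, h)
  f <- velocity_field(array(gx, c(n, n, n, 1)), array(gy, c(n, n, n, 1)),
                      array(gz, c(n, n, n, 1)), spacing = rep(h * 1000, 3),
                      origin = c(0, 0, 0), times = 0)
  w <- vorticity_field(f, 1)
  scale <- max(abs(c(gx, gy, gz))) / h
  expect_lt(max(abs(c(w$vx, w$vy, w$vz))) / scale, 1e-10)
})

test_that("LNH separates parabolic, rigid-helical and mirrored flow", {
  # Poiseuille: azimuthal vorticity is orthogonal to axial velocity
  sp <- phantom_spec(tube_radius = 14, peak_velocity = 1, n_timeframes = 2L,
                     waveform = c(1, 1))
  f <- generate_velocity_field(sp,
    scanner_profile(noise_sigma_fraction = 0, n_timeframes = 2L),
    z_extent_mm = 12)
  cl <- straight_centerline(8, 9)
  pl <- plane_at(cl, 4, extent = 16)
  s <- resample_mpr(f, pl, 1)
  sv <- resample_mpr(vorticity_field(f, 1), pl, 1)
  mask <- phantom_plane_roi(sp, pl)
  # restrict to off-wall, off-axis pixels where both magnitudes are healthy
  g <- flowradiomics:::plane_grid(pl, 1)
  rr <- matrix(sqrt(g$pts[, 1]^2 + g$pts[, 2]^2), g$nu, g$nv)
  core <- mask & rr < 14 - 3 & rr > 2
  h <- lnh_map(s, sv)
  expect_lt(max(abs(h$values[core])), 1e-3)
  # rigid rotation + uniform axial flow: on the axis velocity and vorticity
  # align, LNH -> 1; analytic value w / sqrt(w^2 + Omega^2 r^2) off-axis
  n <- 13; spc <- 2
  ax <- (seq_len(n) - (n + 1) / 2) * spc
  Om <- 5; wz <- 0.5
  vx <- array(0, c(n, n, n, 1)); vy <- vx; vz <- array(wz, c(n, n, n, 1))
  for (j in seq_len(n)) vx[, j, , 1] <- -Om * ax[j] / 1000
  for (i in seq_len(n)) vy[i, , , 1] <- Om * ax[i] / 1000
  fr <- velocity_field(vx, vy, vz, spacing = rep(spc, 3),
                       origin = rep(ax[1], 3), times = 0)
  plr <- structure(list(label = "c", origin = c(0, 0, 0),
                        normal = c(0, 0, 1), e1 = c(1, 0, 0),
                        e2 = c(0, 1, 0), extent = 6.5, arc = 0),
                   class = "plane_definition")
  sr <- resample_mpr(fr, plr, 1)
  svr <- resample_mpr(vorticity_field(fr, 1), plr, 1)
  hr <- lnh_map(sr, svr)
  gc <- flowradiomics:::plane_grid(plr, 1)
  onaxis <- which(abs(gc$pts[, 1]) < 1e-9 & abs(gc$pts[, 2]) < 1e-9)
  expect_equal(hr$values[onaxis], 1, tolerance = 1e-9)
  roff <- sqrt(gc$pts[, 1]^2 + gc$pts[, 2]^2) / 1000
  expect_equal(as.vector(hr$values),
               wz / sqrt(wz^2 + (Om * roff)^2), tolerance = 1e-6)
  # mirrored (left-handed) helix: rotation reversed, LNH flips sign pixelwise
  fm <- velocity_field(-vx, -vy, vz, spacing = rep(spc, 3),
                       origin = rep(ax[1], 3), times = 0)
  sm <- resample_mpr(fm, plr, 1)
  svm <- resample_mpr(vorticity_field(fm, 1), plr, 1)
  hm <- lnh_map(sm, svm)
  expect_equal(hm$values, -hr$values, tolerance = 1e-9)
  # absolute variant
  ha <- lnh_map(sm, svm, absolute = TRUE)
  expect_equal(ha$values, abs(hm$values))
})

test_that("self-normalized normal vorticity is antisymmetric and bounded", {
  n <- 13; spc <- 2
  ax <- (seq_len(n) - (n + 1) / 2) * spc
  Om <- 5
  vx <- array(0, c(n, n, n, 1)); vy <- vx; vz <- vx
  for (j in seq_len(n)) vx[, j, , 1] <- -Om * ax[j] / 1000
  for (i in seq_len(n)) vy[i, , , 1] <- Om * ax[i] / 1000
  f <- velocity_field(vx, vy, vz, spacing = rep(spc, 3),
                      origin = rep(ax[1], 3), times = 0)
  pl <- structure(list(label = "c", origin = c(0, 0, 0), normal = c(0, 0, 1),
                       e1 = c(1, 0, 0), e2 = c(0, 1, 0), extent = 6, arc = 0),
                  class = "plane_definition")
  s <- resample_mpr(f, pl, 1)
  sv <- resample_mpr(vorticity_field(f, 1), pl, 1)
  m <- normal_vorticity_map(s, sv)
  # rigid rotation about the normal: the map self-normalizes to 1
  expect_equal(m$values, matrix(1, nrow(m$values), ncol(m$values)),
               tolerance = 1e-9)
  # flipping the plane normal flips the sign
  pl2 <- pl; pl2$normal <- -pl$normal
  s2 <- s; s2$normal <- -s$normal
  m2 <- normal_vorticity_map(s2, sv)
  expect_equal(m2$values, -m$values, tolerance = 1e-12)
  # irrotational uniform flow: zero map
  fu <- velocity_field(array(0.4, c(5, 5, 5, 1)), array(0, c(5, 5, 5, 1)),
                       array(0.2, c(5, 5, 5, 1)), c(2, 2, 2),
                       rep(-4, 3), 0)
  plu <- structure(list(label = "u", origin = c(0, 0, 0), normal = c(0, 0, 1),
                        e1 = c(1, 0, 0), e2 = c(0, 1, 0), extent = 2, arc = 0),
                   class = "plane_definition")
  su <- resample_mpr(fu, plu, 1)
  svu <- resample_mpr(vorticity_field(fu, 1), plu, 1)
  mu_ <- normal_vorticity_map(su, svu)
  expect_equal(max(abs(mu_$values)), 0)
})

test_that("fixed-range normalization reproduces the endpoint mappings", {
  mk <- function(kind, v) structure(
    list(kind = kind, values = matrix(v, 1, 1), units = "x", mask = NULL,
         valid = matrix(TRUE, 1, 1), normalized = FALSE, spacing = 1,
         plane = "p", timeframe = 1L), class = "parameter_map")
  expect_equal(normalize_map(mk("wpd", 1))$values[1, 1], 4096)
  expect_equal(normalize_map(mk("angle", 0))$values[1, 1], 0)
  expect_equal(normalize_map(mk("angle", 180))$values[1, 1], 4096)
  expect_equal(normalize_map(mk("throughflow", 6))$values[1, 1], 2047)
  expect_equal(normalize_map(mk("throughflow", -6))$values[1, 1], -2048)
  # out-of-range values clip to the range ends
  expect_equal(normalize_map(mk("throughflow", 7))$values[1, 1], 2047)
  expect_equal(normalize_map(mk("lnh", -1))$values[1, 1], -2048)
  expect_equal(normalize_map(mk("vorticity", 1))$values[1, 1], 2047)
  # kind mismatch is refused, double normalization too
  expect_error(normalize_map(mk("wpd", 1), normalization_spec("angle")),
               "spec")
  nm <- normalize_map(mk("angle", 90))
  expect_error(normalize_map(nm), "already")
  # round trip is the identity on in-range values
  set.seed(2)
  v <- runif(100, -6, 6)
  m <- mk("throughflow", 0); m$values <- matrix(v, 10, 10)
  back <- denormalize_map(normalize_map(m))
  expect_equal(back$values, m$values, tolerance = 1e-9)
  expect_error(normalization_spec("nope"), "unknown")
})
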