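# Plane placement along the centerline and trilinear multiplanar resampling.

test_that("default plane placement yields the 12 standardized planes", {
  cl <- straight_centerline(80)
  planes <- place_planes(cl)
  expect_length(planes, 12L)
  labels <- vapply(planes, `[[`, "", "label")
  expect_true(all(c("A1.1", "B1", "B4.1", "D1.1") %in% labels))
  # no intermediate planes: just the four landmarks
  expect_length(place_planes(cl, 0, 0), 4L)
  # straight centerline: every normal is the axis direction
  for (p in planes) {
    expect_equal(unname(p$normal), c(0, 0, 1), tolerance = 1e-9)
    expect_equal(sqrt(sum(p$normal^2)), 1, tolerance = 1e-9)
    expect_equal(sum(p$normal * p$e1), 0, tolerance = 1e-12)
    expect_equal(sum(p$e1 * p$e2), 0, tolerance = 1e-12)
  }
  # intra-segment spacings are equal
  arcs <- vapply(planes, `[[`, 1, "arc")
  asc <- sort(arcs[arcs >= cl$landmarks["A1.1"] & arcs <= cl$landmarks["B1"]])
  expect_lt(max(abs(diff(diff(asc)))), 1e-6)
  des <- sort(arcs[arcs >= cl$landmarks["B4.1"] & arcs <= cl$landmarks["D1.1"]])
  expect_lt(max(abs(diff(diff(des)))), 1e-6)
})

test_that("landmark ordering is validated", {
  pts <- cbind(0, 0, seq(0, 80, length.out = 41))
  expect_error(centerline(pts, c("A1.1" = 30, "B1" = 10, "B4.1" = 50,
                                 "D1.1" = 70)), "out of order")
  expect_error(centerline(pts, c("A1.1" = 10, "B1" = 30)), "landmark")
})

test_that("arched centerlines carry tangent-aligned normals", {
  cl <- arch_centerline(120)
  planes <- place_planes(cl)
  expect_length(planes, 12L)
  for (p in planes) {
    at <- flowradiomics:::centerline_at(cl, p$arc)
    expect_equal(unname(p$normal), unname(at$tangent), tolerance = 1e-9)
  }
})

# helper: velocity field from a linear function v(x) = a + G x (exactly
# representable by trilinear interpolation)
linear_field <- function(a, G, n = 10, spacing = 2, nt = 2) {
  ax <- (seq_len(n) - 1) * spacing - (n - 1) * spacing / 2
  vx <- array(0, c(n, n, n, nt)); vy <- vx; vz <- vx
  for (k in seq_len(n)) for (j in seq_len(n)) {
    p <- cbind(ax, ax[j], ax[k])
    v <- sweep(p %*% t(G), 2, -a)
    for (t in seq_len(nt)) {
      vx[, j, k, t] <- v[, 1]; vy[, j, k, t] <- v[, 2]; vz[, j, k, t] <- v[, 3]
    }
  }
  velocity_field(vx, vy, vz, spacing = rep(spacing, 3),
                 origin = rep(ax[1], 3), times = seq_len(nt) - 1)
}

test_that("trilinear MPR is exact for constant and linear fields", {
  a <- c(0.3, -0.2, 1.1)
  f0 <- linear_field(a, matrix(0, 3, 3))
  cl <- straight_centerline(8, 9)
  pl <- plane_at(cl, 4, extent = 6)
  s <- resample_mpr(f0, pl, 1)
  expect_equal(max(abs(s$vx[s$valid] - a[1])), 0, tolerance = 1e-12)
  expect_equal(max(abs(s$vz[s$valid] - a[3])), 0, tolerance = 1e-12)
  # oblique plane through a linear field: exact reproduction
  G <- matrix(c(0.01, 0.02, -0.01, 0.03, -0.02, 0.005, 0, 0.01, 0.02), 3, 3)
  fl <- linear_field(a, G)
  obl <- structure(list(label = "obl", origin = c(1, 0.5, -0.7),
                        normal = c(1, 1, 1) / sqrt(3),
                        e1 = c(1, -1, 0) / sqrt(2),
                        e2 = c(1, 1, -2) / sqrt(6), extent = 4, arc = 0),
                   class = "plane_definition")
  so <- resample_mpr(fl, obl, 1)
  g <- flowradiomics:::plane_grid(obl, 1)
  truth <- sweep(g$pts %*% t(G), 2, -a)
  expect_equal(as.vector(so$vx)[as.vector(so$valid)],
               truth[as.vector(so$valid), 1], tolerance = 1e-10)
  expect_equal(as.vector(so$vy)[as.vector(so$valid)],
               truth[as.vector(so$valid), 2], tolerance = 1e-10)
})

test_that("MPR is linear in the field and never extrapolates", {
  set.seed(11)
  n <- 8
  mkf <- function() {
    velocity_field(array(rnorm(n^3 * 2), c(n, n, n, 2)),
                   array(rnorm(n^3 * 2), c(n, n, n, 2)),
                   array(rnorm(n^3 * 2), c(n, n, n, 2)),
                   spacing = c(2, 2, 2), origin = c(-7, -7, -7),
                   times = 0:1)
  }
  f1 <- mkf(); f2 <- mkf()
  fc <- velocity_field(2 * f1$vx - 3 * f2$vx, 2 * f1$vy - 3 * f2$vy,
                       2 * f1$vz - 3 * f2$vz, spacing = f1$spacing,
                       origin = f1$origin, times = f1$times)
  pl <- structure(list(label = "p", origin = c(0.3, -0.2, 0.5),
                       normal = c(0, 1, 0), e1 = c(1, 0, 0),
                       e2 = c(0, 0, -1), extent = 12, arc = 0),
                  class = "plane_definition")
  s1 <- resample_mpr(f1, pl, 2); s2 <- resample_mpr(f2, pl, 2)
  sc <- resample_mpr(fc, pl, 2)
  expect_equal(sc$vx[sc$valid], (2 * s1$vx - 3 * s2$vx)[sc$valid],
               tolerance = 1e-12)
  # pixels beyond the grid are invalid, not extrapolated
  expect_true(any(!sc$valid))
  expect_true(all(is.na(sc$vx[!sc$valid])))
  far <- structure(list(label = "far", origin = c(0, 500, 0),
                        normal = c(0, 1, 0), e1 = c(1, 0, 0),
                        e2 = c(0, 0, -1), extent = 4, arc = 0),
                   class = "plane_definition")
  expect_error(resample_mpr(mkf(), far, 1), "outside")
})

test_that("axis-aligned lattice-coincident planes return source voxels", {
  n <- 6
  arr <- array(seq_len(n^3), c(n, n, n, 1))
  f <- velocity_field(arr, arr * 2, arr * 3, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0), times = 0)
  pl <- structure(list(label = "k3", origin = c(2, 2, 3),
                       normal = c(0, 0, 1), e1 = c(1, 0, 0),
                       e2 = c(0, 1, 0), extent = 1, arc = 0),
                  class = "plane_definition")
  s <- resample_mpr(f, pl, 1)
  # pixel at in-plane offset (u, v) must equal voxel [2+u, 2+v, 3+1]
  g <- flowradiomics:::plane_grid(pl, 1)
  for (iu in seq_along(g$u)) for (iv in seq_along(g$v)) {
    expect_equal(s$vx[iu, iv],
                 arr[2 + g$u[iu] + 1, 2 + g$v[iv] + 1, 4, 1])
  }
})

test_that("ROI propagation tracks the jet and preserves area", {
  # static flow: masks identical at all frames
  sp <- phantom_spec(profile_kind = "central_jet", n_timeframes = 3L,
                     waveform = rep(1, 3))
  f <- generate_velocity_field(sp,
    scanner_profile(noise_sigma_fraction = 0, n_timeframes = 3L),
    z_extent_mm = 10)
  cl <- straight_centerline(6, 7)
  pl <- plane_at(cl, 3, extent = 18)
  samples <- lapply(1:3, function(t) resample_mpr(f, pl, t))
  mask <- phantom_plane_roi(sp, pl)
  masks <- propagate_roi(mask, samples)
  for (m in masks) expect_identical(m, mask)
  # known displacement: jet shifted by 4 mm at the second frame
  sp2 <- phantom_spec(profile_kind = "displaced_jet",
                      jet_displacement_fraction = 4 / 14,
                      n_timeframes = 3L, waveform = rep(1, 3))
  f2 <- generate_velocity_field(sp2,
    scanner_profile(noise_sigma_fraction = 0, n_timeframes = 3L),
    z_extent_mm = 10)
  samples2 <- list(samples[[1]], resample_mpr(f2, pl, 2))
  small <- matrix(FALSE, nrow(mask), ncol(mask))
  cidx <- which(mask, arr.ind = TRUE)
  cc <- round(colMeans(cidx))
  small[(cc[1] - 6):(cc[1] + 6), (cc[2] - 6):(cc[2] + 6)] <- TRUE
  masks2 <- propagate_roi(small, samples2, search_mm = 10)
  d1 <- colMeans(which(masks2[[1]], arr.ind = TRUE))
  d2 <- colMeans(which(masks2[[2]], arr.ind = TRUE))
  expect_equal(unname(sqrt(sum((d2 - d1)^2))), 4, tolerance = 1)
  # area preserved exactly under the rigid shift
  expect_equal(sum(masks2[[2]]), sum(small))
  # zero flow: untranslated mask with a warning
  z <- f; z$vx[] <- 0; z$vy[] <- 0; z$vz[] <- 0
  szero <- lapply(1, function(t) resample_mpr(z, pl, t))
  expect_warning(mz <- propagate_roi(mask, szero), "zero flow")
  expect_identical(mz[[1]], mask)
})
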