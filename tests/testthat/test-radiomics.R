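# Discretization, texture families and the signature catalogue.

test_that("fixed-bin-width discretization follows the min-anchored rule", {
  m <- matrix(c(0, 24.9, 25, 50), 2, 2)
  d <- discretize(m, bin_width = 25)
  expect_equal(as.vector(d$levels), c(1L, 1L, 2L, 3L))
  # constant map: single level
  dc <- discretize(matrix(7, 4, 4), bin_width = 25)
  expect_true(all(dc$levels == 1L))
  expect_equal(dc$n_levels, 1L)
  # full normalized span: ceil arithmetic gives 164 levels
  span <- matrix(seq(0, 4096, length.out = 400), 20, 20)
  expect_equal(discretize(span, 25)$n_levels, 164L)
  expect_error(discretize(matrix(1, 2, 2), 25, mask = matrix(FALSE, 2, 2)),
               "empty ROI")
})

test_that("degenerate maps give the documented constants", {
  d <- as_discretized(matrix(1L, 5, 5))
  g <- glcm_features(d)
  expect_equal(unname(g["Id"]), 1)
  expect_equal(unname(g["JointEntropy"]), 0)
  expect_equal(unname(g["Contrast"]), 0)
  n <- ngtdm_features(d)
  expect_equal(unname(n["Coarseness"]), 1e6)
  z <- glszm_features(d)
  expect_equal(unname(z["ZonePercentage"]), 1 / 25)
  # all-distinct levels: every zone is a single pixel, dependences all zero
  lev <- matrix(1:9, 3, 3)
  dd <- as_discretized(lev)
  expect_equal(unname(glszm_features(dd)["ZonePercentage"]), 1)
  expect_equal(unname(gldm_features(dd)["LargeDependenceEmphasis"]), 1)
})

test_that("GLDM dependence counts match the neighbor geometry", {
  dep <- flowradiomics:::gldm_dependence(matrix(1L, 3, 3))
  expect_equal(dep[2, 2], 8L)
  expect_equal(dep[1, 2], 5L)
  expect_equal(dep[1, 1], 3L)
})

test_that("run extraction counts hand-countable runs", {
  lev <- matrix(c(1L, 1L, 2L), 1, 3)
  R <- flowradiomics:::glrlm_matrix(as_discretized(lev))
  # horizontal: run of 2 (level 1) + run of 1 (level 2); the other three
  # directions each see three unit runs
  expect_equal(R[1, 2], 1)
  expect_equal(R[2, 1], 1 + 3)  # level-2 pixel is a unit run in 4 directions
  lev5 <- matrix(3L, 4, 4)
  R5 <- flowradiomics:::glrlm_matrix(as_discretized(lev5))
  expect_equal(R5[3, 4], 4 + 4 + 2)  # rows, columns, two main diagonals
})

test_that("all texture families match independent brute-force oracles", {
  set.seed(42)
  tol <- 1e-8
  for (rep in 1:22) {
    n <- sample(4:12, 1)
    ml <- sample(2:6, 1)
    lev <- random_level_map(n, ml)
    d <- as_discretized(lev)
    expect_equal(glcm_features(d), oracle_glcm_features(lev), tolerance = tol)
    expect_equal(glrlm_features(d), oracle_glrlm_features(lev), tolerance = tol)
    expect_equal(glszm_features(d), oracle_glszm_features(lev), tolerance = tol)
    expect_equal(gldm_features(d), oracle_gldm_features(lev), tolerance = tol)
    expect_equal(ngtdm_features(d), oracle_ngtdm_features(lev), tolerance = tol)
    vals <- matrix(as.numeric(lev), n, n)
    fo <- first_order_features(vals, d = d, mask = !is.na(lev), bin_width = 1)
    expect_equal(fo, oracle_first_order(vals[!is.na(lev)], lev[!is.na(lev)],
                                        d$n_levels), tolerance = tol)
  }
})

test_that("GLCM invariances hold feature by feature", {
  set.seed(7)
  lev <- random_level_map(8, 4, with_na = FALSE)
  d <- as_discretized(lev)
  # relabeling levels by a permutation preserves entropy but not contrast
  perm <- sample(4)
  lev2 <- matrix(perm[lev], 8, 8)
  d2 <- as_discretized(lev2)
  f1 <- glcm_features(d)
  f2 <- glcm_features(structure(list(levels = lev2, n_levels = 4L,
                                     bin_width = 1, mask = !is.na(lev2),
                                     spacing = 1), class = "discretized_map"))
  expect_equal(f1[["JointEntropy"]], f2[["JointEntropy"]], tolerance = 1e-10)
  expect_equal(f1[["JointEnergy"]], f2[["JointEnergy"]], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(f1[["Contrast"]], f2[["Contrast"]])))
})

test_that("first-order percentiles use the interpolating sample quantile", {
  vals <- matrix(as.numeric(1:100), 10, 10)
  fo <- first_order_features(vals, bin_width = 25)
  expect_equal(unname(fo["Percentile90"]), 90.1)
  # constant ROI: moments define skewness/kurtosis as 0
  foc <- first_order_features(matrix(3.5, 4, 4), bin_width = 25)
  expect_equal(unname(foc[c("Variance", "Skewness", "Kurtosis")]), c(0, 0, 0))
})

test_that("checkerboard co-occurrences have unit contrast axially", {
  lev <- outer(1:6, 1:6, function(i, j) ((i + j) %% 2) + 1L)
  d <- as_discretized(lev)
  P_ax <- flowradiomics:::glcm_matrix(d, c(1L, 0L))
  p <- P_ax / sum(P_ax)
  ii <- row(p); jj <- col(p)
  expect_equal(sum((ii - jj)^2 * p), 1)  # every axial pair differs by 1
})

test_that("shape descriptors reproduce analytic geometry", {
  sq <- matrix(FALSE, 14, 14)
  sq[3:12, 3:12] <- TRUE  # 10 x 10 mm square at 1 mm pixels
  f <- shape2d_features(sq, spacing = 1)
  expect_equal(unname(f["PixelArea"]), 100)
  expect_equal(unname(f["MaximumDiameter"]), sqrt(200), tolerance = 1e-9)
  expect_equal(unname(f["Extent"]), 1)
  # disk of radius 10 mm: near-unit circularity, equal principal axes
  g <- expand.grid(i = 1:25, j = 1:25)
  disk <- matrix(sqrt((g$i - 13)^2 + (g$j - 13)^2) <= 10, 25, 25)
  fd <- shape2d_features(disk, spacing = 1)
  expect_gt(unname(fd["Circularity"]), 0.95)
  expect_equal(unname(fd["MajorAxisLength"]), unname(fd["MinorAxisLength"]),
               tolerance = 0.02)
  expect_equal(unname(fd["MajorAxisLength"]), 20, tolerance = 0.05 * 20)
  # the reference frame itself has zero drift and zero area change
  expect_equal(unname(f[c("CentroidDrift", "AreaFractionChange")]), c(0, 0))
  expect_error(shape2d_features(matrix(FALSE, 3, 3)), "empty")
})

test_that("the default catalogue counts are 79 per map and 16 shape", {
  cat <- default_catalogue()
  expect_equal(sum(lengths(cat$families)), 79L)
  expect_equal(length(cat$shape), 16L)
  full <- unlist(lapply(names(cat$families), function(f)
    paste0(f, "__", cat$families[[f]])))
  expect_false(any(duplicated(full)))
  # Every headline reproducible feature family member is retained
  expect_true(all(c("InverseVariance", "Idn", "Idm", "Id") %in%
                    cat$families$glcm))
  expect_true(all(c("GrayLevelNonUniformity", "RunLengthNonUniformity",
                    "RunEntropy") %in% cat$families$glrlm))
  expect_true(all(c("ZonePercentage", "SizeZoneNonUniformity") %in%
                    cat$families$glszm))
  expect_true(all(c("DependenceNonUniformity", "DependenceEntropy") %in%
                    cat$families$gldm))
  expect_true("Coarseness" %in% cat$families$ngtdm)
})

test_that("extract_signature assembles exactly 411 deterministic features", {
  set.seed(3)
  nu <- 15
  mk <- function(kind, vals) {
    m <- structure(list(kind = kind, values = vals, units = "normalized",
                        mask = NULL, valid = matrix(TRUE, nu, nu),
                        normalized = TRUE, spacing = 1, plane = "A1.1",
                        timeframe = 1L), class = "parameter_map")
    m
  }
  g <- expand.grid(i = 1:nu, j = 1:nu)
  mask <- matrix(sqrt((g$i - 8)^2 + (g$j - 8)^2) <= 6, nu, nu)
  maps <- list(
    throughflow = mk("throughflow", matrix(runif(nu^2, 0, 2000), nu, nu)),
    wpd = mk("wpd", matrix(runif(nu^2, 2000, 4096), nu, nu)),
    angle = mk("angle", matrix(runif(nu^2, 0, 1000), nu, nu)),
    lnh = mk("lnh", matrix(runif(nu^2, -2048, 2047), nu, nu)),
    vorticity = mk("vorticity", matrix(runif(nu^2, -500, 500), nu, nu))
  )
  sig <- extract_signature(maps, mask)
  expect_length(sig, 411L)
  expect_true(all(is.finite(sig)))
  counts <- table(sub("__.*", "", names(sig)))
  expect_equal(unname(counts[c("throughflow", "wpd", "angle", "lnh",
                               "vorticity")]), rep(79L, 5),
               ignore_attr = TRUE)
  expect_equal(unname(counts["shape"]), 16L, ignore_attr = TRUE)
  expect_identical(sig, extract_signature(maps, mask))
  expect_error(extract_signature(maps[1:4], mask), "must contain")
})
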