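#' Gray-level texture feature families
#'
#' The five matrix-based families (GLCM, GLRLM, GLSZM, GLDM, NGTDM) plus the
#' first-order statistics follow the image biomarker standardization (IBSI)
#' definitions for 2D maps: distance-1 neighborhoods, the four unique 2D
#' directions for co-occurrences and runs, 8-connected zones, and documented
#' degenerate-case constants (never `NaN`). Co-occurrence matrices are
#' symmetrized and GLCM features averaged over directions; run-length
#' matrices are summed over directions before feature computation.
#'
#' @name texture-features
NULL

glcm_offsets <- function() list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))

# aligned (a, b) level pairs for one pixel offset
offset_pairs <- function(lev, di, dj) {
  nu <- nrow(lev); nv <- ncol(lev)
  ri <- seq(max(1L, 1L - di), min(nu, nu - di))
  cj <- seq(max(1L, 1L - dj), min(nv, nv - dj))
  if (!length(ri) || !length(cj)) return(NULL)
  a <- lev[ri, cj, drop = FALSE]
  b <- lev[ri + di, cj + dj, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  list(a = a[keep], b = b[keep])
}

# symmetric co-occurrence matrix for one direction
glcm_matrix <- function(d, off) {
  ng <- d$n_levels
  pr <- offset_pairs(d$levels, off[1], off[2])
  m <- matrix(0, ng, ng)
  if (!is.null(pr) && length(pr$a)) {
    cnt <- tabulate(pr$a + ng * (pr$b - 1L), nbins = ng * ng)
    m <- matrix(cnt, ng, ng)
  }
  m + t(m)
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  eps <- 2.2e-16
  if (tot == 0) stop("empty co-occurrence matrix")
  p <- P / tot
  i <- matrix(rep(seq_len(ng), ng), ng, ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx2 <- sum((seq_len(ng) - mux)^2 * px); sy2 <- sum((seq_len(ng) - muy)^2 * py)
  # diagonal / cross-diagonal marginal distributions
  k_sum <- 2:(2 * ng); k_dif <- 0:(ng - 1)
  pxy_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), 1)
  pxy_dif <- vapply(k_dif, function(k) sum(p[abs(i - j) == k]), 1)
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hx <- H(px); hy <- H(py); hxy <- H(p)
  ppxy <- px[i] * py[j]
  hxy1 <- -sum(p[ppxy > 0] * log2(ppxy[ppxy > 0] + eps))
  hxy2 <- H(ppxy)
  da <- sum(k_dif * pxy_dif)
  corr <- if (sx2 > 0 && sy2 > 0)
    (sum(i * j * p) - mux * muy) / sqrt(sx2 * sy2) else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  # MCC: second largest eigenvalue of Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k))
  mcc <- if (ng > 1 && all(px > 0) && all(py > 0)) {
    Q <- (p / px) %*% t(p / matrix(py, ng, ng, byrow = TRUE))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  } else 1
  offd <- abs(i - j) > 0
  c(
    Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = H(pxy_dif),
    DifferenceVariance = sum((k_dif - da)^2 * pxy_dif),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[offd] / (i[offd] - j[offd])^2),
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    MCC = mcc,
    SumAverage = sum(k_sum * pxy_sum),
    SumEntropy = H(pxy_sum),
    SumSquares = sx2
  )
}

#' Gray-level co-occurrence features
#'
#' Distance-1 co-occurrences over the four unique 2D directions; matrices are
#' symmetrized per direction and the 24 features averaged over directions.
#'
#' @param d a `discretized_map` from [discretize()].
#' @return named numeric vector of 24 GLCM features.
#' @export
glcm_features <- function(d) {
  if (sum(!is.na(d$levels)) < 2) stop("GLCM needs at least 2 ROI pixels")
  per_dir <- lapply(glcm_offsets(), function(off) {
    M <- glcm_matrix(d, off)
    if (sum(M) == 0) NULL else glcm_features_one(M)
  })
  per_dir <- per_dir[!vapply(per_dir, is.null, TRUE)]
  if (!length(per_dir)) stop("no co-occurring pixel pairs in the ROI")
  Reduce(`+`, per_dir) / length(per_dir)
}

# runs along all 4 directions, summed run-length matrix R[level, length]
glrlm_matrix <- function(d) {
  lev <- d$levels
  nu <- nrow(lev); nv <- ncol(lev)
  lines <- c(
    lapply(seq_len(nu), function(i) lev[i, ]),
    lapply(seq_len(nv), function(j) lev[, j]),
    split(lev, row(lev) - col(lev)),       # anti-diagonals of the lattice
    split(lev, row(lev) + col(lev))        # diagonals
  )
  ng <- d$n_levels
  maxlen <- max(nu, nv)
  R <- matrix(0, ng, maxlen)
  for (v in lines) {
    r <- rle(ifelse(is.na(v), -1L, as.integer(v)))
    keep <- r$values > 0L
    if (any(keep)) {
      gl <- r$values[keep]; ln <- r$lengths[keep]
      for (q in seq_along(gl)) R[gl[q], ln[q]] <- R[gl[q], ln[q]] + 1
    }
  }
  R
}

# shared size-weighted feature set for run-length / size-zone matrices
rl_style_features <- function(M, n_pixels, prefix) {
  ns <- sum(M)
  i <- matrix(rep(seq_len(nrow(M)), ncol(M)), nrow(M), ncol(M))
  j <- matrix(rep(seq_len(ncol(M)), each = nrow(M)), nrow(M), ncol(M))
  p <- M / ns
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  v <- c(
    sum(M / j^2) / ns,                     # short emphasis
    sum(M * j^2) / ns,                     # long emphasis
    sum(rowSums(M)^2) / ns,                # gray level non-uniformity
    sum(rowSums(M)^2) / ns^2,              # ... normalized
    sum(colSums(M)^2) / ns,                # size non-uniformity
    sum(colSums(M)^2) / ns^2,              # ... normalized
    ns / n_pixels,                         # percentage
    sum(p * (i - mu_i)^2),                 # gray level variance
    sum(p * (j - mu_j)^2),                 # size variance
    H(p),                                  # entropy
    sum(M / i^2) / ns,
    sum(M * i^2) / ns,
    sum(M / (i^2 * j^2)) / ns,
    sum(M * i^2 / j^2) / ns,
    sum(M * j^2 / i^2) / ns,
    sum(M * i^2 * j^2) / ns
  )
  names(v) <- paste0(prefix, c(
    "ShortEmphasis", "LongEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "SizeNonUniformity",
    "SizeNonUniformityNormalized", "Percentage", "GrayLevelVariance",
    "SizeVariance", "Entropy", "LowGrayLevelEmphasis",
    "HighGrayLevelEmphasis", "ShortLowGrayLevelEmphasis",
    "ShortHighGrayLevelEmphasis", "LongLowGrayLevelEmphasis",
    "LongHighGrayLevelEmphasis"
  ))
  v
}

#' Gray-level run-length features
#'
#' Runs of equal level along the four 2D directions; the four run-length
#' matrices are summed before the 16 features are computed.
#'
#' @param d a `discretized_map`.
#' @return named numeric vector of 16 GLRLM features.
#' @export
glrlm_features <- function(d) {
  n_pix <- sum(!is.na(d$levels))
  if (n_pix < 1) stop("empty ROI")
  R <- glrlm_matrix(d)
  v <- rl_style_features(R, n_pix, "")
  names(v) <- c("ShortRunEmphasis", "LongRunEmphasis",
                "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                "RunPercentage", "GrayLevelVariance", "RunVariance",
                "RunEntropy", "LowGrayLevelRunEmphasis",
                "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
                "LongRunHighGrayLevelEmphasis")
  v
}

# zones = 8-connected components of equal level; S[level, size]
glszm_matrix <- function(d) {
  lev <- d$levels
  ng <- d$n_levels
  zones <- list()
  for (l in seq_len(ng)) {
    m <- !is.na(lev) & lev == l
    if (!any(m)) next
    lab <- label_components(m, connectivity = 8L)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0])
      zones[[length(zones) + 1]] <- cbind(l, sizes)
    }
  }
  zs <- do.call(rbind, zones)
  S <- matrix(0, ng, max(zs[, 2]))
  for (q in seq_len(nrow(zs))) S[zs[q, 1], zs[q, 2]] <- S[zs[q, 1], zs[q, 2]] + 1
  S
}

#' Gray-level size-zone features
#'
#' Zones are 8-connected components of equal gray level; 16 features follow
#' the IBSI size-zone definitions (zone percentage = zones / ROI pixels).
#'
#' @param d a `discretized_map`.
#' @return named numeric vector of 16 GLSZM features.
#' @export
glszm_features <- function(d) {
  n_pix <- sum(!is.na(d$levels))
  if (n_pix < 1) stop("empty ROI")
  S <- glszm_matrix(d)
  v <- rl_style_features(S, n_pix, "")
  names(v) <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
                "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
                "SmallAreaHighGrayLevelEmphasis",
                "LargeAreaLowGrayLevelEmphasis",
                "LargeAreaHighGrayLevelEmphasis")
  v
}

all_offsets8 <- function() {
  cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
}

# per-pixel count of 8-neighbors inside the ROI whose |level difference| <= alpha
gldm_dependence <- function(lev, alpha = 0L) {
  nu <- nrow(lev); nv <- ncol(lev)
  dep <- matrix(0L, nu, nv)
  offs <- all_offsets8()
  for (k in seq_len(nrow(offs))) {
    di <- offs[k, 1]; dj <- offs[k, 2]
    ri <- seq(max(1L, 1L - di), min(nu, nu - di))
    cj <- seq(max(1L, 1L - dj), min(nv, nv - dj))
    a <- lev[ri, cj, drop = FALSE]
    b <- lev[ri + di, cj + dj, drop = FALSE]
    eq <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
    dep[ri, cj] <- dep[ri, cj] + eq
  }
  dep
}

#' Gray-level dependence features
#'
#' The dependence of a pixel is the number of its 8-neighbors inside the ROI
#' whose gray level differs by at most `alpha` (default 0). The matrix is
#' indexed by (level, dependence + 1) and the size weights of the 14 features
#' use that 1-based column index.
#'
#' @param d a `discretized_map`.
#' @param alpha gray-level tolerance for dependence.
#' @return named numeric vector of 14 GLDM features.
#' @export
gldm_features <- function(d, alpha = 0L) {
  lev <- d$levels
  roi <- !is.na(lev)
  if (!any(roi)) stop("empty ROI")
  dep <- gldm_dependence(lev, alpha)
  ng <- d$n_levels
  maxd <- max(dep[roi]) + 1L
  D <- matrix(0, ng, maxd)
  cnt <- tabulate(lev[roi] + ng * dep[roi], nbins = ng * maxd)
  D <- matrix(cnt, ng, maxd)
  v <- rl_style_features(D, sum(roi), "")
  # the GLDM set has no run-percentage (total always equals the ROI size)
  # and no normalized gray-level non-uniformity
  v <- v[!names(v) %in% c("Percentage", "GrayLevelNonUniformityNormalized")]
  names(v) <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                "GrayLevelNonUniformity",
                "DependenceNonUniformity", "DependenceNonUniformityNormalized",
                "GrayLevelVariance", "DependenceVariance", "DependenceEntropy",
                "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
                "SmallDependenceLowGrayLevelEmphasis",
                "SmallDependenceHighGrayLevelEmphasis",
                "LargeDependenceLowGrayLevelEmphasis",
                "LargeDependenceHighGrayLevelEmphasis")
  v
}

#' Neighboring gray-tone difference features
#'
#' For each ROI pixel with at least one ROI 8-neighbor, the absolute
#' difference between its level and the mean level of those neighbors is
#' accumulated per gray level (`s_i`); together with the level probabilities
#' `p_i` these give Coarseness, Contrast, Busyness, Complexity and Strength.
#' Degenerate denominators follow the documented constants: Coarseness of a
#' constant map is `1e6`; Contrast/Busyness/Strength of a single-level map
#' are 0.
#'
#' @param d a `discretized_map`.
#' @return named numeric vector of 5 NGTDM features.
#' @export
ngtdm_features <- function(d) {
  lev <- d$levels
  roi <- !is.na(lev)
  if (!any(roi)) stop("empty ROI")
  nu <- nrow(lev); nv <- ncol(lev)
  nb_sum <- matrix(0, nu, nv); nb_cnt <- matrix(0L, nu, nv)
  offs <- all_offsets8()
  for (k in seq_len(nrow(offs))) {
    di <- offs[k, 1]; dj <- offs[k, 2]
    ri <- seq(max(1L, 1L - di), min(nu, nu - di))
    cj <- seq(max(1L, 1L - dj), min(nv, nv - dj))
    b <- lev[ri + di, cj + dj, drop = FALSE]
    ok <- !is.na(b)
    add <- b; add[!ok] <- 0L
    nb_sum[ri, cj] <- nb_sum[ri, cj] + add
    nb_cnt[ri, cj] <- nb_cnt[ri, cj] + ok
  }
  use <- roi & nb_cnt > 0
  ng <- d$n_levels
  Amean <- nb_sum[use] / nb_cnt[use]
  lv <- lev[use]
  Nvp <- sum(use)
  s <- vapply(seq_len(ng), function(l) sum(abs(l - Amean)[lv == l]), 1)
  n_i <- tabulate(lv, nbins = ng)
  p <- n_i / Nvp
  present <- which(n_i > 0)
  Ngp <- length(present)
  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (Ngp > 1) {
    pr <- outer(p[present], p[present])
    dd <- outer(present, present, `-`)^2
    (sum(pr * dd) / (Ngp * (Ngp - 1))) * (sum(s) / Nvp)
  } else 0
  busy_den <- sum(abs(outer(present * p[present], present * p[present], `-`)))
  busyness <- if (busy_den > 0) coarse_den / busy_den else 0
  complexity <- if (Ngp > 1) {
    tot <- 0
    for (ii in present) for (jj in present) {
      if (ii != jj)
        tot <- tot + abs(ii - jj) * (p[ii] * s[ii] + p[jj] * s[jj]) /
          (p[ii] + p[jj])
    }
    tot / Nvp
  } else 0
  strength <- if (sum(s) > 0 && Ngp > 1) {
    tot <- 0
    for (ii in present) for (jj in present)
      if (ii != jj) tot <- tot + (p[ii] + p[jj]) * (ii - jj)^2
    tot / sum(s)
  } else 0
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

#' First-order intensity statistics
#'
#' The 18 first-order features of the normalized map intensities inside the
#' ROI. Entropy and uniformity are computed on the discretized gray-level
#' histogram; percentiles use the standard interpolating sample quantile;
#' skewness and kurtosis are the population moment ratios (kurtosis is not
#' excess-corrected) and are defined as 0 for a constant ROI.
#'
#' @param map a normalized `parameter_map` or numeric matrix.
#' @param d the matching `discretized_map` (for entropy/uniformity); computed
#'   on the fly when missing.
#' @param mask optional ROI mask.
#' @param bin_width bin width used when `d` must be computed.
#' @return named numeric vector of 18 first-order features.
#' @export
first_order_features <- function(map, d = NULL, mask = NULL, bin_width = 25) {
  if (inherits(map, "parameter_map")) {
    vals <- map$values
    if (is.null(mask)) mask <- map$mask %||% map$valid
    spacing <- map$spacing %||% 1
  } else {
    vals <- map
    if (is.null(mask)) mask <- !is.na(vals)
    spacing <- 1
  }
  if (is.null(d)) d <- discretize(vals, bin_width, mask)
  x <- vals[mask]
  n <- length(x)
  if (n < 1) stop("empty ROI")
  qs <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 else 0
  inr <- x[x >= qs[1] & x <= qs[5]]
  p_lev <- tabulate(d$levels[mask], nbins = d$n_levels) / n
  p_lev <- p_lev[p_lev > 0]
  c(
    Energy = sum(x^2),
    TotalEnergy = sum(x^2) * spacing^2,
    Entropy = -sum(p_lev * log2(p_lev)),
    Minimum = min(x),
    Percentile10 = qs[1],
    Percentile90 = qs[5],
    Maximum = max(x),
    Mean = m,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation = mean(abs(inr - mean(inr))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p_lev^2)
  )
}
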