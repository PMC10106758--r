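# Independent brute-force oracles for the texture feature families.
# Deliberately written as plain enumerations (nested loops, recursive flood
# fill) sharing no code with the package implementation.

oracle_entropy2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

# ---- GLCM ------------------------------------------------------------------
oracle_glcm_dir <- function(lev, di, dj) {
  ng <- max(lev, na.rm = TRUE)
  P <- matrix(0, ng, ng)
  nu <- nrow(lev); nv <- ncol(lev)
  for (i in seq_len(nu)) for (j in seq_len(nv)) {
    if (is.na(lev[i, j])) next
    for (sgn in c(1, -1)) {
      ii <- i + sgn * di; jj <- j + sgn * dj
      if (ii >= 1 && ii <= nu && jj >= 1 && jj <= nv && !is.na(lev[ii, jj]))
        P[lev[i, j], lev[ii, jj]] <- P[lev[i, j], lev[ii, jj]] + 1
    }
  }
  P
}

oracle_glcm_features_one <- function(P) {
  ng <- nrow(P)
  p <- P / sum(P)
  px <- rowSums(p); py <- colSums(p)
  iv <- seq_len(ng)
  mux <- sum(iv * px); muy <- sum(iv * py)
  sx2 <- sum((iv - mux)^2 * px); sy2 <- sum((iv - muy)^2 * py)
  psum <- numeric(2 * ng); pdif <- numeric(ng)
  for (i in iv) for (j in iv) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  acc <- 0; cp <- 0; cs <- 0; ct <- 0; con <- 0; idf <- 0; idm <- 0
  idmn <- 0; idn <- 0; invv <- 0; je <- 0; corr_num <- 0
  for (i in iv) for (j in iv) {
    acc <- acc + i * j * p[i, j]
    dd <- i + j - mux - muy
    cp <- cp + dd^4 * p[i, j]
    cs <- cs + dd^3 * p[i, j]
    ct <- ct + dd^2 * p[i, j]
    con <- con + (i - j)^2 * p[i, j]
    idf <- idf + p[i, j] / (1 + abs(i - j))
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    idmn <- idmn + p[i, j] / (1 + ((i - j) / ng)^2)
    idn <- idn + p[i, j] / (1 + abs(i - j) / ng)
    if (i != j) invv <- invv + p[i, j] / (i - j)^2
    je <- je + p[i, j]^2
    corr_num <- corr_num + i * j * p[i, j]
  }
  da <- sum((0:(ng - 1)) * pdif)
  dv <- sum(((0:(ng - 1)) - da)^2 * pdif)
  hx <- oracle_entropy2(px); hy <- oracle_entropy2(py)
  hxy <- oracle_entropy2(as.vector(p))
  hxy1 <- 0; hxy2v <- numeric(0)
  for (i in iv) for (j in iv) {
    q <- px[i] * py[j]
    if (p[i, j] > 0 && q > 0) hxy1 <- hxy1 - p[i, j] * log2(q + 2.2e-16)
    hxy2v <- c(hxy2v, q)
  }
  hxy2 <- oracle_entropy2(hxy2v)
  corr <- if (sx2 > 0 && sy2 > 0) (corr_num - mux * muy) / sqrt(sx2 * sy2) else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  mcc <- if (ng > 1 && all(px > 0) && all(py > 0)) {
    Q <- matrix(0, ng, ng)
    for (i in iv) for (j in iv) {
      s <- 0
      for (k in iv) s <- s + p[i, k] * p[j, k] / (px[i] * py[k])
      Q[i, j] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  } else 1
  c(Autocorrelation = acc, ClusterProminence = cp, ClusterShade = cs,
    ClusterTendency = ct, Contrast = con, Correlation = corr,
    DifferenceAverage = da, DifferenceEntropy = oracle_entropy2(pdif),
    DifferenceVariance = dv, Id = idf, Idm = idm, Idmn = idmn, Idn = idn,
    Imc1 = imc1, Imc2 = imc2, InverseVariance = invv, JointAverage = mux,
    JointEnergy = je, JointEntropy = hxy, MaximumProbability = max(p),
    MCC = mcc,
    SumAverage = sum((2:(2 * ng)) * psum[2:(2 * ng)]),
    SumEntropy = oracle_entropy2(psum), SumSquares = sx2)
}

oracle_glcm_features <- function(lev) {
  dirs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  res <- NULL; ndir <- 0
  for (d in dirs) {
    P <- oracle_glcm_dir(lev, d[1], d[2])
    if (sum(P) == 0) next
    f <- oracle_glcm_features_one(P)
    res <- if (is.null(res)) f else res + f
    ndir <- ndir + 1
  }
  res / ndir
}

# ---- GLRLM -----------------------------------------------------------------
oracle_glrlm_matrix <- function(lev) {
  ng <- max(lev, na.rm = TRUE)
  nu <- nrow(lev); nv <- ncol(lev)
  R <- matrix(0, ng, max(nu, nv))
  dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))
  inb <- function(i, j) i >= 1 && i <= nu && j >= 1 && j <= nv
  for (d in dirs) {
    for (i in seq_len(nu)) for (j in seq_len(nv)) {
      if (is.na(lev[i, j])) next
      pi_ <- i - d[1]; pj <- j - d[2]
      # run starts here iff predecessor is absent or different
      if (inb(pi_, pj) && !is.na(lev[pi_, pj]) &&
          lev[pi_, pj] == lev[i, j]) next
      len <- 1
      ci <- i + d[1]; cj <- j + d[2]
      while (inb(ci, cj) && !is.na(lev[ci, cj]) &&
             lev[ci, cj] == lev[i, j]) {
        len <- len + 1; ci <- ci + d[1]; cj <- cj + d[2]
      }
      R[lev[i, j], len] <- R[lev[i, j], len] + 1
    }
  }
  R
}

oracle_rl_features <- function(M, npix) {
  ns <- sum(M)
  ng <- nrow(M); nl <- ncol(M)
  f <- numeric(16)
  mu_i <- 0; mu_j <- 0
  for (i in seq_len(ng)) for (j in seq_len(nl)) {
    mu_i <- mu_i + i * M[i, j] / ns
    mu_j <- mu_j + j * M[i, j] / ns
  }
  acc <- rep(0, 16)
  for (i in seq_len(ng)) for (j in seq_len(nl)) {
    m <- M[i, j]
    if (m == 0) next
    acc[1] <- acc[1] + m / j^2
    acc[2] <- acc[2] + m * j^2
    acc[8] <- acc[8] + m / ns * (i - mu_i)^2
    acc[9] <- acc[9] + m / ns * (j - mu_j)^2
    acc[10] <- acc[10] - m / ns * log2(m / ns)
    acc[11] <- acc[11] + m / i^2
    acc[12] <- acc[12] + m * i^2
    acc[13] <- acc[13] + m / (i^2 * j^2)
    acc[14] <- acc[14] + m * i^2 / j^2
    acc[15] <- acc[15] + m * j^2 / i^2
    acc[16] <- acc[16] + m * i^2 * j^2
  }
  gl <- rowSums(M); rl <- colSums(M)
  c(acc[1] / ns, acc[2] / ns, sum(gl^2) / ns, sum(gl^2) / ns^2,
    sum(rl^2) / ns, sum(rl^2) / ns^2, ns / npix, acc[8], acc[9], acc[10],
    acc[11] / ns, acc[12] / ns, acc[13] / ns, acc[14] / ns, acc[15] / ns,
    acc[16] / ns)
}

oracle_glrlm_features <- function(lev) {
  v <- oracle_rl_features(oracle_glrlm_matrix(lev), sum(!is.na(lev)))
  names(v) <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
                "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
                "RunLengthNonUniformityNormalized", "RunPercentage",
                "GrayLevelVariance", "RunVariance", "RunEntropy",
                "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
                "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
                "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  v
}

# ---- GLSZM -----------------------------------------------------------------
oracle_flood <- function(lev, i, j, visited) {
  # recursive 8-connected flood fill collecting the zone of lev[i, j]
  nu <- nrow(lev); nv <- ncol(lev)
  target <- lev[i, j]
  size <- 0
  grow <- function(i, j) {
    if (i < 1 || i > nu || j < 1 || j > nv) return()
    if (visited[i, j] || is.na(lev[i, j]) || lev[i, j] != target) return()
    visited[i, j] <<- TRUE
    size <<- size + 1
    for (di in -1:1) for (dj in -1:1)
      if (di != 0 || dj != 0) grow(i + di, j + dj)
  }
  grow(i, j)
  list(size = size, visited = visited)
}

oracle_glszm_matrix <- function(lev) {
  ng <- max(lev, na.rm = TRUE)
  visited <- matrix(FALSE, nrow(lev), ncol(lev))
  zones <- list()
  for (i in seq_len(nrow(lev))) for (j in seq_len(ncol(lev))) {
    if (is.na(lev[i, j]) || visited[i, j]) next
    fl <- oracle_flood(lev, i, j, visited)
    visited <- fl$visited
    zones[[length(zones) + 1]] <- c(lev[i, j], fl$size)
  }
  zs <- do.call(rbind, zones)
  S <- matrix(0, ng, max(zs[, 2]))
  for (k in seq_len(nrow(zs))) S[zs[k, 1], zs[k, 2]] <- S[zs[k, 1], zs[k, 2]] + 1
  S
}

oracle_glszm_features <- function(lev) {
  v <- oracle_rl_features(oracle_glszm_matrix(lev), sum(!is.na(lev)))
  names(v) <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
                "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
                "SmallAreaHighGrayLevelEmphasis",
                "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  v
}

# ---- GLDM ------------------------------------------------------------------
oracle_gldm_matrix <- function(lev, alpha = 0) {
  ng <- max(lev, na.rm = TRUE)
  nu <- nrow(lev); nv <- ncol(lev)
  deps <- c()
  gls <- c()
  for (i in seq_len(nu)) for (j in seq_len(nv)) {
    if (is.na(lev[i, j])) next
    d <- 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nu && jj >= 1 && jj <= nv &&
          !is.na(lev[ii, jj]) && abs(lev[ii, jj] - lev[i, j]) <= alpha)
        d <- d + 1
    }
    deps <- c(deps, d); gls <- c(gls, lev[i, j])
  }
  D <- matrix(0, ng, max(deps) + 1)
  for (k in seq_along(deps)) D[gls[k], deps[k] + 1] <- D[gls[k], deps[k] + 1] + 1
  D
}

oracle_gldm_features <- function(lev, alpha = 0) {
  v <- oracle_rl_features(oracle_gldm_matrix(lev, alpha), sum(!is.na(lev)))
  names(v) <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                "DependenceNonUniformity", "DependenceNonUniformityNormalized",
                "Percentage", "GrayLevelVariance", "DependenceVariance",
                "DependenceEntropy", "LowGrayLevelEmphasis",
                "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
                "SmallDependenceHighGrayLevelEmphasis",
                "LargeDependenceLowGrayLevelEmphasis",
                "LargeDependenceHighGrayLevelEmphasis")
  v[!names(v) %in% c("Percentage", "GrayLevelNonUniformityNormalized")]
}

# ---- NGTDM -----------------------------------------------------------------
oracle_ngtdm_features <- function(lev) {
  ng <- max(lev, na.rm = TRUE)
  nu <- nrow(lev); nv <- ncol(lev)
  s <- rep(0, ng); n_i <- rep(0, ng)
  Nvp <- 0
  for (i in seq_len(nu)) for (j in seq_len(nv)) {
    if (is.na(lev[i, j])) next
    nb <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nu && jj >= 1 && jj <= nv && !is.na(lev[ii, jj]))
        nb <- c(nb, lev[ii, jj])
    }
    if (!length(nb)) next
    Nvp <- Nvp + 1
    n_i[lev[i, j]] <- n_i[lev[i, j]] + 1
    s[lev[i, j]] <- s[lev[i, j]] + abs(lev[i, j] - mean(nb))
  }
  p <- n_i / Nvp
  pres <- which(n_i > 0)
  Ngp <- length(pres)
  den <- sum(p * s)
  coarseness <- if (den > 0) 1 / den else 1e6
  contrast <- 0
  if (Ngp > 1) {
    acc <- 0
    for (a in pres) for (b in pres) acc <- acc + p[a] * p[b] * (a - b)^2
    contrast <- acc / (Ngp * (Ngp - 1)) * sum(s) / Nvp
  }
  bden <- 0
  for (a in pres) for (b in pres) bden <- bden + abs(a * p[a] - b * p[b])
  busyness <- if (bden > 0) den / bden else 0
  complexity <- 0
  if (Ngp > 1) {
    acc <- 0
    for (a in pres) for (b in pres) {
      if (a == b) next
      acc <- acc + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    }
    complexity <- acc / Nvp
  }
  strength <- 0
  if (sum(s) > 0 && Ngp > 1) {
    acc <- 0
    for (a in pres) for (b in pres)
      if (a != b) acc <- acc + (p[a] + p[b]) * (a - b)^2
    strength <- acc / sum(s)
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

# ---- first order -----------------------------------------------------------
oracle_first_order <- function(x, lev_roi, n_levels, spacing = 1) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  qs <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  inr <- x[x >= qs[1] & x <= qs[5]]
  p <- rep(0, n_levels)
  for (l in lev_roi) p[l] <- p[l] + 1 / n
  pp <- p[p > 0]
  c(Energy = sum(x^2), TotalEnergy = sum(x^2) * spacing^2,
    Entropy = -sum(pp * log2(pp)), Minimum = min(x), Percentile10 = qs[1],
    Percentile90 = qs[5], Maximum = max(x), Mean = m, Median = qs[3],
    InterquartileRange = qs[4] - qs[2], Range = max(x) - min(x),
    MeanAbsoluteDeviation = sum(abs(x - m)) / n,
    RobustMeanAbsoluteDeviation = sum(abs(inr - mean(inr))) / length(inr),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (m2 > 0) (sum((x - m)^3) / n) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) (sum((x - m)^4) / n) / m2^2 else 0,
    Variance = m2, Uniformity = sum(pp^2))
}

# random small discretized map (levels 1..max_levels, every pixel in ROI
# except a random corner notch to exercise masking)
random_level_map <- function(n = 8, max_levels = 5, with_na = TRUE) {
  lev <- matrix(sample.int(max_levels, n * n, replace = TRUE), n, n)
  if (with_na && n > 3) {
    k <- sample(0:3, 1)
    if (k > 0) lev[seq_len(k), 1] <- NA
  }
  lev
}

as_discretized <- function(lev) {
  structure(list(levels = lev, n_levels = max(lev, na.rm = TRUE),
                 bin_width = 1, mask = !is.na(lev), spacing = 1),
            class = "discretized_map")
}

# simple plane_sample constructor for map unit tests
make_sample <- function(vx, vy, vz, normal = c(0, 0, 1), spacing = 1) {
  structure(list(vx = vx, vy = vy, vz = vz,
                 valid = matrix(TRUE, nrow(vx), ncol(vx)),
                 spacing = spacing, normal = normal,
                 e1 = c(1, 0, 0), e2 = c(0, 1, 0),
                 origin = c(0, 0, 0), label = "test", timeframe = 1L),
            class = "plane_sample")
}
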