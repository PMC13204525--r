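# IBSI-style feature bank: derived images, discretization, and the six
# feature classes computed from texture matrices accumulated in C++.
# Texture matrices are direction-merged (summed over the direction set, then
# normalized) before features are computed.

dirs3d <- function() {
  d <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  # keep one of each +/- pair: lexicographically positive on (z, y, x)
  keep <- d[, 3] > 0 | (d[, 3] == 0 & d[, 2] > 0) |
    (d[, 3] == 0 & d[, 2] == 0 & d[, 1] > 0)
  unname(d[keep, , drop = FALSE])
}

dirs2d <- function() {
  rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L), c(1L, -1L, 0L))
}

offsets_all <- function(two_d = FALSE) {
  zr <- if (two_d) 0L else -1:1
  d <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = zr))
  unname(d[rowSums(abs(d)) > 0, , drop = FALSE])
}

# Fixed-bin-count discretization inside the region; outside voxels are 0.
discretize_region <- function(arr, mask, nbins) {
  v <- arr[mask]
  lo <- min(v); hi <- max(v)
  out <- array(0L, dim(arr))
  if (hi - lo <= 0) {
    out[mask] <- 1L
  } else {
    w <- (hi - lo) / nbins
    out[mask] <- pmin(as.integer(floor((v - lo) / w)) + 1L, nbins)
  }
  out
}

first_order_features <- function(x, nbins, voxel_volume, include_sd = FALSE) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  s <- sort(x)
  q7 <- function(p) { # quantile type 7 from the single sorted copy
    h <- (n - 1) * p; lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[min(lo + 2, n)] - s[lo + 1])
  }
  qs <- c(q7(0.1), q7(0.25), q7(0.75), q7(0.9))
  # discretized probabilities for entropy / uniformity
  rng <- diff(range(x))
  if (rng <= 0) p <- 1 else {
    b <- pmin(floor((x - min(x)) / (rng / nbins)) + 1, nbins)
    p <- tabulate(b, nbins) / n
    p <- p[p > 0]
  }
  mid <- x[x >= qs[1] & x <= qs[4]]
  out <- c(
    Energy = sum(x^2),
    TotalEnergy = voxel_volume * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = s[1],
    Percentile10 = qs[1],
    Percentile90 = qs[4],
    Maximum = s[n],
    Mean = mu,
    Median = q7(0.5),
    InterquartileRange = qs[3] - qs[2],
    Range = rng,
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(mid) > 0) mean(abs(mid - mean(mid))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
  if (include_sd) out <- c(out, StandardDeviation = sqrt(m2))
  out
}

glcm_features <- function(P) {
  # P: direction-merged symmetric co-occurrence counts (nbins x nbins)
  tot <- sum(P)
  ng <- nrow(P)
  if (tot <= 0) return(setNames(rep(0, 24), names(glcm_feature_names())))
  P <- P / tot
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mux <- sum(seq_len(ng) * px)
  sx2 <- sum((seq_len(ng) - mux)^2 * px)
  nz <- P > 0
  ent <- -sum(P[nz] * log2(P[nz]))
  # diagonal / cross sums
  kd <- abs(i - j)
  pd <- as.vector(rowsum(as.vector(P), as.vector(kd))) # |i-j| = 0..ng-1
  kdv <- 0:(ng - 1)
  ks <- i + j
  ps <- as.vector(rowsum(as.vector(P), as.vector(ks)))
  ksv <- 2:(2 * ng)
  da <- sum(kdv * pd)
  hx <- { q <- px[px > 0]; -sum(q * log2(q)) }
  pxy <- outer(px, px)
  ok <- nz & pxy > 0
  hxy1 <- -sum(P[ok] * log2(pxy[ok]))
  hxy2 <- { q <- pxy[pxy > 0]; -sum(q * log2(q)) }
  imc1 <- if (hx > 0) (ent - hxy1) / hx else 0
  imc2 <- { d <- 1 - exp(-2 * (hxy2 - ent)); if (d > 0) sqrt(d) else 0 }
  corr <- if (sx2 > 1e-12) (sum(i * j * P) - mux^2) / sx2 else 1
  mcc <- {
    keep <- px > 0
    if (sum(keep) < 2) 1 else {
      Ps <- P[keep, keep, drop = FALSE]
      pxs <- px[keep]
      # Q(i,j) = sum_k P(i,k) P(j,k) / (px_i px_k)
      Q <- sweep(Ps, 1, pxs, "/") %*% t(sweep(Ps, 2, pxs, "/"))
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      if (length(ev) > 1 && ev[2] > 0) sqrt(ev[2]) else 0
    }
  }
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - 2 * mux)^4 * P),
    ClusterShade = sum((i + j - 2 * mux)^3 * P),
    ClusterTendency = sum((i + j - 2 * mux)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = { q <- pd[pd > 0]; -sum(q * log2(q)) },
    DifferenceVariance = sum((kdv - da)^2 * pd),
    JointEnergy = sum(P^2),
    JointEntropy = ent,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = sum(P[i != j] / (i - j)[i != j]^2),
    MaximumProbability = max(P),
    SumAverage = sum(ksv * ps),
    SumEntropy = { q <- ps[ps > 0]; -sum(q * log2(q)) },
    SumSquares = sx2,
    MCC = mcc)
}

glcm_feature_names <- function() {
  c("Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
    "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
    "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares", "MCC")
}

glrlm_features <- function(R, n_voxels) {
  # R: direction-merged run-length counts (nbins x maxlen)
  nr <- sum(R)
  ng <- nrow(R)
  if (nr <= 0) return(setNames(rep(0, 16), c(
    "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
    "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
    "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
    "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LongRunHighGrayLevelEmphasis")))
  i <- row(R); l <- col(R)
  p <- R / nr
  ri <- rowSums(R); rl <- colSums(R)
  mug <- sum(row(p) * p); mul <- sum(col(p) * p)
  nzp <- p[p > 0]
  c(ShortRunEmphasis = sum(R / l^2) / nr,
    LongRunEmphasis = sum(R * l^2) / nr,
    GrayLevelNonUniformity = sum(ri^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    RunLengthNonUniformity = sum(rl^2) / nr,
    RunLengthNonUniformityNormalized = sum(rl^2) / nr^2,
    RunPercentage = nr / n_voxels,
    GrayLevelVariance = sum((i - mug)^2 * p),
    RunVariance = sum((l - mul)^2 * p),
    RunEntropy = -sum(nzp * log2(nzp)),
    LowGrayLevelRunEmphasis = sum(R / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(R * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(R / (i^2 * l^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(R * i^2 / l^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(R * l^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(R * i^2 * l^2) / nr)
}

glszm_features <- function(zones, n_voxels) {
  # zones: matrix (gray level, zone size), one row per connected zone
  nz <- nrow(zones)
  nms <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
           "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
           "SizeZoneNonUniformityNormalized", "ZonePercentage",
           "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
           "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
           "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
           "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  if (nz == 0) return(setNames(rep(0, 16), nms))
  g <- zones[, 1]; s <- zones[, 2]
  cnt_g <- tabulate(g); cnt_s <- tabulate(s)
  mug <- mean(g); mus <- mean(s)
  # zone-probability entropy over the (g, s) cells
  key <- g * (max(s) + 1) + s
  cell <- tabulate(match(key, unique(key))) / nz
  setNames(c(
    mean(1 / s^2), mean(s^2),
    sum(cnt_g^2) / nz, sum(cnt_g^2) / nz^2,
    sum(cnt_s^2) / nz, sum(cnt_s^2) / nz^2,
    nz / n_voxels,
    mean((g - mug)^2), mean((s - mus)^2),
    -sum(cell * log2(cell)),
    mean(1 / g^2), mean(g^2),
    mean(1 / (g^2 * s^2)), mean(g^2 / s^2),
    mean(s^2 / g^2), mean(g^2 * s^2)), nms)
}

gldm_features <- function(D, n_voxels) {
  # D: counts (nbins x ndep+1); column j+1 holds dependence count j.
  # Dependence size is taken as j + 1 (center voxel included) so it is >= 1.
  nd <- sum(D)
  nms <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
           "GrayLevelNonUniformity", "DependenceNonUniformity",
           "DependenceNonUniformityNormalized", "GrayLevelVariance",
           "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
           "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
           "SmallDependenceHighGrayLevelEmphasis",
           "LargeDependenceLowGrayLevelEmphasis",
           "LargeDependenceHighGrayLevelEmphasis")
  if (nd <= 0) return(setNames(rep(0, 14), nms))
  i <- row(D); j <- col(D) # dependence size = j
  p <- D / nd
  ri <- rowSums(D); rj <- colSums(D)
  mug <- sum(i * p); muj <- sum(j * p)
  nzp <- p[p > 0]
  setNames(c(
    sum(D / j^2) / nd, sum(D * j^2) / nd,
    sum(ri^2) / nd, sum(rj^2) / nd, sum(rj^2) / nd^2,
    sum((i - mug)^2 * p), sum((j - muj)^2 * p),
    -sum(nzp * log2(nzp)),
    sum(D / i^2) / nd, sum(D * i^2) / nd,
    sum(D / (i^2 * j^2)) / nd, sum(D * i^2 / j^2) / nd,
    sum(D * j^2 / i^2) / nd, sum(D * i^2 * j^2) / nd), nms)
}

ngtdm_features <- function(M, n_voxels) {
  # M: (nbins x 2), column 1 = n_i, column 2 = s_i
  nms <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  n_i <- M[, 1]; s_i <- M[, 2]
  N <- sum(n_i)
  if (N <= 0) return(setNames(rep(0, 5), nms))
  p_i <- n_i / N
  act <- which(p_i > 0)
  ngp <- length(act)
  iv <- seq_len(nrow(M))
  denom_coarse <- sum(p_i * s_i)
  coarse <- if (denom_coarse > 0) 1 / denom_coarse else 1e6
  contrast <- if (ngp > 1) {
    s1 <- sum(outer(p_i[act], p_i[act]) * outer(iv[act], iv[act], `-`)^2) /
      (ngp * (ngp - 1))
    s1 * sum(s_i) / N
  } else 0
  denom_busy <- sum(abs(outer(iv[act] * p_i[act], iv[act] * p_i[act], `-`)))
  busy <- if (denom_busy > 0) denom_coarse / denom_busy else 0
  cmplx <- if (ngp > 0) {
    pa <- p_i[act]; ia <- iv[act]; sa <- s_i[act]
    num <- abs(outer(ia, ia, `-`)) *
      (outer(pa * sa, pa * sa, `+`) / outer(pa, pa, `+`))
    sum(num) / N # all ordered pairs
  } else 0
  strength <- if (sum(s_i) > 0 && ngp > 1) {
    pa <- p_i[act]; ia <- iv[act]
    sum(outer(pa, pa, `+`) * outer(ia, ia, `-`)^2) / sum(s_i)
  } else 0
  setNames(c(coarse, contrast, busy, cmplx, strength), nms)
}

shape3d_features <- function(mask_arr, spacing) {
  nv <- sum(mask_arr)
  voxvol <- prod(spacing)
  vol <- nv * voxvol
  sa <- cpp_surface_area(as.integer(mask_arr), dim(mask_arr), spacing)
  idx <- which(mask_arr > 0, arr.ind = TRUE)
  pts <- sweep(idx, 2, spacing, `*`)
  if (nv > 2) {
    ev <- sort(eigen(stats::cov(pts), only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  # boundary voxels for diameters (any 6-neighbor outside), via array shifts
  dm <- dim(mask_arr)
  pad <- array(0L, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- mask_arr
  interior <- pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
  on_border <- !interior[idx]
  bpts <- pts[on_border, , drop = FALSE]
  if (nrow(bpts) > 1000L) # deterministic thinning keeps diameters near-exact
    bpts <- bpts[seq(1L, nrow(bpts), length.out = 1000L), , drop = FALSE]
  dia <- cpp_max_diameters(bpts)
  c(original_shape_MeshVolume = vol,
    original_shape_VoxelVolume = vol,
    original_shape_SurfaceArea = sa,
    original_shape_SurfaceVolumeRatio = sa / vol,
    original_shape_Sphericity = (36 * pi * vol^2)^(1 / 3) / sa,
    original_shape_Maximum3DDiameter = dia[1],
    original_shape_Maximum2DDiameterSlice = dia[2],
    original_shape_Maximum2DDiameterColumn = dia[3],
    original_shape_Maximum2DDiameterRow = dia[4],
    original_shape_MajorAxisLength = axes[1],
    original_shape_MinorAxisLength = axes[2],
    original_shape_LeastAxisLength = axes[3],
    original_shape_Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    original_shape_Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}

shape2d_features <- function(mask2d, spacing2) {
  nms <- c("MeshSurface", "PixelSurface", "Perimeter", "PerimeterSurfaceRatio",
           "Sphericity", "SphericalDisproportion", "MaximumDiameter",
           "MajorAxisLength", "MinorAxisLength", "Elongation")
  np <- sum(mask2d)
  pa <- prod(spacing2)
  area <- np * pa
  m3 <- array(as.integer(mask2d), c(dim(mask2d), 1L))
  per <- cpp_surface_area(as.integer(m3), dim(m3), c(spacing2, 1)) -
    2 * area # exposed faces minus top/bottom leaves the in-plane perimeter
  idx <- which(mask2d > 0, arr.ind = TRUE)
  pts <- sweep(idx, 2, spacing2, `*`)
  if (np > 2) {
    ev <- sort(eigen(stats::cov(pts), only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0)
  dia <- cpp_max_diameters(cbind(pts, 0))[1]
  sph <- if (per > 0) 2 * sqrt(pi * area) / per else 0
  setNames(c(area, area, per, per / area, sph,
             if (sph > 0) 1 / sph else 0, dia,
             4 * sqrt(ev[1]), 4 * sqrt(ev[2]),
             if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0), nms)
}

# Wavelet sub-band (undecimated single-level, averaging low-pass (1,1)/2 and
# detail high-pass (1,-1)/2 taps, half-sample symmetric boundary).
wavelet_axis <- function(arr, ax, high) {
  dm <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(arr, perm), nrow = dm[ax])
  nxt <- reflect_index(seq_len(dm[ax]) + 1L, dm[ax])
  out <- if (high) (m - m[nxt, , drop = FALSE]) / 2 else
    (m + m[nxt, , drop = FALSE]) / 2
  aperm(array(out, dm[perm]), order(perm))
}

#' Extraction profile for the radiomic feature bank
#'
#' Pins the image bank to reproduce the per-region feature count 1688:
#' the original image carries 14 shape descriptors plus 93
#' intensity/texture features (18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM,
#' 14 GLDM, 5 NGTDM), and 17 derived images (8 single-level wavelet
#' sub-bands, Laplacian-of-Gaussian at 5 scales, square, square root,
#' logarithm, exponential) carry the 93 intensity/texture features each:
#' 107 + 17 x 93 = 1688. Discretization uses a fixed bin count inside each
#' region, which makes texture features invariant to adding a constant to
#' the image.
#'
#' @param nbins fixed discretization bin count.
#' @param log_sigmas Laplacian-of-Gaussian scales in mm.
#' @return An `extraction_profile` list.
#' @export
extraction_profile <- function(nbins = 32L, log_sigmas = 1:5) {
  structure(list(nbins = as.integer(nbins), log_sigmas = log_sigmas),
            class = "extraction_profile")
}

derived_images <- function(arr, spacing, profile) {
  out <- list(original = arr)
  combos <- expand.grid(a1 = c("L", "H"), a2 = c("L", "H"), a3 = c("L", "H"))
  for (r in seq_len(nrow(combos))) {
    img <- arr
    for (ax in 1:3)
      img <- wavelet_axis(img, ax, combos[r, ax] == "H")
    out[[paste0("wavelet.", paste0(combos[r, 3], combos[r, 2], combos[r, 1]))]] <- img
  }
  for (s in profile$log_sigmas) {
    sm <- gauss_smooth3(arr, s / spacing)
    lap <- array(0, dim(arr))
    dm <- dim(arr)
    for (ax in 1:3) {
      up <- reflect_index(seq_len(dm[ax]) + 1L, dm[ax])
      dn <- reflect_index(seq_len(dm[ax]) - 1L, dm[ax])
      perm <- c(ax, setdiff(1:3, ax))
      m <- matrix(aperm(sm, perm), nrow = dm[ax])
      d2 <- (m[up, , drop = FALSE] + m[dn, , drop = FALSE] - 2 * m) /
        spacing[ax]^2
      lap <- lap + aperm(array(d2, dm[perm]), order(perm))
    }
    out[[sprintf("log.sigma.%g.mm", s)]] <- lap * s^2
  }
  mx <- max(abs(arr))
  sc <- if (mx > 0) 1 / mx else 1
  out[["square"]] <- (arr * sc)^2
  out[["squareroot"]] <- sign(arr) * sqrt(abs(arr * sc))
  out[["logarithm"]] <- sign(arr) * log1p(abs(arr * sc))
  out[["exponential"]] <- exp(arr * sc)
  out
}

# cached prefixed name vectors for the 93 (3D) / 94 (2D) texture features
texture_name_cache <- local({
  cache <- list()
  function(two_d) {
    key <- if (two_d) "2d" else "3d"
    if (is.null(cache[[key]])) {
      nm <- c(paste0("firstorder_", names(first_order_features(1:4, 8, 1, two_d))),
              paste0("glcm_", glcm_feature_names()),
              paste0("glrlm_", names(glrlm_features(matrix(1, 1, 1), 1))),
              paste0("glszm_", names(glszm_features(matrix(numeric(0), 0, 2), 1))),
              paste0("gldm_", names(gldm_features(matrix(0, 1, 1), 1))),
              paste0("ngtdm_", names(ngtdm_features(matrix(0, 1, 2), 1))))
      cache[[key]] <<- nm
    }
    cache[[key]]
  }
})

# The 93 intensity/texture features of one image restricted to one region.
texture_features_region <- function(img, mask_arr, profile, two_d = FALSE) {
  nvox <- sum(mask_arr)
  bins <- discretize_region(img, mask_arr > 0, profile$nbins)
  dm <- dim(img)
  dirs <- if (two_d) dirs2d() else dirs3d()
  offs <- offsets_all(two_d)
  ib <- as.integer(bins)
  tm <- cpp_texture_all(ib, dm, profile$nbins, dirs, offs, 0L)
  out <- c(first_order_features(img[mask_arr > 0], profile$nbins, 1,
                                include_sd = two_d),
           glcm_features(tm$glcm),
           glrlm_features(tm$glrlm, nvox * nrow(dirs)),
           glszm_features(tm$glszm, nvox),
           gldm_features(tm$gldm, nvox),
           ngtdm_features(tm$ngtdm, nvox))
  names(out) <- texture_name_cache(two_d)
  out
}
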