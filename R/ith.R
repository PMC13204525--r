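#' Select the maximum-area tumor slice
#'
#' Returns the axial (third-axis) slice with the largest in-mask pixel
#' count; ties break to the lowest index. Depends only on the mask.
#'
#' @param volume a [pet_volume].
#' @param mask a non-empty [roi_mask].
#' @return list: `image` (2D matrix), `mask` (2D), `slice` (1-based index),
#'   `spacing` (in-plane).
#' @export
select_max_slice <- function(volume, mask) {
  check_geometry(volume, mask)
  if (sum(mask$data) == 0L) stop("empty mask")
  areas <- apply(mask$data, 3, sum)
  s <- which.max(areas) # first maximum = lowest index on ties
  list(image = volume$data[, , s], mask = mask$data[, , s], slice = s,
       spacing = volume$spacing[1:2])
}

#' Per-pixel radiomic features on a tumor slice
#'
#' For every in-mask pixel, computes 104 descriptors of its 3 x 3
#' neighborhood intersected with the mask: 19 first-order, 24 GLCM, 16
#' GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM (4-direction / 8-connectivity 2D
#' variants with fixed-bin-count window discretization) and 10 2D shape
#' descriptors of the window's in-mask geometry. The default engine is a
#' single-pass C++ implementation; `engine = "r"` computes the same values
#' through the package's R feature functions and serves as the reference in
#' equivalence tests.
#'
#' @param image 2D numeric matrix.
#' @param mask 2D binary matrix (>= 9 in-mask pixels).
#' @param nbins window discretization bin count (<= 8).
#' @param spacing in-plane pixel size (mm).
#' @param engine `"cpp"` or `"r"`.
#' @return A `pixel_feature_map`: `features` (pixels x 104), `coords`
#'   (pixel grid indices), `mask`, `spacing`.
#' @export
pixel_features <- function(image, mask, nbins = 8L, spacing = c(1, 1),
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  mask <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  if (sum(mask) < 9L) stop("mask too small: need >= 9 pixels")
  if (nbins > 8L) stop("nbins must be <= 8 for the per-pixel profile")
  coords <- which(mask > 0, arr.ind = TRUE)
  # order pixels row-fastest to match the C++ scan
  coords <- coords[order(coords[, 2], coords[, 1]), , drop = FALSE]
  if (engine == "cpp") {
    f <- cpp_pixel_features(as.numeric(image), as.integer(mask),
                            c(dim(image), 1L), nbins, spacing)
  } else {
    prof <- extraction_profile(nbins = nbins)
    f <- t(apply(coords, 1, function(rc) {
      xs <- max(1, rc[1] - 1):min(nrow(mask), rc[1] + 1)
      ys <- max(1, rc[2] - 1):min(ncol(mask), rc[2] + 1)
      wm <- mask[xs, ys, drop = FALSE]
      wi <- image[xs, ys, drop = FALSE]
      wi[wm == 0] <- 0
      tex <- texture_features_region(array(wi, c(dim(wi), 1L)),
                                     array(wm, c(dim(wm), 1L)),
                                     prof, two_d = TRUE)
      c(tex, setNames(shape2d_features(wm, spacing),
                      paste0("shape2d_", names(shape2d_features(wm, spacing)))))
    }))
  }
  colnames(f) <- pixel_feature_names()
  structure(list(features = f, coords = coords, mask = mask,
                 spacing = spacing), class = "pixel_feature_map")
}

pixel_feature_names <- function() {
  fo <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10",
          "Percentile90", "Maximum", "Mean", "Median", "InterquartileRange",
          "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
          "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity",
          "StandardDeviation")
  c(paste0("firstorder_", fo),
    paste0("glcm_", glcm_feature_names()),
    paste0("glrlm_", names(glrlm_features(matrix(1, 1, 1), 1))),
    paste0("glszm_", names(glszm_features(matrix(numeric(0), 0, 2), 1))),
    paste0("gldm_", names(gldm_features(matrix(0, 1, 1), 1))),
    paste0("ngtdm_", names(ngtdm_features(matrix(0, 1, 2), 1))),
    paste0("shape2d_", names(shape2d_features(matrix(1, 2, 2), c(1, 1)))))
}

silhouette_mean <- function(X, labels) {
  n <- nrow(X)
  if (length(unique(labels)) < 2L) return(NA_real_)
  D <- as.matrix(stats::dist(X))
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) sum(D[i, own]) / (sum(own) - 1L) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), 0))
    sil[i] <- if (sum(own) > 1L) (b - a) / max(a, b) else 0
  }
  mean(sil)
}

#' Cluster pixel feature vectors
#'
#' K-means on z-scored per-pixel features; `k` is chosen from 2..5 by mean
#' silhouette (on a deterministic subsample of at most 400 pixels when the
#' slice is large) unless fixed.
#'
#' @param pfm a [pixel_features] result.
#' @param k fixed cluster count, or `NULL` to select by silhouette.
#' @param seed integer seed (k-means restarts).
#' @return list: `label_map` (2D matrix, 0 background), `k`, `silhouette`,
#'   `labels` per pixel.
#' @export
cluster_pixels <- function(pfm, k = NULL, seed = 1L) {
  X <- pfm$features
  np <- nrow(X)
  keep <- apply(X, 2, sd) > 0
  Xz <- scale(X[, keep, drop = FALSE])
  kmax <- min(5L, np)
  if (!is.null(k) && k > np) stop("fewer pixels than k")
  set.seed(derive_seed(seed, "ithkmeans"))
  sub <- if (np > 400L) round(seq(1L, np, length.out = 400L)) else seq_len(np)
  run_k <- function(kk) {
    if (kk >= np) {
      list(cluster = seq_len(np), sil = NA_real_)
    } else {
      km <- kmeans(Xz, centers = kk, nstart = 10L, iter.max = 100L)
      list(cluster = km$cluster,
           sil = silhouette_mean(Xz[sub, , drop = FALSE], km$cluster[sub]))
    }
  }
  if (is.null(k)) {
    cand <- 2:kmax
    fits <- lapply(cand, run_k)
    sils <- vapply(fits, `[[`, 0, "sil")
    best <- which.max(sils)
    k <- cand[best]; fit <- fits[[best]]
  } else {
    fit <- run_k(k)
  }
  lm <- matrix(0L, nrow(pfm$mask), ncol(pfm$mask))
  lm[pfm$coords] <- fit$cluster
  list(label_map = lm, k = k, silhouette = fit$sil, labels = fit$cluster)
}

offsets_2d_4conn <- function() {
  rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L), c(0L, -1L, 0L))
}

#' Intratumoral heterogeneity score of a cluster label map
#'
#' For each cluster i with area fraction p_i (over in-mask pixels), let f_i
#' be the fraction of the cluster's area held by its largest 4-connected
#' component. The score is `1 - sum_i p_i * f_i`: it is 0 exactly when every
#' cluster is a single connected component and grows as clusters fragment
#' into spatially scattered pieces, combining cluster area, connectivity and
#' spatial distribution into one scalar in [0, 1).
#'
#' @param label_map 2D integer matrix of cluster ids (0 = background).
#' @return Numeric score in `[0, 1)`.
#' @export
ith_score <- function(label_map) {
  ids <- setdiff(unique(as.vector(label_map)), 0L)
  if (length(ids) == 0L) stop("empty label map")
  total <- sum(label_map > 0L)
  arr <- array(as.integer(label_map), c(dim(label_map), 1L))
  comp <- cpp_label_components(as.integer(arr), dim(arr), offsets_2d_4conn())
  score <- 0
  for (i in ids) {
    in_cl <- label_map == i
    area <- sum(in_cl)
    largest <- max(tabulate(comp[in_cl]))
    score <- score + (area / total) * (largest / area)
  }
  1 - score
}

#' Compute the ITH score for one case
#'
#' Full single-slice pipeline: maximum-area slice, per-pixel features,
#' k-means clustering, fragmentation score.
#'
#' @param volume a [pet_volume].
#' @param mask a non-empty [roi_mask].
#' @param k fixed cluster count or `NULL` (silhouette selection).
#' @param nbins window discretization bins.
#' @param seed integer seed.
#' @return list: `score`, `k`, `slice`, `label_map`, `silhouette`.
#' @export
compute_ith <- function(volume, mask, k = NULL, nbins = 8L, seed = 1L) {
  sl <- select_max_slice(volume, mask)
  pfm <- pixel_features(sl$image, sl$mask, nbins = nbins, spacing = sl$spacing)
  cl <- cluster_pixels(pfm, k = k, seed = seed)
  list(score = ith_score(cl$label_map), k = cl$k, slice = sl$slice,
       label_map = cl$label_map, silhouette = cl$silhouette)
}

#' Univariate logistic model on the ITH score
#'
#' @param scores numeric ITH scores.
#' @param labels binary outcome.
#' @return list: `model` (glm), `auc`, `p` (two-sided Mann-Whitney),
#'   `coefficients`.
#' @export
fit_ith_model <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes required")
  if (sd(scores) == 0) stop("constant scores")
  fit <- suppressWarnings(glm(labels ~ scores, family = binomial()))
  p <- suppressWarnings(wilcox.test(scores[labels == 1], scores[labels == 0],
                                    exact = FALSE)$p.value)
  list(model = fit, auc = auc_rank(scores, labels), p = p,
       coefficients = coef(fit))
}
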