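#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with a normalized kernel and half-sample
#' symmetric (reflective) boundaries, so the grid mean is preserved exactly
#' and `sigma = 0` is the identity. `sigma` is given in mm and converted to
#' voxels per axis through the volume spacing.
#'
#' @param volume a [pet_volume].
#' @param sigma non-negative smoothing scale in mm.
#' @return A smoothed [pet_volume].
#' @export
smooth_volume <- function(volume, sigma = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(volume)
  out <- gauss_smooth3(volume$data, sigma / volume$spacing)
  pet_volume(out, volume$spacing, volume$origin)
}

# Exact 1-D 2-means: over the sorted in-mask intensities, two-means is a
# threshold rule, so the global optimum is found by scanning all n-1 cuts
# for minimal within-cluster sum of squares (vectorized with prefix sums).
split_1d_2means <- function(x) {
  n <- length(x)
  o <- order(x)
  s <- x[o]
  cs <- cumsum(s); cs2 <- cumsum(s^2)
  k <- seq_len(n - 1)
  sse_lo <- cs2[k] - cs[k]^2 / k
  sse_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  tot <- sse_lo + sse_hi
  kbest <- which.min(tot)
  assign <- integer(n)
  assign[o] <- c(rep(1L, kbest), rep(2L, n - kbest)) # 1 = low, 2 = high
  list(assign = assign, cut = (s[kbest] + s[kbest + 1]) / 2,
       sse = tot[kbest],
       centers = c(cs[kbest] / kbest, (cs[n] - cs[kbest]) / (n - kbest)))
}

#' Segment a tumor ROI into two metabolic habitats
#'
#' In-mask intensities are smoothed and clustered into `k = 2` groups by
#' one-dimensional k-means on intensity only. Because 1-D 2-means reduces to
#' an optimal threshold, the partition is found exactly by scanning all cuts
#' — there is no initialization sensitivity. The cluster with the higher
#' centroid is the high-uptake habitat (label 2), the other the low-uptake
#' habitat (label 1); background stays 0. A mean silhouette over the in-mask
#' assignment is reported as a quality diagnostic. If the intensity spread is
#' below `tol`, or either cluster would be smaller than `min_size`, the map
#' is flagged degenerate and the whole ROI is treated as high-uptake.
#'
#' @param volume a [pet_volume].
#' @param mask a non-empty [roi_mask] on the same grid.
#' @param sigma Gaussian pre-smoothing scale in mm (see [smooth_volume]).
#' @param min_size minimum habitat size in voxels.
#' @param tol minimal in-mask intensity spread treated as clusterable.
#' @param seed kept for interface symmetry; the exact scan is deterministic.
#' @return A `habitat_map`: `labels` (3D array, 0/1/2), `silhouette`,
#'   `degenerate` flag, cluster `centers` and the threshold `cut`.
#' @export
segment_habitats <- function(volume, mask, sigma = 1, min_size = 8L,
                             tol = 1e-8, seed = 1L) {
  check_geometry(volume, mask)
  nfg <- sum(mask$data)
  if (nfg == 0L) stop("empty ROI")
  if (nfg < 4L) stop("ROI must contain at least 2k voxels")
  sm <- smooth_volume(volume, sigma)
  fg <- mask$data > 0
  x <- sm$data[fg]
  labels <- array(0L, dim(mask$data))
  degenerate <- FALSE
  sil <- NA_real_
  cut <- NA_real_
  centers <- c(NA_real_, NA_real_)
  if (diff(range(x)) < tol) {
    degenerate <- TRUE
    labels[fg] <- 2L
    warning("constant-intensity ROI: degenerate habitat map (all high-uptake)")
  } else {
    fit <- split_1d_2means(x)
    sizes <- tabulate(fit$assign, 2L)
    if (min(sizes) < min_size) {
      degenerate <- TRUE
      labels[fg] <- 2L
      warning("habitat smaller than min_size: degenerate habitat map")
    } else {
      labels[fg] <- fit$assign
      sil <- silhouette_1d(x, fit$assign)
      cut <- fit$cut
      centers <- fit$centers
    }
  }
  structure(list(labels = labels, silhouette = sil, degenerate = degenerate,
                 centers = centers, cut = cut,
                 spacing = volume$spacing, origin = volume$origin),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat("<habitat_map> low:", sum(x$labels == 1L), "high:", sum(x$labels == 2L),
      if (x$degenerate) "(degenerate)" else
        sprintf("silhouette %.3f", x$silhouette), "\n")
  invisible(x)
}

#' Write a habitat label map as NIfTI
#'
#' Coding: 0 background, 1 low-uptake, 2 high-uptake.
#'
#' @param habitat a [segment_habitats] result.
#' @param path output path.
#' @export
write_habitat_map <- function(habitat, path) {
  img <- RNifti::asNifti(habitat$labels)
  RNifti::pixdim(img) <- habitat$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
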