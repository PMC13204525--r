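#' @useDynLib dpetfusion, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom quantile median sd var cor predict
#'   binomial glm glm.fit plogis qnorm pnorm dist wilcox.test kmeans setNames
#'   coef
#' @importFrom graphics hist
#' @importFrom utils read.csv write.csv head
NULL

#' Construct a PET-like volume
#'
#' A volume is a 3D scalar grid of SUV-like intensities together with its
#' voxel spacing and physical origin (mm). Intensities must be finite and
#' spacing strictly positive.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, per-axis voxel size in mm.
#' @param origin numeric length-3, physical offset in mm.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "pet_volume")
}

#' Construct a binary ROI mask
#'
#' Any value greater than zero is foreground; the mask must share the grid
#' geometry of its paired volume.
#'
#' @param data 3D array; binarized at `> 0`.
#' @inheritParams pet_volume
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array")
  data <- array(as.integer(data > 0), dim = dim(data))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "roi_mask")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("<pet_volume>", paste(dim(x$data), collapse = "x"),
      "spacing", paste(signif(x$spacing, 4), collapse = "x"), "mm\n")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask>", paste(dim(x$data), collapse = "x"),
      "foreground", sum(x$data), "voxels\n")
  invisible(x)
}

check_geometry <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("geometry error: volume ", paste(dim(volume$data), collapse = "x"),
         " and mask ", paste(dim(mask$data), collapse = "x"), " shapes differ")
  invisible(TRUE)
}

#' Read a volume or mask from NIfTI
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return `read_volume()` returns a [pet_volume], `read_mask()` a [roi_mask]
#'   (binarized at `> 0`).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  org <- RNifti::origin(img)
  if (is.null(org) || length(org) != 3L || any(!is.finite(org))) org <- c(0, 0, 0)
  arr <- array(as.numeric(img), dim(img)) # strip NIfTI attributes
  pet_volume(arr, spacing = sp[seq_len(3)], origin = as.numeric(org))
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  roi_mask(v$data, spacing = v$spacing, origin = v$origin)
}

#' Write a volume or mask to NIfTI
#'
#' @param x a [pet_volume] or [roi_mask].
#' @param path output path (`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Crop volume and mask to the mask bounding box plus a margin
#'
#' The crop covers the tight foreground bounding box dilated by `margin`
#' voxels isotropically, clipped to the image extent; the mask foreground is
#' unchanged. Index ranges are reported 0-based and half-open.
#'
#' @param volume a [pet_volume].
#' @param mask a non-empty [roi_mask] on the same grid.
#' @param margin non-negative integer margin in voxels.
#' @return list with `volume`, `mask` (cropped) and `bbox`, a 2x3 matrix of
#'   half-open 0-based index ranges `[start, end)` per axis.
#' @export
crop_with_margin <- function(volume, mask, margin = 5L) {
  check_geometry(volume, mask)
  if (margin < 0) stop("margin must be >= 0")
  if (sum(mask$data) == 0L) stop("empty mask")
  dm <- dim(mask$data)
  idx <- which(mask$data > 0, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dm)
  vol <- volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msk <- mask$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  new_origin <- volume$origin + (lo - 1) * volume$spacing
  bbox <- rbind(start = lo - 1L, end = hi) # half-open, 0-based
  list(volume = pet_volume(vol, volume$spacing, new_origin),
       mask = roi_mask(msk, volume$spacing, new_origin),
       bbox = bbox)
}

resample_axis <- function(nin, nout) {
  p <- (seq_len(nout) - 0.5) * nin / nout - 0.5
  p <- pmin(pmax(p, 0), nin - 1)
  i0 <- pmin(floor(p), nin - 2)
  list(i0 = as.integer(i0) + 1L, w = p - floor(p), nn = as.integer(round(p)) + 1L)
}

#' Resample a volume and mask to a target shape
#'
#' Intensities are interpolated trilinearly (grid centers aligned), the mask
#' by nearest neighbor so it stays binary. Constant volumes are preserved
#' exactly.
#'
#' @inheritParams crop_with_margin
#' @param target integer length-3 target shape, all components `>= 2`.
#' @return list with resampled `volume` and `mask`.
#' @export
resample_to_shape <- function(volume, mask, target = c(64L, 64L, 64L)) {
  check_geometry(volume, mask)
  dm <- dim(volume$data)
  target <- as.integer(target)
  if (any(target < 2L)) stop("target components must be >= 2")
  if (any(dm < 2L)) stop("degenerate input: single-voxel axis")
  ax <- lapply(seq_len(3), function(k) resample_axis(dm[k], target[k]))
  nx <- dm[1]; nxy <- dm[1] * dm[2]
  gx <- rep(ax[[1]]$i0, times = target[2] * target[3])
  wx <- rep(ax[[1]]$w, times = target[2] * target[3])
  wy <- rep(rep(ax[[2]]$w, each = target[1]), times = target[3])
  wz <- rep(ax[[3]]$w, each = target[1] * target[2])
  v <- volume$data
  base <- gx + rep(rep(ax[[2]]$i0 - 1L, each = target[1]), times = target[3]) * nx +
    rep(ax[[3]]$i0 - 1L, each = target[1] * target[2]) * nxy
  # nested linear interpolation over the 8 cell corners
  lerp <- function(a, b, w) a + w * (b - a)
  y0 <- lerp(lerp(v[base], v[base + 1L], wx),
             lerp(v[base + nx], v[base + nx + 1L], wx), wy)
  b1 <- base + nxy
  y1 <- lerp(lerp(v[b1], v[b1 + 1L], wx),
             lerp(v[b1 + nx], v[b1 + nx + 1L], wx), wy)
  out <- lerp(y0, y1, wz)
  nnx <- rep(ax[[1]]$nn, times = target[2] * target[3])
  nny <- rep(rep(ax[[2]]$nn, each = target[1]), times = target[3])
  nnz <- rep(ax[[3]]$nn, each = target[1] * target[2])
  mout <- mask$data[nnx + (nny - 1L) * nx + (nnz - 1L) * nxy]
  new_spacing <- volume$spacing * dm / target
  list(volume = pet_volume(array(out, target), new_spacing, volume$origin),
       mask = roi_mask(array(mout, target), new_spacing, volume$origin))
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' A global configuration seed fans out deterministically to per-stage seeds
#' so that each randomized pipeline stage has its own stream.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 1000003L) * 1009L + (h %% 999983L) + 1L)
}

#' Read a YAML pipeline configuration
#'
#' @param path path to a YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  yaml::read_yaml(path)
}

log_msg <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [dpetfusion] ", ...)
}
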