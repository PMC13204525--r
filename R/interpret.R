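#' 3D Grad-CAM attention map for the convolutional branch
#'
#' Channel activations at the chosen residual block are weighted by the
#' global-average gradient of the logit with respect to them, summed,
#' rectified, trilinearly upsampled to the 64-cube input shape and
#' max-normalized to `[0, 1]`. All-zero maps (no positive evidence) are
#' returned with a `degenerate` flag instead of being normalized.
#'
#' @param model a trained `resnet3d_small` [build_model()] / training result.
#' @param tensor a `tensor_case`.
#' @param block residual block index 1..8 (default 8, the last
#'   convolutional stage).
#' @return An `attention_map`: `map` (64-cube, in `[0, 1]`), `layer`,
#'   `degenerate`.
#' @export
gradcam3d <- function(model, tensor, block = 8L) {
  if (model$config$arch != "resnet3d_small")
    stop("Grad-CAM requires the convolutional architecture")
  if (block < 1L || block > 8L) stop("layer without spatial extent")
  X <- stack_inputs(prepare_many(tensor))
  cache <- model_forward(model, X)
  da <- resnet_grad_at_block(model, cache, block)
  act <- cache$acts[[block]]$out
  w <- colMeans(da[, , 1, drop = FALSE])[, 1] # global-average gradient per channel
  cam <- as.vector(matrix(act[, , 1], ncol = dim(act)[2]) %*% w)
  cam <- pmax(cam, 0)
  side <- round(cache$acts[[block]]$dims[1])
  cam <- array(cam, rep(side, 3))
  up <- resample_to_shape(pet_volume(cam), roi_mask(array(1L, dim(cam))),
                          c(64L, 64L, 64L))$volume$data
  up <- pmax(up, 0)
  degenerate <- max(up) <= 0
  if (!degenerate) up <- up / max(up)
  structure(list(map = up, layer = paste0("block", block),
                 degenerate = degenerate), class = "attention_map")
}

# Gradient of the logit w.r.t. the chosen block's (post-relu) output.
resnet_grad_at_block <- function(model, cache, stop_block) {
  p <- model$params
  B <- dim(cache$X)[3]
  dlogit <- rep(1, B)
  dl <- matrix(dlogit, ncol = 1)
  h1 <- pmax(cache$z1, 0)
  dh1 <- (dl %*% t(p$fc2_W)) * (cache$z1 > 0)
  dpool <- dh1 %*% t(p$fc1_W)
  nv <- dim(cache$last)[1]; C <- dim(cache$last)[2]
  da <- array(rep(as.vector(t(dpool)) / nv, each = nv), c(nv, C, B))
  block_dims <- resnet_block_dims()
  for (k in 8:1) {
    if (k == stop_block) return(da)
    ac <- cache$acts[[k]]
    da <- da * (ac$a_pre > 0)
    r2 <- cpp_conv3d_bw(ac$h, da, ac$dims, p[[paste0("b", k, "_W2")]], TRUE)
    dh <- r2$dx * (ac$h_pre > 0)
    r1 <- cpp_conv3d_bw(ac$x_in, dh, ac$dims, p[[paste0("b", k, "_W1")]], TRUE)
    da <- da + r1$dx
    if (k == 7L) {
      da <- cpp_avgpool_bw(da, block_dims[[6]], 2L)
    } else if (k == 3L) {
      pr <- proj_bw(cache$t1_in, da, p$proj_P)
      da <- cpp_avgpool_bw(pr$dx, block_dims[[2]], 2L)
    }
  }
  stop("unreachable")
}

#' Exact SHAP attributions for a linear model
#'
#' On the link (log-odds) scale a linear model's Shapley values are exact
#' and closed-form: `contribution_j = coef_j * (x_j - background_j)` with
#' base value `link(background)`. Additivity
#' `base + sum_j contribution_j = link(x)` holds to machine precision.
#'
#' @param coefficients named coefficient vector including `(Intercept)`, or
#'   a `meta_model`.
#' @param X numeric matrix of cases (columns matching the coefficients).
#' @param background named vector of background (training-mean) feature
#'   values.
#' @return An `attribution_set`: `contributions` (cases x features),
#'   `base`, `link` (per-case log-odds).
#' @export
linear_shap <- function(coefficients, X, background) {
  if (inherits(coefficients, "meta_model")) coefficients <- coefficients$coefficients
  X <- as.matrix(X)
  feats <- setdiff(names(coefficients), "(Intercept)")
  if (!all(feats %in% colnames(X)))
    stop("feature name mismatch: ", paste(setdiff(feats, colnames(X)), collapse = ", "))
  if (!all(feats %in% names(background))) stop("background must cover all features")
  cf <- coefficients[feats]
  ctr <- sweep(X[, feats, drop = FALSE], 2, background[feats], `-`)
  contributions <- sweep(ctr, 2, cf, `*`)
  base <- unname(coefficients["(Intercept)"] + sum(cf * background[feats]))
  structure(list(contributions = contributions, base = base,
                 link = base + rowSums(contributions)),
            class = "attribution_set")
}

#' Pearson correlation matrix of selected features
#'
#' Standard Pearson r with an exact unit diagonal; zero-variance features
#' are flagged and their rows/columns set to `NA`.
#'
#' @param X numeric matrix (cases x features), >= 3 rows, >= 2 columns.
#' @return correlation matrix with attribute `flagged` (zero-variance
#'   feature names).
#' @export
pearson_matrix <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L || nrow(X) < 3L) stop("need >= 2 features and >= 3 cases")
  sds <- apply(X, 2, sd)
  flagged <- colnames(X)[sds == 0]
  R <- suppressWarnings(cor(X))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R)[sds > 0] <- 1
  attr(R, "flagged") <- flagged
  R
}
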