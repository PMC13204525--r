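#' Standardize a tumor crop into a model-ready tensor
#'
#' Crops the tumor with a margin (microenvironment context), resamples to
#' 64 x 64 x 64 and z-scores within the crop (standard-deviation floor for
#' constant crops). Context outside the crop is excluded.
#'
#' @param volume a [pet_volume].
#' @param mask a non-empty [roi_mask].
#' @param margin crop margin in voxels.
#' @param target cubic side of the standardized tensor.
#' @return A `tensor_case`: `grid` (target^3 array, mean 0 / sd 1).
#' @export
tensorize <- function(volume, mask, margin = 5L, target = 64L) {
  cr <- crop_with_margin(volume, mask, margin)
  rs <- resample_to_shape(cr$volume, cr$mask, rep(target, 3))
  g <- rs$volume$data
  s <- sd(g)
  g <- (g - mean(g)) / max(s, 1e-6)
  structure(list(grid = g), class = "tensor_case")
}

#' Model configuration for the compact volumetric classifiers
#'
#' `resnet3d_small` is a stem convolution, eight residual blocks in four
#' stages, global average pooling and two fully connected layers;
#' `vit3d` splits the volume into non-overlapping patches, projects each to
#' a 64-dimensional latent space and applies 3 transformer layers before a
#' classification head. Both ingest the 64-cube tensor through a fixed 4x
#' average-pooling stem (16-cube working grid) to stay CPU-trainable.
#'
#' @param arch `"resnet3d_small"` or `"vit3d"`.
#' @param width resnet base channel width.
#' @param patch ViT patch size at the 64-cube scale; must divide 64.
#' @param embed ViT latent dimension.
#' @param depth ViT transformer layer count.
#' @param heads ViT attention heads (must divide `embed`).
#' @param mlp_dim ViT feed-forward width.
#' @param lr,epochs,batch Adam learning rate, epochs, minibatch size.
#' @param seed parameter-init and shuffling seed.
#' @return A `model_config` list.
#' @export
model_config <- function(arch = c("resnet3d_small", "vit3d"), width = 8L,
                         patch = 16L, embed = 64L, depth = 3L, heads = 4L,
                         mlp_dim = 128L, lr = 3e-3, epochs = 10L, batch = 16L,
                         seed = 1L) {
  arch <- match.arg(arch)
  if (64L %% patch != 0L) stop("invalid patch size: must divide 64")
  if (depth < 1L) stop("depth must be >= 1")
  if (embed %% heads != 0L) stop("heads must divide embed")
  structure(list(arch = arch, width = as.integer(width), patch = as.integer(patch),
                 embed = as.integer(embed), depth = as.integer(depth),
                 heads = as.integer(heads), mlp_dim = as.integer(mlp_dim),
                 lr = lr, epochs = as.integer(epochs), batch = as.integer(batch),
                 seed = as.integer(seed)),
            class = "model_config")
}

# working grid: 64^3 tensor average-pooled 4x to 16^3
POOL0 <- 4L
WDIM <- 16L

resnet_block_dims <- function() {
  d <- function(n) rep(n, 3L)
  list(d(8L), d(8L), d(4L), d(4L), d(4L), d(4L), d(2L), d(2L))
}

# Input channels on the working grid: pooled intensities plus pooled squared
# intensities, so sub-pool second moments stay linearly accessible.
NCH <- 2L

prepare_input <- function(tensor) {
  x <- array(c(tensor$grid, tensor$grid^2), c(64L^3, NCH, 1L))
  matrix(cpp_avgpool_fw(x, c(64L, 64L, 64L), POOL0), ncol = NCH)
}

stack_inputs <- function(prepared) {
  B <- length(prepared)
  array(unlist(prepared, use.names = FALSE), c(WDIM^3, NCH, B))
}

rnorm_mat <- function(nr, nc, sd) matrix(rnorm(nr * nc, sd = sd), nr, nc)

conv_fw <- function(x, dims, W, b) {
  y <- cpp_conv3d_fw(x, dims, W)
  nv <- dim(y)[1]; B <- dim(y)[3]
  y + rep(rep(b, each = nv), times = B)
}

conv_bw <- function(x, dy, dims, W, need_dx = TRUE) {
  r <- cpp_conv3d_bw(x, dy, dims, W, need_dx)
  r$db <- rowSums(colSums(dy)) # sum over voxels and batch
  r
}

proj_fw <- function(x, P, b) {
  # 1x1 channel projection of an (nvox, C, B) map
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 3, 2)), ncol = d[2])
  y <- m %*% P
  y <- sweep(y, 2, b, `+`)
  aperm(array(y, c(d[1], d[3], ncol(P))), c(1, 3, 2))
}

proj_bw <- function(x, dy, P) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 3, 2)), ncol = d[2])
  dm <- matrix(aperm(dy, c(1, 3, 2)), ncol = ncol(P))
  list(dx = aperm(array(dm %*% t(P), c(d[1], d[3], d[2])), c(1, 3, 2)),
       dP = t(m) %*% dm, db = colSums(dm))
}

#' Build a compact volumetric model
#'
#' Initializes parameters (He-scaled; zero-initialized output head, so an
#' untrained model predicts probability 0.5) and reports the parameter
#' count.
#'
#' @param config a [model_config].
#' @return A `deep_model` with `params`, `config` and `n_params`.
#' @export
build_model <- function(config) {
  set.seed(derive_seed(config$seed, paste0("init", config$arch)))
  p <- list()
  if (config$arch == "resnet3d_small") {
    w <- config$width
    he <- function(cin) sqrt(2 / (27 * cin))
    p$stem_W <- rnorm_mat(27 * NCH, w, he(NCH)); p$stem_b <- numeric(w)
    widths <- c(w, w, rep(2L * w, 6)) # channel width per residual block
    for (k in 1:8) {
      ch <- widths[k]
      p[[paste0("b", k, "_W1")]] <- rnorm_mat(27 * ch, ch, he(ch))
      p[[paste0("b", k, "_b1")]] <- numeric(ch)
      p[[paste0("b", k, "_W2")]] <- rnorm_mat(27 * ch, ch, he(ch))
      p[[paste0("b", k, "_b2")]] <- numeric(ch)
    }
    p$proj_P <- rnorm_mat(w, 2L * w, sqrt(2 / w)); p$proj_b <- numeric(2L * w)
    p$fc1_W <- rnorm_mat(2L * w, 2L * w, sqrt(2 / (2 * w)))
    p$fc1_b <- numeric(2L * w)
    p$fc2_W <- matrix(0, 2L * w, 1); p$fc2_b <- 0
  } else {
    d <- config$embed
    ip <- config$patch %/% POOL0            # patch size on the working grid
    TN <- (WDIM %/% ip)^3                   # token count
    pd <- NCH * ip^3
    p$embed_W <- rnorm_mat(pd, d, 1 / sqrt(pd)); p$embed_b <- numeric(d)
    p$pos <- rnorm_mat(TN, d, 0.02)
    for (l in seq_len(config$depth)) {
      nm <- function(s) paste0("l", l, "_", s)
      p[[nm("ln1_g")]] <- rep(1, d); p[[nm("ln1_b")]] <- numeric(d)
      for (m in c("q", "k", "v", "o")) {
        p[[nm(paste0("W", m))]] <- rnorm_mat(d, d, 1 / sqrt(d))
        p[[nm(paste0("b", m))]] <- numeric(d)
      }
      p[[nm("ln2_g")]] <- rep(1, d); p[[nm("ln2_b")]] <- numeric(d)
      p[[nm("M1")]] <- rnorm_mat(d, config$mlp_dim, 1 / sqrt(d))
      p[[nm("mb1")]] <- numeric(config$mlp_dim)
      p[[nm("M2")]] <- rnorm_mat(config$mlp_dim, d, 1 / sqrt(config$mlp_dim))
      p[[nm("mb2")]] <- numeric(d)
    }
    p$lnf_g <- rep(1, d); p$lnf_b <- numeric(d)
    p$head_W <- matrix(0, d, 1); p$head_b <- 0
  }
  structure(list(params = p, config = config,
                 n_params = sum(vapply(p, length, 0L)),
                 fusion_dim = 0L),
            class = "deep_model")
}

#' Attach a feature-fusion projection to a model
#'
#' Adds a zero-initialized learnable linear projection from `n_feat` selected
#' radiomic features to the pooled-representation width; its output is added
#' element-wise (residual) to the pooled representation, so the initial
#' forward pass equals the unfused network exactly.
#'
#' @param model a [build_model] result.
#' @param n_feat number of radiomic features to inject.
#' @return The extended `deep_model`.
#' @export
add_fusion_projection <- function(model, n_feat) {
  dim_pool <- if (model$config$arch == "resnet3d_small")
    2L * model$config$width else model$config$embed
  model$params$fus_W <- matrix(0, n_feat, dim_pool)
  model$fusion_dim <- as.integer(n_feat)
  model
}

# ---- layer-norm and attention primitives (row-wise over token matrices) ----

ln_fw <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xh <- xc * inv
  list(y = sweep(sweep(xh, 2, g, `*`), 2, b, `+`), xh = xh, inv = inv)
}

ln_bw <- function(cache, g, dY) {
  dxh <- sweep(dY, 2, g, `*`)
  xh <- cache$xh
  dg <- colSums(dY * xh); db <- colSums(dY)
  n <- ncol(xh)
  dx <- cache$inv * (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh))
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# sigmoid-approximated GELU (x * sigmoid(1.702 x)): standard fast variant
gelu <- function(x) x / (1 + exp(-1.702 * x))
gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s + 1.702 * x * s * (1 - s)
}

# ---- forward/backward ------------------------------------------------------

# X: (nvox, 1, B) working-grid input; R: optional (B x n_feat) fusion matrix.
model_forward <- function(model, X, R = NULL) {
  p <- model$params
  cfg <- model$config
  B <- dim(X)[3]
  cache <- list(X = X, R = R)
  if (cfg$arch == "resnet3d_small") {
    # stem at 16^3, residual stages at 8/4/4/2 (pool after stem, after
    # block 2 with channel expansion, and after block 6)
    a <- conv_fw(X, c(16L, 16L, 16L), p$stem_W, p$stem_b)
    cache$stem_pre <- a
    a <- pmax(a, 0)
    a <- cpp_avgpool_fw(a, c(16L, 16L, 16L), 2L)
    block_dims <- resnet_block_dims()
    acts <- list()
    for (k in 1:8) {
      if (k == 3L) {
        a <- cpp_avgpool_fw(a, block_dims[[2]], 2L)
        cache$t1_in <- a
        a <- proj_fw(a, p$proj_P, p$proj_b)
      } else if (k == 7L) {
        a <- cpp_avgpool_fw(a, block_dims[[6]], 2L)
      }
      dims <- block_dims[[k]]
      x_in <- a
      h_pre <- conv_fw(x_in, dims, p[[paste0("b", k, "_W1")]], p[[paste0("b", k, "_b1")]])
      h <- pmax(h_pre, 0)
      r <- conv_fw(h, dims, p[[paste0("b", k, "_W2")]], p[[paste0("b", k, "_b2")]])
      a_pre <- x_in + r
      a <- pmax(a_pre, 0)
      acts[[k]] <- list(x_in = x_in, h_pre = h_pre, h = h, a_pre = a_pre,
                        dims = dims, out = a)
    }
    cache$acts <- acts
    pool <- t(colMeans(a)) # (B x 2w)
    cache$last <- a
  } else {
    ip <- cfg$patch %/% POOL0
    TN <- (WDIM %/% ip)^3
    pd <- NCH * ip^3
    pid <- patch_indices(WDIM, ip) # (ip^3 x TN)
    # stacked patches: rows = B*TN tokens, channels concatenated per token
    XP <- matrix(0, B * TN, pd)
    for (b in seq_len(B)) {
      rows <- (b - 1) * TN + seq_len(TN)
      for (ch in seq_len(NCH))
        XP[rows, (ch - 1) * nrow(pid) + seq_len(nrow(pid))] <-
          t(matrix(X[, ch, b][pid], nrow = nrow(pid)))
    }
    cache$XP <- XP
    E <- sweep(XP %*% p$embed_W, 2, p$embed_b, `+`)
    E <- E + do.call(rbind, rep(list(p$pos), B))
    cache$layers <- vector("list", cfg$depth)
    dh <- cfg$embed %/% cfg$heads
    for (l in seq_len(cfg$depth)) {
      nm <- function(s) paste0("l", l, "_", s)
      lc <- list(x_in = E)
      ln1 <- ln_fw(E, p[[nm("ln1_g")]], p[[nm("ln1_b")]])
      lc$ln1 <- ln1
      Q <- sweep(ln1$y %*% p[[nm("Wq")]], 2, p[[nm("bq")]], `+`)
      K <- sweep(ln1$y %*% p[[nm("Wk")]], 2, p[[nm("bk")]], `+`)
      V <- sweep(ln1$y %*% p[[nm("Wv")]], 2, p[[nm("bv")]], `+`)
      lc$Q <- Q; lc$K <- K; lc$V <- V
      O <- matrix(0, B * TN, cfg$embed)
      lc$A <- vector("list", B)
      for (b in seq_len(B)) {
        rows <- (b - 1) * TN + seq_len(TN)
        Ab <- vector("list", cfg$heads)
        for (h in seq_len(cfg$heads)) {
          cols <- (h - 1) * dh + seq_len(dh)
          S <- softmax_rows(Q[rows, cols, drop = FALSE] %*%
                              t(K[rows, cols, drop = FALSE]) / sqrt(dh))
          O[rows, cols] <- S %*% V[rows, cols, drop = FALSE]
          Ab[[h]] <- S
        }
        lc$A[[b]] <- Ab
      }
      lc$O <- O
      E <- E + sweep(O %*% p[[nm("Wo")]], 2, p[[nm("bo")]], `+`)
      lc$x_mid <- E
      ln2 <- ln_fw(E, p[[nm("ln2_g")]], p[[nm("ln2_b")]])
      lc$ln2 <- ln2
      H_pre <- sweep(ln2$y %*% p[[nm("M1")]], 2, p[[nm("mb1")]], `+`)
      lc$H_pre <- H_pre
      E <- E + sweep(gelu(H_pre) %*% p[[nm("M2")]], 2, p[[nm("mb2")]], `+`)
      cache$layers[[l]] <- lc
    }
    lnf <- ln_fw(E, p$lnf_g, p$lnf_b)
    cache$lnf <- lnf; cache$E_fin <- E
    # mean over tokens per case
    pool <- t(vapply(seq_len(B), function(b)
      colMeans(lnf$y[(b - 1) * TN + seq_len(TN), , drop = FALSE]),
      numeric(cfg$embed)))
    cache$TN <- TN
  }
  if (model$fusion_dim > 0L) {
    if (is.null(R) || ncol(R) != model$fusion_dim)
      stop("feature count mismatch vs. fitted projection")
    pool <- pool + R %*% p$fus_W
  }
  cache$pool <- pool
  if (cfg$arch == "resnet3d_small") {
    z1 <- sweep(pool %*% p$fc1_W, 2, p$fc1_b, `+`)
    cache$z1 <- z1
    logits <- as.numeric(pmax(z1, 0) %*% p$fc2_W + p$fc2_b)
  } else {
    logits <- as.numeric(pool %*% p$head_W + p$head_b)
  }
  cache$logits <- logits
  cache
}

model_backward <- function(model, cache, dlogit) {
  p <- model$params
  cfg <- model$config
  B <- length(dlogit)
  g <- list()
  dl <- matrix(dlogit, ncol = 1)
  if (cfg$arch == "resnet3d_small") {
    h1 <- pmax(cache$z1, 0)
    g$fc2_W <- t(h1) %*% dl
    g$fc2_b <- sum(dl)
    dh1 <- (dl %*% t(p$fc2_W)) * (cache$z1 > 0)
    g$fc1_W <- t(cache$pool) %*% dh1
    g$fc1_b <- colSums(dh1)
    dpool <- dh1 %*% t(p$fc1_W)
  } else {
    g$head_W <- t(cache$pool) %*% dl
    g$head_b <- sum(dl)
    dpool <- dl %*% t(p$head_W)
  }
  if (model$fusion_dim > 0L) {
    g$fus_W <- t(cache$R) %*% dpool
  }
  if (cfg$arch == "resnet3d_small") {
    # global mean pool backward: (B x C) -> (nvox, C, B)
    nv <- dim(cache$last)[1]; C <- dim(cache$last)[2]
    da <- array(rep(as.vector(t(dpool)) / nv, each = nv), c(nv, C, B))
    block_dims <- resnet_block_dims()
    for (k in 8:1) {
      ac <- cache$acts[[k]]
      da <- da * (ac$a_pre > 0)
      r2 <- conv_bw(ac$h, da, ac$dims, p[[paste0("b", k, "_W2")]])
      g[[paste0("b", k, "_W2")]] <- r2$dw
      g[[paste0("b", k, "_b2")]] <- r2$db
      dh <- r2$dx * (ac$h_pre > 0)
      r1 <- conv_bw(ac$x_in, dh, ac$dims, p[[paste0("b", k, "_W1")]])
      g[[paste0("b", k, "_W1")]] <- r1$dw
      g[[paste0("b", k, "_b1")]] <- r1$db
      da <- da + r1$dx # residual skip
      if (k == 7L) {
        da <- cpp_avgpool_bw(da, block_dims[[6]], 2L)
      } else if (k == 3L) {
        pr <- proj_bw(cache$t1_in, da, p$proj_P)
        g$proj_P <- pr$dP; g$proj_b <- pr$db
        da <- cpp_avgpool_bw(pr$dx, block_dims[[2]], 2L)
      }
    }
    da <- cpp_avgpool_bw(da, c(16L, 16L, 16L), 2L)
    da <- da * (cache$stem_pre > 0)
    r0 <- conv_bw(cache$X, da, c(WDIM, WDIM, WDIM), p$stem_W, need_dx = FALSE)
    g$stem_W <- r0$dw; g$stem_b <- r0$db
  } else {
    TN <- cache$TN
    d <- cfg$embed
    dh_ <- d %/% cfg$heads
    # pool backward
    dY <- matrix(0, B * TN, d)
    for (b in seq_len(B))
      dY[(b - 1) * TN + seq_len(TN), ] <-
        matrix(dpool[b, ] / TN, TN, d, byrow = TRUE)
    lb <- ln_bw(cache$lnf, p$lnf_g, dY)
    g$lnf_g <- lb$dg; g$lnf_b <- lb$db
    dE <- lb$dx
    for (l in rev(seq_len(cfg$depth))) {
      nm <- function(s) paste0("l", l, "_", s)
      lc <- cache$layers[[l]]
      Hg <- gelu(lc$H_pre)
      g[[nm("M2")]] <- t(Hg) %*% dE
      g[[nm("mb2")]] <- colSums(dE)
      dH <- (dE %*% t(p[[nm("M2")]])) * gelu_grad(lc$H_pre)
      g[[nm("M1")]] <- t(lc$ln2$y) %*% dH
      g[[nm("mb1")]] <- colSums(dH)
      lb2 <- ln_bw(lc$ln2, p[[nm("ln2_g")]], dH %*% t(p[[nm("M1")]]))
      g[[nm("ln2_g")]] <- lb2$dg; g[[nm("ln2_b")]] <- lb2$db
      dE <- dE + lb2$dx
      # attention backward
      g[[nm("Wo")]] <- t(lc$O) %*% dE
      g[[nm("bo")]] <- colSums(dE)
      dO <- dE %*% t(p[[nm("Wo")]])
      dQ <- matrix(0, B * TN, d); dK <- dQ; dV <- dQ
      for (b in seq_len(B)) {
        rows <- (b - 1) * TN + seq_len(TN)
        for (h in seq_len(cfg$heads)) {
          cols <- (h - 1) * dh_ + seq_len(dh_)
          S <- lc$A[[b]][[h]]
          dOb <- dO[rows, cols, drop = FALSE]
          dV[rows, cols] <- t(S) %*% dOb
          dS <- dOb %*% t(lc$V[rows, cols, drop = FALSE])
          dZ <- (dS - rowSums(dS * S)) * S
          dQ[rows, cols] <- dZ %*% lc$K[rows, cols, drop = FALSE] / sqrt(dh_)
          dK[rows, cols] <- t(dZ) %*% lc$Q[rows, cols, drop = FALSE] / sqrt(dh_)
        }
      }
      g[[nm("Wq")]] <- t(lc$ln1$y) %*% dQ; g[[nm("bq")]] <- colSums(dQ)
      g[[nm("Wk")]] <- t(lc$ln1$y) %*% dK; g[[nm("bk")]] <- colSums(dK)
      g[[nm("Wv")]] <- t(lc$ln1$y) %*% dV; g[[nm("bv")]] <- colSums(dV)
      dln1 <- dQ %*% t(p[[nm("Wq")]]) + dK %*% t(p[[nm("Wk")]]) +
        dV %*% t(p[[nm("Wv")]])
      lb1 <- ln_bw(lc$ln1, p[[nm("ln1_g")]], dln1)
      g[[nm("ln1_g")]] <- lb1$dg; g[[nm("ln1_b")]] <- lb1$db
      dE <- dE + lb1$dx
    }
    g$embed_W <- t(cache$XP) %*% dE
    g$embed_b <- colSums(dE)
    dpos <- matrix(0, TN, d)
    for (b in seq_len(B))
      dpos <- dpos + dE[(b - 1) * TN + seq_len(TN), , drop = FALSE]
    g$pos <- dpos
  }
  g
}

patch_indices <- local({
  cache <- list()
  function(n, ip) {
    key <- paste(n, ip)
    if (is.null(cache[[key]])) {
      npatch <- n %/% ip
      grid <- array(seq_len(n^3), c(n, n, n))
      idx <- matrix(0L, ip^3, npatch^3)
      t <- 0L
      for (pz in seq_len(npatch)) for (py in seq_len(npatch)) for (px in seq_len(npatch)) {
        t <- t + 1L
        idx[, t] <- as.integer(grid[(px - 1) * ip + seq_len(ip),
                                    (py - 1) * ip + seq_len(ip),
                                    (pz - 1) * ip + seq_len(ip)])
      }
      cache[[key]] <<- idx
    }
    cache[[key]]
  }
})

# ---- training --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

#' Train a compact model on prepared tensors
#'
#' Minibatch Adam on binary cross-entropy; fully seeded (parameter init and
#' shuffling), no use of any held-out data.
#'
#' @param prepared list of prepared working-grid inputs (see
#'   [predict_proba.deep_model()] for the public path via tensors).
#' @param y binary labels.
#' @param config a [model_config].
#' @param R optional (cases x features) fusion matrix for feature-level
#'   fusion models.
#' @param model optional pre-built model (e.g. with fusion projection).
#' @return The trained `deep_model` (with `history` of epoch losses).
#' @keywords internal
train_deep <- function(prepared, y, config, R = NULL, model = NULL) {
  if (is.null(model)) model <- build_model(config)
  opt <- adam_init(model$params)
  set.seed(derive_seed(config$seed, "shuffle"))
  n <- length(y)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(n)
    tot <- 0
    for (start in seq(1, n, by = config$batch)) {
      idx <- ord[start:min(start + config$batch - 1, n)]
      X <- stack_inputs(prepared[idx])
      Rb <- if (!is.null(R)) R[idx, , drop = FALSE] else NULL
      cache <- model_forward(model, X, Rb)
      pr <- sigmoid(cache$logits)
      yb <- y[idx]
      tot <- tot + sum(-(yb * log(clip01(pr)) + (1 - yb) * log(clip01(1 - pr))))
      dlogit <- (pr - yb) / length(idx)
      grads <- model_backward(model, cache, dlogit)
      up <- adam_step(model$params, grads, opt, config$lr)
      model$params <- up$params
      opt <- up$state
    }
    history[ep] <- tot / n
  }
  model$history <- history
  model
}

#' Predicted probabilities from a trained volumetric model
#'
#' Deterministic sigmoid of the model logit.
#'
#' @param object a trained `deep_model`.
#' @param newdata a `tensor_case`, a list of them, or prepared inputs.
#' @param R optional fusion feature matrix (feature-level fusion models).
#' @param ... unused.
#' @export
predict_proba.deep_model <- function(object, newdata, R = NULL, ...) {
  prepared <- prepare_many(newdata)
  out <- numeric(length(prepared))
  bs <- 32L
  for (start in seq(1, length(prepared), by = bs)) {
    idx <- start:min(start + bs - 1, length(prepared))
    X <- stack_inputs(prepared[idx])
    Rb <- if (!is.null(R)) R[idx, , drop = FALSE] else NULL
    out[idx] <- sigmoid(model_forward(object, X, Rb)$logits)
  }
  out
}

prepare_many <- function(newdata) {
  if (inherits(newdata, "tensor_case")) return(list(prepare_input(newdata)))
  if (is.list(newdata) && length(newdata) && inherits(newdata[[1]], "tensor_case"))
    return(lapply(newdata, prepare_input))
  newdata # already prepared
}

#' Cross-validated configuration selection and final training
#'
#' For each candidate configuration, computes out-of-fold probabilities by
#' stratified 5-fold cross-validation within the training set only and
#' scores it by the mean AUC across folds; the best configuration is then
#' retrained on the full training set. Out-of-fold probabilities of the
#' chosen configuration are retained for the stacking meta-learner. Held-out
#' partitions are never touched.
#'
#' @param tensors list of `tensor_case` (training cases).
#' @param y binary training labels.
#' @param configs list of [model_config] candidates.
#' @param folds CV folds.
#' @param seed fold-assignment seed.
#' @param R optional fusion matrix (rows match `tensors`).
#' @param fusion_builder optional function(config) returning a pre-built
#'   model (used for feature-level fusion).
#' @return list: `model` (final), `config`, `oof` (probabilities), `cv_auc`
#'   per config (mean across folds), `foldid`.
#' @export
cv_select_and_train <- function(tensors, y, configs = default_configs(),
                                folds = 5L, seed = 1L, R = NULL,
                                fusion_builder = NULL) {
  y <- as.integer(y)
  if (length(y) == 0L) stop("empty training set")
  if (length(unique(y)) < 2L || min(table(y)) < folds)
    stop("too few cases per class for the fold count")
  prepared <- prepare_many(tensors)
  foldid <- stratified_folds(y, folds, derive_seed(seed, "deepcv"))
  cv_auc <- numeric(length(configs))
  oofs <- vector("list", length(configs))
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    oof <- numeric(length(y))
    fold_aucs <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- foldid != f
      base <- if (is.null(fusion_builder)) NULL else fusion_builder(cfg)
      fit <- train_deep(prepared[tr], y[tr], cfg,
                        R = if (is.null(R)) NULL else R[tr, , drop = FALSE],
                        model = base)
      oof[!tr] <- predict_proba(fit, prepared[!tr],
                                R = if (is.null(R)) NULL else R[!tr, , drop = FALSE])
      fold_aucs[f] <- auc_rank(oof[!tr], y[!tr])
    }
    cv_auc[ci] <- mean(fold_aucs)
    oofs[[ci]] <- oof
  }
  best <- which.max(cv_auc)
  cfg <- configs[[best]]
  base <- if (is.null(fusion_builder)) NULL else fusion_builder(cfg)
  final <- train_deep(prepared, y, cfg, R = R, model = base)
  list(model = final, config = cfg, oof = oofs[[best]], cv_auc = cv_auc,
       foldid = foldid, configs = configs)
}

#' Default candidate configurations (one per architecture)
#' @param seed init seed shared by the candidates.
#' @export
default_configs <- function(seed = 1L) {
  list(model_config("resnet3d_small", width = 8L, epochs = 8L, lr = 3e-3, seed = seed),
       model_config("vit3d", epochs = 12L, lr = 1e-3, seed = seed))
}
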