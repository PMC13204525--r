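test_that("Grad-CAM concentrates on the active quadrant of a constructed net", {
  # width-1 network with pass-through residual blocks: zero block convs give
  # a = relu(...(relu(stem))) so attention tracks the stem activation
  cfg <- model_config("resnet3d_small", width = 1L, seed = 1L)
  m <- build_model(cfg)
  for (k in 1:8) {
    m$params[[paste0("b", k, "_W1")]][] <- 0
    m$params[[paste0("b", k, "_W2")]][] <- 0
  }
  m$params$stem_W[] <- 0
  # column layout ci + Cin*k: center offset k = 13 (0-based), channel 1
  m$params$stem_W[2L * 13L + 1L, 1] <- 1 # stem output = input channel 1
  m$params$proj_P[] <- matrix(c(1, 1), 1)
  m$params$fc1_W <- diag(2); m$params$fc1_b[] <- 0
  m$params$fc2_W[] <- 1; m$params$fc2_b <- 0
  g <- array(0, c(64, 64, 64))
  g[1:32, 1:32, 1:32] <- 3 # one octant lights up
  tz <- structure(list(grid = g), class = "tensor_case")
  am <- gradcam3d(m, tz, block = 2L)
  expect_false(am$degenerate)
  expect_true(all(am$map >= 0 & am$map <= 1))
  expect_equal(max(am$map), 1)
  mass <- sum(am$map[1:32, 1:32, 1:32]) / sum(am$map)
  expect_gte(mass, 0.7)

  # zero head -> zero gradients -> degenerate all-zero map
  m0 <- build_model(cfg)
  am0 <- gradcam3d(m0, tz, block = 4L)
  expect_true(am0$degenerate)
  expect_true(all(am0$map == 0))
  expect_error(gradcam3d(m, tz, block = 9L), "spatial")
  expect_error(gradcam3d(build_model(model_config("vit3d")), tz),
               "convolutional")
})

test_that("Grad-CAM is deterministic for fixed model and input", {
  cfg <- model_config("resnet3d_small", width = 2L, seed = 3L)
  m <- build_model(cfg)
  m$params$fc2_W[] <- 0.5
  tc <- toy_case(71)
  tz <- tensorize(tc$volume, tc$mask)
  a1 <- gradcam3d(m, tz)
  a2 <- gradcam3d(m, tz)
  expect_identical(a1$map, a2$map)
})

test_that("linear SHAP is exactly additive on the log-odds scale", {
  cf <- c("(Intercept)" = 0.4, f1 = 1.0, f2 = -2.0)
  X <- matrix(c(1.5, 0.75), 1, dimnames = list(NULL, c("f1", "f2")))
  bg <- c(f1 = 1.0, f2 = 0.5)
  at <- linear_shap(cf, X, bg)
  expect_equal(unname(at$contributions[1, ]), c(0.5, -0.5))
  expect_equal(at$base, 0.4 + 1 * 1 - 2 * 0.5)

  set.seed(72)
  Xr <- matrix(rnorm(60), 20, dimnames = list(NULL, c("f1", "f2", "f3")))
  cfr <- c("(Intercept)" = -0.3, f1 = 0.8, f2 = -1.1, f3 = 2.2)
  bgr <- colMeans(Xr)
  atr <- linear_shap(cfr, Xr, bgr)
  link_direct <- cfr[1] + Xr %*% cfr[-1]
  expect_equal(unname(atr$link), unname(as.numeric(link_direct)),
               tolerance = 1e-12)
  # x at the background mean contributes nothing
  at0 <- linear_shap(cfr, matrix(bgr, 1, dimnames = list(NULL, names(bgr))), bgr)
  expect_equal(unname(at0$contributions[1, ]), c(0, 0, 0))
  expect_error(linear_shap(cfr, Xr[, 1:2], bgr), "mismatch")
})

test_that("Pearson matrix: unit diagonal, sign symmetry, hand example", {
  set.seed(73)
  x <- rnorm(10)
  X <- cbind(a = x, b = -x, c = rnorm(10))
  R <- pearson_matrix(X)
  expect_equal(unname(diag(R)), rep(1, 3))
  expect_equal(R["a", "b"], -1)
  expect_equal(R, t(R))
  # 4-point hand example
  h <- cbind(u = c(1, 2, 3, 4), v = c(2, 1, 4, 3))
  num <- sum((h[, 1] - 2.5) * (h[, 2] - 2.5))
  den <- sqrt(sum((h[, 1] - 2.5)^2) * sum((h[, 2] - 2.5)^2))
  expect_equal(pearson_matrix(h)["u", "v"], num / den)
  # zero-variance feature flagged
  Z <- cbind(a = x, flat = rep(1, 10))
  Rz <- pearson_matrix(Z)
  expect_equal(attr(Rz, "flagged"), "flat")
  expect_true(is.na(Rz["a", "flat"]))
  expect_error(pearson_matrix(X[1:2, ]), ">= 2 features")
})
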