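test_that("stacking: perfect branches fuse perfectly, identical branches tie", {
  set.seed(61)
  y <- rep(c(0L, 1L), each = 50)
  truth <- clip01(as.numeric(y))
  meta <- stack_decision(list(deep = truth, radiomics = truth), y, seed = 1L)
  fused <- predict_proba(meta, list(deep = truth, radiomics = truth))
  expect_equal(auc(fused, y), 1.0)

  p <- plogis(y + rnorm(100))
  meta2 <- stack_decision(list(deep = p, radiomics = p), y, seed = 1L)
  fused2 <- predict_proba(meta2, list(deep = p, radiomics = p))
  expect_equal(auc(fused2, y), auc(p, y)) # monotone map of one input
})

test_that("stacking favors the informative branch and loses little AUC", {
  set.seed(62)
  n <- 200L
  y <- rep(c(0L, 1L), each = n / 2)
  pA <- plogis(3 * (y - 0.5) + rnorm(n, sd = 0.8))
  pB <- runif(n)
  meta <- stack_decision(list(deep = pA, radiomics = pB), y, seed = 2L)
  w <- meta$coefficients
  expect_gt(w[["deep"]], abs(w[["radiomics"]]))
  set.seed(63)
  yte <- rep(c(0L, 1L), each = n / 2)
  pAte <- plogis(3 * (yte - 0.5) + rnorm(n, sd = 0.8))
  pBte <- runif(n)
  fused <- predict_proba(meta, list(deep = pAte, radiomics = pBte))
  expect_gte(auc(fused, yte), auc(pAte, yte) - 0.02)
})

test_that("a zero-weight meta model predicts one half everywhere", {
  meta <- structure(list(coefficients = c("(Intercept)" = 0, deep = 0,
                                          radiomics = 0),
                         branches = c("deep", "radiomics")),
                    class = "meta_model")
  p <- predict_proba(meta, list(deep = runif(10), radiomics = runif(10)))
  expect_equal(p, rep(0.5, 10))
  expect_error(predict_proba(meta, list(deep = runif(10))), "missing branch")
  # extreme probabilities are clipped before the logit
  p2 <- predict_proba(meta, list(deep = c(0, 1), radiomics = c(0, 1)))
  expect_true(all(is.finite(p2)))
})

test_that("zero-initialized projection reproduces the image-only network", {
  set.seed(64)
  cfg <- model_config("vit3d", heads = 2L, depth = 1L, seed = 7L)
  base <- build_model(cfg)
  fused <- add_fusion_projection(build_model(cfg), 4L)
  prepared <- lapply(1:3, function(i) matrix(rnorm(16^3 * 2), ncol = 2))
  X <- stack_inputs(prepared)
  R <- matrix(rnorm(12), 3)
  expect_equal(model_forward(fused, X, R)$logits,
               model_forward(base, X)$logits, tolerance = 1e-12)
})

test_that("zeroed radiomics inputs reproduce the image-only pathway at inference", {
  co <- small_cohort(n = 20L, seed = 65L, prevalence = 0.5, test2_n = 2L)
  tens <- lapply(co$cases[1:20], function(cs) tensorize(cs$volume, cs$mask))
  y <- co$split$label[1:20]
  if (length(unique(y)) < 2) y <- rep(c(0L, 1L), 10)
  Xf <- matrix(rnorm(40), 20, dimnames = list(NULL, c("r1", "r2")))
  cfg <- model_config("vit3d", heads = 2L, epochs = 2L, seed = 3L)
  ff <- feature_fusion_train(tens, Xf, y, cfg)
  p_zero <- predict_proba(ff, tens, features = matrix(0, 20, 2,
                                                      dimnames = list(NULL, c("r1", "r2"))))
  # strip the fusion projection: same weights, image-only pathway
  img_only <- ff$model
  img_only$fusion_dim <- 0L
  p_img <- predict_proba(img_only, tens)
  expect_equal(p_zero, p_img, tolerance = 1e-12)
  expect_error(predict_proba(ff, tens, features = matrix(0, 20, 2)),
               "mismatch")
})

test_that("repeated training with one seed reproduces fusion outputs", {
  set.seed(66)
  tens <- lapply(1:12, function(i) {
    tc <- toy_case(200 + i, grid = c(14L, 14L, 14L), radius = 4)
    tensorize(tc$volume, tc$mask)
  })
  y <- rep(c(0L, 1L), 6)
  Xf <- matrix(rnorm(24), 12, dimnames = list(NULL, c("a", "b")))
  cfg <- model_config("vit3d", heads = 2L, epochs = 2L, seed = 11L)
  f1 <- feature_fusion_train(tens, Xf, y, cfg)
  f2 <- feature_fusion_train(tens, Xf, y, cfg)
  expect_equal(predict_proba(f1, tens, features = Xf),
               predict_proba(f2, tens, features = Xf), tolerance = 1e-12)
})
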