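test_that("tensorize produces standardized 64-cube tensors", {
  tc <- toy_case(41)
  tz <- tensorize(tc$volume, tc$mask)
  expect_equal(dim(tz$grid), c(64L, 64L, 64L))
  expect_equal(mean(tz$grid), 0, tolerance = 1e-10)
  expect_equal(sd(tz$grid), 1, tolerance = 1e-6)
  tz2 <- tensorize(tc$volume, tc$mask)
  expect_identical(tz$grid, tz2$grid) # bitwise reproducible

  # constant crop: z-score guard floors the sd, output is all zeros
  v <- pet_volume(array(4, c(16, 16, 16)))
  m <- ball_mask(c(16L, 16L, 16L), 4)
  tzc <- tensorize(v, m)
  expect_true(all(tzc$grid == 0))
  expect_error(tensorize(v, roi_mask(array(0L, c(16, 16, 16)))), "empty")
})

test_that("ViT patch arithmetic: patch 16 gives 64 tokens of width 64", {
  cfg <- model_config("vit3d", patch = 16L)
  m <- build_model(cfg)
  # (64/16)^3 = 64 tokens; learned position terms are one row per token
  expect_equal(nrow(m$params$pos), 64L)
  expect_equal(ncol(m$params$pos), 64L)
  expect_equal(ncol(m$params$embed_W), 64L)
  expect_error(model_config("vit3d", patch = 12L), "patch")
  expect_error(model_config("vit3d", depth = 0L), "depth")
})

test_that("resnet has a stem, 8 residual blocks and two FC layers", {
  m <- build_model(model_config("resnet3d_small", width = 4L))
  nm <- names(m$params)
  expect_true("stem_W" %in% nm)
  expect_equal(sum(grepl("^b[1-8]_W1$", nm)), 8L)
  expect_true(all(c("fc1_W", "fc2_W") %in% nm))
  expect_gt(m$n_params, 0)
  # forward on zeros gives a finite logit; zero-initialized head gives p=0.5
  X <- stack_inputs(list(matrix(0, 16^3, 2)))
  lg <- model_forward(m, X)$logits
  expect_true(is.finite(lg))
  expect_equal(sigmoid(lg), 0.5)
})

test_that("builds and predictions are seed-reproducible and probabilistic", {
  m1 <- build_model(model_config("vit3d", seed = 5L))
  m2 <- build_model(model_config("vit3d", seed = 5L))
  expect_identical(m1$params, m2$params)
  tc <- toy_case(42)
  tz <- tensorize(tc$volume, tc$mask)
  m1$params$head_W[] <- 0.3
  p1 <- predict_proba(m1, tz)
  p2 <- predict_proba(m1, tz)
  expect_identical(p1, p2)
  expect_true(p1 > 0 && p1 < 1)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(9)
  B <- 2L
  prepared <- lapply(1:B, function(i) matrix(rnorm(16^3 * 2), ncol = 2))
  y <- c(0, 1)
  for (cfg in list(model_config("resnet3d_small", width = 2L),
                   model_config("vit3d", embed = 8L, heads = 2L, depth = 1L,
                                mlp_dim = 12L))) {
    model <- build_model(cfg)
    model <- add_fusion_projection(model, 2L)
    if (cfg$arch == "resnet3d_small")
      model$params$fc2_W[] <- rnorm(length(model$params$fc2_W), sd = 0.3)
    else model$params$head_W[] <- rnorm(length(model$params$head_W), sd = 0.3)
    R <- matrix(rnorm(B * 2L), B)
    X <- stack_inputs(prepared)
    loss <- function(m) {
      pr <- sigmoid(model_forward(m, X, R)$logits)
      -sum(y * log(pr) + (1 - y) * log(1 - pr))
    }
    cache <- model_forward(model, X, R)
    grads <- model_backward(model, cache, sigmoid(cache$logits) - y)
    for (nm in c("stem_W", "b5_W2", "fc1_W", "fus_W",
                 "embed_W", "l1_Wq", "l1_M2", "lnf_g")) {
      if (is.null(grads[[nm]])) next
      ix <- 1L
      eps <- 1e-5
      mp <- model; mp$params[[nm]][ix] <- mp$params[[nm]][ix] + eps
      mm <- model; mm$params[[nm]][ix] <- mm$params[[nm]][ix] - eps
      num <- (loss(mp) - loss(mm)) / (2 * eps)
      expect_equal(as.numeric(grads[[nm]])[ix], num, tolerance = 1e-3,
                   label = paste(cfg$arch, nm))
    }
  }
})

test_that("CV fold assignment is reproducible and selection is honest", {
  set.seed(10)
  y <- rep(c(0L, 1L), each = 15)
  f1 <- stratified_folds(y, 5L, 123L)
  f2 <- stratified_folds(y, 5L, 123L)
  expect_identical(f1, f2)
  expect_true(all(table(f1, y) == 3))
  expect_error(cv_select_and_train(list(), integer(0),
                                   configs = default_configs()),
               "too few|empty|missing",
               class = "error")
})

test_that("label-permuted training yields chance-level out-of-fold AUC", {
  co <- small_cohort(n = 50L, seed = 19L, prevalence = 0.5, test2_n = 2L)
  tens <- lapply(co$cases[1:50], function(cs) tensorize(cs$volume, cs$mask))
  set.seed(20)
  yperm <- sample(rep(c(0L, 1L), 25))
  fit <- cv_select_and_train(
    prepare_many(tens), yperm,
    configs = list(model_config("vit3d", heads = 2L, epochs = 3L, seed = 3L)),
    seed = 3L)
  a <- auc_rank(fit$oof, yperm)
  expect_gte(a, 0.3)
  expect_lte(a, 0.7)
})
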