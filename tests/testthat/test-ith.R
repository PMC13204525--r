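test_that("maximum-area slice selection follows the max + lowest-index rule", {
  g <- c(6L, 6L, 4L)
  m <- array(0L, g)
  m[1:5, 1, 1] <- 1L                 # area 5
  m[1:3, 1:3, 2] <- 1L               # area 9
  m[1:3, 1:3, 3] <- 1L               # area 9 (tie)
  m[1:3, 1, 4] <- 1L                 # area 3
  v <- pet_volume(array(rnorm(prod(g)), g))
  sl <- select_max_slice(v, roi_mask(m))
  expect_equal(sl$slice, 2L)
  # invariant to intensities
  sl2 <- select_max_slice(pet_volume(array(0, g)), roi_mask(m))
  expect_equal(sl2$slice, 2L)
  # single-slice mask
  m1 <- array(0L, g); m1[2:4, 2:4, 3] <- 1L
  expect_equal(select_max_slice(v, roi_mask(m1))$slice, 3L)
})

test_that("per-pixel profile has exactly 104 dimensions", {
  set.seed(51)
  img <- matrix(rnorm(100, 10), 10, 10)
  msk <- matrix(1L, 10, 10)
  pf <- pixel_features(img, msk)
  expect_equal(ncol(pf$features), 104L)
  expect_equal(nrow(pf$features), 100L)
  expect_false(anyDuplicated(colnames(pf$features)) > 0)
  expect_true(all(is.finite(pf$features)))
  expect_error(pixel_features(img, matrix(0L, 10, 10)), "too small")
})

test_that("constant image gives identical interior vectors with zero contrast", {
  img <- matrix(5, 8, 8)
  pf <- pixel_features(img, matrix(1L, 8, 8))
  interior <- pf$coords[, 1] %in% 2:7 & pf$coords[, 2] %in% 2:7
  fi <- pf$features[interior, , drop = FALSE]
  expect_true(all(apply(fi, 2, function(x) diff(range(x)) == 0)))
  expect_true(all(fi[, "glcm_Contrast"] == 0))
  expect_true(all(fi[, "firstorder_Entropy"] == 0))
})

test_that("window statistics match direct arithmetic on a listed 3x3 patch", {
  patch <- matrix(c(2, 7, 1, 8, 2, 8, 1, 8, 2), 3, 3)
  img <- matrix(0, 5, 5); img[2:4, 2:4] <- patch
  msk <- matrix(0L, 5, 5); msk[2:4, 2:4] <- 1L
  pf <- pixel_features(img, msk)
  center <- pf$coords[, 1] == 3 & pf$coords[, 2] == 3
  expect_equal(unname(pf$features[center, "firstorder_Mean"]), mean(patch))
  expect_equal(unname(pf$features[center, "firstorder_Maximum"]), max(patch))
  expect_equal(unname(pf$features[center, "firstorder_Minimum"]), min(patch))
  expect_equal(unname(pf$features[center, "firstorder_Median"]), median(patch))
})

test_that("the C++ fast path agrees with the R reference implementation", {
  set.seed(52)
  img <- matrix(rnorm(49, 20, 5), 7, 7)
  msk <- matrix(rbinom(49, 1, 0.85), 7, 7)
  if (sum(msk) < 9) msk[] <- 1L
  fc <- pixel_features(img, msk, engine = "cpp")
  fr <- pixel_features(img, msk, engine = "r")
  expect_equal(fc$features, fr$features, tolerance = 1e-8)
})

test_that("pixel clustering separates two texturally distinct halves", {
  # separated feature clouds: a flat low-intensity half vs a high-intensity
  # checkerboard half, so intensity AND texture descriptors both separate;
  # the seam columns are masked out so no window mixes the populations
  set.seed(53)
  img <- cbind(matrix(1 + rnorm(50, sd = 0.01), 10, 5),
               matrix(10 + 5 * (outer(1:10, 1:5, `+`) %% 2) +
                        rnorm(50, sd = 0.01), 10, 5))
  msk <- matrix(1L, 10, 10); msk[, 5:6] <- 0L
  pf <- pixel_features(img, msk)
  cl <- cluster_pixels(pf, k = 2L, seed = 1L)
  interior <- pf$coords[, 2] %in% c(2:4, 8:9) & pf$coords[, 1] %in% 2:9
  side <- pf$coords[interior, 2] > 5
  lab <- cl$labels[interior]
  agree <- max(mean((lab == lab[1]) == (side == side[1])),
               mean((lab == lab[1]) == (side != side[1])))
  expect_gte(agree, 0.95)
  # k equal to the pixel count yields singletons
  sub <- pixel_features(img[1:4, 1:4], matrix(1L, 4, 4))
  cls <- cluster_pixels(sub, k = 16L, seed = 1L)
  expect_equal(sort(unique(cls$labels)), 1:16)
  expect_error(cluster_pixels(sub, k = 17L), "fewer pixels")
  # seeded reproducibility
  c1 <- cluster_pixels(pf, seed = 9L)
  c2 <- cluster_pixels(pf, seed = 9L)
  expect_identical(c1$label_map, c2$label_map)
})

test_that("ITH score: zero iff single-component clusters, 0.5 for an equal split", {
  one <- matrix(0L, 6, 6); one[2:5, 2:5] <- 1L
  expect_equal(ith_score(one), 0)
  # one cluster in two equal, separated components
  two <- matrix(0L, 6, 6); two[1:2, 1:2] <- 1L; two[5:6, 5:6] <- 1L
  expect_equal(ith_score(two), 0.5)
  # two clusters, each one component, arbitrary areas
  mixed <- matrix(0L, 6, 6); mixed[1:3, 1:6] <- 1L; mixed[4:6, 1:6] <- 2L
  expect_equal(ith_score(mixed), 0)
  expect_error(ith_score(matrix(0L, 3, 3)), "empty")
})

test_that("fragmentation never decreases the ITH score; relabeling is neutral", {
  base <- matrix(0L, 8, 8)
  base[2:7, 2:4] <- 1L
  base[2:7, 6:7] <- 2L
  s0 <- ith_score(base)
  frag <- base
  frag[4, 2:4] <- 0L # split cluster 1's component in two
  s1 <- ith_score(frag)
  expect_gte(s1, s0)
  # diagonal pixels are not 4-connected
  diagm <- matrix(0L, 4, 4); diagm[1, 1] <- 1L; diagm[2, 2] <- 1L
  expect_equal(ith_score(diagm), 0.5)
  relab <- base; relab[base == 1L] <- 7L; relab[base == 2L] <- 3L
  expect_equal(ith_score(relab), s0)
})

test_that("the univariate ITH model behaves as a rank statistic", {
  set.seed(54)
  y <- rep(c(0L, 1L), each = 100)
  expect_equal(fit_ith_model(as.numeric(y), y)$auc, 1.0)
  s <- runif(200)
  fit <- fit_ith_model(s, y)
  expect_gte(fit$auc, 0.4); expect_lte(fit$auc, 0.6)
  expect_equal(fit_ith_model(qlogis(pmin(pmax(s, .01), .99)), y)$auc, fit$auc)
  expect_error(fit_ith_model(rep(0.5, 200), y), "constant")
})
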