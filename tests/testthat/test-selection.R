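test_that("U-test filter drops flat features and keeps separated ones", {
  set.seed(1)
  y <- rep(c(0L, 1L), each = 10)
  X <- cbind(flat = rep(3, 20),
             sep = c(rnorm(10, 0), rnorm(10, 50)),
             noise = rnorm(20))
  ut <- utest_filter(X, y, alpha = 0.05)
  expect_equal(unname(ut$p["flat"]), 1)
  expect_false("flat" %in% ut$kept)
  expect_true("sep" %in% ut$kept)
  expect_lt(ut$p[["sep"]], 1e-3)
  # retained columns are z-scored with training statistics
  expect_equal(unname(colMeans(ut$table)), rep(0, ncol(ut$table)),
               tolerance = 1e-12)
  expect_error(utest_filter(X, rep(1L, 20)), "both classes")
})

test_that("U-test type-I retention rate matches alpha on null features", {
  set.seed(2)
  n <- 60L; p <- 1000L
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- sample(rep(c(0L, 1L), each = n / 2))
  ut <- utest_filter(X, y, alpha = 0.05)
  frac <- length(ut$kept) / p
  se <- sqrt(0.05 * 0.95 / p)
  expect_lt(abs(frac - 0.05), 3 * se + 0.01) # normal-approx p adds slight slack
})

test_that("mRMR picks the informative non-redundant set and matches brute force", {
  set.seed(3)
  n <- 80L
  y <- rep(c(0L, 1L), each = n / 2)
  f1 <- y + rnorm(n, sd = 0.05)
  X <- cbind(f1 = f1, f2 = f1 + rnorm(n, sd = 1e-4), f3 = rnorm(n))
  sel <- mrmr_select(X, y, m = 2L)
  expect_equal(sel, c("f1", "f3"))

  # brute-force greedy with the same MI estimator
  brute_greedy <- function(X, y, m, nbins = 8L) {
    binned <- apply(X, 2, dpetfusion:::bin_ef, nbins = nbins)
    rel <- apply(binned, 2, dpetfusion:::mi_disc, b = y)
    chosen <- integer(0)
    for (s in seq_len(m)) {
      best <- -Inf; pick <- NA
      for (j in setdiff(seq_len(ncol(X)), chosen)) {
        red <- if (length(chosen)) mean(vapply(chosen, function(k)
          dpetfusion:::mi_disc(binned[, j], binned[, k]), 0)) else 0
        sc <- rel[j] - red
        if (sc > best) { best <- sc; pick <- j }
      }
      chosen <- c(chosen, pick)
    }
    colnames(X)[chosen]
  }
  set.seed(4)
  X2 <- matrix(rnorm(80 * 8), 80, dimnames = list(NULL, paste0("g", 1:8)))
  X2[, 1] <- y + rnorm(80, sd = 0.3)
  X2[, 2] <- y + rnorm(80, sd = 0.5)
  expect_equal(mrmr_select(X2, y, m = 5L), brute_greedy(X2, y, 5L))

  # exhaustion returns a permutation; row duplication leaves selection fixed
  expect_setequal(mrmr_select(X2, y, m = 8L), colnames(X2))
  dup <- rbind(X2, X2)
  expect_equal(mrmr_select(dup, rep(y, 2), m = 5L), mrmr_select(X2, y, m = 5L))
  expect_error(mrmr_select(X2, y, m = 0L), "positive")
})

test_that("LASSO recovers planted informative features with few false positives", {
  set.seed(0)
  n <- 300L; p <- 50L
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
  eta <- 2 * X[, 1] - 2 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  sel <- lasso_select(X, y, seed = 0L)
  expect_true(all(c("x1", "x2") %in% sel$features))
  expect_lte(length(setdiff(sel$features, c("x1", "x2"))), 3L)
  # full shrinkage endpoint is empty; zero-variance columns get zero weight
  cf_inf <- coef(sel$cv$glmnet.fit, s = max(sel$cv$lambda) * 100)
  expect_equal(sum(as.numeric(cf_inf)[-1] != 0), 0L)
  Xz <- cbind(X, zv = 0)
  selz <- lasso_select(Xz, y, seed = 0L)
  expect_equal(unname(selz$coefficients["zv"]), 0)
})

test_that("classifiers separate a separable toy and stay null under permutation", {
  set.seed(5)
  n <- 40L
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(a = y * 4 + rnorm(n, sd = 0.1), b = rnorm(n))
  Xte <- cbind(a = y * 4 + rnorm(n, sd = 0.1), b = rnorm(n))
  for (algo in c("LR", "RF", "XGB", "KNN", "GNB")) {
    fit <- fit_radiomics_classifier(X, y, algo, seed = 1L)
    expect_equal(auc_rank(predict_proba(fit, Xte), y), 1.0,
                 tolerance = 1e-9, label = algo)
    fit2 <- fit_radiomics_classifier(X, y, algo, seed = 1L)
    expect_identical(fit$config, fit2$config)
  }
  set.seed(6)
  yperm <- sample(y)
  for (algo in c("LR", "GNB")) {
    fit <- fit_radiomics_classifier(X, yperm, algo, seed = 2L)
    expect_gte(fit$cv_auc, 0.3)
    expect_lte(fit$cv_auc, 0.7)
  }
})

test_that("bootstrap stability finds dominant signals and rejects pure noise", {
  set.seed(7)
  n <- 60L
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(copy = y + rnorm(n, sd = 0.01),
             matrix(rnorm(n * 24), n, dimnames = list(NULL, paste0("n", 1:24))))
  colnames(X)[1] <- "copy"
  st <- stability_bootstrap(X, y, B = 100L, seed = 1L)
  expect_gte(unname(st$frequency["copy"]), 0.99)
  expect_true(all(st$frequency >= 0 & st$frequency <= 1))
  st2 <- stability_bootstrap(X, y, B = 100L, seed = 1L)
  expect_identical(st$frequency, st2$frequency)

  # pure noise: no feature recurs like a dominant signal does (marginally
  # significant noise features do recur across correlated resamples, so the
  # null ceiling sits well above the nominal retention rate)
  set.seed(0)
  Xn <- matrix(rnorm(n * 25), n, dimnames = list(NULL, paste0("z", 1:25)))
  stn <- stability_bootstrap(Xn, y, B = 100L, seed = 0L)
  expect_lt(max(c(0, stn$counts)), 0.7)
  expect_error(stability_bootstrap(X, y, B = 10L), ">= 50")
})
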