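test_that("threshold metrics match direct confusion arithmetic", {
  y <- c(rep(1L, 22), rep(0L, 17))
  # TP=20, FN=2, TN=11, FP=6
  p <- c(rep(0.9, 20), rep(0.1, 2), rep(0.2, 11), rep(0.8, 6))
  m <- threshold_metrics(p, y)
  expect_equal(m$sen, 20 / 22)
  expect_equal(m$spe, 11 / 17)
  expect_equal(m$acc, 31 / 39)
  expect_equal(m$ppv, 20 / 26)
  expect_equal(m$npv, 11 / 13)
  expect_equal(round(c(m$sen, m$spe, m$acc, m$ppv, m$npv), 3),
               c(0.909, 0.647, 0.795, 0.769, 0.846))
  expect_equal(m$tp + m$fn, m$n1)
  expect_equal(m$tn + m$fp, m$n0)

  perf <- threshold_metrics(y, y)
  expect_true(all(unlist(perf[c("acc", "sen", "spe", "ppv", "npv")]) == 1))

  deg <- threshold_metrics(rep(0.4, 10), rep(c(0, 1), 5))
  expect_equal(deg$sen, 0); expect_equal(deg$spe, 1)
  expect_true(is.na(deg$ppv) && deg$undefined[["ppv"]])
  expect_error(threshold_metrics(numeric(0), integer(0)), "empty")
})

test_that("AUC equals brute-force pair counting and trapezoidal ROC area", {
  pairs_auc <- function(p, y) { # exhaustive pair enumeration oracle
    pos <- p[y == 1]; neg <- p[y == 0]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  trap_auc <- function(p, y) {
    th <- sort(unique(c(-Inf, p, Inf)), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(p[y == 1] >= t), 0)
    fpr <- vapply(th, function(t) mean(p[y == 0] >= t), 0)
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  toy_p <- c(0.9, 0.8, 0.8, 0.3, 0.2, 0.1)
  toy_y <- c(1, 0, 1, 1, 0, 0)
  expect_equal(auc(toy_p, toy_y), pairs_auc(toy_p, toy_y))
  expect_equal(auc(toy_y, toy_y), 1.0)
  expect_equal(auc(rep(0.7, 6), toy_y), 0.5)
  for (s in 1:5) {
    set.seed(s)
    y <- rbinom(50, 1, 0.5); if (length(unique(y)) < 2) next
    p <- round(runif(50), 2)
    expect_equal(auc(p, y), pairs_auc(p, y))
    expect_equal(auc(p, y), trap_auc(p, y), tolerance = 1e-12)
  }
})

test_that("bootstrap CI collapses for zero-variance metrics and is seeded", {
  y <- rep(c(0L, 1L), each = 20)
  ci <- bootstrap_ci(function(p, l) auc(p, l), as.numeric(y), y,
                     B = 300L, seed = 1L)
  expect_equal(ci$lower, 1); expect_equal(ci$upper, 1)
  set.seed(2)
  p <- plogis(y + rnorm(40))
  c1 <- bootstrap_ci(function(p, l) auc(p, l), p, y, B = 300L, seed = 5L)
  c2 <- bootstrap_ci(function(p, l) auc(p, l), p, y, B = 300L, seed = 5L)
  expect_identical(c1[c("lower", "upper")], c2[c("lower", "upper")])
  expect_true(c1$lower <= c1$point && c1$point <= c1$upper)
  expect_error(bootstrap_ci(function(p, l) auc(p, l), p, y, B = 50L), ">= 200")
})

test_that("PR curve and average precision match hand computation", {
  expect_equal(pr_curve(c(.9, .8, .7, .2, .1), c(1, 1, 1, 0, 0))$ap, 1.0)
  # 5-case toy, scores descending: labels 1,0,1,1,0
  p <- c(.9, .8, .7, .6, .5); y <- c(1, 0, 1, 1, 0)
  # steps: rec 1/3 @ prec 1; rec 2/3 @ prec 3/4 ... hand sum:
  hand <- (1 / 3) * 1 + 0 + (1 / 3) * (2 / 3) + (1 / 3) * (3 / 4) + 0
  expect_equal(pr_curve(p, y)$ap, hand)
  # random scores: AP tends to prevalence
  set.seed(3)
  y2 <- rbinom(4000, 1, 0.3)
  expect_lt(abs(pr_curve(runif(4000), y2)$ap - 0.3), 0.05)
  expect_error(pr_curve(runif(5), rep(0, 5)), "no positives")
})

test_that("decision curve: perfect classifier attains the prevalence bound", {
  y <- rep(c(0L, 1L), times = c(12, 8))
  dc <- decision_curve(as.numeric(y), y)
  expect_true(all(abs(dc$nb_model - 0.4) < 1e-12))
  expect_true(all(dc$nb_none == 0))
  expect_true(all(dc$nb_model <= dc$prevalence + 1e-12))
  expect_equal(unname(dc$final_range["lo"]), 0.01)
  expect_equal(unname(dc$final_range["hi"]), 0.99)
  # constant-1 predictions equal treat-all: no strict benefit anywhere
  dc2 <- decision_curve(rep(1, 20), y)
  expect_equal(nrow(dc2$intervals), 0L)
  # 10-case toy at pt = 0.5 against hand arithmetic
  p <- c(.9, .8, .7, .6, .55, .45, .3, .2, .1, .05)
  y3 <- c(1, 1, 1, 0, 1, 0, 0, 1, 0, 0)
  dc3 <- decision_curve(p, y3)
  tp <- sum(p >= 0.5 & y3 == 1); fp <- sum(p >= 0.5 & y3 == 0)
  expect_equal(dc3$nb_model[dc3$threshold == 0.5],
               tp / 10 - fp / 10 * 0.5 / 0.5)
})

test_that("Hanley-McNeil variance has the closed-form limits and monotonicity", {
  hm <- hanley_mcneil(0.5, 1, 1)
  expect_equal(hm$V, 0.25)
  v <- vapply(c(5, 10, 20, 40), function(n) hanley_mcneil(0.8, n, 15)$V, 0)
  expect_true(all(diff(v) < 0))
  v2 <- vapply(c(5, 10, 20, 40), function(n) hanley_mcneil(0.8, 15, n)$V, 0)
  expect_true(all(diff(v2) < 0))
  expect_true(hm$power >= 0 && hm$power <= 1)
  expect_gt(hanley_mcneil(0.8, 20, 20)$power, hanley_mcneil(0.6, 20, 20)$power)
  expect_error(hanley_mcneil(1, 10, 10), "degenerate")
})

test_that("confusion reconstruction inverts printed two-decimal metrics", {
  r <- reconstruct_confusion(1.00, 1.00, 10, 7)
  expect_equal(r$tp, 10L); expect_equal(r$tn, 7L); expect_equal(r$acc, 1.00)
  r2 <- reconstruct_confusion(0.91, 0.65, 22, 17)
  expect_true(r2$consistent && r2$unique)
  expect_equal(r2$tp, 20L); expect_equal(r2$tn, 11L)
  # impossible printed pair
  r3 <- reconstruct_confusion(0.99, 0.5, 4, 4)
  expect_false(r3$consistent)
})

test_that("threshold-response curves and probability densities are coherent", {
  set.seed(8)
  y <- rbinom(100, 1, 0.6)
  p <- plogis(2 * y + rnorm(100) - 1)
  tr <- threshold_response(p, y)
  expect_equal(tr$sen[1], 1); expect_equal(tr$spe[1], 0)
  expect_true(all(diff(tr$sen) <= 1e-12))
  expect_true(all(diff(tr$spe) >= -1e-12))
  d <- probability_density(p, y, breaks = 20L)
  for (cl in 0:1)
    expect_equal(sum(d$density[d$class == cl]) * (1 / 20), 1, tolerance = 1e-9)
})

test_that("clinical baseline: encoding contract, dominant signal, weak null", {
  co <- small_cohort(n = 60L, seed = 23L, test2_n = 2L)
  cl <- co$clinical
  enc <- dpetfusion:::encode_clinical(cl)
  expect_equal(sum(grepl("^regimen_", colnames(enc$X))),
               length(unique(cl$regimen)))
  expect_error(
    dpetfusion:::encode_clinical(transform(cl[1, ], regimen = "OTHER"),
                                 enc$encoder),
    "unseen category")

  # dominant covariate: suvmax replaced by the label separates perfectly
  y <- co$split$label
  cl2 <- cl; cl2$suvmax <- y * 10 + 1
  fit <- baseline_clinical_model(cl2, y, seed = 1L)
  expect_equal(auc(predict_proba(fit, cl2), y), 1.0)

  # label-independent covariates stay weak on held-out cases
  set.seed(9)
  n <- 200L
  null_clin <- data.frame(age = rnorm(n, 52, 10), ki67 = runif(n, 5, 95),
                          cT = sample(1:4, n, TRUE), cN = sample(1:3, n, TRUE),
                          grade = sample(2:3, n, TRUE),
                          regimen = sample(c("TCbHP", "PCbHP"), n, TRUE),
                          suvmax = runif(n, 14, 65))
  yn <- rbinom(n, 1, 0.5)
  fit0 <- baseline_clinical_model(null_clin[1:120, ], yn[1:120], seed = 2L)
  a <- auc(predict_proba(fit0, null_clin[121:200, ]), yn[121:200])
  expect_gte(a, 0.3); expect_lte(a, 0.7)
})
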