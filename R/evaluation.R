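#' Pair-counting AUC
#'
#' Mann-Whitney estimator: fraction of (positive, negative) pairs ranked
#' correctly, ties counting one half.
#'
#' @param probs numeric scores.
#' @param labels binary labels.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(probs, labels) auc_rank(probs, labels)

#' Fixed-cutoff classification metrics
#'
#' Sensitivity, specificity, accuracy, PPV and NPV at a probability cutoff
#' (prediction positive when `prob >= cutoff`). Ratios with zero denominator
#' are reported as `NA` with an `undefined` flag.
#'
#' @param probs probabilities.
#' @param labels binary labels.
#' @param cutoff decision threshold (default 0.5).
#' @return A `metric_report` list: `auc`, `acc`, `sen`, `spe`, `ppv`, `npv`,
#'   `tp`, `fp`, `tn`, `fn`, `n1`, `n0`, `cutoff`, `undefined`.
#' @export
threshold_metrics <- function(probs, labels, cutoff = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("empty input")
  if (length(unique(labels)) < 2L) stop("both classes required")
  pred <- as.integer(probs >= cutoff)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  n1 <- tp + fn; n0 <- tn + fp
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  ppv <- sdiv(tp, tp + fp); npv <- sdiv(tn, tn + fn)
  structure(list(auc = auc_rank(probs, labels),
                 acc = (tp + tn) / (n1 + n0),
                 sen = tp / n1, spe = tn / n0, ppv = ppv, npv = npv,
                 tp = tp, fp = fp, tn = tn, fn = fn, n1 = n1, n0 = n0,
                 cutoff = cutoff,
                 undefined = c(ppv = is.na(ppv), npv = is.na(npv))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("AUC %.3f ACC %.3f SEN %.3f SPE %.3f PPV %s NPV %s (cutoff %g)\n",
              x$auc, x$acc, x$sen, x$spe,
              ifelse(is.na(x$ppv), "NA", sprintf("%.3f", x$ppv)),
              ifelse(is.na(x$npv), "NA", sprintf("%.3f", x$npv)), x$cutoff))
  invisible(x)
}

#' Stratified bootstrap percentile confidence interval
#'
#' Case-level resampling with replacement, stratified by class; percentile
#' 2.5/97.5 interval. Resamples on which the metric is undefined are redrawn
#' and counted; more than 10% undefined flags the interval.
#'
#' @param metric function(probs, labels) returning a scalar.
#' @param probs probabilities.
#' @param labels binary labels.
#' @param B resamples (>= 200).
#' @param seed integer seed.
#' @param level confidence level.
#' @return list: `lower`, `upper`, `point`, `flagged`, `n_redrawn`.
#' @export
bootstrap_ci <- function(metric, probs, labels, B = 2000L, seed = 1L,
                         level = 0.95) {
  if (B < 200L) stop("B must be >= 200")
  labels <- as.integer(labels)
  i1 <- which(labels == 1L); i0 <- which(labels == 0L)
  set.seed(seed)
  vals <- numeric(B)
  redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- c(sample(i1, length(i1), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      v <- tryCatch(metric(probs[idx], labels[idx]), error = function(e) NA_real_)
      if (is.finite(v)) break
      redrawn <- redrawn + 1L
      if (redrawn > 10L * B) stop("metric undefined on nearly all resamples")
    }
    vals[b] <- v
  }
  a <- (1 - level) / 2
  q <- unname(quantile(vals, c(a, 1 - a), type = 7))
  list(lower = q[1], upper = q[2], point = metric(probs, labels),
       flagged = redrawn > 0.1 * B, n_redrawn = redrawn)
}

#' Precision-recall curve and average precision
#'
#' Step-interpolated average precision: the sum of precision times recall
#' increments over descending score thresholds, with the recall endpoints 0
#' and 1 handled explicitly.
#'
#' @param probs probabilities.
#' @param labels binary labels.
#' @return list: `precision`, `recall`, `thresholds`, `ap`.
#' @export
pr_curve <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L) stop("no positives")
  o <- order(probs, decreasing = TRUE)
  lab <- labels[o]
  tp <- cumsum(lab)
  # collapse tied thresholds to their last index
  keep <- c(diff(probs[o]) != 0, TRUE)
  tp_k <- tp[keep]
  fp_k <- (seq_along(lab))[keep] - tp_k
  prec <- tp_k / (tp_k + fp_k)
  rec <- tp_k / n1
  ap <- sum(diff(c(0, rec)) * prec)
  list(precision = c(1, prec), recall = c(0, rec),
       thresholds = c(Inf, probs[o][keep]), ap = ap)
}

#' Decision-curve analysis
#'
#' Net benefit `NB(pt) = TP/n - FP/n * pt/(1-pt)` over a threshold grid,
#' with the treat-all and treat-none references. Beneficial intervals are
#' maximal threshold runs where the model strictly exceeds both references;
#' the longest run is reported as the final continuous range.
#'
#' @param probs probabilities.
#' @param labels binary labels.
#' @param step threshold grid step (grid excludes 0 and 1).
#' @return A `decision_curve` list: `threshold`, `nb_model`, `nb_all`,
#'   `nb_none`, `intervals` (matrix), `final_range`.
#' @export
decision_curve <- function(probs, labels, step = 0.01) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes required")
  n <- length(labels)
  prev <- mean(labels)
  pt <- seq(step, 1 - step, by = step)
  nb <- vapply(pt, function(t) {
    tp <- sum(probs >= t & labels == 1L)
    fp <- sum(probs >= t & labels == 0L)
    tp / n - fp / n * t / (1 - t)
  }, 0)
  nb_all <- prev - (1 - prev) * pt / (1 - pt)
  beneficial <- nb > pmax(nb_all, 0)
  runs <- rle(beneficial)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- cbind(lo = pt[starts[runs$values]], hi = pt[ends[runs$values]])
  final <- if (nrow(iv)) iv[which.max(iv[, 2] - iv[, 1]), ] else c(lo = NA, hi = NA)
  structure(list(threshold = pt, nb_model = nb, nb_all = nb_all,
                 nb_none = rep(0, length(pt)), intervals = iv,
                 final_range = final, prevalence = prev),
            class = "decision_curve")
}

#' Hanley-McNeil AUC variance and power against AUC = 0.5
#'
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`,
#' `V = [A(1-A) + (n1-1)(Q1-A^2) + (n0-1)(Q2-A^2)] / (n1 n0)`.
#' Power for the two-sided level-alpha test of `A = 0.5` uses the
#' null-variance critical value and the alternative variance (normal
#' approximation); `null_variance = FALSE` uses `V(A)` in both places.
#'
#' @param A AUC in (0, 1).
#' @param n1,n0 positive / negative class sizes.
#' @param alpha two-sided significance level.
#' @param null_variance use `V(0.5)` for the critical value (default).
#' @return A `power_report`: `A`, `n1`, `n0`, `Q1`, `Q2`, `V`, `V0`,
#'   `power`, `alpha`.
#' @export
hanley_mcneil <- function(A, n1, n0, alpha = 0.05, null_variance = TRUE) {
  if (A <= 0 || A >= 1) stop("degenerate AUC: need 0 < A < 1")
  if (n1 < 1 || n0 < 1) stop("class sizes must be >= 1")
  vA <- function(a) {
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) / (n1 * n0)
  }
  V <- vA(A); V0 <- vA(0.5)
  se_crit <- sqrt(if (null_variance) V0 else V)
  z <- qnorm(1 - alpha / 2)
  power <- pnorm((A - 0.5 - z * se_crit) / sqrt(V)) +
    pnorm((0.5 - A - z * se_crit) / sqrt(V))
  structure(list(A = A, n1 = n1, n0 = n0, Q1 = A / (2 - A),
                 Q2 = 2 * A^2 / (1 + A), V = V, V0 = V0, power = power,
                 alpha = alpha), class = "power_report")
}

#' Reconstruct integer confusion matrices from printed metrics
#'
#' Finds every integer pair `(TP, TN)` with `TP/n1` and `TN/n0` rounding
#' (half away from zero) to the printed 2-decimal sensitivity and
#' specificity, and derives the remaining rounded metrics. A unique solution
#' is returned directly; ambiguity or inconsistency is flagged.
#'
#' @param sen_printed,spe_printed printed 2-decimal values.
#' @param n1,n0 class sizes.
#' @return list: `tp`, `tn`, `acc`, `ppv`, `npv` (2-decimal), `unique`,
#'   `consistent`, `candidates`.
#' @export
reconstruct_confusion <- function(sen_printed, spe_printed, n1, n0) {
  r2 <- function(x) floor(x * 100 + 0.5) / 100 # round half away from zero
  tp_c <- which(vapply(0:n1, function(tp) r2(tp / n1) == sen_printed,
                       logical(1))) - 1L
  tn_c <- which(vapply(0:n0, function(tn) r2(tn / n0) == spe_printed,
                       logical(1))) - 1L
  cand <- expand.grid(tp = tp_c, tn = tn_c)
  if (nrow(cand) == 0L)
    return(list(consistent = FALSE, unique = FALSE, candidates = cand))
  derive <- function(tp, tn) {
    fp <- n0 - tn; fn <- n1 - tp
    c(acc = r2((tp + tn) / (n1 + n0)),
      ppv = if (tp + fp > 0) r2(tp / (tp + fp)) else NA_real_,
      npv = if (tn + fn > 0) r2(tn / (tn + fn)) else NA_real_)
  }
  uniq <- nrow(cand) == 1L
  best <- cand[1, ]
  d <- derive(best$tp, best$tn)
  list(tp = best$tp, tn = best$tn, acc = d[["acc"]], ppv = d[["ppv"]],
       npv = d[["npv"]], unique = uniq, consistent = TRUE, candidates = cand)
}

#' Sensitivity/specificity threshold-response curves
#'
#' @param probs probabilities.
#' @param labels binary labels.
#' @param step cutoff grid step.
#' @return data frame: `cutoff`, `sen`, `spe`.
#' @export
threshold_response <- function(probs, labels, step = 0.01) {
  labels <- as.integer(labels)
  cut <- seq(0, 1, by = step)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  data.frame(cutoff = cut,
             sen = vapply(cut, function(t) sum(probs >= t & labels == 1L) / n1, 0),
             spe = vapply(cut, function(t) sum(probs < t & labels == 0L) / n0, 0))
}

#' Per-class predicted-probability density summaries
#'
#' Histogram densities on a common grid; each class integrates to 1.
#'
#' @param probs probabilities.
#' @param labels binary labels.
#' @param breaks number of bins over `[0, 1]`.
#' @return data frame: `mid`, `density`, `class`.
#' @export
probability_density <- function(probs, labels, breaks = 20L) {
  labels <- as.integer(labels)
  br <- seq(0, 1, length.out = breaks + 1L)
  out <- lapply(c(0L, 1L), function(cl) {
    h <- hist(pmin(pmax(probs[labels == cl], 0), 1), breaks = br, plot = FALSE)
    data.frame(mid = h$mids, density = h$density, class = cl)
  })
  do.call(rbind, out)
}

#' Clinical baseline logistic model
#'
#' Standardizes the continuous covariates (age, Ki-67, SUVmax) with training
#' statistics, one-hot encodes the categorical covariates (regimen, cT, cN,
#' grade), and grid-searches an elastic-net logistic model (regularization
#' type via the mixing parameter, strength, class weighting) by stratified
#' 5-fold cross-validated AUC; the best configuration is refit on the full
#' training data.
#'
#' @param clinical data frame with columns `age`, `ki67`, `cT`, `cN`,
#'   `grade`, `regimen`, `suvmax`.
#' @param labels binary labels.
#' @param folds CV folds.
#' @param seed fold seed.
#' @return A `clinical_model` with a [predict_proba()] method.
#' @export
baseline_clinical_model <- function(clinical, labels, folds = 5L, seed = 1L) {
  y <- as.integer(labels)
  enc <- encode_clinical(clinical)
  X <- enc$X
  grid <- expand.grid(alpha = c(0, 0.5, 1), lambda = 10^seq(-4, 1, 1),
                      balanced = c(FALSE, TRUE))
  fit_fun <- function(X, y, g) {
    w <- if (g$balanced) ifelse(y == 1L, 0.5 / mean(y), 0.5 / mean(1 - y))
    else rep(1, length(y))
    glmnet::glmnet(X, y, family = "binomial", alpha = g$alpha,
                   lambda = g$lambda, weights = w, standardize = FALSE)
  }
  pred_fun <- function(fit, X) as.numeric(predict(fit, X, type = "response"))
  cvres <- cv_grid_auc(X, y, grid, fit_fun, pred_fun, folds,
                       derive_seed(seed, "baseline"))
  best <- grid[cvres$best, , drop = FALSE]
  final <- fit_fun(X, y, best)
  structure(list(model = final, config = best, encoder = enc$encoder,
                 cv_auc = cvres$aucs[cvres$best]),
            class = "clinical_model")
}

encode_clinical <- function(clinical, encoder = NULL) {
  cont <- c("age", "ki67", "suvmax")
  cats <- c("cT", "cN", "grade", "regimen")
  if (is.null(encoder)) {
    encoder <- list(center = colMeans(clinical[cont]),
                    scale = vapply(clinical[cont], sd, 0),
                    levels = lapply(clinical[cats],
                                    function(x) sort(unique(as.character(x)))))
    encoder$scale[encoder$scale == 0] <- 1
  }
  Xc <- scale(as.matrix(clinical[cont]), encoder$center, encoder$scale)
  oh <- lapply(cats, function(v) {
    lev <- encoder$levels[[v]]
    x <- as.character(clinical[[v]])
    if (any(!x %in% lev))
      stop("unseen category in '", v, "' at inference: ",
           paste(setdiff(x, lev), collapse = ", "))
    m <- outer(x, lev, `==`) * 1
    colnames(m) <- paste0(v, "_", lev)
    m
  })
  list(X = cbind(Xc, do.call(cbind, oh)), encoder = encoder)
}

#' @export
predict_proba.clinical_model <- function(object, newdata, ...) {
  X <- encode_clinical(newdata, object$encoder)$X
  as.numeric(predict(object$model, X, type = "response"))
}

#' Full metric report with bootstrap confidence intervals
#'
#' @param probs probabilities.
#' @param labels binary labels.
#' @param cutoff decision threshold.
#' @param B bootstrap resamples.
#' @param seed bootstrap seed.
#' @return `metric_report` augmented with a `ci` list per metric.
#' @export
evaluate_predictions <- function(probs, labels, cutoff = 0.5, B = 2000L,
                                 seed = 1L) {
  rep <- threshold_metrics(probs, labels, cutoff)
  mk <- function(fn) bootstrap_ci(fn, probs, labels, B = B, seed = seed)
  rep$ci <- list(
    auc = mk(function(p, l) auc_rank(p, l)),
    acc = mk(function(p, l) mean((p >= cutoff) == l)),
    sen = mk(function(p, l) sum(p >= cutoff & l == 1) / sum(l == 1)),
    spe = mk(function(p, l) sum(p < cutoff & l == 0) / sum(l == 0)))
  rep
}
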