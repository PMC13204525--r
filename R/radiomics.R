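#' Extract the radiomic feature bank for one region
#'
#' Computes the 1688 named features of the pinned [extraction_profile] for a
#' single region: 14 shape descriptors from the original image plus 93
#' intensity/texture features on the original and each of the 17 derived
#' images. The volume is cropped to the region bounding box (with context
#' margin for the filters) before the derived images are computed.
#'
#' @param volume a [pet_volume].
#' @param mask a non-empty [roi_mask] delimiting the region.
#' @param profile an [extraction_profile].
#' @return Named numeric vector of length 1688.
#' @export
extract_region_features <- function(volume, mask, profile = extraction_profile()) {
  check_geometry(volume, mask)
  if (sum(mask$data) == 0L) stop("empty mask")
  cr <- crop_with_margin(volume, mask, margin = 4L)
  imgs <- derived_images(cr$volume$data, cr$volume$spacing, profile)
  region_features_from_images(imgs, cr$mask$data, cr$volume$spacing, profile)
}

region_features_from_images <- function(imgs, mask_arr, spacing, profile) {
  out <- shape3d_features(mask_arr, spacing)
  # texture matrices only involve in-region voxels, so restrict every image
  # to the tight region bounding box before the C++ scans
  idx <- which(mask_arr > 0, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  m <- mask_arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  for (nm in names(imgs)) {
    im <- imgs[[nm]][lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    fx <- texture_features_region(im, m, profile)
    names(fx) <- paste0(nm, "_", names(fx))
    out <- c(out, fx)
  }
  out
}

#' Build the cases-by-features table over whole ROI and habitats
#'
#' For each case the whole-ROI and the two habitat subregions (high-/
#' low-uptake) are extracted with the same profile, giving 3 x 1688 = 5064
#' columns tagged `whole_`, `high_`, `low_`. Degenerate habitats (all-high
#' maps or regions smaller than `min_region`) yield missing values that are
#' imputed with the column median across cases; the affected case/region
#' pairs are recorded in the `imputed` attribute.
#'
#' @param cases list of cases, each with `volume` and `mask` entries (e.g.
#'   [generate_case] output).
#' @param habitat_maps list of [segment_habitats] results, parallel to
#'   `cases`.
#' @param profile an [extraction_profile].
#' @param min_region smallest region (voxels) extracted directly.
#' @return A `feature_table`: numeric matrix (cases x 5064) with attributes
#'   `region` (per-column tag) and `imputed`.
#' @export
build_feature_table <- function(cases, habitat_maps,
                                profile = extraction_profile(),
                                min_region = 8L) {
  if (length(habitat_maps) != length(cases)) stop("missing habitat map")
  rows <- vector("list", length(cases))
  imputed <- list()
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    hm <- habitat_maps[[i]]
    cr <- crop_with_margin(cs$volume, cs$mask, margin = 4L)
    imgs <- derived_images(cr$volume$data, cr$volume$spacing, profile)
    hab_crop <- hm$labels[(cr$bbox[1, 1] + 1L):cr$bbox[2, 1],
                          (cr$bbox[1, 2] + 1L):cr$bbox[2, 2],
                          (cr$bbox[1, 3] + 1L):cr$bbox[2, 3], drop = FALSE]
    region_masks <- list(whole = cr$mask$data,
                         high = array(as.integer(hab_crop == 2L), dim(hab_crop)),
                         low = array(as.integer(hab_crop == 1L), dim(hab_crop)))
    vec <- list()
    for (rg in names(region_masks)) {
      m <- region_masks[[rg]]
      if (sum(m) < min_region) {
        v <- rep(NA_real_, 1688L)
        names(v) <- names(region_features_from_template())
        imputed[[length(imputed) + 1L]] <- list(case = i, region = rg)
      } else {
        v <- region_features_from_images(imgs, m, cr$volume$spacing, profile)
      }
      names(v) <- paste0(rg, "_", names(v))
      vec[[rg]] <- v
    }
    rows[[i]] <- c(vec[["whole"]], vec[["high"]], vec[["low"]])
  }
  tab <- do.call(rbind, rows)
  # median imputation for degenerate regions
  for (j in which(colSums(is.na(tab)) > 0)) {
    med <- median(tab[, j], na.rm = TRUE)
    tab[is.na(tab[, j]), j] <- if (is.finite(med)) med else 0
  }
  region <- sub("_.*$", "", colnames(tab))
  structure(tab, region = region, imputed = imputed, class = "feature_table")
}

# cached template of the 1688 per-region feature names
region_features_from_template <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      arr <- array(c(1:27) / 27, c(3, 3, 3))
      msk <- array(1L, c(3, 3, 3))
      cache <<- region_features_from_images(
        derived_images(arr, c(1, 1, 1), extraction_profile()),
        msk, c(1, 1, 1), extraction_profile())
    }
    cache
  }
})

#' Mann-Whitney U filter with training z-scoring
#'
#' Retains features whose two-sided Mann-Whitney test (normal approximation
#' with tie correction) gives p < alpha, then z-scores the retained columns
#' using the training rows' statistics.
#'
#' @param table numeric matrix or `feature_table` (cases x features).
#' @param labels binary vector, one per row.
#' @param alpha retention threshold.
#' @return list with `table` (z-scored retained columns), `kept` names,
#'   `p` (all p-values), `center`, `scale`.
#' @export
utest_filter <- function(table, labels, alpha = 0.05) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes required")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L); n <- n1 + n0
  p <- apply(table, 2, function(x) {
    r <- rank(x)
    u <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
    ties <- tabulate(match(x, x))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    s2 <- n1 * n0 / 12 * ((n + 1) - tie_term)
    if (s2 <= 0) return(1)
    z <- (u - n1 * n0 / 2) / sqrt(s2)
    2 * pnorm(-abs(z))
  })
  kept <- colnames(table)[p < alpha]
  sub <- table[, kept, drop = FALSE]
  ctr <- colMeans(sub)
  scl <- apply(sub, 2, sd)
  scl[scl == 0] <- 1
  structure(list(table = scale(sub, ctr, scl), kept = kept, p = p,
                 center = ctr, scale = scl), class = "utest_filter")
}

# Mutual information between two equal-frequency-binned variables.
bin_ef <- function(x, nbins) {
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = nbins + 1), type = 7))
  if (length(qs) < 2) return(rep(1L, length(x)))
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

mi_disc <- function(a, b) {
  a <- as.integer(a) - min(as.integer(a)) + 1L
  b <- as.integer(b) - min(as.integer(b)) + 1L
  ka <- max(a); kb <- max(b)
  p <- matrix(tabulate(a + ka * (b - 1L), ka * kb), ka, kb) / length(a)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection maximizing `MI(feature; label) - mean MI(feature;
#' selected)` with mutual information estimated on equal-frequency binned
#' features (default 8 bins). Ties break deterministically by column order.
#'
#' @param table numeric matrix (cases x features).
#' @param labels binary labels.
#' @param m number of features to select (capped at the column count).
#' @param nbins equal-frequency bin count for the MI estimator.
#' @param quotient use the relevance/redundancy quotient instead of the
#'   difference criterion.
#' @return Character vector of `m` selected feature names, in order.
#' @export
mrmr_select <- function(table, labels, m = 30L, nbins = 8L, quotient = FALSE) {
  if (m <= 0) stop("m must be positive")
  m <- min(m, ncol(table))
  binned <- apply(table, 2, bin_ef, nbins = nbins)
  y <- as.integer(labels)
  rel <- apply(binned, 2, mi_disc, b = y)
  selected <- integer(0)
  red_sum <- rep(0, ncol(table))
  for (step in seq_len(m)) {
    if (step == 1L) {
      score <- rel
    } else {
      red_sum <- red_sum + apply(binned, 2, mi_disc, b = binned[, selected[step - 1L]])
      score <- if (quotient) rel / (red_sum / (step - 1L) + 1e-12)
      else rel - red_sum / (step - 1L)
    }
    score[selected] <- -Inf
    selected <- c(selected, which.max(score)) # which.max: first index on ties
  }
  colnames(table)[selected]
}

#' LASSO feature selection with stratified cross-validation
#'
#' L1-penalized logistic regression over glmnet's log-spaced lambda grid;
#' lambda is chosen by stratified 5-fold cross-validation minimizing binomial
#' deviance and the final set is the features with nonzero coefficients at
#' the chosen lambda.
#'
#' @param table numeric matrix (cases x features), typically z-scored.
#' @param labels binary labels.
#' @param folds CV fold count.
#' @param seed integer seed for the fold assignment.
#' @return A `selected_feature_set`: `features`, `lambda`, `coefficients`
#'   (including intercept), plus the fitted glmnet object.
#' @export
lasso_select <- function(table, labels, folds = 5L, seed = 1L) {
  if (ncol(table) < 2L) stop("need at least 2 features")
  y <- as.integer(labels)
  foldid <- stratified_folds(y, folds, derive_seed(seed, "lasso"))
  cv <- glmnet::cv.glmnet(table, y, family = "binomial", foldid = foldid,
                          type.measure = "deviance", standardize = FALSE)
  cf <- coef(cv, s = "lambda.min")
  nz <- rownames(cf)[which(as.numeric(cf) != 0)]
  nz <- setdiff(nz, "(Intercept)")
  structure(list(features = nz, lambda = cv$lambda.min,
                 coefficients = setNames(as.numeric(cf), rownames(cf)),
                 cv = cv), class = "selected_feature_set")
}

#' Run the full U-test, mRMR, LASSO cascade
#'
#' @inheritParams utest_filter
#' @param m_mrmr features retained by mRMR.
#' @param alpha U-test threshold.
#' @param seed seed for the LASSO fold assignment.
#' @return list with the `utest` filter object, `mrmr` names, `lasso`
#'   selection and `features` (the final set).
#' @export
select_features <- function(table, labels, alpha = 0.05, m_mrmr = 30L,
                            seed = 1L) {
  ut <- utest_filter(table, labels, alpha)
  if (length(ut$kept) < 2L)
    return(list(utest = ut, mrmr = ut$kept, features = ut$kept, lasso = NULL))
  mr <- mrmr_select(ut$table, labels, m = m_mrmr)
  ls <- lasso_select(ut$table[, mr, drop = FALSE], labels, seed = seed)
  list(utest = ut, mrmr = mr, lasso = ls, features = ls$features)
}

# ---- classifiers -----------------------------------------------------------

cv_grid_auc <- function(X, y, grid, fit_fun, pred_fun, folds, seed) {
  foldid <- stratified_folds(y, folds, seed)
  oofs <- matrix(NA_real_, length(y), nrow(grid))
  aucs <- vapply(seq_len(nrow(grid)), function(g) {
    oof <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- foldid != f
      fit <- fit_fun(X[tr, , drop = FALSE], y[tr], grid[g, , drop = FALSE])
      oof[!tr] <- pred_fun(fit, X[!tr, , drop = FALSE])
    }
    oofs[, g] <<- oof
    auc_rank(oof, y)
  }, 0)
  list(best = which.max(aucs), aucs = aucs, foldid = foldid,
       oof = oofs[, which.max(aucs)])
}

#' Fit one of the five radiomics classifiers with grid-searched CV
#'
#' Hyperparameters are tuned by mean stratified 5-fold cross-validated AUC
#' on the training rows only, then the best configuration is refit on the
#' full training set. Algorithms: logistic regression (`LR`, elastic-net
#' grid), random forest (`RF`), gradient-boosted trees (`XGB`), k-nearest
#' neighbors (`KNN`) and Gaussian naive Bayes (`GNB`).
#'
#' @param X numeric matrix of selected (z-scored) features.
#' @param y binary labels.
#' @param algo one of `"LR"`, `"RF"`, `"XGB"`, `"KNN"`, `"GNB"`.
#' @param folds CV folds.
#' @param seed seed controlling folds and stochastic learners.
#' @return A `radiomics_classifier` with a [predict_proba()] method; carries
#'   the CV report (per-config AUCs and chosen config).
#' @export
fit_radiomics_classifier <- function(X, y, algo = c("LR", "RF", "XGB", "KNN", "GNB"),
                                     folds = 5L, seed = 1L) {
  algo <- match.arg(algo)
  y <- as.integer(y)
  if (min(table(y)) < folds) stop("too few cases per class for 5-fold CV")
  spec <- switch(algo,
    LR = list(
      grid = expand.grid(alpha = c(0, 0.5, 1), lambda = 10^seq(-4, 1, 1)),
      fit = function(X, y, g) glmnet::glmnet(X, y, family = "binomial",
                                             alpha = g$alpha, lambda = g$lambda,
                                             standardize = FALSE),
      pred = function(fit, X) as.numeric(predict(fit, X, type = "response"))),
    RF = list(
      grid = expand.grid(mtry_frac = c(0.33, 0.6, 1), min_node = c(1, 3, 5)),
      fit = function(X, y, g) {
        ranger::ranger(x = X, y = factor(y, levels = 0:1), probability = TRUE,
                       num.trees = 300,
                       mtry = max(1L, floor(g$mtry_frac * ncol(X))),
                       min.node.size = g$min_node, seed = seed)
      },
      pred = function(fit, X) predict(fit, X)$predictions[, "1"]),
    XGB = list(
      grid = expand.grid(max_depth = c(2, 3), eta = c(0.1, 0.3),
                         nrounds = c(50, 150)),
      fit = function(X, y, g) xgboost::xgboost(
        X, factor(y, levels = 0:1), max_depth = g$max_depth,
        learning_rate = g$eta, nrounds = g$nrounds, nthread = 1,
        verbosity = 0),
      pred = function(fit, X) as.numeric(predict(fit, X))),
    KNN = list(
      grid = data.frame(k = c(3, 5, 7, 9, 11)),
      fit = function(X, y, g) list(X = X, y = y, k = g$k),
      pred = function(fit, X) {
        k <- min(fit$k, nrow(fit$X))
        pr <- class::knn(fit$X, X, factor(fit$y, levels = 0:1), k = k,
                         prob = TRUE, use.all = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "1", p, 1 - p)
      }),
    GNB = list(
      grid = data.frame(laplace = 0),
      fit = function(X, y, g) e1071::naiveBayes(
        x = as.data.frame(X), y = factor(y, levels = 0:1)),
      pred = function(fit, X) predict(fit, as.data.frame(X), type = "raw")[, "1"]))
  cvres <- cv_grid_auc(X, y, spec$grid, spec$fit, spec$pred, folds,
                       derive_seed(seed, paste0("cls", algo)))
  best <- spec$grid[cvres$best, , drop = FALSE]
  set.seed(derive_seed(seed, paste0("fit", algo)))
  final <- spec$fit(X, y, best)
  structure(list(algo = algo, model = final, config = best,
                 cv_auc = cvres$aucs[cvres$best], oof = cvres$oof,
                 cv_report = cvres[c("aucs", "foldid")],
                 features = colnames(X), pred_fun = spec$pred),
            class = "radiomics_classifier")
}

#' Predicted probabilities from a fitted branch model
#'
#' @param object a fitted model from this package.
#' @param newdata input appropriate to the model.
#' @param ... unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(object, newdata, ...) UseMethod("predict_proba")

#' @export
predict_proba.radiomics_classifier <- function(object, newdata, ...) {
  if (!all(object$features %in% colnames(newdata)))
    stop("feature name mismatch at prediction time")
  object$pred_fun(object$model, newdata[, object$features, drop = FALSE])
}

#' Bootstrap stability of the selection cascade
#'
#' Reruns the full U-test, mRMR, LASSO cascade on `B` bootstrap resamples of
#' the training rows and reports the frequency with which each feature of
#' the original final set is re-selected. Single-class resamples are redrawn
#' (and counted).
#'
#' @inheritParams select_features
#' @param B number of bootstrap resamples (>= 50).
#' @return list: `frequency` (named, for the original final set), `counts`
#'   over all ever-selected features, `redrawn`.
#' @export
stability_bootstrap <- function(table, labels, B = 100L, alpha = 0.05,
                                m_mrmr = 30L, seed = 1L) {
  if (B < 50L) stop("B must be >= 50")
  base <- select_features(table, labels, alpha, m_mrmr, seed)
  counts <- integer(0)
  redrawn <- 0L
  set.seed(derive_seed(seed, "stability"))
  for (b in seq_len(B)) {
    repeat {
      idx <- sample(nrow(table), replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
      redrawn <- redrawn + 1L
    }
    sel <- tryCatch(
      select_features(table[idx, , drop = FALSE], labels[idx], alpha, m_mrmr,
                      seed = seed + b)$features,
      error = function(e) character(0))
    for (f in sel) counts[f] <- (if (is.na(counts[f])) 0L else counts[f]) + 1L
  }
  freq <- setNames(numeric(length(base$features)), base$features)
  for (f in base$features) freq[f] <- (if (is.na(counts[f])) 0 else counts[f]) / B
  list(frequency = freq, counts = counts / B, redrawn = redrawn,
       base_features = base$features)
}
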