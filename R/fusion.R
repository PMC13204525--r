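#' Decision-level fusion by stacking
#'
#' Trains a logistic meta-learner on the logit-transformed out-of-fold
#' branch probabilities (probabilities are clipped to `[1e-6, 1 - 1e-6]`
#' before the logit). The ridge-strength / class-weighting grid is tuned by
#' stratified 5-fold cross-validated AUC on training data only; the frozen
#' model is then applied unchanged to test-set probabilities.
#'
#' @param branch_probs named list of training probability vectors (one per
#'   branch, out-of-fold for honest stacking).
#' @param labels binary training labels.
#' @param folds CV folds.
#' @param seed fold seed.
#' @return A `meta_model` with a [predict_proba()] method and
#'   `coefficients` on the logit scale.
#' @export
stack_decision <- function(branch_probs, labels, folds = 5L, seed = 1L) {
  y <- as.integer(labels)
  X <- logit_matrix(branch_probs, length(y))
  grid <- expand.grid(lambda = c(0, 10^seq(-4, 0, 1)), balanced = c(FALSE, TRUE))
  fit_fun <- function(X, y, g) {
    w <- if (g$balanced) ifelse(y == 1L, 0.5 / mean(y), 0.5 / mean(1 - y))
    else rep(1, length(y))
    if (g$lambda == 0) {
      # separation and collinear branches are expected with strong inputs:
      # silence the convergence warnings, zero out aliased coefficients
      cf <- suppressWarnings(
        glm.fit(cbind(1, X), y, weights = w, family = binomial())$coefficients)
      cf[is.na(cf)] <- 0
      cf
    } else {
      fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                            lambda = g$lambda, weights = w, standardize = FALSE)
      as.numeric(coef(fit))
    }
  }
  pred_fun <- function(cf, X) as.numeric(plogis(cbind(1, X) %*% cf))
  cvres <- cv_grid_auc(X, y, grid, fit_fun, pred_fun, folds,
                       derive_seed(seed, "stack"))
  best <- grid[cvres$best, , drop = FALSE]
  cf <- fit_fun(X, y, best)
  names(cf) <- c("(Intercept)", colnames(X))
  structure(list(coefficients = cf, branches = colnames(X), config = best,
                 cv_auc = cvres$aucs[cvres$best]),
            class = "meta_model")
}

logit_matrix <- function(branch_probs, n) {
  if (is.null(names(branch_probs)) || any(names(branch_probs) == ""))
    stop("branch probabilities must be a named list")
  lens <- vapply(branch_probs, length, 0L)
  if (any(lens != n)) stop("missing branch probabilities for some cases")
  X <- vapply(branch_probs, function(p) logit(clip01(p)), numeric(n))
  if (is.null(dim(X))) X <- matrix(X, nrow = n)
  colnames(X) <- names(branch_probs)
  X
}

#' @export
predict_proba.meta_model <- function(object, newdata, ...) {
  if (!all(object$branches %in% names(newdata)))
    stop("missing branch: need ", paste(object$branches, collapse = ", "))
  X <- logit_matrix(newdata[object$branches], length(newdata[[1]]))
  as.numeric(plogis(cbind(1, X) %*% object$coefficients))
}

#' Feature-level fusion network training
#'
#' Extends the deep architecture with a zero-initialized learnable linear
#' projection from the selected (training-z-scored) radiomic features to the
#' pooled-representation width; the projected vector is added element-wise
#' (residual) to the pooled network representation and the whole network is
#' retrained end-to-end with the deep branch's training procedure. Because
#' the projection starts at zero, the initial forward pass equals the
#' image-only network exactly.
#'
#' @param tensors list of `tensor_case` (training cases).
#' @param features (cases x selected features) matrix, z-scored with
#'   training statistics.
#' @param labels binary labels.
#' @param config a [model_config].
#' @return A `fusion_model`: trained `deep_model` plus `feature_names`.
#' @export
feature_fusion_train <- function(tensors, features, labels, config) {
  features <- as.matrix(features)
  model <- add_fusion_projection(build_model(config), ncol(features))
  fit <- train_deep(prepare_many(tensors), as.integer(labels), config,
                    R = features, model = model)
  structure(list(model = fit, feature_names = colnames(features),
                 config = config), class = "fusion_model")
}

#' @export
predict_proba.fusion_model <- function(object, newdata, features, ...) {
  features <- as.matrix(features)
  if (!is.null(object$feature_names) &&
      !identical(colnames(features), object$feature_names))
    stop("feature name mismatch vs. fitted projection")
  predict_proba(object$model, newdata, R = features)
}

#' Predict from a fusion artifact
#'
#' Thin dispatcher: a `meta_model` takes a named list of branch
#' probabilities; a `fusion_model` takes tensors plus the z-scored selected
#' feature matrix.
#'
#' @param object a `meta_model` or `fusion_model`.
#' @param ... passed to the matching [predict_proba()] method.
#' @return Probability vector.
#' @export
predict_fused <- function(object, ...) predict_proba(object, ...)
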