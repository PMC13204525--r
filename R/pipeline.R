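#' Apply a fitted U-test filter's z-scoring to new cases
#'
#' @param ut a [utest_filter] result fitted on training rows.
#' @param table feature matrix for new cases (full column set).
#' @return z-scored matrix restricted to the retained columns.
#' @export
transform_features <- function(ut, table) {
  if (!all(ut$kept %in% colnames(table))) stop("missing feature columns")
  scale(table[, ut$kept, drop = FALSE], ut$center, ut$scale)
}

#' Run the full fusion pipeline on a cohort
#'
#' End-to-end orchestration: habitat segmentation, radiomic feature bank,
#' U-test / mRMR / LASSO selection, the requested classical classifiers,
#' the deep branch with 5-fold configuration selection, the single-slice
#' ITH model, the clinical baseline, and decision- plus feature-level
#' fusion. Everything statistical is fitted on the `train` partition only;
#' `test1` / `test2` rows are never consulted during selection or tuning.
#'
#' @param cohort a [generate_cohort] result (or any list with `cases`,
#'   `split`, `clinical` of the same shape).
#' @param seed global pipeline seed (fans out per stage).
#' @param deep_configs list of [model_config] candidates for the deep
#'   branch.
#' @param radiomics_algos classical classifiers to fit; the one with the
#'   best cross-validated AUC feeds the fusion stages.
#' @param branches subset of
#'   `c("radiomics", "deep", "ith", "clinical", "fusion")` to run.
#' @param alpha,m_mrmr selection-cascade settings.
#' @param ith_k fixed ITH cluster count (`NULL`: silhouette selection).
#' @return A `dpet_pipeline` list: `predictions` (long data frame with
#'   `case_id`, `partition`, `label`, `branch`, `prob`), fitted models,
#'   and the selection report.
#' @export
run_pipeline <- function(cohort, seed = 1L,
                         deep_configs = default_configs(seed),
                         radiomics_algos = c("LR", "RF", "XGB", "KNN", "GNB"),
                         branches = c("radiomics", "deep", "ith", "clinical",
                                      "fusion"),
                         alpha = 0.05, m_mrmr = 30L, ith_k = NULL) {
  split <- cohort$split
  tr <- split$partition == "train"
  y_tr <- split$label[tr]
  out <- list(split = split, seed = seed)
  preds <- list()
  add_pred <- function(branch, prob, oof = NULL) {
    df <- data.frame(case_id = split$case_id, partition = split$partition,
                     label = split$label, branch = branch, prob = prob)
    if (!is.null(oof)) df$prob[tr] <- oof
    preds[[branch]] <<- df
  }

  if (any(c("radiomics", "fusion") %in% branches)) {
    log_msg("habitat segmentation + feature extraction")
    habs <- lapply(cohort$cases, function(cs)
      segment_habitats(cs$volume, cs$mask, seed = derive_seed(seed, "hab")))
    tab <- build_feature_table(cohort$cases, habs)
    out$habitats <- habs
    out$selection <- select_features(tab[tr, , drop = FALSE], y_tr,
                                     alpha = alpha, m_mrmr = m_mrmr,
                                     seed = derive_seed(seed, "sel"))
    Xall <- transform_features(out$selection$utest, tab)
    sel <- out$selection$features
    if (length(sel) < 1L) {
      # LASSO shrank everything away: fall back to the top mRMR features
      sel <- head(out$selection$mrmr, 5L)
      out$selection$fallback <- TRUE
    }
    Xsel <- Xall[, sel, drop = FALSE]
    out$feature_table <- tab
    out$selected_matrix <- Xsel
    log_msg("radiomics classifiers: ", paste(radiomics_algos, collapse = ", "))
    out$radiomics_models <- lapply(radiomics_algos, function(a)
      fit_radiomics_classifier(Xsel[tr, , drop = FALSE], y_tr, algo = a,
                               seed = derive_seed(seed, "cls")))
    names(out$radiomics_models) <- radiomics_algos
    cvs <- vapply(out$radiomics_models, `[[`, 0, "cv_auc")
    out$radiomics_best <- radiomics_algos[which.max(cvs)]
    best <- out$radiomics_models[[out$radiomics_best]]
    add_pred("radiomics", predict_proba(best, Xsel), oof = best$oof)
  }

  tensors <- NULL
  if (any(c("deep", "fusion") %in% branches)) {
    log_msg("deep branch (", length(deep_configs), " config(s), 5-fold CV)")
    tensors <- lapply(cohort$cases, function(cs) tensorize(cs$volume, cs$mask))
    prepared <- prepare_many(tensors)
    out$deep <- cv_select_and_train(prepared[tr], y_tr, configs = deep_configs,
                                    seed = derive_seed(seed, "deep"))
    add_pred("deep", predict_proba(out$deep$model, prepared),
             oof = out$deep$oof)
  }

  if ("ith" %in% branches) {
    log_msg("ITH branch")
    out$ith_scores <- vapply(cohort$cases, function(cs)
      compute_ith(cs$volume, cs$mask, k = ith_k,
                  seed = derive_seed(seed, "ith"))$score, 0)
    out$ith_model <- fit_ith_model(out$ith_scores[tr], y_tr)
    add_pred("ith", as.numeric(plogis(cbind(1, out$ith_scores) %*%
                                        coef(out$ith_model$model))))
  }

  if ("clinical" %in% branches) {
    log_msg("clinical baseline")
    out$clinical_model <- baseline_clinical_model(
      cohort$clinical[tr, , drop = FALSE], y_tr,
      seed = derive_seed(seed, "clin"))
    add_pred("clinical", predict_proba(out$clinical_model, cohort$clinical))
  }

  if ("fusion" %in% branches) {
    log_msg("decision- and feature-level fusion")
    out$meta <- stack_decision(
      list(deep = preds$deep$prob[tr], radiomics = preds$radiomics$prob[tr]),
      y_tr, seed = derive_seed(seed, "meta"))
    fused <- predict_proba(out$meta, list(deep = preds$deep$prob,
                                          radiomics = preds$radiomics$prob))
    add_pred("decision_fusion", fused)
    out$feature_fusion <- feature_fusion_train(
      tensors[tr], out$selected_matrix[tr, , drop = FALSE], y_tr,
      out$deep$config)
    add_pred("feature_fusion",
             predict_proba(out$feature_fusion, prepare_many(tensors),
                           features = out$selected_matrix))
  }

  out$predictions <- do.call(rbind, preds)
  rownames(out$predictions) <- NULL
  structure(out, class = "dpet_pipeline")
}

#' @export
print.dpet_pipeline <- function(x, ...) {
  cat("<dpet_pipeline> branches:",
      paste(unique(x$predictions$branch), collapse = ", "), "\n")
  for (b in unique(x$predictions$branch))
    for (p in c("test1", "test2")) {
      a <- tryCatch(branch_auc(x, b, p), error = function(e) NA)
      if (!is.na(a)) cat(sprintf("  %-16s %-6s AUC %.3f\n", b, p, a))
    }
  invisible(x)
}

#' AUC of one branch on one partition
#'
#' @param pipeline a [run_pipeline] result.
#' @param branch branch name.
#' @param partition `"train"`, `"test1"` or `"test2"`.
#' @export
branch_auc <- function(pipeline, branch, partition = "test1") {
  d <- pipeline$predictions
  d <- d[d$branch == branch & d$partition == partition, ]
  if (nrow(d) == 0L) stop("no predictions for ", branch, "/", partition)
  auc_rank(d$prob, d$label)
}
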