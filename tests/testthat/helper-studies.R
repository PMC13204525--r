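# Simulation-study helpers used by the acceptance suite.

# Complementary-signal study conditions: coarse-vs-fine texture with a
# core-rim contrast difference (the handcrafted-feature channel) plus a
# differing count of sharp high-uptake foci (the image-model channel).
complementary_config <- function() {
  generator_config(texture_granularity_by_label = c(6, 2),
                   rim_core_contrast_by_label = c(1.4, 2.2),
                   fragmentation_by_label = c(1L, 6L),
                   focus_amplitude = 2, focus_sigma = 1.8)
}

# Null study conditions: identical per-class imaging parameters and zero
# clinical effects, so no branch has anything to learn.
null_config <- function() {
  generator_config(texture_granularity_by_label = c(4, 4),
                   rim_core_contrast_by_label = c(1.8, 1.8),
                   fragmentation_by_label = c(2L, 2L),
                   clinical_effects = c(age = 0, ki67 = 0, cT = 0, cN = 0,
                                        grade = 0, regimen = 0, suvmax = 0))
}

make_labeled_set <- function(n, seed, cfg, prevalence = 0.5) {
  set.seed(seed)
  labs <- rbinom(n, 1L, prevalence)
  # guard against a degenerate draw in small sets
  if (length(unique(labs)) < 2L) labs[1:2] <- c(0L, 1L)
  cases <- lapply(seq_len(n), function(i)
    generate_case(cfg, labs[i], seed = seed * 1000L + i))
  list(cases = cases, y = labs)
}

acceptance_deep_config <- function(seed) {
  model_config("vit3d", heads = 2L, epochs = 10L, lr = 3e-3, batch = 24L,
               seed = seed)
}

# One seed of the recovery / complementarity study: 120 training and 300
# held-out cases under the complementary configuration; returns test AUCs of
# both branches and both fusion modes, plus the deep branch's out-of-fold AUC.
run_complementary_seed <- function(seed, cfg = complementary_config(),
                                   n_train = 120L, n_test = 300L) {
  tr <- make_labeled_set(n_train, seed * 17L + 1L, cfg)
  te <- make_labeled_set(n_test, seed * 17L + 2L, cfg)
  habs_tr <- lapply(tr$cases, function(cs) segment_habitats(cs$volume, cs$mask))
  habs_te <- lapply(te$cases, function(cs) segment_habitats(cs$volume, cs$mask))
  tab_tr <- build_feature_table(tr$cases, habs_tr)
  tab_te <- build_feature_table(te$cases, habs_te)
  sel <- select_features(tab_tr, tr$y, seed = seed)
  feats <- sel$features
  if (length(feats) < 1L) feats <- head(sel$mrmr, 5L)
  Xtr <- transform_features(sel$utest, tab_tr)[, feats, drop = FALSE]
  Xte <- transform_features(sel$utest, tab_te)[, feats, drop = FALSE]
  rad <- fit_radiomics_classifier(Xtr, tr$y, "LR", seed = seed)
  p_rad <- predict_proba(rad, Xte)
  ttr <- lapply(tr$cases, function(cs) tensorize(cs$volume, cs$mask))
  tte <- lapply(te$cases, function(cs) tensorize(cs$volume, cs$mask))
  ptr <- prepare_many(ttr); pte <- prepare_many(tte)
  dp <- cv_select_and_train(ptr, tr$y,
                            configs = list(acceptance_deep_config(seed)),
                            seed = seed)
  p_deep <- predict_proba(dp$model, pte)
  meta <- stack_decision(list(deep = dp$oof, radiomics = rad$oof), tr$y,
                         seed = seed)
  p_dec <- predict_proba(meta, list(deep = p_deep, radiomics = p_rad))
  ff <- feature_fusion_train(ttr, Xtr, tr$y, dp$config)
  p_ff <- predict_proba(ff, pte, features = Xte)
  list(radiomics = auc_rank(p_rad, te$y),
       radiomics_200 = auc_rank(p_rad[1:200], te$y[1:200]),
       deep = auc_rank(p_deep, te$y),
       deep_oof = auc_rank(dp$oof, tr$y),
       decision_fusion = auc_rank(p_dec, te$y),
       feature_fusion = auc_rank(p_ff, te$y),
       n_features = length(feats))
}

# Null study: every branch trained under the no-signal configuration and
# evaluated on held-out cases.
run_null_study <- function(seed = 1L, n_train = 100L, n_test = 400L) {
  cfg <- null_config()
  tr <- make_labeled_set(n_train, seed * 31L + 1L, cfg)
  te <- make_labeled_set(n_test, seed * 31L + 2L, cfg)
  habs_tr <- lapply(tr$cases, function(cs) segment_habitats(cs$volume, cs$mask))
  habs_te <- lapply(te$cases, function(cs) segment_habitats(cs$volume, cs$mask))
  tab_tr <- build_feature_table(tr$cases, habs_tr)
  tab_te <- build_feature_table(te$cases, habs_te)
  sel <- select_features(tab_tr, tr$y, seed = seed)
  feats <- if (length(sel$features) >= 1L) sel$features else head(sel$mrmr, 5L)
  Xtr <- transform_features(sel$utest, tab_tr)[, feats, drop = FALSE]
  Xte <- transform_features(sel$utest, tab_te)[, feats, drop = FALSE]
  rad <- fit_radiomics_classifier(Xtr, tr$y, "LR", seed = seed)
  dp <- cv_select_and_train(prepare_many(lapply(tr$cases, function(cs)
    tensorize(cs$volume, cs$mask))), tr$y,
    configs = list(acceptance_deep_config(seed)), seed = seed)
  pte <- prepare_many(lapply(te$cases, function(cs)
    tensorize(cs$volume, cs$mask)))
  ith_tr <- vapply(tr$cases, function(cs)
    compute_ith(cs$volume, cs$mask, seed = seed)$score, 0)
  ith_te <- vapply(te$cases, function(cs)
    compute_ith(cs$volume, cs$mask, seed = seed)$score, 0)
  clin_tr <- do.call(rbind, lapply(tr$cases, `[[`, "clinical"))
  clin_te <- do.call(rbind, lapply(te$cases, `[[`, "clinical"))
  clin <- baseline_clinical_model(clin_tr, tr$y, seed = seed)
  list(radiomics = auc_rank(predict_proba(rad, Xte), te$y),
       deep = auc_rank(predict_proba(dp$model, pte), te$y),
       ith = auc_rank(ith_te, te$y),
       clinical = auc_rank(predict_proba(clin, clin_te), te$y))
}
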