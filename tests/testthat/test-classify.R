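test_that("the default combination catalogue is the 3 x 5 product", {
  cat <- enumerate_combinations()
  expect_equal(nrow(cat), 15)
  r_post <- cat$features[[which(cat$scope == "R" &
                                  cat$family_set == "posterior_activity")]]
  expect_setequal(r_post, c("iaf_posterior_R", "amp_posterior_R"))
  for (i in which(cat$scope == "R"))
    expect_false(any(grepl("_L$", cat$features[[i]])))
  inter_rows <- vapply(cat$features,
                       function(f) any(grepl("inter", f)), logical(1))
  expect_equal(sort(unique(cat$family_set[inter_rows])),
               "all_activity_intra_inter")
  expect_error(enumerate_combinations(scopes = character(0)), "empty")
})

test_that("classification metrics implement their definitions", {
  m <- classification_metrics(3, 0, 2, 0)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$balanced_accuracy, 1)
  # printed-value consistency: BA is the mean of sens and spec
  expect_equal((78.8 + 69.7) / 2, 74.25)
  m2 <- classification_metrics(2, 1, 1, 2,
                               scores = rep(0.5, 6),
                               truth = c("HSG", "HSG", "HSG",
                                         "LSG", "LSG", "LSG"))
  expect_equal(m2$auc, 0.5)  # all ties
  expect_equal(m2$balanced_accuracy,
               (m2$sensitivity + m2$specificity) / 2)
  m3 <- classification_metrics(0, 0, 3, 1)
  expect_true(is.na(m3$sensitivity))
})

test_that("ROC aggregation averages vertically with anchors", {
  # deterministic step curves: TPR tpr_mid at FPR 0.5, rising to 1
  # only at FPR 1 (both negatives score between the two positive bands)
  mk <- function(tpr_mid) {
    n_pos <- 5
    pos_high <- round(tpr_mid * n_pos)
    scores <- c(rep(5, pos_high), rep(1, n_pos - pos_high), 3, 2)
    truth <- c(rep("HSG", n_pos), "LSG", "LSG")
    list(scores = scores, truth = truth)
  }
  agg <- aggregate_roc(list(mk(0.2), mk(0.8)))
  at_half <- agg[abs(agg$fpr - 0.5) < 1e-9, ]
  expect_equal(at_half$tpr_mean, 0.5)
  expect_equal(at_half$tpr_sd, stats::sd(c(0.2, 0.8)), tolerance = 1e-9)
  expect_equal(agg$tpr_mean[1], 0.5)  # (0.2 + 0.8) / 2 at FPR 0
  expect_equal(agg$tpr_mean[nrow(agg)], 1)
  # identical folds give a zero-width band
  agg0 <- aggregate_roc(list(mk(0.6), mk(0.6)))
  expect_true(all(agg0$tpr_sd == 0))
})

test_that("nested CV is perfect on separable clusters and reproducible", {
  feats <- synthetic_feature_table(n_per_group = 12, delta = 30,
                                   right_only = FALSE, seed = 51)
  rep1 <- nested_cv(feats, n_repeats = 2, k_inner = 5, seed = 7)
  expect_equal(rep1$summary$mean[rep1$summary$metric == "balanced_accuracy"],
               1)
  expect_equal(rep1$summary$mean[rep1$summary$metric == "auc"], 1)
  # mean ROC of separable folds passes through (0, 1)
  expect_equal(rep1$roc$tpr_mean[1], 1)
  expect_equal(rep1$roc$tpr_mean[2], 1)
  rep2 <- nested_cv(feats, n_repeats = 2, k_inner = 5, seed = 7)
  expect_identical(rep1$folds$combination, rep2$folds$combination)
  expect_identical(rep1$summary, rep2$summary)
  rep3 <- nested_cv(feats, n_repeats = 2, k_inner = 5, seed = 8)
  expect_false(identical(rep1$folds$test_idx, rep3$folds$test_idx))
})

test_that("selection frequencies are a normalised ranking", {
  feats <- synthetic_feature_table(n_per_group = 12, delta = 3,
                                   right_only = TRUE, seed = 52)
  rep <- nested_cv(feats, n_repeats = 2, k_inner = 5, seed = 9)
  rk <- ranking_report(rep)
  expect_equal(sum(rk$frequency_pct), 100, tolerance = 1e-9)
  expect_true(all(rk$frequency_pct >= 0))
  expect_true(all(diff(rk$frequency_pct) <= 0))
  # single-combination grid concentrates all selections
  grid1 <- default_search_grid(
    enumerate_combinations(scopes = "R", family_sets = "posterior_activity"))
  rep1 <- nested_cv(feats, grid = grid1, n_repeats = 1, k_inner = 5, seed = 9)
  expect_equal(rep1$selection$frequency_pct[1], 100)
})

test_that("right-hemisphere-only effects steer selection to right-only sets", {
  feats <- synthetic_feature_table(n_per_group = 24, delta = 2.2,
                                   right_only = TRUE, seed = 53)
  rep <- nested_cv(feats, n_repeats = 4, k_inner = 5, seed = 10)
  sel <- rep$selection
  right <- sum(sel$frequency_pct[sel$scope == "R"])
  left <- sum(sel$frequency_pct[sel$scope == "L"])
  expect_gt(right, left)
})

test_that("permuted labels keep balanced accuracy inside the null band", {
  # label permutation of a fixed finite table couples train and test
  # associations negatively, so single-permutation CV accuracy sits at
  # or below chance; the mean over permutations must stay within three
  # null-distribution SDs of 0.5
  feats <- synthetic_feature_table(n_per_group = 24, delta = 2,
                                   right_only = TRUE, seed = 54)
  set.seed(55)
  ba <- vapply(1:6, function(i) {
    pf <- feats
    pf$group <- sample(pf$group)
    run <- nested_cv(pf, n_repeats = 1, k_inner = 5, seed = 10 + i)
    mean(run$repetitions$balanced_accuracy)
  }, numeric(1))
  expect_lt(abs(mean(ba) - 0.5), 3 * stats::sd(ba))
  expect_lte(mean(ba), 0.62)  # never systematically above chance
})

test_that("outer-fold selection never peeks at the test fold", {
  feats <- synthetic_feature_table(n_per_group = 12, delta = 1.5,
                                   right_only = TRUE, seed = 56)
  base <- nested_cv(feats, n_repeats = 1, k_inner = 5, seed = 12)
  # corrupt the *feature values* (not labels) of fold 1's test subjects
  idx <- base$folds$test_idx[[1]]
  feats2 <- feats
  feats2[idx, alpha_feature_names()] <-
    matrix(1e6 * rnorm(length(idx) * 14), length(idx))
  mod <- nested_cv(feats2, n_repeats = 1, k_inner = 5, seed = 12)
  expect_identical(mod$folds$combination[1], base$folds$combination[1])
  expect_identical(mod$folds$family[1], base$folds$family[1])
  expect_identical(mod$folds$C[1], base$folds$C[1])
  # standardisation leakage guard: the scaler fitted for that fold is
  # computed from training rows only, so it must be unchanged too
  expect_equal(mod$folds$scaler[[1]], base$folds$scaler[[1]],
               tolerance = 1e-12)
})

test_that("degenerate inputs are rejected with clear errors", {
  feats <- synthetic_feature_table(n_per_group = 12, seed = 57)
  one_class <- feats[feats$group == "HSG", ]
  expect_error(nested_cv(one_class), "both classes")
  feats_na <- feats; feats_na$iaf_posterior_R[3] <- NA
  expect_error(nested_cv(feats_na), "missing")
  small <- feats[c(1:5, 13:17), ]
  expect_error(nested_cv(small, k_outer = 10), "k_outer")
})
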