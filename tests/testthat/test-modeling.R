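test_that("dynamic fold selection follows the five-per-fold rule", {
  expect_identical(choose_k(c(a = 15, b = 20)), 3L)
  expect_identical(choose_k(c(a = 9, b = 50)), NA_integer_)
  expect_identical(choose_k(c(a = 200, b = 300)), 10L)
  expect_identical(choose_k(c(a = 10, b = 10)), 2L)
  # brute-force table over the whole minority range
  for (n_min in 0:200) {
    want <- if (n_min < 10) NA_integer_ else min(n_min %/% 5L, 10L)
    expect_identical(choose_k(c(a = n_min, b = 300)), want)
  }
  # user override respected, but unfillable folds rejected
  expect_identical(choose_k(c(a = 31, b = 93), user_k = 10), 10L)
  expect_error(choose_k(c(a = 4, b = 50), user_k = 5), "unfillable")
})

test_that("stratified folds balance classes and are reproducible", {
  ids <- sprintf("s%02d", 1:35)
  labels <- stats::setNames(rep(c("a", "b"), c(15, 20)), ids)
  plan <- stratified_folds(labels, 3, seed = 1)
  for (f in 1:3) {
    test_ids <- names(plan$assignments)[plan$assignments == f]
    tab <- table(labels[test_ids])
    expect_identical(as.integer(tab["a"]), 5L)   # 15/3 exactly
    expect_gte(as.integer(tab["b"]), 6L)         # floor(20/3)
  }
  expect_identical(stratified_folds(labels, 3, seed = 1), plan)
  expect_false(identical(stratified_folds(labels, 3, seed = 2)$assignments,
                         plan$assignments))
  expect_error(stratified_folds(labels, 16, seed = 1), "at least k")
})

test_that("cross-validation is perfect on separable data", {
  sf <- separable_fm(n_per_class = 10, n_noise = 3, seed = 31)
  plan <- stratified_folds(sf$labels, 2, seed = 5)
  rep <- crossvalidate(sf$fm, sf$labels, plan,
                       forest_params = list(n_trees = 100), seed = 5)
  expect_equal(rep$mean$roc_auc, 1.0)
  expect_equal(rep$mean$accuracy, 1.0)
  expect_identical(nrow(rep$per_fold), 2L)
  # metric identities from the stored confusion counts
  pf <- rep$per_fold
  expect_equal(pf$accuracy, (pf$tp + pf$tn) / (pf$tp + pf$tn + pf$fp + pf$fn))
  expect_equal(pf$sensitivity, pf$tp / (pf$tp + pf$fn))
  expect_equal(pf$specificity, pf$tn / (pf$tn + pf$fp))
  expect_equal(pf$f1, 2 * pf$tp / (2 * pf$tp + pf$fp + pf$fn))
  expect_true(all(pf$roc_auc >= 0 & pf$roc_auc <= 1))
})

test_that("cross-validated AUC is near 0.5 under the null", {
  # scaled down from a 200-sample design for runtime: 30 + 30 samples,
  # 5 seeds, 50-tree forests
  aucs <- vapply(1:5, function(seed) {
    n <- 60
    vals <- mccims:::with_seed(400 + seed, matrix(stats::runif(n * 5), n))
    rownames(vals) <- sprintf("s%02d", 1:n)
    colnames(vals) <- sprintf("Peak_%04d", 1:5)
    labels <- stats::setNames(rep(c("a", "b"), each = n / 2), rownames(vals))
    fm <- new_feature_matrix(vals)
    plan <- stratified_folds(labels, 3, seed = seed)
    crossvalidate(fm, labels, plan, forest_params = list(n_trees = 50),
                  seed = seed)$mean$roc_auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("single-class test folds are rejected", {
  sf <- separable_fm(n_per_class = 4, n_noise = 2, seed = 41)
  plan <- stratified_folds(sf$labels, 2, seed = 1)
  # corrupt the plan: put every 'case' into fold 1
  plan$assignments[sf$labels == "case"] <- 1L
  plan$assignments[sf$labels == "control"] <- 2L
  expect_error(crossvalidate(sf$fm, sf$labels, plan, seed = 1),
               "single class")
})

test_that("best-method selection ranks by AUC, then accuracy, then name", {
  mk <- function(auc, acc) list(mean = list(roc_auc = auc, accuracy = acc))
  expect_identical(select_best_method(list(tophat = mk(0.8, 0.9),
                                           watershed = mk(0.95, 0.8))),
                   "watershed")
  expect_identical(select_best_method(list(b = mk(0.9, 0.8),
                                           a = mk(0.9, 0.9))), "a")
  expect_identical(select_best_method(list(b = mk(0.9, 0.8),
                                           a = mk(0.9, 0.8))), "a")
  expect_identical(select_best_method(list(only = mk(0.5, 0.5))), "only")
})

test_that("the stratified split uses floor arithmetic per class", {
  ids <- sprintf("s%02d", 1:42)
  labels <- stats::setNames(rep(c("citrus", "menthol"), c(20, 22)), ids)
  sp <- split_dataset(labels, 0.8, seed = 1)
  expect_identical(length(sp$train_ids), 16L + 17L)
  expect_identical(length(sp$validation_ids), 4L + 5L)
  tab <- table(labels[sp$train_ids])
  expect_identical(as.integer(tab[c("citrus", "menthol")]), c(16L, 17L))

  ids2 <- sprintf("t%03d", 1:128)
  labels2 <- stats::setNames(rep(c("COPD", "Control"), c(93, 35)), ids2)
  sp2 <- split_dataset(labels2, 0.9, seed = 1)
  tab2 <- table(labels2[sp2$train_ids])
  expect_identical(as.integer(tab2[c("COPD", "Control")]), c(83L, 31L))

  expect_identical(split_dataset(labels, 0.8, seed = 7),
                   split_dataset(labels, 0.8, seed = 7))
  expect_false(identical(split_dataset(labels, 0.8, seed = 8)$train_ids,
                         sp$train_ids))
  expect_error(split_dataset(labels, 0.01), "training members")
})

test_that("final training produces an interpretable self-contained bundle", {
  sf <- separable_fm(n_per_class = 8, n_noise = 4, seed = 51)
  scores <- score_features(sf$fm, sf$labels, n_trees = 100, seed = 2)
  top <- select_top(scores, 3, by = "gini")
  bundle <- train_final(sf$fm, sf$labels, top,
                        forest_params = list(n_trees = 100), seed = 2)
  # the separating feature heads the tree and splits perfectly
  expect_identical(bundle$peak_ids[bundle$tree$nodes$feature[1]],
                   "Peak_0001")
  expect_identical(mccims:::tree_depth(bundle$tree), 1L)
  # resubstitution predictions are perfect on separable data
  preds <- predict_bundle(bundle, fm = sf$fm)
  expect_identical(stats::setNames(preds$label, preds$sample_id),
                   sf$labels)

  # min_samples_leaf > n/2 -> single-leaf majority tree
  b2 <- train_final(sf$fm, sf$labels, top,
                    tree_params = list(min_samples_leaf = 12),
                    forest_params = list(n_trees = 50), seed = 2)
  expect_true(is.na(b2$tree$nodes$feature[1]))

  expect_error(train_final(sf$fm, sf$labels, character(0)), "empty")
  expect_error(train_final(sf$fm, sf$labels, "Peak_9999"), "absent")
})

test_that("bundles survive a save/load round-trip", {
  sf <- separable_fm(n_per_class = 6, n_noise = 3, seed = 61)
  scores <- score_features(sf$fm, sf$labels, n_trees = 60, seed = 3)
  bundle <- train_final(sf$fm, sf$labels, select_top(scores, 2),
                        forest_params = list(n_trees = 60), seed = 3)
  dir <- withr::local_tempdir()
  save_bundle(bundle, dir)
  expect_true(all(file.exists(file.path(
    dir, c("params.json", "forest.csv", "tree.csv", "tree.dot",
           "tree.txt")))))
  back <- load_bundle(dir)
  expect_identical(back$peak_ids, bundle$peak_ids)
  expect_identical(back$classes, bundle$classes)
  p1 <- predict_bundle(bundle, fm = sf$fm)
  p2 <- predict_bundle(back, fm = sf$fm)
  expect_equal(p1, p2)
})

test_that("prediction handles degenerate and incomplete inputs", {
  sf <- separable_fm(n_per_class = 6, n_noise = 2, seed = 71)
  scores <- score_features(sf$fm, sf$labels, n_trees = 60, seed = 1)
  bundle <- train_final(sf$fm, sf$labels, select_top(scores, 2),
                        forest_params = list(n_trees = 60), seed = 1)
  # feature-matrix input missing a required column -> filled 0, warned
  partial <- new_feature_matrix(
    sf$fm$values[, bundle$peak_ids[1], drop = FALSE])
  expect_warning(preds <- predict_bundle(bundle, fm = partial),
                 "missing columns")
  expect_identical(nrow(preds), length(sf$labels))
  # all-zero features -> a deterministic majority-style vote, still a label
  zero <- new_feature_matrix(
    matrix(0, 1, 2, dimnames = list("z", bundle$peak_ids)))
  pz <- predict_bundle(bundle, fm = zero)
  expect_true(pz$label %in% bundle$classes)
  expect_true(pz$prob_positive >= 0 && pz$prob_positive <= 1)
})

test_that("resubstitution reporting is flagged when CV is omitted", {
  sf <- separable_fm(n_per_class = 5, n_noise = 2, seed = 81)
  rep <- resubstitution_report(sf$fm, sf$labels,
                               forest_params = list(n_trees = 50), seed = 1)
  expect_true(rep$cv_omitted)
  expect_identical(rep$k, NA_integer_)
  expect_equal(rep$mean$accuracy, 1.0)
})
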