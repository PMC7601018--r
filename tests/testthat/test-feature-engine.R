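# Exhaustive per-column oracle for presence-based reduction.
brute_reduce_keep <- function(values, labels, min_intensity, pct) {
  classes <- sort(unique(labels))
  vapply(seq_len(ncol(values)), function(j) {
    any(vapply(classes, function(cl) {
      v <- values[labels == cl, j]
      mean(v >= min_intensity) >= pct / 100
    }, TRUE))
  }, TRUE)
}

test_that("feature reduction keeps class-conserved features", {
  # the illustrative thresholds: min intensity 0.3, percentage 30%
  vals <- rbind(a1 = c(0.4, 0.0, 0.9),
                a2 = c(0.4, 0.0, 0.9),
                a3 = c(0.0, 0.0, 0.9),
                b1 = c(0.0, 0.2, 0.9),
                b2 = c(0.0, 0.2, 0.9),
                b3 = c(0.0, 0.2, 0.9))
  colnames(vals) <- c("Peak_0001", "Peak_0002", "Peak_0003")
  labels <- stats::setNames(rep(c("a", "b"), each = 3), rownames(vals))
  fm <- new_feature_matrix(vals)
  red <- reduce_features(fm, labels, min_intensity = 0.3, pct_threshold = 30)
  # col 1: present in 2/3 of class a (>= 30%) -> kept;
  # col 2: 0.2 < 0.3 everywhere -> dropped; col 3: 100% of both -> kept
  expect_identical(red$peak_ids, c("Peak_0001", "Peak_0003"))
  # sub-threshold values in kept columns survive unchanged
  expect_equal(red$values["a3", "Peak_0001"], 0)
  # all-zero column dropped for any positive min intensity
  expect_false("Peak_0002" %in% red$peak_ids)
  # 100%-present feature kept at the maximum threshold
  red100 <- reduce_features(fm, labels, min_intensity = 0.3,
                            pct_threshold = 100)
  expect_true("Peak_0003" %in% red100$peak_ids)
})

test_that("feature reduction agrees with the exhaustive oracle", {
  for (case in 1:25) {
    vals <- mccims:::with_seed(100 + case, matrix(stats::runif(20 * 30), 20))
    rownames(vals) <- sprintf("s%02d", 1:20)
    colnames(vals) <- sprintf("Peak_%04d", 1:30)
    labels <- stats::setNames(rep(c("a", "b"), each = 10), rownames(vals))
    mi <- stats::runif(1)
    pct <- stats::runif(1, 0, 100)
    keep <- brute_reduce_keep(vals, labels, mi, pct)
    red <- suppressWarnings(
      reduce_features(new_feature_matrix(vals), labels, mi, pct))
    expect_identical(red$peak_ids, colnames(vals)[keep])
  }
})

test_that("Mann-Whitney p-values use the exact tail for small tie-free groups", {
  vals <- cbind(
    sep = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),   # complete separation
    same = rep(0.5, 10),
    mid = c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10)
  )
  rownames(vals) <- sprintf("s%02d", 1:10)
  colnames(vals) <- c("Peak_0001", "Peak_0002", "Peak_0003")
  labels <- stats::setNames(rep(c("a", "b"), each = 5), rownames(vals))
  p <- mwu_pvalues(new_feature_matrix(vals), labels)
  # exhaustive enumeration: 2 extreme splits of C(10,5) = 252
  expect_equal(p[1], 2 / 252)
  expect_equal(p[2], 1.0)
  # label swap leaves the two-sided p unchanged
  swapped <- stats::setNames(rep(c("b", "a"), each = 5), rownames(vals))
  expect_equal(mwu_pvalues(new_feature_matrix(vals), swapped), p)
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_error(bh_fdr(c(0.5, 1.5)), "\\[0, 1\\]")
  # oracle: the reference implementation, across random vectors
  for (seed in 1:10) {
    p <- mccims:::with_seed(seed, stats::runif(25))
    expect_equal(bh_fdr(p), stats::p.adjust(p, method = "BH"))
    # permutation invariance and monotonicity
    perm <- mccims:::with_seed(seed + 50, sample(length(p)))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
    expect_true(all(bh_fdr(p) >= p - 1e-15))
  }
})

test_that("Gini importance finds the separating feature and sums to one", {
  for (seed in c(1, 5, 9, 23, 77)) {
    sf <- separable_fm(n_per_class = 8, n_noise = 6, seed = seed)
    g <- gini_importance(sf$fm, sf$labels, n_trees = 150, seed = seed)
    expect_equal(sum(g), 1, tolerance = 1e-9)
    expect_identical(which.max(g), 1L)
  }
  # permuting sample order leaves the importance vector unchanged
  sf <- separable_fm(seed = 3)
  perm <- mccims:::with_seed(2, sample(length(sf$labels)))
  fm_perm <- new_feature_matrix(sf$fm$values[perm, ])
  g1 <- gini_importance(sf$fm, sf$labels, n_trees = 100, seed = 4)
  g2 <- gini_importance(fm_perm, sf$labels[perm], n_trees = 100, seed = 4)
  expect_identical(which.max(g1), which.max(g2))
})

test_that("top-n selection ranks deterministically with tie rules", {
  scores <- data.frame(
    peak_id = c("Peak_0002", "Peak_0001", "Peak_0003"),
    p_value = c(0.01, 0.01, 0.5),
    q_value = c(0.02, 0.02, 0.5),
    gini_decrease = c(0.5, 0.5, 0.1),
    stringsAsFactors = FALSE)
  scores$rank_mwu <- order(order(scores$q_value, -scores$gini_decrease,
                                 scores$peak_id))
  scores$rank_gini <- order(order(-scores$gini_decrease, scores$q_value,
                                  scores$peak_id))
  # equal gini and q: ordered by peak id
  expect_identical(select_top(scores, 2, by = "gini"),
                   c("Peak_0001", "Peak_0002"))
  expect_warning(all_ids <- select_top(scores, 10, by = "mwu"),
                 "returning all")
  expect_identical(length(all_ids), 3L)
  expect_error(select_top(scores, 0), "n must be")
})

test_that("score_features assembles consistent ranks and coordinates", {
  sf <- separable_fm(n_per_class = 6, n_noise = 4, seed = 2)
  sc <- score_features(sf$fm, sf$labels, n_trees = 100, seed = 1)
  expect_identical(sort(sc$rank_mwu), seq_len(nrow(sc)))
  expect_identical(sort(sc$rank_gini), seq_len(nrow(sc)))
  expect_true(all(sc$q_value >= sc$p_value - 1e-15))
  expect_identical(sc$peak_id[sc$rank_gini == 1], "Peak_0001")
  # significance decisions at the q < 0.05 cutoff
  expect_lt(sc$q_value[sc$peak_id == "Peak_0001"], 0.05)
})
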