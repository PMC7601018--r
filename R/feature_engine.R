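# Feature reduction and the two feature-scoring paths: Mann-Whitney U with
# Benjamini-Hochberg FDR correction, and random-forest mean decrease in
# Gini index.

#' Presence-based feature reduction
#'
#' A feature is "present" in a measurement when its intensity is at least
#' `min_intensity`.  A feature column is kept iff its presence fraction is
#' at least `pct_threshold` percent within class A **or** within class B.
#' Sub-threshold values in surviving columns are retained unchanged; the
#' intensity threshold only affects the presence test.
#'
#' @param fm a `mcc_feature_matrix`.
#' @param labels named character vector of class labels covering every
#'   sample in `fm`; exactly two classes.
#' @param min_intensity minimum intensity for a peak to count as present.
#' @param pct_threshold percentage in \[0, 100\] (default 50).
#' @return reduced `mcc_feature_matrix` (column order preserved); an empty
#'   result triggers a warning, not an error.
#' @export
reduce_features <- function(fm, labels, min_intensity = 0.01,
                            pct_threshold = 50) {
  labels <- labels[fm$sample_ids]
  if (anyNA(labels)) stop("labels missing for some samples")
  check_binary_labels(labels)
  classes <- sort(unique(labels))
  present <- fm$values >= min_intensity
  keep <- rep(FALSE, length(fm$peak_ids))
  for (cl in classes) {
    frac <- colMeans(present[labels == cl, , drop = FALSE])
    keep <- keep | frac >= pct_threshold / 100
  }
  if (!any(keep)) {
    warning("feature reduction removed every feature")
  }
  out <- fm_subset_cols(fm, keep)
  out$labels <- labels
  out$params <- c(fm$params, list(min_intensity = min_intensity,
                                  pct_threshold = pct_threshold))
  out
}

#' Mann-Whitney U p-values per feature
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test of the aligned peak
#' intensities between the two classes, per feature.  The exact null
#' distribution is used when both groups have at most `exact_max` samples
#' and the feature is tie-free; otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param fm a `mcc_feature_matrix`.
#' @param labels named character vector (two classes).
#' @param exact_max group-size bound for the exact distribution.
#' @return numeric vector of p-values, one per feature column.
#' @export
mwu_pvalues <- function(fm, labels, exact_max = 8) {
  labels <- labels[fm$sample_ids]
  check_binary_labels(labels)
  classes <- sort(unique(labels))
  ia <- labels == classes[1]
  ib <- labels == classes[2]
  vapply(seq_along(fm$peak_ids), function(j) {
    x <- fm$values[ia, j]
    y <- fm$values[ib, j]
    if (all(c(x, y) == c(x, y)[1])) return(1.0)  # constant feature
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                         correct = TRUE)$p.value
    )
  }, 0)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Random-forest mean decrease in Gini importance
#'
#' Trains a seeded random forest on the full feature matrix and returns the
#' per-feature mean decrease in Gini impurity, normalized to sum to 1.
#'
#' @param fm a `mcc_feature_matrix`.
#' @param labels named character vector (two classes, each with at least
#'   two samples).
#' @param n_trees number of trees.
#' @param seed RNG seed (default 42).
#' @return numeric vector of importances summing to 1.
#' @export
gini_importance <- function(fm, labels, n_trees = 500, seed = 42) {
  labels <- labels[fm$sample_ids]
  check_binary_labels(labels)
  if (min(table(labels)) < 2) stop("each class needs at least 2 samples")
  forest <- rf_train(fm$values, labels, n_trees = n_trees, seed = seed)
  imp <- forest$importance
  tot <- sum(imp)
  if (tot <= 0) return(rep(1 / length(imp), length(imp)))
  imp / tot
}

#' Score features with both rankings
#'
#' Computes Mann-Whitney p-values, BH q-values, Gini importances, and the
#' two deterministic rank orders.
#'
#' @param fm a reduced `mcc_feature_matrix`.
#' @param labels named character vector of class labels.
#' @param n_trees forest size for the Gini path.
#' @param seed RNG seed.
#' @return data.frame `peak_id, p_value, q_value, gini_decrease, rank_mwu,
#'   rank_gini, rt_center, irm_center`.
#' @export
score_features <- function(fm, labels, n_trees = 500, seed = 42) {
  p <- mwu_pvalues(fm, labels)
  q <- bh_fdr(p)
  g <- gini_importance(fm, labels, n_trees = n_trees, seed = seed)
  ids <- fm$peak_ids
  # mwu rank: ascending q, ties by descending gini then id;
  # gini rank: descending gini, ties by ascending q then id
  rank_mwu <- order(order(q, -g, ids))
  rank_gini <- order(order(-g, q, ids))
  data.frame(
    peak_id = ids, p_value = p, q_value = q, gini_decrease = g,
    rank_mwu = rank_mwu, rank_gini = rank_gini,
    rt_center = fm$coords$rt_center, irm_center = fm$coords$irm_center,
    stringsAsFactors = FALSE
  )
}

#' Select the top-n features of a ranking
#'
#' @param scores data.frame from [score_features()].
#' @param n number of features to keep.
#' @param by ranking to use: `"gini"` (descending importance) or `"mwu"`
#'   (ascending q-value). Ties are broken by the other criterion, then by
#'   peak id.
#' @return character vector of peak ids in rank order.
#' @export
select_top <- function(scores, n = 10, by = c("gini", "mwu")) {
  by <- match.arg(by)
  if (n < 1) stop("n must be >= 1")
  o <- if (by == "gini") {
    order(scores$rank_gini)
  } else {
    order(scores$rank_mwu)
  }
  if (n > nrow(scores)) {
    warning(sprintf("requested top %d of only %d features; returning all",
                    n, nrow(scores)))
    n <- nrow(scores)
  }
  scores$peak_id[o][seq_len(n)]
}

#' Write a feature-score table
#'
#' @param scores data.frame from [score_features()].
#' @param dest destination CSV path.
#' @return `dest`, invisibly.
#' @export
write_scores <- function(scores, dest) {
  cols <- c("peak_id", "p_value", "q_value", "gini_decrease",
            "rank_mwu", "rank_gini", "rt_center", "irm_center")
  df <- scores[, cols]
  lines <- c(paste(cols, collapse = ","),
             vapply(seq_len(nrow(df)), function(i) {
               paste(c(df$peak_id[i],
                       fmt_num(c(df$p_value[i], df$q_value[i],
                                 df$gini_decrease[i])),
                       df$rank_mwu[i], df$rank_gini[i],
                       fmt_num(c(df$rt_center[i], df$irm_center[i]))),
                     collapse = ",")
             }, ""))
  writeLines(lines, dest, useBytes = TRUE)
  invisible(dest)
}
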