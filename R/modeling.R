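# Model estimation: dynamic fold selection, stratified cross-validation
# with per-fold metrics, final random-forest + decision-tree training,
# best-method selection, dataset splitting and prediction.

#' Choose the number of cross-validation folds
#'
#' The fold count grows by one for every five samples in the minority
#' class, capped at ten, so every test fold keeps at least five samples per
#' class: `k = min(floor(n_min / 5), 10)`.  With fewer than ten minority
#' samples cross-validation is omitted (returns `NA`).  A user-supplied `k`
#' overrides the rule but must not exceed the minority count.
#'
#' @param class_counts named integer vector of per-class sample counts
#'   (two classes).
#' @param user_k optional user override.
#' @return integer fold count, or `NA_integer_` when CV is omitted.
#' @export
choose_k <- function(class_counts, user_k = NULL) {
  if (length(class_counts) != 2) stop("exactly two classes required")
  n_min <- as.integer(min(class_counts))
  if (!is.null(user_k)) {
    user_k <- as.integer(user_k)
    if (user_k < 2) stop("k must be at least 2")
    if (user_k > n_min) {
      stop(sprintf("k=%d exceeds the minority class size %d (unfillable folds)",
                   user_k, n_min))
    }
    return(user_k)
  }
  if (n_min < 10) return(NA_integer_)
  min(n_min %/% 5L, 10L)
}

#' Build a stratified fold plan
#'
#' Samples are shuffled within class (seeded) and dealt round-robin over the
#' `k` folds, so per-class fold sizes differ by at most one and the class
#' distribution of every fold approximates the full dataset.
#'
#' @param labels named character vector of class labels keyed by sample id.
#' @param k fold count, at least 2; every class must have at least `k`
#'   samples.
#' @param seed RNG seed.
#' @return list with `k`, `seed`, and `assignments` (named integer vector
#'   of fold indices in 1..k).
#' @export
stratified_folds <- function(labels, k, seed = 42) {
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2")
  tab <- table(labels)
  if (any(tab < k)) {
    stop("every class needs at least k samples for k-fold CV")
  }
  assignments <- integer(0)
  classes <- sort(names(tab))
  for (ci in seq_along(classes)) {
    ids <- sort(names(labels)[labels == classes[ci]])
    ids <- with_seed(derive_seed(seed, ci), sample(ids))
    a <- stats::setNames(rep_len(seq_len(k), length(ids)), ids)
    assignments <- c(assignments, a)
  }
  list(k = k, seed = seed, assignments = assignments[sort(names(assignments))])
}

# Trapezoid ROC curve and AUC from scores (higher = more positive).
roc_curve <- function(scores, truth01) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- truth01[o]
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / max(sum(y), 1))
  fpr <- c(0, fp[last] / max(sum(1 - y), 1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

fold_metrics <- function(truth, pred, prob, positive, negative) {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth == negative & pred == negative)
  fp <- sum(truth == negative & pred == positive)
  fn <- sum(truth == positive & pred == negative)
  acc <- (tp + tn) / length(truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  roc <- roc_curve(prob, as.integer(truth == positive))
  list(tp = tp, tn = tn, fp = fp, fn = fn, accuracy = acc,
       sensitivity = sens, specificity = spec, f1 = f1,
       roc_auc = roc$auc, roc = roc)
}

#' Cross-validated performance estimation
#'
#' Trains one random forest per fold on the training split and scores the
#' held-out split: accuracy, F1, sensitivity, specificity and trapezoid
#' ROC-AUC from vote-fraction probabilities, averaged over the `k` folds.
#'
#' @param fm a reduced `mcc_feature_matrix`.
#' @param labels named character vector of class labels.
#' @param plan fold plan from [stratified_folds()].
#' @param forest_params list: `n_trees`, `mtry`, `min_samples_split`,
#'   `min_samples_leaf`.
#' @param seed RNG seed; per-fold seeds are derived from it.
#' @param positive_class label treated as positive for ROC/sensitivity;
#'   defaults to the lexicographically greater label.
#' @return an evaluation report: `per_fold` data.frame, `mean` and `sd`
#'   metric lists, `roc_points`, `k`, `positive_class`.
#' @export
crossvalidate <- function(fm, labels, plan, forest_params = list(),
                          seed = 42, positive_class = NULL) {
  labels <- labels[fm$sample_ids]
  check_binary_labels(labels)
  classes <- sort(unique(labels))
  positive <- positive_class %||% classes[2]
  negative <- setdiff(classes, positive)
  assignments <- plan$assignments[fm$sample_ids]
  metrics <- list()
  roc_points <- list()
  for (f in seq_len(plan$k)) {
    test <- which(assignments == f)
    train <- which(assignments != f)
    if (length(unique(labels[test])) < 2) {
      stop(sprintf(
        "test fold %d contains a single class; AUC undefined - use stratified folds",
        f))
    }
    forest <- rf_train(
      fm$values[train, , drop = FALSE], labels[train],
      n_trees = forest_params$n_trees %||% 500,
      seed = derive_seed(seed, f),
      mtry = forest_params$mtry,
      min_samples_split = forest_params$min_samples_split %||% 2,
      min_samples_leaf = forest_params$min_samples_leaf %||% 1
    )
    prob <- rf_predict_prob(forest, fm$values[test, , drop = FALSE])
    if (positive != forest$classes[2]) prob <- 1 - prob
    pred <- ifelse(prob > 0.5, positive, negative)
    mt <- fold_metrics(labels[test], pred, prob, positive, negative)
    metrics[[f]] <- mt
    roc_points[[f]] <- data.frame(fold = f, fpr = mt$roc$fpr,
                                  tpr = mt$roc$tpr)
  }
  per_fold <- do.call(rbind, lapply(seq_along(metrics), function(f) {
    m <- metrics[[f]]
    data.frame(fold = f, accuracy = m$accuracy, f1 = m$f1,
               sensitivity = m$sensitivity, specificity = m$specificity,
               roc_auc = m$roc_auc, tp = m$tp, fp = m$fp, tn = m$tn,
               fn = m$fn)
  }))
  metric_names <- c("accuracy", "f1", "sensitivity", "specificity", "roc_auc")
  list(
    per_fold = per_fold,
    mean = as.list(colMeans(per_fold[metric_names])),
    sd = as.list(vapply(per_fold[metric_names], stats::sd, 0)),
    roc_points = do.call(rbind, roc_points),
    k = plan$k,
    positive_class = positive,
    cv_omitted = FALSE
  )
}

#' Resubstitution report when cross-validation is omitted
#'
#' With fewer than ten minority-class samples CV is omitted; the model is
#' trained on all data and scored on the same data, flagged `cv_omitted`.
#'
#' @inheritParams crossvalidate
#' @return an evaluation report with a single pseudo-fold and
#'   `cv_omitted = TRUE`.
#' @export
resubstitution_report <- function(fm, labels, forest_params = list(),
                                  seed = 42, positive_class = NULL) {
  labels <- labels[fm$sample_ids]
  check_binary_labels(labels)
  classes <- sort(unique(labels))
  positive <- positive_class %||% classes[2]
  negative <- setdiff(classes, positive)
  forest <- rf_train(fm$values, labels,
                     n_trees = forest_params$n_trees %||% 500,
                     seed = derive_seed(seed, 1L),
                     mtry = forest_params$mtry)
  prob <- rf_predict_prob(forest, fm$values)
  if (positive != forest$classes[2]) prob <- 1 - prob
  pred <- ifelse(prob > 0.5, positive, negative)
  mt <- fold_metrics(labels, pred, prob, positive, negative)
  per_fold <- data.frame(fold = 1L, accuracy = mt$accuracy, f1 = mt$f1,
                         sensitivity = mt$sensitivity,
                         specificity = mt$specificity, roc_auc = mt$roc_auc,
                         tp = mt$tp, fp = mt$fp, tn = mt$tn, fn = mt$fn)
  metric_names <- c("accuracy", "f1", "sensitivity", "specificity", "roc_auc")
  list(per_fold = per_fold,
       mean = as.list(per_fold[1, metric_names]),
       sd = as.list(stats::setNames(rep(0, 5), metric_names)),
       roc_points = data.frame(fold = 1L, fpr = mt$roc$fpr,
                               tpr = mt$roc$tpr),
       k = NA_integer_, positive_class = positive, cv_omitted = TRUE)
}

#' Select the best detection method by mean ROC-AUC
#'
#' Ties are broken by higher mean accuracy, then by method-name order.
#'
#' @param reports named list of evaluation reports.
#' @return name of the winning method.
#' @export
select_best_method <- function(reports) {
  if (!length(reports)) stop("no reports to select from")
  auc <- vapply(reports, function(r) r$mean$roc_auc, 0)
  acc <- vapply(reports, function(r) r$mean$accuracy, 0)
  nm <- names(reports)
  nm[order(-auc, -acc, nm)][1]
}

#' Stratified train/validation split
#'
#' Per class, `floor(train_ratio * n_class)` seeded-shuffled samples go to
#' training, the remainder to validation; disjoint and exhaustive.
#'
#' @param labels named character vector keyed by sample id.
#' @param train_ratio fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with sorted `train_ids` and `validation_ids`.
#' @export
split_dataset <- function(labels, train_ratio = 0.8, seed = 42) {
  if (train_ratio <= 0 || train_ratio >= 1) {
    stop("train_ratio must lie strictly between 0 and 1")
  }
  train_ids <- character(0)
  classes <- sort(unique(labels))
  for (ci in seq_along(classes)) {
    ids <- sort(names(labels)[labels == classes[ci]])
    n_train <- floor(train_ratio * length(ids))
    if (n_train < 1) {
      stop(sprintf("class '%s' would lose all training members", classes[ci]))
    }
    ids <- with_seed(derive_seed(seed, ci), sample(ids))
    train_ids <- c(train_ids, ids[seq_len(n_train)])
  }
  list(train_ids = sort(train_ids),
       validation_ids = sort(setdiff(names(labels), train_ids)))
}

#' Train the final model bundle
#'
#' Trains the full-data random forest on the selected top features (the
#' classifier used for prediction) and a decision tree on the same features
#' (the interpretable surrogate).  The bundle is self-contained: it stores
#' the preprocessing chain, detection method and parameters, alignment
#' grid, selected features with coordinates, and both models, so prediction
#' needs nothing beyond the bundle and new raw files.
#'
#' @param fm reduced `mcc_feature_matrix` (training data).
#' @param labels named character vector of class labels.
#' @param top_ids character vector of selected peak ids (subset of `fm`
#'   columns).
#' @param tree_params list: `min_samples_split`, `min_samples_leaf`,
#'   `max_depth`.
#' @param forest_params list: `n_trees`, `mtry`.
#' @param seed RNG seed.
#' @param positive_class positive label for reporting.
#' @param pipeline list describing upstream stages (`chain`, `detection`,
#'   `detection_params`, `grid`), stored verbatim for prediction.
#' @param report optional training evaluation report to embed.
#' @return an object of class `mcc_model_bundle`.
#' @export
train_final <- function(fm, labels, top_ids, tree_params = list(),
                        forest_params = list(), seed = 42,
                        positive_class = NULL, pipeline = list(),
                        report = NULL) {
  if (!length(top_ids)) stop("top_ids must not be empty")
  if (!all(top_ids %in% fm$peak_ids)) {
    stop("top_ids contains features absent from the feature matrix")
  }
  labels <- labels[fm$sample_ids]
  check_binary_labels(labels)
  classes <- sort(unique(labels))
  X <- fm$values[, top_ids, drop = FALSE]
  forest <- rf_train(X, labels,
                     n_trees = forest_params$n_trees %||% 500,
                     seed = derive_seed(seed, 1000L),
                     mtry = forest_params$mtry)
  y01 <- as.integer(labels == classes[2])
  tree <- with_seed(derive_seed(seed, 2000L), tree_fit(
    X, y01,
    min_samples_split = tree_params$min_samples_split %||% 2,
    min_samples_leaf = tree_params$min_samples_leaf %||% 1,
    max_depth = tree_params$max_depth %||% Inf,
    mtry = ncol(X)
  ))
  coords <- fm$coords[match(top_ids, fm$coords$peak_id), , drop = FALSE]
  rownames(coords) <- NULL
  structure(
    list(
      chain = pipeline$chain %||% list(),
      detection = pipeline$detection %||% NA_character_,
      detection_params = pipeline$detection_params %||% list(),
      grid = pipeline$grid %||% build_grid(),
      peak_ids = top_ids,
      coords = coords,
      forest = forest,
      tree = tree,
      tree_params = tree_params,
      classes = classes,
      positive_class = positive_class %||% classes[2],
      seed = seed,
      report = report
    ),
    class = "mcc_model_bundle"
  )
}

#' @export
print.mcc_model_bundle <- function(x, ...) {
  cat(sprintf(
    "<mcc_model_bundle> %s vs %s, %d features, detection=%s, %d trees\n",
    x$classes[1], x$classes[2], length(x$peak_ids), x$detection,
    x$forest$n_trees))
  invisible(x)
}

# Feature vector(s) for new raw measurements under a bundle.
bundle_features <- function(bundle, measurements) {
  vals <- matrix(0, nrow = length(measurements),
                 ncol = length(bundle$peak_ids),
                 dimnames = list(
                   vapply(measurements, `[[`, "", "sample_id"),
                   bundle$peak_ids))
  for (i in seq_along(measurements)) {
    m <- apply_chain(measurements[[i]], bundle$chain)
    pk <- detect_peaks(m, methods = bundle$detection,
                       params = bundle$detection_params)[[bundle$detection]]
    if (!nrow(pk)) next
    pk <- clip_to_grid(pk, bundle$grid)
    ids <- assign_cell(bundle$grid, pk$rt, pk$irm)
    for (pid in unique(ids[ids %in% bundle$peak_ids])) {
      vals[i, pid] <- max(pk$intensity[ids == pid])
    }
  }
  vals
}

#' Predict class labels with a trained bundle
#'
#' Raw measurements are passed through the stored preprocessing chain,
#' detection method and alignment grid to reconstruct the training
#' features; a feature-matrix input skips straight to column lookup
#' (missing columns are filled with 0 and flagged).  The stored forest then
#' votes.
#'
#' @param bundle a `mcc_model_bundle`.
#' @param measurements list of raw `mcc_measurement` objects, or `NULL`.
#' @param fm a `mcc_feature_matrix`, or `NULL` (exactly one input required).
#' @return data.frame `sample_id, label, prob_positive` where
#'   `prob_positive` is the vote fraction for `bundle$positive_class`.
#' @export
predict_bundle <- function(bundle, measurements = NULL, fm = NULL) {
  if (is.null(measurements) == is.null(fm)) {
    stop("provide exactly one of measurements or fm")
  }
  X <- if (!is.null(measurements)) {
    bundle_features(bundle, measurements)
  } else {
    missing <- setdiff(bundle$peak_ids, fm$peak_ids)
    if (length(missing)) {
      warning("feature-matrix input missing columns filled with 0: ",
              paste(missing, collapse = ","))
    }
    out <- matrix(0, nrow = length(fm$sample_ids),
                  ncol = length(bundle$peak_ids),
                  dimnames = list(fm$sample_ids, bundle$peak_ids))
    shared <- intersect(bundle$peak_ids, fm$peak_ids)
    out[, shared] <- fm$values[, shared, drop = FALSE]
    out
  }
  prob_ref <- rf_predict_prob(bundle$forest, X)
  prob_pos <- if (bundle$positive_class == bundle$forest$classes[2]) {
    prob_ref
  } else {
    1 - prob_ref
  }
  negative <- setdiff(bundle$classes, bundle$positive_class)
  label <- ifelse(prob_pos > 0.5, bundle$positive_class, negative)
  data.frame(sample_id = rownames(X), label = label,
             prob_positive = prob_pos, stringsAsFactors = FALSE)
}
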