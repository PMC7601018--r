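# Classification trees (CART, Gini impurity) and a bagged random forest on
# top of them.  Written in-package: the pipeline needs deterministic seeded
# training, vote-fraction probabilities, and mean-decrease-in-Gini
# importances with exact control over tie-breaking.

gini_impurity <- function(npos, n) {
  p <- npos / n
  2 * p * (1 - p)
}

# Best split of y01 (0/1 integer) on one feature column.  Returns NULL or
# list(threshold, decrease-weighted impurity pieces).
best_split_col <- function(xcol, y01, min_leaf) {
  n <- length(xcol)
  o <- order(xcol)
  xs <- xcol[o]
  ys <- y01[o]
  cum_pos <- cumsum(ys)
  npos <- cum_pos[n]
  i <- seq_len(n - 1L)
  valid <- xs[i] < xs[i + 1L] & i >= min_leaf & (n - i) >= min_leaf
  if (!any(valid)) return(NULL)
  i <- i[valid]
  nl <- i
  nr <- n - i
  pl <- cum_pos[i] / nl
  pr <- (npos - cum_pos[i]) / nr
  weighted <- (nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)) / n
  b <- which.min(weighted)
  list(threshold = (xs[i[b]] + xs[i[b] + 1L]) / 2,
       weighted = weighted[b])
}

#' Train a CART classification tree
#'
#' Binary Gini-impurity tree with midpoint thresholds.  Node-level feature
#' subsampling (`mtry`) uses the ambient RNG, so callers seed it.
#'
#' @param X numeric matrix (samples x features).
#' @param y01 integer vector of 0/1 class indicators.
#' @param min_samples_split minimum node size eligible for splitting.
#' @param min_samples_leaf minimum samples in each child.
#' @param max_depth depth limit (`Inf` = grow to purity).
#' @param mtry number of features drawn at each node.
#' @return list with `nodes` (data.frame: `feature`, `threshold`, `left`,
#'   `right`, `n`, `npos`, `prob`) and `importance` (summed Gini decreases,
#'   weighted by node fraction).
#' @export
tree_fit <- function(X, y01, min_samples_split = 2, min_samples_leaf = 1,
                     max_depth = Inf, mtry = ncol(X)) {
  n_total <- length(y01)
  p <- ncol(X)
  importance <- numeric(p)
  feature <- integer(0); threshold <- numeric(0)
  left <- integer(0); right <- integer(0)
  nn <- integer(0); npos_v <- integer(0)

  add_node <- function() {
    feature[length(feature) + 1L] <<- NA_integer_
    threshold[length(threshold) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- NA_integer_
    right[length(right) + 1L] <<- NA_integer_
    nn[length(nn) + 1L] <<- 0L
    npos_v[length(npos_v) + 1L] <<- 0L
    length(feature)
  }

  recurse <- function(idx, depth) {
    id <- add_node()
    n <- length(idx)
    npos <- sum(y01[idx])
    nn[id] <<- n
    npos_v[id] <<- npos
    g <- gini_impurity(npos, n)
    if (n < min_samples_split || g == 0 || depth >= max_depth ||
        n < 2 * min_samples_leaf) {
      return(id)
    }
    feats <- if (mtry < p) sort(sample.int(p, mtry)) else seq_len(p)
    best <- NULL
    best_f <- NA_integer_
    for (f in feats) {
      sp <- best_split_col(X[idx, f], y01[idx], min_samples_leaf)
      if (is.null(sp)) next
      if (is.null(best) || sp$weighted < best$weighted - 1e-12) {
        best <- sp
        best_f <- f
      }
    }
    if (is.null(best) || g - best$weighted <= 1e-12) {
      return(id)
    }
    importance[best_f] <<- importance[best_f] +
      (n / n_total) * (g - best$weighted)
    go_left <- X[idx, best_f] <= best$threshold
    feature[id] <<- best_f
    threshold[id] <<- best$threshold
    left[id] <<- recurse(idx[go_left], depth + 1L)
    right[id] <<- recurse(idx[!go_left], depth + 1L)
    id
  }

  recurse(seq_len(n_total), 0L)
  nodes <- data.frame(feature = feature, threshold = threshold,
                      left = left, right = right, n = nn, npos = npos_v)
  nodes$prob <- nodes$npos / nodes$n
  list(nodes = nodes, importance = importance)
}

# Leaf probability of class 1 for each row of X.
tree_predict_prob <- function(tree, X) {
  nodes <- tree$nodes
  out <- numeric(nrow(X))
  walk <- function(idx, node) {
    f <- nodes$feature[node]
    if (is.na(f)) {
      out[idx] <<- nodes$prob[node]
      return(invisible())
    }
    go_left <- X[idx, f] <= nodes$threshold[node]
    if (any(go_left)) walk(idx[go_left], nodes$left[node])
    if (any(!go_left)) walk(idx[!go_left], nodes$right[node])
  }
  if (nrow(X)) walk(seq_len(nrow(X)), 1L)
  out
}

tree_depth <- function(tree) {
  nodes <- tree$nodes
  depth_of <- function(node) {
    if (is.na(nodes$feature[node])) return(0L)
    1L + max(depth_of(nodes$left[node]), depth_of(nodes$right[node]))
  }
  depth_of(1L)
}

#' Train a random forest
#'
#' Bagged CART trees with per-node feature subsampling
#' (`mtry = floor(sqrt(p))` by default) and seeded, reproducible training.
#' Class probabilities are vote fractions: each tree votes its leaf's
#' majority class.
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param labels character/factor class labels (two classes).
#' @param n_trees number of trees.
#' @param seed RNG seed.
#' @param mtry features per node; default `floor(sqrt(ncol(X)))`.
#' @param min_samples_split,min_samples_leaf tree growth controls.
#' @return an object of class `mcc_forest` with `trees`, `classes`
#'   (sorted; the second is the probability reference), `importance` (mean
#'   decrease in Gini, unnormalized), `feature_names`.
#' @export
rf_train <- function(X, labels, n_trees = 500, seed = 42, mtry = NULL,
                     min_samples_split = 2, min_samples_leaf = 1) {
  stopifnot(is.matrix(X))
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2) stop("random forest requires exactly 2 classes")
  y01 <- as.integer(as.character(labels) == classes[2])
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, as.integer(floor(sqrt(p))))
  trees <- vector("list", n_trees)
  importance <- numeric(p)
  with_seed(seed, {
    for (t in seq_len(n_trees)) {
      idx <- sample.int(n, n, replace = TRUE)
      tr <- tree_fit(X[idx, , drop = FALSE], y01[idx],
                     min_samples_split = min_samples_split,
                     min_samples_leaf = min_samples_leaf,
                     mtry = mtry)
      trees[[t]] <- tr$nodes
      importance <- importance + tr$importance
    }
  })
  structure(
    list(trees = trees, classes = classes,
         importance = importance / n_trees,
         feature_names = colnames(X), n_trees = n_trees, seed = seed,
         mtry = mtry),
    class = "mcc_forest"
  )
}

#' Forest vote-fraction probabilities
#'
#' @param forest a `mcc_forest`.
#' @param X numeric matrix whose columns match `forest$feature_names`.
#' @return numeric vector: fraction of trees voting for the second
#'   (reference) class; exact leaf ties vote for the first class.
#' @export
rf_predict_prob <- function(forest, X) {
  if (!is.null(forest$feature_names)) {
    if (is.null(colnames(X)) ||
        !identical(colnames(X), forest$feature_names)) {
      X <- X[, forest$feature_names, drop = FALSE]
    }
  }
  votes <- numeric(nrow(X))
  for (tr in forest$trees) {
    prob <- tree_predict_prob(list(nodes = tr), X)
    votes <- votes + as.numeric(prob > 0.5)
  }
  votes / length(forest$trees)
}

#' Forest class predictions
#'
#' @param forest a `mcc_forest`.
#' @param X feature matrix.
#' @return character vector of predicted labels (probability > 0.5 goes to
#'   the reference class; ties go to the first class).
#' @export
rf_predict <- function(forest, X) {
  prob <- rf_predict_prob(forest, X)
  ifelse(prob > 0.5, forest$classes[2], forest$classes[1])
}

#' Render a decision tree as Graphviz DOT
#'
#' @param tree a [tree_fit()] result.
#' @param feature_names character vector naming the tree's features.
#' @param class_names the two class labels (order: class 0, class 1).
#' @return character scalar of DOT source.
#' @export
tree_to_dot <- function(tree, feature_names, class_names) {
  nodes <- tree$nodes
  lines <- c("digraph decision_tree {", "  node [shape=box];")
  for (i in seq_len(nrow(nodes))) {
    f <- nodes$feature[i]
    label <- if (is.na(f)) {
      maj <- if (nodes$prob[i] > 0.5) class_names[2] else class_names[1]
      sprintf("%s\\nn=%d [%d, %d]", maj, nodes$n[i],
              nodes$n[i] - nodes$npos[i], nodes$npos[i])
    } else {
      sprintf("%s <= %.6g\\nn=%d [%d, %d]", feature_names[f],
              nodes$threshold[i], nodes$n[i],
              nodes$n[i] - nodes$npos[i], nodes$npos[i])
    }
    lines <- c(lines, sprintf("  n%d [label=\"%s\"];", i, label))
    if (!is.na(f)) {
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"yes\"];", i, nodes$left[i]),
                 sprintf("  n%d -> n%d [label=\"no\"];", i, nodes$right[i]))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Render a decision tree as an indented rule list
#'
#' @inheritParams tree_to_dot
#' @return character scalar, one rule per line.
#' @export
tree_to_text <- function(tree, feature_names, class_names) {
  nodes <- tree$nodes
  lines <- character(0)
  visit <- function(node, indent) {
    pad <- strrep("  ", indent)
    f <- nodes$feature[node]
    if (is.na(f)) {
      maj <- if (nodes$prob[node] > 0.5) class_names[2] else class_names[1]
      lines <<- c(lines, sprintf("%spredict %s (n=%d)", pad, maj,
                                 nodes$n[node]))
      return(invisible())
    }
    lines <<- c(lines, sprintf("%sif %s <= %.6g:", pad, feature_names[f],
                               nodes$threshold[node]))
    visit(nodes$left[node], indent + 1L)
    lines <<- c(lines, sprintf("%selse:", pad))
    visit(nodes$right[node], indent + 1L)
  }
  visit(1L, 0L)
  paste(lines, collapse = "\n")
}
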