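# Model-bundle serialization.  A bundle directory is self-contained and
# plain-text: params.json (preprocessing chain, detection, grid, classes,
# seeds, selected peak ids + coordinates, tree parameters), forest.csv and
# tree.csv (node tables), tree.dot / tree.txt renderings, and optionally
# report.json + roc_points.csv from training.

grid_to_list <- function(grid) {
  list(w = grid$w, srt = grid$srt, rt_max = grid$rt_max,
       irm_max = grid$irm_max, equation_variant = grid$equation_variant)
}

grid_from_list <- function(x) {
  build_grid(w = x$w, srt = x$srt, rt_max = x$rt_max, irm_max = x$irm_max,
             equation_variant = x$equation_variant)
}

forest_to_df <- function(forest) {
  do.call(rbind, lapply(seq_along(forest$trees), function(t) {
    nodes <- forest$trees[[t]]
    cbind(data.frame(tree = t, node = seq_len(nrow(nodes))), nodes)
  }))
}

forest_from_df <- function(df, classes, feature_names, importance, seed,
                           mtry) {
  trees <- lapply(split(df, df$tree), function(d) {
    d <- d[order(d$node), c("feature", "threshold", "left", "right", "n",
                            "npos", "prob")]
    rownames(d) <- NULL
    d
  })
  structure(
    list(trees = trees[order(as.integer(names(trees)))], classes = classes,
         importance = importance, feature_names = feature_names,
         n_trees = length(trees), seed = seed, mtry = mtry),
    class = "mcc_forest"
  )
}

#' Save a model bundle to a directory
#'
#' @param bundle a `mcc_model_bundle`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- list(
    chain = bundle$chain,
    detection = bundle$detection,
    detection_params = bundle$detection_params,
    grid = grid_to_list(bundle$grid),
    peak_ids = bundle$peak_ids,
    coords = bundle$coords,
    classes = bundle$classes,
    positive_class = bundle$positive_class,
    seed = bundle$seed,
    tree_params = bundle$tree_params,
    forest = list(seed = bundle$forest$seed, mtry = bundle$forest$mtry,
                  importance = bundle$forest$importance,
                  feature_names = bundle$forest$feature_names)
  )
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  utils::write.csv(forest_to_df(bundle$forest),
                   file.path(dir, "forest.csv"), row.names = FALSE)
  tree_df <- cbind(data.frame(node = seq_len(nrow(bundle$tree$nodes))),
                   bundle$tree$nodes)
  utils::write.csv(tree_df, file.path(dir, "tree.csv"), row.names = FALSE)
  writeLines(tree_to_dot(bundle$tree, bundle$peak_ids, bundle$classes),
             file.path(dir, "tree.dot"))
  writeLines(tree_to_text(bundle$tree, bundle$peak_ids, bundle$classes),
             file.path(dir, "tree.txt"))
  if (!is.null(bundle$report)) {
    write_report(bundle$report, dir)
  }
  invisible(dir)
}

write_report <- function(report, dir) {
  jsonlite::write_json(
    list(k = report$k, cv_omitted = report$cv_omitted,
         positive_class = report$positive_class,
         mean = report$mean, sd = report$sd, per_fold = report$per_fold),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  utils::write.csv(report$roc_points, file.path(dir, "roc_points.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a model bundle from a directory
#'
#' @param dir a directory written by [save_bundle()].
#' @return a `mcc_model_bundle`.
#' @export
load_bundle <- function(dir) {
  params <- jsonlite::read_json(file.path(dir, "params.json"),
                                simplifyVector = TRUE, simplifyDataFrame = TRUE)
  chain <- lapply(params$chain, function(st) {
    list(step = st$step, params = as.list(st$params))
  })
  forest_df <- utils::read.csv(file.path(dir, "forest.csv"))
  forest <- forest_from_df(forest_df, params$classes,
                           params$forest$feature_names,
                           params$forest$importance,
                           params$forest$seed, params$forest$mtry)
  tree_df <- utils::read.csv(file.path(dir, "tree.csv"))
  tree <- list(nodes = tree_df[order(tree_df$node),
                               c("feature", "threshold", "left", "right",
                                 "n", "npos", "prob")])
  rownames(tree$nodes) <- NULL
  structure(
    list(
      chain = chain,
      detection = params$detection,
      detection_params = as.list(params$detection_params),
      grid = grid_from_list(params$grid),
      peak_ids = params$peak_ids,
      coords = params$coords,
      forest = forest,
      tree = tree,
      tree_params = as.list(params$tree_params),
      classes = params$classes,
      positive_class = params$positive_class,
      seed = params$seed,
      report = NULL
    ),
    class = "mcc_model_bundle"
  )
}
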