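# End-to-end pipeline drivers behind the CLI modes.  All drivers work on
# in-memory objects and optionally write their artifacts (resolved config,
# peak lists, feature matrices, per-method reports, scores, tree renderings,
# bundle) to an output directory.

default_params <- function() {
  list(
    # preprocessing
    rip_irm = NULL, noise_region_max_irm = 0.4,
    gaussian_sigma = 1.0, drop_levels = 2, median_size = 3,
    savgol_window = 9, savgol_polyorder = 2,
    # detection
    methods = c("tophat", "jibb", "watershed"),
    tophat_window = c(5, 5), jibb_rise_steps = 3, jibb_factor = 1.5,
    watershed_levels = 256, noise_factor = 1.5,
    # alignment
    align = "probe", grid_w = 0.025, grid_srt = 0.0,
    eps = 0.01, min_samples = 2,
    # reduction / selection
    min_intensity = 0.1, pct_threshold = 50, top_n = 10, rank_by = "gini",
    # modeling
    k = NULL, n_trees = 500, mtry = NULL,
    min_samples_split = 2, min_samples_leaf = 1, max_depth = NULL,
    positive_class = NULL
  )
}

resolve_params <- function(overrides = list()) {
  params <- default_params()
  for (nm in names(overrides)) params[[nm]] <- overrides[[nm]]
  params
}

# Detect peaks with every requested method on every measurement.
detect_all <- function(measurements, methods, params) {
  out <- stats::setNames(vector("list", length(methods)), methods)
  for (meth in methods) out[[meth]] <- list()
  for (m in measurements) {
    pks <- detect_peaks(m, methods = methods, params = params)
    for (meth in methods) out[[meth]][[m$sample_id]] <- pks[[meth]]
  }
  lapply(out, function(lst) {
    df <- do.call(rbind, lst)
    if (is.null(df)) peaks_df() else { rownames(df) <- NULL; df }
  })
}

align_peaks <- function(peaks, params, sample_ids) {
  grid <- build_grid(w = params$grid_w, srt = params$grid_srt)
  if (identical(params$align, "dbscan")) {
    dbscan_align(peaks, eps = params$eps, min_samples = params$min_samples,
                 grid = grid, sample_ids = sample_ids)
  } else {
    probe_cluster(peaks, grid = grid, sample_ids = sample_ids)
  }
}

evaluate_fm <- function(fm, labels, params, seed) {
  counts <- table(labels[fm$sample_ids])
  k <- choose_k(counts, user_k = params$k)
  forest_params <- list(n_trees = params$n_trees, mtry = params$mtry)
  if (is.na(k)) {
    resubstitution_report(fm, labels, forest_params, seed = seed,
                          positive_class = params$positive_class)
  } else {
    plan <- stratified_folds(labels[fm$sample_ids], k, seed = seed)
    crossvalidate(fm, labels, plan, forest_params, seed = seed,
                  positive_class = params$positive_class)
  }
}

#' Automatic-mode pipeline
#'
#' Fully autonomous analysis: default preprocessing chain, all requested
#' detection methods, probe-clustering alignment, feature reduction at the
#' default percentage threshold, dynamic fold selection, per-method
#' cross-validation, selection of the best method by mean ROC-AUC, feature
#' scoring, and final training on the top-n features.
#'
#' @param measurements named list of raw `mcc_measurement` objects.
#' @param labels named character vector of class labels.
#' @param params overrides of [default_params()] entries.
#' @param seed master seed.
#' @param out_dir optional artifact directory.
#' @return list: `bundle`, `best_method`, `reports` (per method), `scores`,
#'   `top_ids`, `feature_matrices`, `params`.
#' @export
run_automatic_pipeline <- function(measurements, labels, params = list(),
                                   seed = 42, out_dir = NULL) {
  params <- resolve_params(params)
  labels <- labels[vapply(measurements, `[[`, "", "sample_id")]
  check_binary_labels(labels)
  pre <- lapply(measurements, preprocess_default, params = params)
  peaks_by_method <- detect_all(pre, params$methods, params)
  sample_ids <- names(labels)
  reports <- list()
  reduced <- list()
  fms <- list()
  for (meth in names(peaks_by_method)) {
    fm <- align_peaks(peaks_by_method[[meth]], params, sample_ids)
    fms[[meth]] <- fm
    red <- reduce_features(fm, labels, min_intensity = params$min_intensity,
                           pct_threshold = params$pct_threshold)
    reduced[[meth]] <- red
    reports[[meth]] <- evaluate_fm(red, labels, params, seed)
  }
  best <- select_best_method(reports)
  red_best <- reduced[[best]]
  scores <- score_features(red_best, labels, n_trees = params$n_trees,
                           seed = derive_seed(seed, 3000L))
  top_ids <- select_top(scores, n = min(params$top_n, nrow(scores)),
                        by = params$rank_by)
  chain <- pre[[1]]$provenance
  bundle <- train_final(
    red_best, labels, top_ids,
    tree_params = list(min_samples_split = params$min_samples_split,
                       min_samples_leaf = params$min_samples_leaf,
                       max_depth = params$max_depth %||% Inf),
    forest_params = list(n_trees = params$n_trees, mtry = params$mtry),
    seed = seed, positive_class = params$positive_class,
    pipeline = list(chain = chain, detection = best,
                    detection_params = params,
                    grid = build_grid(params$grid_w, params$grid_srt)),
    report = reports[[best]]
  )
  result <- list(bundle = bundle, best_method = best, reports = reports,
                 scores = scores, top_ids = top_ids,
                 feature_matrices = fms, params = params, seed = seed)
  if (!is.null(out_dir)) {
    write_run_artifacts(result, peaks_by_method, out_dir)
  }
  result
}

write_run_artifacts <- function(result, peaks_by_method, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$params
  cfg$seed <- result$seed
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (meth in names(peaks_by_method)) {
    write_peaks(peaks_by_method[[meth]],
                file.path(out_dir, sprintf("peaks_%s.csv", meth)))
  }
  for (meth in names(result$feature_matrices)) {
    write_feature_matrix(result$feature_matrices[[meth]],
                         file.path(out_dir,
                                   sprintf("features_%s.csv", meth)))
  }
  write_scores(result$scores, file.path(out_dir, "scores.csv"))
  writeLines(result$best_method, file.path(out_dir, "best_method.txt"))
  write_report(result$reports[[result$best_method]], out_dir)
  save_bundle(result$bundle, file.path(out_dir, "bundle"))
  file.copy(file.path(out_dir, "bundle", "tree.dot"),
            file.path(out_dir, "tree.dot"), overwrite = TRUE)
  invisible(out_dir)
}

#' Custom-mode pipeline
#'
#' Executes exactly the configured stages: the preprocessing steps listed
#' in `params$steps` (names from the provenance vocabulary: `normalize`,
#' `baseline`, `subtract_noise`, `wavelet`, `gaussian`, `median`,
#' `savgol`), a single detection method `params$method`, the configured
#' alignment, reduction, scoring and final training.
#'
#' @inheritParams run_automatic_pipeline
#' @return list as in [run_automatic_pipeline()] (single-method `reports`).
#' @export
run_custom_pipeline <- function(measurements, labels, params = list(),
                                seed = 42, out_dir = NULL) {
  steps <- params$steps %||% c("normalize", "baseline", "subtract_noise",
                               "gaussian")
  method <- params$method %||% "watershed"
  params$methods <- method
  params <- resolve_params(params)
  chain <- lapply(steps, function(s) {
    list(step = s, params = switch(s,
      gaussian = list(sigma = params$gaussian_sigma),
      wavelet = list(drop_levels = params$drop_levels),
      median = list(size = params$median_size),
      savgol = list(window = params$savgol_window,
                    polyorder = params$savgol_polyorder),
      subtract_noise = list(region_max_irm = params$noise_region_max_irm),
      list()))
  })
  labels <- labels[vapply(measurements, `[[`, "", "sample_id")]
  check_binary_labels(labels)
  pre <- lapply(measurements, apply_chain, chain = chain)
  peaks_by_method <- detect_all(pre, method, params)
  fm <- align_peaks(peaks_by_method[[method]], params, names(labels))
  red <- reduce_features(fm, labels, min_intensity = params$min_intensity,
                         pct_threshold = params$pct_threshold)
  report <- evaluate_fm(red, labels, params, seed)
  scores <- score_features(red, labels, n_trees = params$n_trees,
                           seed = derive_seed(seed, 3000L))
  top_ids <- select_top(scores, n = min(params$top_n, nrow(scores)),
                        by = params$rank_by)
  bundle <- train_final(
    red, labels, top_ids,
    tree_params = list(min_samples_split = params$min_samples_split,
                       min_samples_leaf = params$min_samples_leaf,
                       max_depth = params$max_depth %||% Inf),
    forest_params = list(n_trees = params$n_trees, mtry = params$mtry),
    seed = seed, positive_class = params$positive_class,
    pipeline = list(chain = pre[[1]]$provenance, detection = method,
                    detection_params = params,
                    grid = build_grid(params$grid_w, params$grid_srt)),
    report = report
  )
  result <- list(bundle = bundle, best_method = method,
                 reports = stats::setNames(list(report), method),
                 scores = scores, top_ids = top_ids,
                 feature_matrices = stats::setNames(list(fm), method),
                 params = params, seed = seed)
  if (!is.null(out_dir)) write_run_artifacts(result, peaks_by_method, out_dir)
  result
}

#' Existing-results pipeline
#'
#' Starts from an uploaded feature matrix, skipping preprocessing, peak
#' detection and alignment: reduction, scoring, evaluation and final
#' training only.
#'
#' @param fm a `mcc_feature_matrix` (e.g. from [read_feature_matrix()]).
#' @param labels named character vector of class labels.
#' @inheritParams run_automatic_pipeline
#' @return list as in [run_automatic_pipeline()].
#' @export
run_existing_pipeline <- function(fm, labels, params = list(), seed = 42,
                                  out_dir = NULL) {
  params <- resolve_params(params)
  labels <- labels[fm$sample_ids]
  check_binary_labels(labels)
  red <- reduce_features(fm, labels, min_intensity = params$min_intensity,
                         pct_threshold = params$pct_threshold)
  report <- evaluate_fm(red, labels, params, seed)
  scores <- score_features(red, labels, n_trees = params$n_trees,
                           seed = derive_seed(seed, 3000L))
  top_ids <- select_top(scores, n = min(params$top_n, nrow(scores)),
                        by = params$rank_by)
  bundle <- train_final(
    red, labels, top_ids,
    tree_params = list(min_samples_split = params$min_samples_split,
                       min_samples_leaf = params$min_samples_leaf,
                       max_depth = params$max_depth %||% Inf),
    forest_params = list(n_trees = params$n_trees, mtry = params$mtry),
    seed = seed, positive_class = params$positive_class,
    pipeline = list(chain = list(), detection = "IMPORTED",
                    detection_params = list(),
                    grid = build_grid(params$grid_w, params$grid_srt)),
    report = report
  )
  result <- list(bundle = bundle, best_method = "IMPORTED",
                 reports = list(IMPORTED = report), scores = scores,
                 top_ids = top_ids,
                 feature_matrices = list(IMPORTED = fm), params = params,
                 seed = seed)
  if (!is.null(out_dir)) {
    write_run_artifacts(result,
                        stats::setNames(list(peaks_df()), "imported"),
                        out_dir)
  }
  result
}
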