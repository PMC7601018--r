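# FeatureMatrix: measurements x aligned peak ids.

#' Construct a FeatureMatrix
#'
#' Rows are measurements, columns are aligned peak ids (`Peak_0000`, ...).
#' A value of 0 encodes absence of the peak in that measurement. `coords`
#' maps every peak id to the (RT, IRM) center of its alignment-grid cell;
#' ids not derived from a grid may carry `NA` coordinates.
#'
#' @param values numeric matrix with sample ids as rownames and peak ids as
#'   colnames; all values >= 0.
#' @param coords data.frame with columns `peak_id`, `rt_center`,
#'   `irm_center`, one row per column of `values`.
#' @param labels optional named character vector of class labels keyed by
#'   sample id.
#' @param params list describing the alignment that produced the matrix.
#' @return an object of class `mcc_feature_matrix`.
#' @export
new_feature_matrix <- function(values, coords = NULL, labels = NULL,
                               params = list()) {
  stopifnot(is.matrix(values))
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("feature matrix needs sample ids as rownames and peak ids as colnames")
  }
  sample_ids <- rownames(values) %||% character(0)
  peak_ids <- colnames(values) %||% character(0)
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate peak-id columns")
  if (any(values < 0)) stop("feature-matrix values must be non-negative")
  if (is.null(coords)) {
    coords <- data.frame(
      peak_id = peak_ids,
      rt_center = rep(NA_real_, length(peak_ids)),
      irm_center = rep(NA_real_, length(peak_ids)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(setequal(coords$peak_id, peak_ids))
  coords <- coords[match(peak_ids, coords$peak_id), , drop = FALSE]
  rownames(coords) <- NULL
  structure(
    list(
      sample_ids = sample_ids,
      peak_ids = peak_ids,
      values = values,
      coords = coords,
      labels = labels,
      params = params
    ),
    class = "mcc_feature_matrix"
  )
}

#' @export
print.mcc_feature_matrix <- function(x, ...) {
  cat(sprintf("<mcc_feature_matrix> %d samples x %d peaks\n",
              length(x$sample_ids), length(x$peak_ids)))
  invisible(x)
}

#' @export
dim.mcc_feature_matrix <- function(x) dim(x$values)

# Subset columns of a feature matrix, keeping coords in step.
fm_subset_cols <- function(fm, keep) {
  values <- fm$values[, keep, drop = FALSE]
  coords <- fm$coords[match(colnames(values), fm$coords$peak_id), ,
                      drop = FALSE]
  rownames(coords) <- NULL
  new_feature_matrix(values, coords, fm$labels, fm$params)
}
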