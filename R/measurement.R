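# The Measurement container: one sample's RT x IRM intensity heatmap.

#' Construct a Measurement
#'
#' A `Measurement` holds a single MCC-IMS sample: a matrix of non-negative
#' intensities over retention time (RT, seconds, rows) and inverse reduced
#' ion mobility (IRM, Vs/cm2, columns), together with its identifier, an
#' optional class label, and an append-only provenance list recording every
#' preprocessing step applied so the identical chain can be replayed on
#' held-out samples at prediction time.
#'
#' @param sample_id character scalar identifying the sample.
#' @param rt_axis numeric vector of retention times (s), strictly increasing.
#' @param irm_axis numeric vector of inverse reduced ion mobilities
#'   (Vs/cm2), strictly increasing.
#' @param intensity numeric matrix, `length(rt_axis)` rows by
#'   `length(irm_axis)` columns, finite and non-negative.
#' @param label optional class-label string.
#' @param provenance list of applied preprocessing steps; each element is a
#'   list with `step` (name) and `params`. Empty means raw.
#' @return an object of class `mcc_measurement`.
#' @export
new_measurement <- function(sample_id, rt_axis, irm_axis, intensity,
                            label = NULL, provenance = list()) {
  m <- structure(
    list(
      sample_id = as.character(sample_id),
      rt_axis = as.numeric(rt_axis),
      irm_axis = as.numeric(irm_axis),
      intensity = intensity,
      label = label,
      provenance = provenance
    ),
    class = "mcc_measurement"
  )
  validate_measurement(m)
  m
}

#' Validate a Measurement's invariants
#'
#' Checks axis monotonicity, shape agreement, finiteness and non-negativity.
#'
#' @param m a `mcc_measurement`.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_measurement <- function(m) {
  stopifnot(inherits(m, "mcc_measurement"))
  if (length(m$rt_axis) < 1 || length(m$irm_axis) < 1) {
    stop("measurement axes must be non-empty")
  }
  if (any(diff(m$rt_axis) <= 0)) {
    stop("rt axis not strictly increasing")
  }
  if (any(diff(m$irm_axis) <= 0)) {
    stop("irm axis not strictly increasing")
  }
  if (!is.matrix(m$intensity) ||
      nrow(m$intensity) != length(m$rt_axis) ||
      ncol(m$intensity) != length(m$irm_axis)) {
    stop("intensity shape does not match axes")
  }
  if (!all(is.finite(m$intensity))) {
    stop("intensity contains non-finite values")
  }
  if (any(m$intensity < 0)) {
    stop("intensity contains negative values")
  }
  invisible(m)
}

# Return a copy with new intensities and one provenance step appended.
append_step <- function(m, intensity, step, params = list()) {
  m$intensity <- intensity
  m$provenance <- c(m$provenance, list(list(step = step, params = params)))
  m
}

#' @export
print.mcc_measurement <- function(x, ...) {
  cat(sprintf(
    "<mcc_measurement> %s: %d RT x %d IRM, RT [%g, %g] s, IRM [%g, %g] Vs/cm2\n",
    x$sample_id, length(x$rt_axis), length(x$irm_axis),
    min(x$rt_axis), max(x$rt_axis), min(x$irm_axis), max(x$irm_axis)
  ))
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  if (length(x$provenance)) {
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "step"),
                               collapse = " -> "), "\n")
  } else {
    cat("  provenance: raw\n")
  }
  invisible(x)
}
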