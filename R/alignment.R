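# Peak alignment: maps per-measurement peaks to shared peak ids, either via
# the deterministic probe-clustering grid (fixed IRM cell width w, RT row
# heights growing geometrically with scaling factor srt) or via DBSCAN on
# peak positions with grid-based labeling of cluster means.

#' Build a probe-clustering grid
#'
#' The grid spans RT in \[0, 2000\] s and IRM in \[0, 1.6\] Vs/cm2.  RT row
#' boundaries follow the recurrence
#' `H(0) = 0`, `H(1) = 3`, `H(q) = H(q-1) + (1 + srt) * H(q-1)`,
#' i.e. geometric growth by a factor `2 + srt`; the boundary list stops at
#' the first value >= 2000 s, clipped to 2000.  Columns are uniform cells of
#' width `w`. Peak ids are numbered left to right (IRM) and bottom to top
#' (RT): `id = q * n_cols + c`, printed as `Peak_%04d`.
#'
#' With `equation_variant = "additive"` the row heights (not the boundaries)
#' grow by `1 + srt` instead: `H(q) = H(q-1) + (1 + srt) * (H(q-1) - H(q-2))`.
#' The default `"printed"` variant is the recurrence above.
#'
#' @param w IRM cell width in Vs/cm2 (default 0.025).
#' @param srt RT scaling factor (default 0).
#' @param rt_max,irm_max grid domain limits.
#' @param equation_variant `"printed"` (default) or `"additive"`.
#' @return an object of class `mcc_grid` with `boundaries`, `n_cols`, `w`,
#'   `srt`, `rt_max`, `irm_max`.
#' @export
build_grid <- function(w = 0.025, srt = 0.0, rt_max = 2000, irm_max = 1.6,
                       equation_variant = c("printed", "additive")) {
  equation_variant <- match.arg(equation_variant)
  if (w <= 0) stop("grid width w must be positive")
  if (w > irm_max) stop("grid width w exceeds the IRM domain")
  if (srt < 0) stop("srt must be non-negative")
  H <- c(0, 3)
  while (H[length(H)] < rt_max) {
    q <- length(H)  # next index (0-based q = length(H))
    nxt <- if (equation_variant == "printed") {
      (2 + srt) * H[q]
    } else {
      H[q] + (1 + srt) * (H[q] - H[q - 1])
    }
    H <- c(H, nxt)
  }
  H[length(H)] <- rt_max  # clip the final boundary
  structure(
    list(w = w, srt = srt, rt_max = rt_max, irm_max = irm_max,
         boundaries = H, n_cols = as.integer(ceiling(irm_max / w)),
         equation_variant = equation_variant),
    class = "mcc_grid"
  )
}

#' @export
print.mcc_grid <- function(x, ...) {
  cat(sprintf("<mcc_grid> w=%g srt=%g: %d RT rows x %d IRM cols\n",
              x$w, x$srt, length(x$boundaries) - 1L, x$n_cols))
  invisible(x)
}

# 0-based numeric cell index for (rt, irm) vectors; rows and columns are
# half-open, with the top/right domain boundary clipped into the last cell.
cell_index <- function(grid, rt, irm) {
  if (any(rt < 0 | rt > grid$rt_max) || any(irm < 0 | irm > grid$irm_max)) {
    stop("coordinates outside the grid domain; clip before assignment")
  }
  nrows <- length(grid$boundaries) - 1L
  q <- findInterval(rt, grid$boundaries, rightmost.closed = FALSE) - 1L
  q[q >= nrows] <- nrows - 1L       # rt == rt_max
  col <- floor(irm / grid$w)
  col[col >= grid$n_cols] <- grid$n_cols - 1L
  q * grid$n_cols + col
}

format_peak_id <- function(index) sprintf("Peak_%04d", index)

#' Assign a peak position to a grid cell id
#'
#' @param grid a [build_grid()] spec.
#' @param rt retention time(s), seconds, within \[0, rt_max\].
#' @param irm inverse reduced ion mobility value(s) within \[0, irm_max\].
#' @return character vector of `Peak_%04d` ids.
#' @export
assign_cell <- function(grid, rt, irm) {
  format_peak_id(cell_index(grid, rt, irm))
}

#' Decode peak ids into cell-center coordinates
#'
#' @param peak_ids character vector; ids not matching `Peak_<digits>` get
#'   `NA` coordinates.
#' @param grid a [build_grid()] spec.
#' @return data.frame `peak_id, rt_center, irm_center`.
#' @export
decode_peak_coords <- function(peak_ids, grid = build_grid()) {
  out <- data.frame(peak_id = peak_ids, rt_center = NA_real_,
                    irm_center = NA_real_, stringsAsFactors = FALSE)
  ok <- grepl("^Peak_[0-9]+$", peak_ids)
  if (any(ok)) {
    index <- as.integer(sub("^Peak_", "", peak_ids[ok]))
    q <- index %/% grid$n_cols
    cc <- index %% grid$n_cols
    nrows <- length(grid$boundaries) - 1L
    valid <- q < nrows
    rt_c <- ifelse(valid,
                   (grid$boundaries[pmin(q, nrows - 1L) + 1L] +
                      grid$boundaries[pmin(q, nrows - 1L) + 2L]) / 2,
                   NA_real_)
    out$rt_center[ok] <- rt_c
    out$irm_center[ok] <- ifelse(valid, (cc + 0.5) * grid$w, NA_real_)
  }
  out
}

# Clip peak coordinates into the grid domain before assignment.
clip_to_grid <- function(peaks, grid) {
  peaks$rt <- pmin(pmax(peaks$rt, 0), grid$rt_max)
  peaks$irm <- pmin(pmax(peaks$irm, 0), grid$irm_max)
  peaks
}

# Build a feature matrix from (sample, cell id, intensity) triples, taking
# the per-(sample, cell) intensity maximum, with columns sorted by id.
fm_from_assignments <- function(sample_ids, assigned, intensities,
                                all_sample_ids, grid, params) {
  cols <- sort(unique(assigned))
  values <- matrix(0, nrow = length(all_sample_ids), ncol = length(cols),
                   dimnames = list(all_sample_ids, cols))
  if (length(assigned)) {
    agg <- stats::aggregate(
      intensities,
      by = list(sample_id = sample_ids, peak_id = assigned),
      FUN = max
    )
    values[cbind(match(agg$sample_id, all_sample_ids),
                 match(agg$peak_id, cols))] <- agg$x
  }
  new_feature_matrix(values, decode_peak_coords(cols, grid), params = params)
}

#' Probe-clustering peak alignment
#'
#' Assigns every detected peak to its grid cell; the feature value for a
#' (measurement, cell) pair is the maximum intensity among that
#' measurement's peaks falling in the cell, 0 when absent.  Deterministic
#' and invariant to measurement order.
#'
#' @param peaks data.frame of peaks pooled across measurements.
#' @param grid a [build_grid()] spec.
#' @param sample_ids optional character vector of all sample ids (so that
#'   measurements without any peak still appear as all-zero rows); defaults
#'   to the ids present in `peaks`.
#' @return a [new_feature_matrix()].
#' @export
probe_cluster <- function(peaks, grid = build_grid(), sample_ids = NULL) {
  all_ids <- sort(unique(c(sample_ids, peaks$sample_id)))
  if (!length(all_ids)) stop("no samples to align")
  peaks <- clip_to_grid(peaks, grid)
  assigned <- if (nrow(peaks)) assign_cell(grid, peaks$rt, peaks$irm)
              else character(0)
  fm_from_assignments(peaks$sample_id, assigned, peaks$intensity, all_ids,
                      grid,
                      params = list(alignment = "probe", w = grid$w,
                                    srt = grid$srt,
                                    equation_variant = grid$equation_variant))
}

# Plain DBSCAN on a Euclidean distance matrix; deterministic expansion in
# index order. Returns integer cluster labels, 0 = noise.
dbscan_labels <- function(d, eps, min_samples) {
  n <- nrow(d)
  labels <- integer(n)          # 0 = unassigned/noise
  visited <- logical(n)
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neighbors, length, 0L) >= min_samples
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      for (nb in neighbors[[j]]) {
        if (labels[nb] == 0L) labels[nb] <- cl
        if (!visited[nb] && core[nb]) {
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
  }
  labels
}

#' DBSCAN peak alignment
#'
#' Runs density clustering on pooled peak positions; RT and IRM are
#' normalized by the grid domain (`rt/rt_max`, `irm/irm_max`) so the two
#' incommensurate axes contribute comparably to the Euclidean distance.
#' Each cluster is labeled by the grid cell of its mean position; peaks
#' classified as noise keep their own position's cell id.  Distinct
#' clusters that map to the same cell are merged with a warning.
#'
#' @param peaks data.frame of peaks pooled across measurements.
#' @param eps neighborhood radius in normalized coordinates.
#' @param min_samples minimum neighborhood size for a core sample.
#' @param grid grid used for labeling (defaults to the standard grid).
#' @param sample_ids optional full sample-id list, as in [probe_cluster()].
#' @return a [new_feature_matrix()].
#' @export
dbscan_align <- function(peaks, eps = 0.01, min_samples = 2,
                         grid = build_grid(), sample_ids = NULL) {
  if (eps <= 0) stop("eps must be positive")
  if (min_samples < 1) stop("min_samples must be >= 1")
  all_ids <- sort(unique(c(sample_ids, peaks$sample_id)))
  params <- list(alignment = "dbscan", eps = eps, min_samples = min_samples,
                 w = grid$w, srt = grid$srt)
  if (!nrow(peaks)) {
    if (!length(all_ids)) {
      return(new_feature_matrix(
        matrix(0, 0, 0, dimnames = list(character(0), character(0))),
        params = params))
    }
    return(fm_from_assignments(character(0), character(0), numeric(0),
                               all_ids, grid, params))
  }
  peaks <- clip_to_grid(peaks, grid)
  pos <- cbind(peaks$rt / grid$rt_max, peaks$irm / grid$irm_max)
  d <- as.matrix(stats::dist(pos))
  labels <- dbscan_labels(d, eps, min_samples)
  assigned <- character(nrow(peaks))
  noise <- labels == 0L
  if (any(noise)) {
    assigned[noise] <- assign_cell(grid, peaks$rt[noise], peaks$irm[noise])
  }
  for (cl in setdiff(unique(labels), 0L)) {
    sel <- labels == cl
    assigned[sel] <- assign_cell(grid, mean(peaks$rt[sel]),
                                 mean(peaks$irm[sel]))
  }
  ids_by_cluster <- split(assigned, labels)
  cluster_ids <- vapply(ids_by_cluster[names(ids_by_cluster) != "0"],
                        function(v) v[1], "")
  if (anyDuplicated(cluster_ids)) {
    warning("distinct DBSCAN clusters map to the same grid cell; merged")
  }
  fm_from_assignments(peaks$sample_id, assigned, peaks$intensity, all_ids,
                      grid, params)
}
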