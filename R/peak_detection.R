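# Peak detection: four in-package methods plus an optional hook for the
# external PEAX binary.  All methods are deterministic and return a
# data.frame of peaks ordered by (rt, irm) whose intensities equal the
# measurement value at the reported coordinates.

peaks_df <- function(sample_id = character(0), rt = numeric(0),
                     irm = numeric(0), intensity = numeric(0),
                     method = character(0), name = NULL) {
  df <- data.frame(sample_id = sample_id, rt = rt, irm = irm,
                   intensity = intensity, method = method,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- name
  if (nrow(df)) {
    df <- df[order(df$rt, df$irm), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

# Connected components (4-connectivity) of a logical matrix by iterative
# minimum-label propagation; labels are dense integers, deterministic
# (ordered by first cell in column-major order).
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, nr, nc))
  lab[idx] <- seq_along(idx)
  repeat {
    up    <- rbind(rep(Inf, nc), lab[-nr, , drop = FALSE])
    down  <- rbind(lab[-1, , drop = FALSE], rep(Inf, nc))
    left  <- cbind(rep(Inf, nr), lab[, -nc, drop = FALSE])
    right <- cbind(lab[, -1, drop = FALSE], rep(Inf, nr))
    new <- pmin(lab, up, down, left, right)
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nr, nc)
  out[idx] <- as.integer(factor(lab[idx]))
  out
}

# Grayscale erosion / dilation with a rectangular structuring element.
erode_rect <- function(x, wr, wc) {
  rr <- (wr - 1L) %/% 2L
  rc <- (wc - 1L) %/% 2L
  p <- pad_replicate(x, rr, rc)
  nr <- nrow(x)
  nc <- ncol(x)
  out <- matrix(Inf, nr, nc)
  for (di in 0:(wr - 1L)) {
    for (dj in 0:(wc - 1L)) {
      out <- pmin(out, p[di + seq_len(nr), dj + seq_len(nc)])
    }
  }
  out
}

dilate_rect <- function(x, wr, wc) {
  rr <- (wr - 1L) %/% 2L
  rc <- (wc - 1L) %/% 2L
  p <- pad_replicate(x, rr, rc)
  nr <- nrow(x)
  nc <- ncol(x)
  out <- matrix(-Inf, nr, nc)
  for (di in 0:(wr - 1L)) {
    for (dj in 0:(wc - 1L)) {
      out <- pmax(out, p[di + seq_len(nr), dj + seq_len(nc)])
    }
  }
  out
}

# Pick the maximum cell of a component; ties resolve to the smallest
# (rt index, irm index).
component_apex <- function(vals, rows, cols) {
  o <- order(-vals, rows, cols)[1]
  c(rows[o], cols[o])
}

region_peaks <- function(m, labs, method) {
  idx <- which(labs > 0L, arr.ind = TRUE)
  if (!nrow(idx)) return(peaks_df())
  comp <- labs[idx]
  vals <- m$intensity[idx]
  rows <- idx[, 1]
  cols <- idx[, 2]
  apices <- vapply(split(seq_along(comp), comp), function(ii) {
    component_apex(vals[ii], rows[ii], cols[ii])
  }, integer(2))
  peaks_df(
    sample_id = rep(m$sample_id, ncol(apices)),
    rt = m$rt_axis[apices[1, ]],
    irm = m$irm_axis[apices[2, ]],
    intensity = m$intensity[t(apices)],
    method = rep(method, ncol(apices))
  )
}

#' Tophat peak detection
#'
#' Two-step morphological extraction: intensities below `noise_threshold`
#' are zeroed, a white tophat (signal minus its opening) with a rectangular
#' structuring element highlights high-intensity areas, overlapping
#' highlighted windows are merged into connected regions, and each region
#' contributes one peak at its intensity maximum.
#'
#' @param m a preprocessed `mcc_measurement`.
#' @param noise_threshold absolute intensity threshold; everything below is
#'   discarded.
#' @param window integer vector `c(rt_points, irm_points)` of odd
#'   structuring-element dimensions.
#' @param response_threshold minimum tophat response for a cell to count as
#'   highlighted; defaults to `0.4 * noise_threshold` (the response of a
#'   peak is roughly a quarter of its apex for peaks wider than the
#'   structuring element, while smooth backgrounds respond near zero).
#' @return data.frame of peaks (`sample_id,rt,irm,intensity,method`).
#' @export
detect_tophat <- function(m, noise_threshold, window = c(5, 5),
                          response_threshold = NULL) {
  validate_measurement(m)
  if (noise_threshold < 0) stop("noise_threshold must be non-negative")
  window <- as.integer(window)
  if (any(window %% 2L == 0L)) stop("tophat window dimensions must be odd")
  if (window[1] > nrow(m$intensity) || window[2] > ncol(m$intensity)) {
    stop("tophat window larger than the measurement")
  }
  x <- m$intensity
  x[x < noise_threshold] <- 0
  opened <- dilate_rect(erode_rect(x, window[1], window[2]),
                        window[1], window[2])
  tophat <- x - opened
  # The tophat response, not the raw signal, defines the highlighted areas:
  # on smooth backgrounds (RIP tailing) the strictly-positive residual set
  # degenerates to almost the whole signal support, merging all structure
  # into one region, so the response itself is thresholded.
  response_threshold <- response_threshold %||% (0.4 * noise_threshold)
  mask <- tophat >= response_threshold & x > 0
  labs <- label_components(mask)
  region_peaks(m, labs, "TOPHAT")
}

#' JIBB peak detection
#'
#' A grid point is a peak candidate iff its intensity is `factor` times
#' above the mean noise level and, in each of the four axis directions, the
#' `rise_steps` neighbors approaching it are non-decreasing toward it
#' (equivalently non-increasing when moving away).  Adjacent candidates are
#' merged and each merged region contributes one peak at its maximum, ties
#' resolving to the smallest (rt, irm).
#'
#' @param m a preprocessed `mcc_measurement`.
#' @param noise a noise estimate from [estimate_noise()].
#' @param rise_steps number of consecutive monotone neighbors required
#'   (default 3: the test is an AND over `4 * rise_steps` difference
#'   conditions, so longer runs veto true apices once noise wiggles a
#'   flank, while 3 steps still span most of a typical peak's clean flank).
#' @param factor multiple of the noise level a peak must exceed.
#' @param min_threshold explicit absolute threshold, required when
#'   `noise$level` is zero (the factor rule degenerates).
#' @param strict if `TRUE`, every approaching step must rise strictly;
#'   the default `FALSE` allows plateaus (discretized real peaks often
#'   carry flat tops) but consequently admits isolated width-1 spikes,
#'   which strict mode rejects.
#' @return data.frame of peaks.
#' @export
detect_jibb <- function(m, noise, rise_steps = 3, factor = 1.5,
                        min_threshold = NULL, strict = FALSE) {
  validate_measurement(m)
  rise_steps <- as.integer(rise_steps)
  if (rise_steps < 1L) stop("rise_steps must be >= 1")
  if (noise$level <= 0 && is.null(min_threshold)) {
    stop("noise level is zero: supply an explicit min_threshold")
  }
  thr <- max(factor * noise$level, min_threshold %||% 0)
  x <- m$intensity
  nr <- nrow(x)
  nc <- ncol(x)
  if (nr < 2L * rise_steps + 1L || nc < 2L * rise_steps + 1L) {
    return(peaks_df())
  }
  # moving-window AND of non-negative / non-positive successive differences
  run_all <- function(ind, k) {
    # ind: matrix of 0/1; returns TRUE where the k entries ending at each
    # position (along rows) are all 1
    cs <- apply(ind, 2, cumsum)
    cs <- rbind(matrix(0, 1, ncol(ind)), cs)
    (cs[(k + 1):(nrow(ind) + 1), , drop = FALSE] -
       cs[1:(nrow(ind) + 1 - k), , drop = FALSE]) == k
  }
  cand <- x >= thr
  # RT direction
  d_rt <- diff(x)                              # d_rt[i,] = x[i+1,]-x[i,]
  up_ok <- if (strict) d_rt > 0 else d_rt >= 0
  dn_ok <- if (strict) d_rt < 0 else d_rt <= 0
  nonneg <- run_all(up_ok * 1, rise_steps)     # rows i..i+k-1 of d all ok
  nonpos <- run_all(dn_ok * 1, rise_steps)
  ok_rt <- matrix(FALSE, nr, nc)
  rows_mid <- (rise_steps + 1L):(nr - rise_steps)
  # rising toward row i: d[i-k..i-1] >= 0  -> nonneg window ending at i-1
  # falling after row i:  d[i..i+k-1] <= 0 -> nonpos window ending at i+k-1
  ok_rt[rows_mid, ] <- nonneg[rows_mid - rise_steps, , drop = FALSE] &
    nonpos[rows_mid, , drop = FALSE]
  # IRM direction (transpose)
  xt <- t(x)
  d_irm <- diff(xt)
  up_ok_i <- if (strict) d_irm > 0 else d_irm >= 0
  dn_ok_i <- if (strict) d_irm < 0 else d_irm <= 0
  nonneg_i <- run_all(up_ok_i * 1, rise_steps)
  nonpos_i <- run_all(dn_ok_i * 1, rise_steps)
  ok_irm_t <- matrix(FALSE, nc, nr)
  cols_mid <- (rise_steps + 1L):(nc - rise_steps)
  ok_irm_t[cols_mid, ] <- nonneg_i[cols_mid - rise_steps, , drop = FALSE] &
    nonpos_i[cols_mid, , drop = FALSE]
  mask <- cand & ok_rt & t(ok_irm_t)
  labs <- label_components(mask)
  region_peaks(m, labs, "JIBB")
}

#' Watershed peak detection
#'
#' Mimics a water level falling linearly from the global intensity maximum
#' to the noise level in `levels` steps.  At each step, connected components
#' (4-connectivity) of super-threshold points are computed; every component
#' that emerges without containing an already-labeled peak spawns a new peak
#' at its maximum.
#'
#' @param m a preprocessed `mcc_measurement`.
#' @param noise a noise estimate from [estimate_noise()]; the sweep stops at
#'   `noise$level`.
#' @param levels number of linear water-level steps.
#' @return data.frame of peaks; empty when nothing exceeds the noise level.
#' @export
detect_watershed <- function(m, noise, levels = 256) {
  validate_measurement(m)
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  x <- m$intensity
  mx <- max(x)
  if (mx <= noise$level) return(peaks_df())
  thrs <- seq(mx, noise$level, length.out = levels)
  nr <- nrow(x)
  nc <- ncol(x)
  # Successive super-threshold masks are nested, so labels are maintained
  # incrementally: each active cell carries the minimum linear index of its
  # component, seeded from the previous (higher) level and re-propagated
  # only until stationary.
  prio <- matrix(seq_len(nr * nc), nr, nc)
  lab <- matrix(Inf, nr, nc)
  inf_row <- rep(Inf, nc)
  inf_col <- rep(Inf, nr)
  peak_rows <- integer(0)
  peak_cols <- integer(0)
  for (thr in thrs) {
    active <- x >= thr
    newly <- active & !is.finite(lab)
    lab[newly] <- prio[newly]
    repeat {
      up    <- rbind(inf_row, lab[-nr, , drop = FALSE])
      down  <- rbind(lab[-1, , drop = FALSE], inf_row)
      left  <- cbind(inf_col, lab[, -nc, drop = FALSE])
      right <- cbind(lab[, -1, drop = FALSE], inf_col)
      new <- pmin(lab, up, down, left, right)
      new[!active] <- Inf
      if (identical(new, lab)) break
      lab <- new
    }
    occupied <- lab[cbind(peak_rows, peak_cols)]
    act_idx <- which(active)
    fresh_mask <- !(lab[act_idx] %in% occupied)
    if (!any(fresh_mask)) next
    fi <- act_idx[fresh_mask]
    comp <- lab[fi]
    rows <- (fi - 1L) %% nr + 1L
    cols <- (fi - 1L) %/% nr + 1L
    vals <- x[fi]
    for (ii in split(seq_along(comp), comp)) {
      apex <- component_apex(vals[ii], rows[ii], cols[ii])
      peak_rows <- c(peak_rows, apex[1])
      peak_cols <- c(peak_cols, apex[2])
    }
  }
  peaks_df(
    sample_id = rep(m$sample_id, length(peak_rows)),
    rt = m$rt_axis[peak_rows],
    irm = m$irm_axis[peak_cols],
    intensity = x[cbind(peak_rows, peak_cols)],
    method = rep("WATERSHED", length(peak_rows))
  )
}

#' Layer / annotation rectangle peak extraction
#'
#' For each named rectangle of the annotation, reports the in-rectangle
#' intensity maximum as a peak (if positive).  Rectangles that do not cover
#' any grid point are skipped with a warning.
#'
#' @param m a preprocessed `mcc_measurement`.
#' @param layer annotation data.frame as read by [read_layer()].
#' @return data.frame of peaks with a `name` column carrying the rectangle
#'   name.
#' @export
detect_layer <- function(m, layer) {
  validate_measurement(m)
  out <- list()
  for (i in seq_len(nrow(layer))) {
    rec <- layer[i, ]
    ri <- which(m$rt_axis >= rec$rt_center - rec$rt_radius &
                  m$rt_axis <= rec$rt_center + rec$rt_radius)
    ci <- which(m$irm_axis >= rec$irm_center - rec$irm_radius &
                  m$irm_axis <= rec$irm_center + rec$irm_radius)
    if (!length(ri) || !length(ci)) {
      warning(sprintf("layer rectangle '%s' outside measurement domain; skipped",
                      rec$name))
      next
    }
    sub <- m$intensity[ri, ci, drop = FALSE]
    if (max(sub) <= 0) next
    w <- which(sub == max(sub), arr.ind = TRUE)
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE][1, ]
    out[[length(out) + 1]] <- peaks_df(
      sample_id = m$sample_id,
      rt = m$rt_axis[ri[w[1]]],
      irm = m$irm_axis[ci[w[2]]],
      intensity = max(sub),
      method = "LAYER",
      name = rec$name
    )
  }
  if (!length(out)) return(peaks_df(name = character(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$rt, df$irm), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' External PEAX hook
#'
#' PEAX is an external, academically licensed peak extraction binary that is
#' wrapped, never re-implemented.  If the binary is absent a structured
#' `mccims_peax_unavailable` error is raised so pipelines can continue with
#' the in-package methods.
#'
#' @param m a `mcc_measurement`.
#' @param binary_path path to the PEAX executable.
#' @return data.frame of peaks parsed from the PEAX output.
#' @export
run_peax <- function(m, binary_path = NULL) {
  if (is.null(binary_path) || !file.exists(binary_path)) {
    stop(mccims_error(
      "PEAX binary not found; PEAX is optional and external - install it and pass binary_path, or use the built-in methods",
      class = "mccims_peax_unavailable"
    ))
  }
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  write_measurement(m, infile)
  status <- system2(binary_path, c(infile, outfile), stdout = FALSE,
                    stderr = FALSE)
  if (status != 0) stop("PEAX exited with status ", status)
  parse_peax_output(outfile, m$sample_id)
}

#' Parse a PEAX output file
#'
#' Tab-separated with a header containing at least the columns `t`
#' (retention time), `r` (inverse reduced ion mobility) and `signal`.
#'
#' @param path PEAX output file.
#' @param sample_id sample id to attach to the parsed peaks.
#' @return data.frame of peaks with method `PEAX`.
#' @export
parse_peax_output <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(peaks_df())
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("t", "r", "signal")
  if (!all(need %in% header)) {
    stop("PEAX output missing columns: ",
         paste(setdiff(need, header), collapse = ","))
  }
  ti <- match("t", header)
  ri <- match("r", header)
  si <- match("signal", header)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  rt <- irm <- intensity <- numeric(length(rows))
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) < length(header)) {
      stop(sprintf("malformed PEAX output row at line %d", i + 1L))
    }
    v <- suppressWarnings(as.numeric(rows[[i]][c(ti, ri, si)]))
    if (any(is.na(v))) {
      stop(sprintf("malformed PEAX output row at line %d", i + 1L))
    }
    rt[i] <- v[1]
    irm[i] <- v[2]
    intensity[i] <- v[3]
  }
  peaks_df(rep(sample_id, length(rt)), rt, irm, intensity,
           rep("PEAX", length(rt)))
}

#' Run one or more detection methods on a measurement
#'
#' @param m a preprocessed `mcc_measurement`.
#' @param methods character vector among `tophat`, `jibb`, `watershed`,
#'   `layer`, `peax`.
#' @param params list of per-method parameters (`tophat_threshold`,
#'   `tophat_window`, `jibb_rise_steps`, `jibb_factor`, `watershed_levels`,
#'   `layer`, `peax_binary`, `noise_region_max_irm`, `noise_factor`).
#' @return named list of peak data.frames, one per method.
#' @export
detect_peaks <- function(m, methods = c("tophat", "jibb", "watershed"),
                         params = list()) {
  noise <- estimate_noise(
    m, region_max_irm = params$noise_region_max_irm %||% 0.4)
  out <- list()
  for (meth in methods) {
    out[[meth]] <- switch(meth,
      # default threshold: 10% of the maximum (RIP-normalized spectra put
      # relevant analytes well above this), never below the noise floor
      tophat = detect_tophat(
        m,
        noise_threshold = params$tophat_threshold %||%
          max(0.1 * max(m$intensity),
              noise$level * (params$noise_factor %||% 1.5), 1e-12),
        window = params$tophat_window %||% c(5, 5)),
      jibb = detect_jibb(
        m, noise,
        rise_steps = params$jibb_rise_steps %||% 3,
        factor = params$jibb_factor %||% 1.5,
        min_threshold = params$jibb_min_threshold %||% 1e-12),
      watershed = detect_watershed(
        m, noise, levels = params$watershed_levels %||% 256),
      layer = detect_layer(m, params$layer),
      peax = run_peax(m, params$peax_binary),
      stop("unknown detection method: ", meth)
    )
  }
  out
}
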