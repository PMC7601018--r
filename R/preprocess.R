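# Preprocessing operators.  Every operator returns a new Measurement with
# the same axes, non-negative intensities, and one provenance step appended,
# so a stored chain can be replayed verbatim on new samples.

#' Locate the reactant ion peak (RIP) column
#'
#' The RIP is the dominant carrier-ion signal present in every spectrum.
#' Its IRM position is taken as the column with the largest total intensity;
#' ties resolve to the smallest index with a warning.
#'
#' @param m a `mcc_measurement`.
#' @return integer IRM column index (1-based).
#' @export
locate_rip <- function(m) {
  validate_measurement(m)
  sums <- colSums(m$intensity)
  idx <- which(sums == max(sums))
  if (length(idx) > 1) {
    warning("RIP column tie; using smallest IRM index")
  }
  idx[1]
}

#' Normalize intensities against the RIP maximum
#'
#' Scales all intensities by the maximum intensity found in the RIP column,
#' so the RIP maximum maps to exactly 1 and analyte intensities become
#' fractions of it. Idempotent.
#'
#' @param m a `mcc_measurement` with at least one positive intensity.
#' @param rip_irm optional IRM coordinate (Vs/cm2) overriding automatic RIP
#'   localization; the nearest IRM column is used.
#' @return normalized `mcc_measurement`.
#' @export
normalize_intensities <- function(m, rip_irm = NULL) {
  validate_measurement(m)
  if (all(m$intensity == 0)) stop("no RIP detectable: all intensities zero")
  col <- if (is.null(rip_irm)) {
    locate_rip(m)
  } else {
    which.min(abs(m$irm_axis - rip_irm))
  }
  rip_max <- max(m$intensity[, col])
  if (rip_max <= 0) stop("no RIP detectable: RIP column has no signal")
  append_step(m, m$intensity / rip_max, "normalize",
              list(rip_col = col, rip_max = rip_max))
}

#' Baseline correction / RIP detailing
#'
#' Reduces RIP tailing by subtracting, from each RT row (one IMS spectrum),
#' that row's 25% quantile intensity (linear-interpolation quantile), then
#' clamping at zero.
#'
#' @param m a `mcc_measurement`.
#' @param prob quantile probability (default 0.25).
#' @return baseline-corrected `mcc_measurement`.
#' @export
baseline_correct_rip <- function(m, prob = 0.25) {
  validate_measurement(m)
  q <- apply(m$intensity, 1, stats::quantile, probs = prob, names = FALSE,
             type = 7)
  out <- clamp0(m$intensity - q)  # q recycles down columns (per-row subtract)
  append_step(m, out, "baseline", list(prob = prob))
}

#' Estimate the technical noise level
#'
#' Averages all intensities in IRM columns below `region_max_irm`
#' (default 0.4 Vs/cm2), a region that contains neither metabolite peaks
#' nor the RIP.
#'
#' @param m a `mcc_measurement`.
#' @param region_max_irm upper IRM bound of the noise region (Vs/cm2).
#' @return list with `level` (mean intensity) and `region_max_irm`.
#' @export
estimate_noise <- function(m, region_max_irm = 0.4) {
  validate_measurement(m)
  cols <- which(m$irm_axis < region_max_irm)
  if (!length(cols)) {
    stop("no IRM columns below ", region_max_irm,
         "; set region_max_irm to cover a peak-free region")
  }
  list(level = mean(m$intensity[, cols]), region_max_irm = region_max_irm)
}

#' Subtract a fixed noise level
#'
#' @param m a `mcc_measurement`.
#' @param noise a noise estimate from [estimate_noise()] (or a list with a
#'   non-negative `level`).
#' @return `mcc_measurement` with `noise$level` subtracted everywhere and
#'   clamped at zero.
#' @export
subtract_noise <- function(m, noise) {
  validate_measurement(m)
  if (noise$level < 0) stop("noise level must be non-negative")
  append_step(m, clamp0(m$intensity - noise$level), "subtract_noise",
              list(level = noise$level,
                   region_max_irm = noise$region_max_irm %||% 0.4))
}

#' Wavelet denoising (Daubechies 8)
#'
#' Applies a per-RT-row multilevel Daubechies-8 decomposition, zeroes the
#' finest `drop_levels` detail bands, reconstructs, and clamps at zero.
#' `drop_levels = 0` is a no-op up to reconstruction round-off.
#'
#' @param m a `mcc_measurement`; rows must be at least 16 points long.
#' @param drop_levels number of finest detail bands to zero.
#' @return denoised `mcc_measurement`.
#' @export
denoise_wavelet <- function(m, drop_levels = 2) {
  validate_measurement(m)
  out <- t(apply(m$intensity, 1, wavelet_denoise_row,
                 drop_levels = as.integer(drop_levels)))
  append_step(m, clamp0(out), "wavelet",
              list(wavelet = "db8", drop_levels = drop_levels))
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing filter
#'
#' 2D Gaussian kernel (separable), nearest-value edge extension.
#'
#' @param m a `mcc_measurement`.
#' @param sigma_points kernel standard deviation in grid units.
#' @return smoothed `mcc_measurement`.
#' @export
filter_gaussian <- function(m, sigma_points = 1.0) {
  validate_measurement(m)
  k <- gaussian_kernel1d(sigma_points)
  r <- (length(k) - 1L) %/% 2L
  x <- pad_replicate(m$intensity, r, r)
  nr <- nrow(m$intensity)
  nc <- ncol(m$intensity)
  # rows direction
  tmp <- matrix(0, nr, ncol(x))
  for (j in seq_along(k)) {
    tmp <- tmp + k[j] * x[(j - 1L) + seq_len(nr), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) {
    out <- out + k[j] * tmp[, (j - 1L) + seq_len(nc), drop = FALSE]
  }
  append_step(m, clamp0(out), "gaussian", list(sigma = sigma_points))
}

#' Median smoothing filter
#'
#' Replaces every intensity by the median of its `size_points` x
#' `size_points` neighborhood (nearest-value edge extension). Removes
#' isolated spikes.
#'
#' @param m a `mcc_measurement`.
#' @param size_points odd window size.
#' @return filtered `mcc_measurement`.
#' @export
filter_median <- function(m, size_points = 3) {
  validate_measurement(m)
  size_points <- as.integer(size_points)
  if (size_points %% 2L == 0L) stop("median window size must be odd")
  if (size_points > nrow(m$intensity) || size_points > ncol(m$intensity)) {
    stop("median window larger than the measurement")
  }
  r <- (size_points - 1L) %/% 2L
  x <- pad_replicate(m$intensity, r, r)
  nr <- nrow(m$intensity)
  nc <- ncol(m$intensity)
  stack <- array(0, dim = c(nr, nc, size_points^2))
  s <- 1L
  for (di in 0:(size_points - 1L)) {
    for (dj in 0:(size_points - 1L)) {
      stack[, , s] <- x[di + seq_len(nr), dj + seq_len(nc)]
      s <- s + 1L
    }
  }
  out <- apply(stack, c(1, 2), stats::median)
  append_step(m, out, "median", list(size = size_points))
}

savgol_coeffs <- function(window, polyorder) {
  half <- (window - 1L) %/% 2L
  A <- outer(seq(-half, half), 0:polyorder, `^`)
  # least-squares polynomial fit evaluated at the window center
  solve(crossprod(A), t(A))[1, ]
}

#' Savitzky-Golay smoothing filter
#'
#' Per-RT-row local polynomial regression (weighted moving average) along
#' the IRM direction; reproduces polynomials up to `polyorder` exactly.
#' Nearest-value edge extension.
#'
#' @param m a `mcc_measurement`.
#' @param window_points odd window length, at least `polyorder + 2`.
#' @param polyorder polynomial order of the local fit.
#' @return smoothed `mcc_measurement`.
#' @export
filter_savgol <- function(m, window_points = 9, polyorder = 2) {
  validate_measurement(m)
  window_points <- as.integer(window_points)
  if (window_points %% 2L == 0L) stop("Savitzky-Golay window must be odd")
  if (window_points < polyorder + 2) {
    stop("Savitzky-Golay window must be at least polyorder + 2")
  }
  if (window_points > ncol(m$intensity)) {
    stop("Savitzky-Golay window larger than the IRM axis")
  }
  co <- savgol_coeffs(window_points, as.integer(polyorder))
  r <- (window_points - 1L) %/% 2L
  x <- pad_replicate(m$intensity, 0L, r)
  nr <- nrow(m$intensity)
  nc <- ncol(m$intensity)
  out <- matrix(0, nr, nc)
  for (j in seq_along(co)) {
    out <- out + co[j] * x[, (j - 1L) + seq_len(nc), drop = FALSE]
  }
  append_step(m, clamp0(out), "savgol",
              list(window = window_points, polyorder = polyorder))
}

#' Default preprocessing chain
#'
#' The automatic-mode chain: normalize against the RIP, baseline-correct,
#' estimate and subtract the noise level, Gaussian smoothing. Each step is
#' recorded in provenance so [apply_chain()] can replay it.
#'
#' @param m a raw `mcc_measurement`.
#' @param params list of optional overrides: `rip_irm`,
#'   `noise_region_max_irm`, `gaussian_sigma`.
#' @return preprocessed `mcc_measurement`.
#' @export
preprocess_default <- function(m, params = list()) {
  m <- normalize_intensities(m, rip_irm = params$rip_irm)
  m <- baseline_correct_rip(m)
  noise <- estimate_noise(m, region_max_irm = params$noise_region_max_irm %||% 0.4)
  m <- subtract_noise(m, noise)
  filter_gaussian(m, sigma_points = params$gaussian_sigma %||% 1.0)
}

#' Replay a preprocessing chain
#'
#' Applies the steps of a stored chain (step names + parameters, as produced
#' in measurement provenance or a model bundle) to a raw measurement.
#'
#' @param m a raw `mcc_measurement`.
#' @param chain list of `list(step=, params=)` entries.
#' @return preprocessed `mcc_measurement`.
#' @export
apply_chain <- function(m, chain) {
  for (st in chain) {
    p <- st$params
    m <- switch(st$step,
      normalize = normalize_intensities(m),
      baseline = baseline_correct_rip(m, prob = p$prob %||% 0.25),
      subtract_noise = subtract_noise(
        m, estimate_noise(m, region_max_irm = p$region_max_irm %||% 0.4)),
      wavelet = denoise_wavelet(m, drop_levels = p$drop_levels %||% 2),
      gaussian = filter_gaussian(m, sigma_points = p$sigma %||% 1.0),
      median = filter_median(m, size_points = p$size %||% 3),
      savgol = filter_savgol(m, window_points = p$window %||% 9,
                             polyorder = p$polyorder %||% 2),
      stop("unknown preprocessing step: ", st$step)
    )
  }
  m
}
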