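# Synthetic MCC-IMS spectra with known ground truth: a reactant ion peak
# (RIP) column with exponential tailing toward higher IRM, class-conditional
# 2D Gaussian analyte peaks, and clamped Gaussian noise.  The generator
# exists so every pipeline stage is testable offline against planted truth.

#' Specify a synthetic spectrum generator
#'
#' Defaults state a plausible small bench scenario: an 80 x 160 grid over
#' RT 0-50 s and IRM 0-1.2 Vs/cm2, a RIP at 0.48 Vs/cm2 of height 10
#' (arbitrary raw units) with exponential tailing, analyte peaks of height
#' 5 = 10x the noise standard deviation of 0.5 and widths of 4-6 grid
#' points per axis (so monotone flanks span a detection window), and
#' positional jitter small enough (3 sd < half a default grid-cell width of
#' 0.025 Vs/cm2) that a planted peak stays in its alignment cell.
#'
#' @param rt_points,irm_points grid sizes.
#' @param rt_max_axis,irm_max_axis axis upper limits (axes start at 0).
#' @param rip_irm RIP position (Vs/cm2).
#' @param rip_height RIP apex intensity (raw units).
#' @param rip_sigma RIP width in IRM (Vs/cm2).
#' @param tail_height,tail_decay exponential RIP-tailing amplitude and
#'   per-IRM-unit decay constant.
#' @param peaks data.frame of planted analyte peaks: `rt_center`,
#'   `irm_center`, `rt_sigma`, `irm_sigma`, `height`, `label` (`NA` =
#'   shared by both classes).
#' @param noise_sd standard deviation of the additive clamped Gaussian
#'   noise.
#' @param rt_jitter_sd,irm_jitter_sd per-sample positional jitter of the
#'   planted peak centers.
#' @param seed master seed.
#' @return list of class `mcc_synth_spec`.
#' @export
synth_spec <- function(rt_points = 80, irm_points = 160,
                       rt_max_axis = 50, irm_max_axis = 1.2,
                       rip_irm = 0.48, rip_height = 10, rip_sigma = 0.02,
                       tail_height = 3, tail_decay = 8,
                       peaks = default_synth_peaks(),
                       noise_sd = 0.5,
                       rt_jitter_sd = 0.4, irm_jitter_sd = 0.004,
                       seed = 42) {
  stopifnot(all(peaks$rt_sigma > 0), all(peaks$irm_sigma > 0))
  stopifnot(rip_irm >= 0, rip_irm <= irm_max_axis)
  stopifnot(all(peaks$rt_center <= 2000), all(peaks$irm_center <= 1.6))
  structure(
    list(rt_points = as.integer(rt_points),
         irm_points = as.integer(irm_points),
         rt_max_axis = rt_max_axis, irm_max_axis = irm_max_axis,
         rip_irm = rip_irm, rip_height = rip_height, rip_sigma = rip_sigma,
         tail_height = tail_height, tail_decay = tail_decay,
         peaks = peaks, noise_sd = noise_sd,
         rt_jitter_sd = rt_jitter_sd, irm_jitter_sd = irm_jitter_sd,
         seed = seed),
    class = "mcc_synth_spec"
  )
}

#' Default planted analyte peaks
#'
#' One discriminative peak per class near the canonical example positions
#' (RT 28.7 s; IRM ~0.6 for the first class, ~0.84 for the second) plus one
#' shared peak both classes carry.  IRM centers sit at the center of their
#' default alignment-grid cell (w = 0.025) so that sub-cell positional
#' jitter cannot split a planted peak across two cells.
#'
#' @param class_a,class_b the two class labels.
#' @param height analyte apex height (raw units).
#' @return data.frame of peak definitions.
#' @export
default_synth_peaks <- function(class_a = "citrus", class_b = "menthol",
                                height = 5) {
  data.frame(
    rt_center = c(28.7, 28.7, 10.0),
    irm_center = c(0.6125, 0.8375, 0.7125),
    rt_sigma = c(3.5, 3.5, 3.0),
    irm_sigma = c(0.03, 0.03, 0.025),
    height = c(height, height, height * 0.8),
    label = c(class_a, class_b, NA),
    stringsAsFactors = FALSE
  )
}

#' Generate one synthetic measurement
#'
#' Intensity = RIP column (Gaussian in IRM, constant along RT)
#' + exponential tail toward higher IRM + 2D Gaussians for shared peaks and
#' peaks matching `label` (centers jittered per sample) + clamped Gaussian
#' noise.
#'
#' @param spec a [synth_spec()].
#' @param label class label of the sample.
#' @param sample_id sample identifier.
#' @param sample_seed per-sample RNG seed.
#' @return list with `measurement` (a `mcc_measurement`) and
#'   `ground_truth`: a data.frame of planted apices
#'   (`sample_id, rt, irm, intensity, method = "TRUTH"`), positions after
#'   jitter.
#' @export
generate_measurement <- function(spec, label, sample_id, sample_seed) {
  rt_axis <- seq(0, spec$rt_max_axis, length.out = spec$rt_points)
  irm_axis <- seq(0, spec$irm_max_axis, length.out = spec$irm_points)
  rip <- spec$rip_height * exp(-(irm_axis - spec$rip_irm)^2 /
                                 (2 * spec$rip_sigma^2))
  tail <- ifelse(irm_axis >= spec$rip_irm,
                 spec$tail_height *
                   exp(-spec$tail_decay * (irm_axis - spec$rip_irm)),
                 0)
  base_row <- rip + tail
  intensity <- matrix(base_row, nrow = spec$rt_points,
                      ncol = spec$irm_points, byrow = TRUE)
  active <- spec$peaks[is.na(spec$peaks$label) | spec$peaks$label == label, ,
                       drop = FALSE]
  truth <- list()
  with_seed(sample_seed, {
    for (i in seq_len(nrow(active))) {
      pk <- active[i, ]
      rt_c <- pk$rt_center + stats::rnorm(1, 0, spec$rt_jitter_sd)
      irm_c <- pk$irm_center + stats::rnorm(1, 0, spec$irm_jitter_sd)
      bump <- pk$height *
        exp(-(rt_axis - rt_c)^2 / (2 * pk$rt_sigma^2)) %o%
        exp(-(irm_axis - irm_c)^2 / (2 * pk$irm_sigma^2))
      intensity <- intensity + bump
      truth[[i]] <- data.frame(
        sample_id = sample_id, rt = rt_c, irm = irm_c,
        intensity = pk$height, method = "TRUTH",
        shared = is.na(pk$label), stringsAsFactors = FALSE)
    }
    if (spec$noise_sd > 0) {
      intensity <- intensity +
        matrix(stats::rnorm(length(intensity), 0, spec$noise_sd),
               nrow = nrow(intensity))
    }
  })
  intensity <- clamp0(intensity)
  list(
    measurement = new_measurement(sample_id, rt_axis, irm_axis, intensity,
                                  label = label),
    ground_truth = if (length(truth)) do.call(rbind, truth) else
      data.frame(sample_id = character(0), rt = numeric(0),
                 irm = numeric(0), intensity = numeric(0),
                 method = character(0), shared = logical(0))
  )
}

#' Generate a synthetic two-class dataset
#'
#' Per-sample seeds are derived deterministically from the spec's master
#' seed, so the same spec always yields the same dataset.
#'
#' @param spec a [synth_spec()].
#' @param n_per_class named integer vector, e.g. `c(citrus = 20,
#'   menthol = 22)`.
#' @return list with `measurements` (named list), `labels` (named character
#'   vector) and `ground_truth` (pooled planted-apex data.frame).
#' @export
generate_dataset <- function(spec, n_per_class) {
  if (length(n_per_class) != 2) stop("two classes required")
  classes <- sort(names(n_per_class))
  measurements <- list()
  labels <- character(0)
  truth <- list()
  counter <- 0L
  for (cl in classes) {
    for (i in seq_len(n_per_class[[cl]])) {
      counter <- counter + 1L
      sid <- sprintf("%s_%02d", cl, i)
      g <- generate_measurement(spec, cl, sid,
                                sample_seed = derive_seed(spec$seed, counter))
      measurements[[sid]] <- g$measurement
      labels[sid] <- cl
      truth[[sid]] <- g$ground_truth
    }
  }
  list(measurements = measurements, labels = labels,
       ground_truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Named dataset presets
#'
#' `candy` mirrors the two-flavor candy design (20 "citrus" vs 22
#' "menthol" samples); `copd` mirrors the clinical design (93 "COPD" vs 35
#' "Control"); `minimal` is a fast 6 vs 6 smoke-test set.
#'
#' @param preset one of `"candy"`, `"copd"`, `"minimal"`.
#' @param seed master seed.
#' @return list as from [generate_dataset()], plus `spec`.
#' @export
synth_preset <- function(preset = c("candy", "copd", "minimal"), seed = 42) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    candy = list(spec = synth_spec(seed = seed),
                 n = c(citrus = 20L, menthol = 22L)),
    copd = list(
      spec = synth_spec(
        peaks = default_synth_peaks(class_a = "COPD", class_b = "Control"),
        seed = seed),
      n = c(COPD = 93L, Control = 35L)),
    minimal = list(
      spec = synth_spec(rt_points = 64, irm_points = 128, seed = seed),
      n = c(citrus = 6L, menthol = 6L))
  )
  out <- generate_dataset(cfg$spec, cfg$n)
  out$spec <- cfg$spec
  out
}
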