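# Shared fixtures, built in code.

# Minimal measurement with explicit axes/intensities.
make_measurement <- function(intensity, rt = seq_len(nrow(intensity)),
                             irm = seq(0.1, by = 0.1,
                                       length.out = ncol(intensity)),
                             id = "fx") {
  new_measurement(id, rt, irm, intensity)
}

# A clean 2D Gaussian bump on a zero background.
gaussian_measurement <- function(rt_points = 64, irm_points = 120,
                                 rt_c = 25, irm_c = 0.6,
                                 rt_sigma = 2, irm_sigma = 0.04,
                                 height = 1, id = "gauss") {
  rt <- seq(0, 50, length.out = rt_points)
  irm <- seq(0, 1.2, length.out = irm_points)
  bump <- height * exp(-(rt - rt_c)^2 / (2 * rt_sigma^2)) %o%
    exp(-(irm - irm_c)^2 / (2 * irm_sigma^2))
  new_measurement(id, rt, irm, bump)
}

# Grid apex (rt, irm) of a measurement's maximum.
matrix_apex <- function(m) {
  w <- which(m$intensity == max(m$intensity), arr.ind = TRUE)[1, ]
  c(rt = m$rt_axis[w[1]], irm = m$irm_axis[w[2]])
}

# Tiny labelled feature matrix.
make_fm <- function(values, labels = NULL) {
  fm <- new_feature_matrix(values)
  fm$labels <- labels
  fm
}

# A separable two-class feature matrix: feature 1 separates, the rest are
# seeded uniform noise.
separable_fm <- function(n_per_class = 10, n_noise = 5, gap = 1, seed = 7) {
  n <- 2 * n_per_class
  vals <- withr_seed_matrix(n, n_noise + 1, seed)
  labels <- rep(c("case", "control"), each = n_per_class)
  vals[, 1] <- runif_seeded(n, seed + 1) * 0.3 +
    ifelse(labels == "case", gap, 0)
  ids <- sprintf("s%02d", seq_len(n))
  rownames(vals) <- ids
  colnames(vals) <- sprintf("Peak_%04d", seq_len(n_noise + 1))
  list(fm = new_feature_matrix(vals), labels = stats::setNames(labels, ids))
}

withr_seed_matrix <- function(n, p, seed) {
  mccims:::with_seed(seed, matrix(stats::runif(n * p), n, p))
}

runif_seeded <- function(n, seed) {
  mccims:::with_seed(seed, stats::runif(n))
}
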