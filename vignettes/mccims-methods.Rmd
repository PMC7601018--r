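---
title: "mccims: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mccims: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mccims)
```

# The problem and the model

An MCC-IMS measurement is a matrix of non-negative, arbitrary-unit
intensities over retention time (RT, seconds; rows) and inverse reduced ion
mobility (IRM, Vs/cm²; columns). Each volatile organic compound appears as
an approximately 2D-Gaussian peak; the carrier gas contributes a reactant
ion peak (RIP) — a dominant, RT-persistent column with intensity tailing
toward higher IRM. Given two groups of labelled measurements (binary
case–control), the package asks: which peak positions differ between the
groups, and how well does a classifier built on them separate unseen
samples?

The statistical model is deliberately non-parametric end to end: peak
positions are aligned to a fixed grid, per-feature association is measured
by the Mann–Whitney U test (with Benjamini–Hochberg FDR control) and by the
mean decrease in Gini impurity of a random forest, and the classifier is a
bagged forest whose vote fractions feed a trapezoid ROC. A single CART tree
trained on the same selected features serves only as an interpretable
surrogate — tuning it never changes the classifier.

# Preprocessing assumptions

* **Normalization** divides by the maximum intensity in the RIP column, so
  the RIP maps to exactly 1.0 and analyte intensities become fractions of
  it. The RIP column is located as the IRM column with the largest total
  intensity (ties resolve to the smallest index with a warning); an
  explicit `rip_irm` coordinate overrides this. Normalization is a
  monotone transform, hence idempotent and apex-order preserving.
* **Baseline correction** subtracts the 25% intensity quantile of each RT
  row (one IMS spectrum) and clamps at zero. The per-row granularity is a
  design choice: RIP tailing varies along RT, so a global quantile would
  under-correct early spectra. The quantile uses linear interpolation
  (R type 7); results depend on this rule, so it is fixed and documented.
* **Noise estimation** averages all intensities in IRM columns strictly
  below `region_max_irm = 0.4` Vs/cm², a region holding neither analytes
  nor the RIP; `subtract_noise` removes that level everywhere, clamped at
  zero. All subtraction results are clamped because intensities are
  physical non-negatives.
* **Denoising** offers four operators, each shape- and axis-preserving:
  a per-RT-row Daubechies-8 wavelet shrinkage that zeroes the finest
  `drop_levels = 2` detail bands (whether the reference implementation
  applies the transform per row, per column or in 2D is unstated; per-row
  was chosen and is flagged here), a 2D Gaussian kernel
  (`gaussian_sigma = 1.0` grid units), a 2D median filter
  (`median_size = 3`), and a per-row Savitzky–Golay filter
  (`savgol_window = 9`, `savgol_polyorder = 2`), all with nearest-value
  edge extension. The default automatic chain is
  normalize → baseline → noise subtraction → Gaussian smoothing; every
  step is recorded in the measurement's provenance so prediction can
  replay the identical chain on raw held-out files.

# Peak detection

**Tophat.** Intensities below the user threshold are zeroed, and a white
tophat (signal minus its morphological opening) with a 5×5 rectangular
structuring element highlights compact bright structure. One deliberate
deviation from the naive recipe: cells count as highlighted when the
*tophat response* is at least `response_threshold` (default 0.4 × the
intensity threshold), not merely positive. On smooth backgrounds the
strictly-positive residual set degenerates to almost the entire signal
support — the opening of a monotone profile equals the profile, so noise
makes the residual weakly positive nearly everywhere — which merges the
RIP, its tail and every analyte into a single region and reports only the
RIP apex. Thresholding the response restores the intended "highlight
high-intensity areas" semantics; the 0.4 factor reflects that a peak wider
than the structuring element responds with roughly a quarter of its apex
height while smooth backgrounds respond near zero. The automatic-mode
intensity threshold defaults to 10% of the measurement maximum (floored at
1.5 × the noise level): on RIP-normalized spectra, analytes of interest sit
well above 0.1 while smoothed noise stays below ~0.05.

**JIBB (monotone-rise search).** A grid point is a candidate iff its
intensity is `factor = 1.5` times the mean noise level and, in all four
axis directions, the `rise_steps` neighbours approaching it are
non-decreasing toward it. The run length is the sensitive knob: the test
is an AND over `4 × rise_steps` successive-difference conditions, so at
realistic signal-to-noise a long run is vetoed by a single smoothed-noise
wiggle on one flank. The default is 3 (spanning ~0.75 σ of a typical
peak's clean flank, still a 12-condition test); the non-strict (≥)
comparison is used because discretized real peaks carry flat tops — the
cost is that an isolated width-1 spike also qualifies, and `strict = TRUE`
is available for the strict reading. Plateau ties resolve to the smallest
(RT, IRM).

**Watershed.** A water level falls linearly from the global maximum to the
noise level in `levels = 256` steps; at each step the connected components
(4-connectivity) of super-threshold cells are computed, and a component
that emerges without containing an already-labelled peak spawns one at its
maximum. The discretization (256 linear levels) and connectivity are
package choices; the method is exact for the metaphor at the chosen
resolution. Because the floor is the (small) post-subtraction noise level,
watershed emits many noise speckles by design — feature reduction is the
stage that removes them.

**Layer rectangles.** Each named rectangle of a VisualNow-style annotation
contributes the in-rectangle maximum as a peak if positive; rectangles are
independent (overlaps yield one peak each), empty or out-of-domain
rectangles are skipped with a warning.

Every detector is deterministic, returns peaks ordered by (RT, IRM), and
reports the measurement's own intensity at the reported coordinate.

# Alignment

The probe-clustering grid spans RT ∈ [0, 2000] s and IRM ∈ [0, 1.6] Vs/cm².
Row boundaries follow the printed recurrence
`H(0) = 0, H(1) = 3, H(q) = H(q−1) + (1 + s_rt)·H(q−1)` — i.e. boundaries
grow geometrically by `2 + s_rt` — clipped at 2000 s. This form is
implemented exactly as stated even though one may suspect the intent was
for the row *heights* to grow by `1 + s_rt`; the `equation_variant =
"additive"` escape hatch provides that reading without guessing. Columns
are uniform cells of width `w`; defaults `w = 0.025`, `s_rt = 0` are the
package's own (no defaults are published; 0.025 Vs/cm² gives IRM
resolution at which typical neighbouring analytes land in distinct cells).
Rows and columns are half-open with the top/right domain edge clipped into
the last cell, so assignment is a total function. Feature values take the
per-(sample, cell) intensity maximum — apex semantics when several
detections share a cell.

DBSCAN alignment clusters pooled peak positions with Euclidean distance on
`(rt/2000, irm/1.6)` — the axes are incommensurate, so both are normalized
by their domain — with defaults `eps = 0.01`, `min_samples = 2`. Clusters
are labelled by the grid cell of their mean position; noise peaks keep
their own cell. At prediction time new peaks are assigned directly to grid
cells, because cluster means are training-time quantities; the grid
guarantees the feature positions match.

# Feature reduction, scoring, model estimation

Reduction keeps a feature iff its presence fraction (value ≥
`min_intensity`) reaches `pct_threshold` (default 50%) in either class.
Presence is a test, not a mask: sub-threshold values in surviving columns
are retained. `min_intensity` defaults to 0.1 in RIP-normalized units —
low enough that weaker analytes survive, high enough to remove watershed
noise speckles (≲ 5 sd of smoothed noise ≈ 0.05); the boundary comparison
is ≥ on both thresholds.

Mann–Whitney p-values switch from the exact null distribution to the
tie-corrected normal approximation when a group exceeds 8 samples or ties
occur; p-values near the 0.05 significance cutoff can depend on this
switch, which is why it is fixed and documented. BH q-values use the
step-up rule with monotonicity enforcement. Gini importances come from a
seeded forest (default 500 trees, `mtry = ⌊√p⌋`, fully grown), normalized
to sum to 1. The two rank orders break ties by the other criterion and
then by peak id, so rankings are total and deterministic.

Fold selection implements `k = min(⌊n_min/5⌋, 10)` with CV omitted below
10 minority samples — the only form consistent with a worked 15/20 → 3
example and the rationale that every test fold keeps ≥ 5 samples per
class. When CV is omitted the package trains on all data and reports
resubstitution metrics flagged `cv_omitted = TRUE` rather than silently
reporting nothing. A user-supplied `k` overrides the rule (this is how a
ten-fold run with a 31-sample minority is reproduced) but must not exceed
the minority count. The ROC positive class defaults to the
lexicographically greater label, overridable via `positive_class`. In
automatic mode all methods share one preprocessed stack; the winner is the
highest mean ROC-AUC, ties broken by mean accuracy, then method name.

Decision-tree defaults are unlimited depth, `min_samples_split = 2`,
`min_samples_leaf = 1`; raising them trades training fit for
generalization of the *interpretation* only.

# The synthetic generator

`synth_spec()` states one fixed world: an 80 × 160 grid over RT 0–50 s and
IRM 0–1.2 Vs/cm²; a RIP at 0.48 Vs/cm² of height 10 raw units (σ = 0.02)
with exponential tailing (amplitude 3, decay 8 per Vs/cm²); analyte peaks
of height 5 = 10 × the noise sd of 0.5, with widths σ_rt = 3.5 s (~5.5
grid points) and σ_irm = 0.03 (~4 points) so monotone flanks span a
detection window and the RIP-tail saddle lies ~10 points from the planted
apex; clamped Gaussian noise; and positional jitter (sd 0.4 s in RT,
0.004 Vs/cm² in IRM — 3 sd below half a default grid cell, so a planted
peak stays in its alignment cell). The two discriminative peaks sit at RT
28.7 s, IRM 0.6125 and 0.8375: near the canonical example coordinates but
snapped to the *centers* of their default grid cells, because the raw
coordinates 0.600/0.846 fall on or within jitter range of cell boundaries
and would split a peak's feature value across two columns by floating-point
accident rather than by biology.

What the generator emulates: the RIP with tailing, class-conditional and
shared 2D-Gaussian analytes, additive technical noise, and sub-cell
positional jitter. What it does not: drift-gas chemistry, humidity
effects, RT warping between runs, batch effects across devices, or
correlated (structured) noise. A green recovery test therefore establishes
that the pipeline machinery is correct under the stated world — not that
any particular clinical dataset will separate.

# Numerical choices and degenerate inputs

* Quantiles: linear interpolation (type 7). Wavelet: periodized orthogonal
  transform, odd lengths padded by repeating the last sample (dropped on
  reconstruction); perfect reconstruction to 1e-9 is asserted.
* Connected components: iterative minimum-label propagation,
  4-connectivity; deterministic labels.
* All apex tie-breaks: smallest (RT, IRM).
* All-zero measurement → "no RIP detectable" error at normalization; a
  zero noise level makes JIBB's factor rule degenerate and an explicit
  `min_threshold` is required.
* Every randomized routine takes a seed; per-fold, per-sample and
  per-stage seeds are derived arithmetically from the master seed and stay
  below 2³¹. RNG state is saved and restored around seeded sections, so
  library calls never perturb ambient randomness.
* Forest probabilities are vote fractions; an exact 0.5 leaf votes for the
  lexicographically smaller class, so predictions are deterministic.

# Known limitations

The random forest and CART implementation is pure R, sized for the tens to
low hundreds of samples typical of breath studies, not for thousands.
Multi-class problems, covariate adjustment, oversampling of imbalanced
classes and cross-device scaling are out of scope. PEAX is wrapped as an
optional external binary, never re-implemented. The decision tree is an
interpretation aid; its misclassifications do not reflect the forest's.
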