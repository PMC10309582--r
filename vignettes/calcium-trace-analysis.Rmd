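---
title: "Methods: from calcium movies to clustered response profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from calcium movies to clustered response profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its methods: the models and
procedures implemented, the parameters that matter, the numerical
decisions taken where the design was genuinely open, and what the
simulator-based validation does and does not establish about real
recordings.

## The experimental design being modeled

The package targets single-channel fluorescence time-lapse recordings of
a calcium indicator (e.g. Fluo-4-AM) in cultured cells under a
stimulus-response protocol: a short pre-stimulus series, addition of an
agonist such as ATP to the bath, and several minutes of post-stimulus
acquisition of the same field. The defaults throughout encode a 1-min
baseline followed by a 10-min response at 1 frame/s — 660 frames, with
`stimulus_frame = 60` marking the last pre-stimulus frame. The two
series are represented as one concatenated stack with a single time
axis, because every downstream quantity (baseline, transient shape,
eigenfunctions) is defined on one clock. Both the frame interval and the
stimulus frame are configuration, not assumptions baked into any
algorithm.

## Drift correction

Stage and sample drift over ten minutes is modeled as a rigid 2-D
translation per frame, estimated against the first frame. The estimator
takes the peak of the FFT cross-correlation of the mean-removed frames
and refines it on a ±1.5 px window sampled at 0.1 px (a matrix-multiply
DFT with upsampling factor 10). Two numerical choices deserve note:

* **No full spectral whitening.** Classical phase correlation divides
  the cross-spectrum by its magnitude. On smooth, low-noise scenes —
  exactly what a background-subtracted field of fluorescent somata looks
  like — the high-frequency bins carry no signal, and whitening promotes
  their noise to equal weight; in testing this misplaced the integer
  peak on noise-free frames with half-pixel shifts. The unwhitened
  cross-correlation of mean-removed frames has no such failure mode and
  is exact on circularly shifted frames, so it is used instead.
* **Tie-breaking and fill.** Ties in the refined correlation peak go to
  the smaller-magnitude shift, making the estimate deterministic.
  Correction resamples each frame by separable Catmull-Rom cubic
  convolution; pixels sampled outside the field are filled with the
  frame's median, which perturbs background statistics minimally, and
  integer shifts reproduce pixel values exactly.

Rotation and scale changes are out of scope: recordings are short,
same-field acquisitions in which translation dominates.

## Semi-automated soma segmentation

Segmentation reproduces a marker-based masking recipe on a time
projection of the movie (maximum projection by default — a cell that
only lights up after the stimulus still appears; mean projection is
available for very noisy data, and the indicator's "leaky" baseline
fluorescence outlines even silent cells):

1. **Seeds.** Local maxima with prominence at least
   `maxima_rel_prominence` (default 0.1) times the projection's
   intensity range, found via the h-maxima transform (greyscale
   reconstruction by dilation), then thinned so that no two seeds are
   closer than `maxima_min_distance_px` (default 10 px), strongest
   first. Prominence is relative, which makes seeding invariant to
   detector gain.
2. **Tile borders.** The plane is partitioned into nearest-seed regions
   (Euclidean; equidistant pixels go to the smaller seed index, so the
   tessellation is deterministic), and the one-pixel border between
   adjacent tiles is retained.
3. **Threshold.** Li & Tam's iterative scheme for the Li/Lee minimum
   cross-entropy threshold separates cells from background. The
   iteration `t ← (μ_bg − μ_fg)/(log μ_bg − log μ_fg)` is
   scale-equivariant, so the whole pipeline yields an identical label
   map when the stack is multiplied by any positive constant (verified
   by test).
4. **Cut, clean, label.** Tile borders are removed from the thresholded
   foreground (the polarity-unambiguous form of XOR-ing a threshold mask
   with an inverted tile mask), touching cells thereby separate; opening
   with a 2 px disk removes specks and smooths outlines; background
   holes not connected to the border are filled; connected components
   (8-connectivity by default) are filtered to `[50, 5000]` px² and,
   optionally, stripped of border-touching components, then relabelled
   by decreasing area.

The original recipe includes manual inspection steps (removing clumps,
splitting ROIs joined by a pixel or two). Those are replaced here by the
area filter, the edge filter and the tile-border cut; the ROI table can
be edited and re-read (`write_rois()` / `read_rois()`) where human
curation is still wanted. Defaults suit 20× fields at roughly 1 px/µm
with somata of 5–15 px radius; all of them live in `seg_params()` and in
the run configuration, never in code.

## Traces and ΔF/F₀

Each ROI's raw trace is the arithmetic mean gray value per frame over
the ROI's pixels — a linear functional of the stack, which the tests
exploit. Normalization is ΔF/F₀ = (F − F₀)/F₀ with F₀ the mean of the
**last** `n_baseline = 20` frames before the stimulus. Anchoring the
window at the stimulus (rather than the recording start) uses the
baseline frames closest to stimulation and is robust to settling early
in the recording. Cells with F₀ ≤ 0 abort the run with the cell named:
a nonpositive baseline is a segmentation artifact that should be seen,
not silently dropped. Peak amplitude is the maximum ΔF/F₀ over all
post-stimulus frames (no window bound — the designs targeted here have a
single stimulus), and group summaries are reported as mean ± sd (n − 1
denominator). Per-group random subsampling (e.g. 52 cells per line) is
uniform without replacement under a fixed seed; nothing in the method
favors any more elaborate scheme.

## Functional PCA

The curves are densely and completely observed on a common regular grid,
so the package fixes the dense-design estimator: cross-sectional mean
μ(t), sample covariance C (n − 1 denominator), and eigendecomposition of
`W^{1/2} C W^{1/2}` with quadrature weights W. Eigenfunctions are
normalized to unit L² norm under the quadrature inner product and scores
are the weighted projections of the centered curves.

* **Quadrature weights.** On a (numerically) uniform grid the weights
  are `w_t = Δt` for every t. This makes the estimator *exactly* a
  rescaled matrix PCA — eigenvalues are Δt times those of C, scores are
  PCA scores times √Δt — which is what the oracle tests assert to 1e-8.
  Trapezoid weights (half weight at the endpoints) would break that
  identity at the 1e-3 level for no statistical gain on a dense grid, so
  they are used only for genuinely non-uniform grids, with a warning.
* **No covariance smoothing.** Smoothing-based fPCA estimators exist for
  sparse or irregular designs; at 1 frame/s with every cell fully
  observed the raw estimator is deterministic, faster, and directly
  checkable. A `smooth` flag is reserved in the interface and rejects
  `TRUE`, making the choice explicit rather than silent.
* **Determinacy of signs and ranks.** Each eigenfunction is oriented so
  its largest-magnitude value is positive (eigenvectors are defined only
  up to sign, and different LAPACK paths choose differently); eigenvalues
  below 1e-12·λ₁ are treated as numerically zero and dropped, so the
  retained rank is at most min(n − 1, T).

Truncation keeps the smallest K whose cumulative fraction of variance
explained reaches `fve_threshold` (default 0.95). Reconstruction from K
scores is the denoised data; with all components it reproduces the input
to 1e-8 (tested), and the reconstruction error is monotone in K.

## Clustering, the elbow, and the embedding

k-means runs on the truncated FPC scores with k-means++ seeding, Lloyd
iterations, and the best of 10 restarts by within-cluster sum of squares
(WSS); labels are renumbered by decreasing cluster size (ties: smaller
centroid norm), so results do not depend on cell order or restart order.
Scores are used unstandardized: their scale is √λₖ, which is exactly the
information a variance-based truncation means to keep.

The elbow scan fits every k in `1:8` and suggests the interior k with
the largest discrete second difference of the WSS curve. Two properties
of that rule matter in practice:

* It finds the point of greatest curvature, which is the dominant
  structural break. When cluster separations are hierarchical — e.g.
  three groups that differ along one amplitude axis with unequal gaps —
  the dominant break is the *first* split and the rule suggests k = 2
  even when finer, real structure exists at k = 3. With near-equilateral
  geometry it suggests k = 3 reliably. For this reason the suggestion is
  never silently final: the full WSS curve is always returned and
  printed, `run_config(k = …)` overrides it, and the intended workflow
  is to confirm the choice against the embedding — mirroring how k is
  chosen by elbow plot *plus* visual evaluation in practice.
* A suggestion whose relative WSS drop is below 5% is flagged
  low-confidence (a near-flat curve has no meaningful elbow).

UMAP (n_neighbors = 15, min_dist = 0.1, fixed seed, single-threaded so
coordinates are reproducible) is display only. Clustering never sees the
embedding, so no embedding distortion can change an assignment — the
package treats "cluster on scores, draw on UMAP" as a design rule, and a
test asserts that re-embedding under other seeds leaves labels
untouched.

## The simulator: what it emulates, and what it does not

`simulate_traces()` draws, per cell, F(t) = F₀·bleach(t)·(1 + a·g(t)) +
F₀·σ·ε(t): a baseline F₀ (100 ± 10% across cells), an optional shared
exponential photobleach, a stimulus-locked transient g — a
double-exponential with rise τ_r = 5 s and decay τ_d = 30 s, normalized
so its sampled peak is exactly 1, hence peak ΔF/F₀ = a — and Gaussian
noise expressed *relative to the cell's baseline*, so `noise_sd = 0.05`
means 0.05 ΔF/F₀ units regardless of detector gain. Three archetypes set
the amplitude distributions (truncated at zero): non-responders a = 0,
low responders 0.3 ± 0.05, high responders 1.2 ± 0.15. The means encode
clearly separated response classes; the spreads add modest cell-to-cell
variability without blurring class identity. Archetype counts follow the
configured proportions exactly (largest-remainder rounding, then a
seeded shuffle), so truth tables are never off by rounding.

`simulate_movie()` renders each cell as a 2-D Gaussian soma (σ drawn
from 4–7 px) on a flat background with per-pixel read noise (clamped at
the sensor floor 0), optional sinusoidal stage drift applied to the soma
centers (recorded relative to frame 1 as ground truth), and a truth
label map. The truth footprint of a soma is its **2σ disc**, which
encloses ≈86% of the fluorescence mass — about what an annotator would
outline as the cell body. The 1σ disc would be the wrong reference for
segmentation scoring: any background-separating threshold on a Gaussian
profile captures ~1.5–2σ, so even a perfect segmenter could not match a
1σ truth disc at IoU ≥ 0.5, whereas against the 2σ footprint the
pipeline scores IoU ≈ 0.7–0.9 per soma.

What the simulator deliberately does **not** emulate: indicator
biophysics (the double-exponential is a shape of controllable amplitude,
not a calcium-binding model), spontaneous (non-stimulus-locked)
transients, overlapping or irregularly shaped cells, neuropil
contamination, focus changes, and non-rigid motion. Passing the
simulator-based tests therefore establishes that the implementation is
correct under the stated generative model — recovery of known drift,
footprints, amplitudes, shapes and archetypes — not that the defaults
are optimal for any particular real preparation.

One consequence worth stating plainly: with the three archetypes
differing only in amplitude, all structure is collinear in function
space, the between-class gaps are unequal (0.3 vs 0.9 ΔF/F₀), and the
maximum-curvature elbow on the WSS curve lands on the dominant split at
k = 2 — reproducibly, across seeds — while k-means at k = 3 recovers the
three archetypes essentially perfectly (ARI ≈ 1). This is a property of
the elbow rule under collinear hierarchical separations, not an
implementation artifact, and it is why the human-in-the-loop override
exists.

## Reproducibility and problem sizes

Every stochastic step (simulation, k-means seeding, UMAP) takes an
explicit seed and restores the caller's RNG state; `run_declutter()`
writes a manifest of every parameter and seed actually used, and two
runs with the same configuration produce byte-identical CSVs. The test
suite validates trace-level properties at n = 100–600 cells on the full
660-frame grid, and movie-level properties on 96–224 px fields with
6–30 somata — sizes chosen so the whole suite exercises every stage,
including a full-size 30-soma segmentation recovery, at desk scale.

## Known limitations

* Rigid translation only; rotation, scale and non-rigid deformation are
  not corrected.
* One global Li threshold per field: strong illumination gradients
  should be flattened beforehand.
* The fPCA estimator assumes a common complete grid; cells with missing
  frames are not supported (and would need the sparse estimator the
  `smooth` flag reserves space for).
* The elbow suggestion inherits the biases discussed above; treat it as
  a proposal.
* 32-bit float TIFFs are stored as value/65535 (a package convention;
  integer TIFFs round-trip bit-exactly).
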