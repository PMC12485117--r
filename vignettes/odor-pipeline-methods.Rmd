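---
title: "Methods: dual-channel odor-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-channel odor-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`olfactr` analyzes simultaneous volumetric recordings of a calcium
indicator and a fluorescent neurotransmitter sensor (ACh or 5-HT) during
repeated odor trials. This vignette documents the models and procedures,
the parameters that matter, the synthetic-data generator used for
validation, and the numerical and design choices that were genuinely open.

## Input model and assumptions

The pipeline assumes its inputs are already denoised, motion-corrected and
atlas-aligned: per channel a voxels × frames fluorescence matrix at the
analysis frame rate (2.3 Hz by default), an integer region-label volume
(0 = unassigned), and a trial table (odor label, onset frame, session).
Raw-optics effects (PSF, reconstruction, photon statistics) are out of
scope. All downstream statistics treat voxels as the atomic spatial unit;
nothing assumes cellular resolution.

## ΔF/F extraction

For each voxel and frame, the baseline `F0` is the mean of the lowest
`ceil(0.30 · w)` intensities among the `w = min(200, available)` preceding
frames, and `ΔF/F = (F − F0)/F0`. At 2.3 Hz the 200-frame window spans
~87 s, long enough to cover two inter-trial intervals, so the lower-30%
selection keeps the baseline clear of the preceding response's tail.
Warm-up rule: frames with fewer than 200 preceding frames use all available
preceding frames, and the first frame returns 0 — this keeps early
resting-state data rather than discarding a warm-up block. The window and
fraction are per-channel parameters. `F0 ≤ 0` raises an error: the input
must be positive raw fluorescence, not an already-normalized trace. The
implementation is compiled (partial selection per frame) and is tested for
exact agreement with a naive sort-per-frame oracle.

## Response metrics

* **Responsiveness** — Pearson correlation between a voxel's ΔF/F and the
  binary stimulus vector; voxels with two-sided `p ≥ 0.05` (t reference) or
  zero variance are masked. Region summaries average the top 20% of valid
  correlations per region.
* **Intensity** — per-trial sd (default) or AUC (frame sum × frame
  interval, ΔF/F·s) of the response window, averaged over trials.
* **Phase delay / pulse width** — on the trial-averaged trace: time from
  odor onset to the peak, and the full width at half maximum with linear
  interpolation at the half-max crossings. "Start" is interpreted as odor
  onset, not a threshold crossing: a threshold definition is noise-sensitive
  near the foot of the response where the derivative is small. Traces
  without a positive peak are flagged undefined.
* **Odor tuning** — difference between the mean per-trial response AUC for
  the target odor and for the other odors pooled. The pooled (rather than
  pairwise-minimum) comparison was chosen because with balanced designs it
  makes the three tuning values sum to zero, a convenient algebraic
  invariant that is tested. Significance per voxel is a two-sided
  Mann–Whitney U between the two AUC groups with Benjamini–Hochberg
  correction across voxels; the gating test had to be chosen here, since
  only the existence of a significance gate is part of the procedure's
  definition.

## Functional connectivity

Node traces are response windows spliced over trials (or a resting
segment). Region-level networks keep the full weighted Pearson matrix;
voxel-level networks keep the top 30% of correlations as edges, with the
edge count `ceiling(q · n_pairs)` and ties at the cutoff broken by node id
for determinism. Community detection (Louvain, seeded, resolution 1, and
greedy modularity, both exposed with their adjusted-Rand agreement) runs on
the positive-weight subgraph, since negative weights are not valid
modularity weights; weighted degree sums signed weights, while the
community ratio — the share of edge weight internal to the community
holding most olfactory regions — is restricted to positive weights. Both
flags are documented in the function help.

The dual-channel comparison uses the deflation ratio `(M − M̄)/M̄`, with
`M̄` the mean over off-diagonal entries only (the unit diagonal is
non-informative and would otherwise bias the scaling). The difference
matrix Δ subtracts the calcium channel's deflation ratio from the
neurochemical channel's; by construction Δ is invariant to positive
rescaling of either correlation matrix (tested). `Δ_w⁺ − Δ_b⁺` is the mean
of positive Δ entries within calcium-defined clusters minus between them; a
class with no positive entries contributes 0, and the metric is undefined
for a single cluster. Clusters are the Louvain communities of the
calcium-channel voxel graph; hierarchical (average-linkage on `1 − r`)
ordering is used only for display.

Degree-distribution comparisons use the 1-D Wasserstein-1 distance
(ECDF-difference integral) and the energy distance
`sqrt(2E|X−Y| − E|X−X′| − E|Y−Y′|)`; the clustering coefficient is
`C_v = 2E(v)/(k_v(k_v−1))` on the thresholded unweighted graph with
`C_v = 0` for degree < 2.

## Decoding tiers

All tiers share the same cross-validation discipline: stratified 5-fold
assignment (seeded; trials of a session may split across folds — the design
gives no reason to block by session, and stratification keeps class
balance), every transform fitted on training folds only, each trial tested
exactly once. The SVM is linear, one-vs-rest, cost 1: the choice of kernel
and multiclass scheme was open, and a linear machine keeps the composed
weight-map interpretation exact. A guard test asserts the fitted transforms
are byte-identical when test trials are perturbed.

* **Block accuracy map** — 4×4×2-voxel blocks; per-trial features are the
  flattened voxels × frames (× channels); PCA keeping 90% variance, then
  SVM. Channels are concatenated as raw features before the block PCA.
* **Region tier** — PCA (80% variance) fitted on all feature frames
  (offsets 0–13) of the training trials, LDA fitted at offset 2 only (the
  frame where the response is near maximal), all frames projected and
  reshaped to trials × (frames × LDA dims), SVM on these trajectories.
* **Multi-region tier** — voxels inside the mask (the community holding
  most olfactory regions; for a second channel, the regions with accuracy
  gain) are cut into 10×10×10 blocks; block PCA (90%) per channel, PCs
  concatenated, global PCA to 25 dimensions, then LDA and SVM as above. If
  fewer dimensions are available the reduction shrinks with a warning.
* **Region-average tier** — the region tier run on region-mean traces with
  a 99.8% variance threshold, appropriate for the low-dimensional feature
  space.

Identification weights compose block-PCA × global-PCA × LDA into a single
linear map to voxel space; each odor's weight is the magnitude of that map
applied to the odor's discriminant direction (class mean minus grand mean
in LDA space), averaged over folds. Frame-index convention: offset 0 is the
first frame at/after odor onset, so "the third frame" is offset 2.

## Manifolds and temporal stability

Each trial's full window (−2 s to +33 s) is projected by the transforms of
the fold in which it was a *test* trial. Folds are aligned to fold 1 by
orthogonal Procrustes on the class-mean trajectory matrices — rotation and
reflection only, no scaling or translation, since LDA coordinates are
already centered by construction; the alignment procedure itself was an
open choice, and the residual misfit is reported so users can detect
misalignment. Metrics use Euclidean distance in the discriminant space:
distance to the origin (the mean location of the first time point),
inter-class distance per odor pair, and intra-class distance among
same-odor trials. The return-to-one-fifth time searches only after the
post-onset peak (otherwise the rising limb trivially crosses the level);
crossings are linearly interpolated, and a level never reached is flagged
absent rather than clamped. The random-state level is the 29–30 s average;
the average intra-class distance summarizes 0–12 s. Stage analysis splits
sessions into four equal stages, recomputes the metrics per stage, and
reports per-session return locations (29–30 s mean position; first two
discriminant coordinates, which is the natural choice when the discriminant
space has exactly two axes for three odors).

## Motion controls

Motion energy is the pixel-mean absolute frame difference of the behavior
video. Behavioral features are the top 30 PCs of per-trial stimulation-
window motion frames (deterministic sign convention: largest-magnitude
loading positive). Ridge regression (λ = 1 on standardized predictors — the
penalty had to be fixed somewhere; it is exposed in the interface and λ = 0
is forbidden) predicts the leading neural PCs from behavior, stimulus
(per-odor indicators / trial-averaged responses), or both, with
cross-validated R². The behavior-explained component and the residual
reconstruct the input exactly, and both can be fed to odor decoding: if the
odor information is motion-independent, residualizing leaves accuracy
unchanged; if it is routed through motion, the residual falls to chance —
both directions are exercised in the validation suite. Lagged correlations
shift motion within ±1 s in 0.1 s steps (linear interpolation for sub-frame
shifts); positive lags mean the neural signal trails motion.

## Scheirer–Ray–Hare test

All observations are ranked jointly with midranks for ties; two-way ANOVA
sums of squares are formed on the ranks (group-size-weighted main effects,
interaction as cell SS minus main effects) and each effect's statistic is
`H = SS_effect / MS_total` with `MS_total` the total rank variance. Using
the observed rank variance applies the standard tie correction implicitly:
ties shrink the total rank variance by exactly the tie-correction factor.
P-values use the chi-squared reference with the effect's degrees of
freedom; an all-tied response returns `H = 0, p = 1`. The suite checks
agreement to 1e-10 with an independent oracle (rank, then `aov()` on ranks)
and the empirical type-I error at α = 0.05 on a balanced 2×2 null with 10
observations per cell, a size at which the chi-squared approximation is
adequate.

## The synthetic generator

`generate_experiment()` emulates the statistical structure the analysis
assumes: 3 odors × 60 sessions (180 trials) in a pseudo-random order with
no consecutive repeats and each session a permutation of the odor set; 5 s
stimuli with 30 s intervals after a 10-min resting period; fluorescence
`baseline_F · (1 + signal + coupling · motion + noise)` clipped at zero.
Responses are unit-peak difference-of-exponentials kernels — two parameters
that map directly onto phase delay and pulse width — with per-channel
delay, rise and decay constants (defaults: fast sub-second rise for the
calcium- and ACh-like channels, `serotonin_params()` for a slow 5-HT-like
channel, motivated by the indicators' reported on/off kinetics). Odor
ensembles occupy configurable fractions of atlas regions; per-session drift
schedules are multiplicative (`drift_preset()`: calcium-like linear decay
with stage means 1.0/0.85/0.70/0.55, flat ACh-like, early-drop 5-HT-like —
qualitative families, not hard-coded claims); the behavior stack is built
so its frame-difference energy equals the planted motion trace exactly, and
an odor-locked motion mode supports the confound controls. Volumes are
generated directly at the analysis rate (desk-scale size); `downsample()`
provides block-mean rate reduction for rate-handling tests, our stand-in
for however the acquisition rate was reduced in a real rig. The default
grid is 24×24×8 voxels with 8 regions (4 olfactory): large enough for
4×4×2 blocks, small enough for minutes-scale runs.

What the generator does **not** emulate: spatial autocorrelation of noise,
denoising artifacts, indicator saturation or bleaching, hemodynamic-like
confounds, inter-animal variability, or real atlas geometry (regions are
equal slabs). Passing tests therefore demonstrate that the pipeline's
machinery is correct and recovers planted structure under its own
assumptions — not that those assumptions hold for any particular real
recording. Per-voxel noise is Gaussian with configurable sd (default 0.05
ΔF/F); the noise level of real denoised data is not documented, so tests
sweep amplitude-to-noise ratios instead of relying on one value.

## Problem sizes and numerical choices

The validation suite runs on reduced spatial grids (typically 8×4×2 to
12×6×4 voxels, 4 regions) while keeping the trial structure — balanced
pseudo-random order, 5 s / 30 s timing — at 10–60 sessions depending on
what the check needs; chance-calibration and recovery checks use the full
180 trials. These sizes are the package's choice of desk-scale validation
conditions. Other numerical conventions: PCA components with numerically
null variance are never retained (they would be constant within groups and
break the discriminant fit); the top-fraction edge count uses the ceiling;
Louvain is seeded; crossings and FWHM use linear interpolation;
permutation controls and fold assignment derive from explicit seeds, and
identical configurations are bit-reproducible.

## Known limitations

- Region-level networks keep signed weights in degrees but exclude negative
  weights from community structure and ratios; alternative conventions
  exist and the flags are documented rather than hidden.
- The identification-weight map ignores the (nonlinear) SVM decision stage;
  it attributes weight through the linear PCA/LDA maps only, which is
  exactly why the SVM is constrained to a linear kernel.
- Orthogonal Procrustes aligns folds up to rotation/reflection; if two
  folds' discriminant spaces differ by more than that (e.g. grossly
  different training data), the reported residual is the only warning.
- The Scheirer–Ray–Hare chi-squared reference is asymptotic; for very small
  cells its type-I error drifts, which is why the validity check fixes the
  cell size it certifies.
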