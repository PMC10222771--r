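---
title: "Multimodal locomotion classification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal locomotion classification: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

momofuse classifies short activities of daily living (ADLs) from three
concurrently recorded sensor modalities: environment-mounted ambient
switches/PIR sensors, body-worn inertial units, and a fixed camera. This
vignette explains the models behind each stage, the parameters that matter,
and the choices made where the design was genuinely open. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## Pipeline overview

Each modality is denoised with a filter matched to its physics, cut into
4-second windows, and summarized by a modality-specific feature family.
The per-window features are fused into a single vector, a subset of fused
dimensions is selected by the cross-entropy method, and a recursive neural
network (RvNN) classifies each window. Evaluation uses stratified k-fold
cross-validation, row-normalized confusion matrices, and — for the vision
branch — per-keypoint distance from ground-truth joints.

## Preprocessing

**Ambient channels** pass through a zero-phase Butterworth low-pass
(`butterworth_lowpass()`). Ambient switch/PIR signals are events on a
seconds timescale, so the default is order 3 with a 5 Hz cutoff — the upper
end of the ADL band; both are configurable in `filter_config()`. The filter
runs forward and backward after odd-reflection edge padding, so the phase
response is exactly zero, DC level is preserved to numerical precision, and
the amplitude at the cutoff is the squared single-pass half-power gain,
$|H(f_c)|^2 = 1/2$. The tests verify all three properties.

**Inertial channels** are denoised by per-channel wavelet shrinkage
(`wavelet_quaternion_filter()`): a periodized db4 decomposition (3 levels by
default), universal (VisuShrink) thresholding of the detail coefficients
with $\hat\sigma\sqrt{2\log n}$ where $\hat\sigma$ is the median absolute
deviation of the finest details, and reconstruction. Orientation
quaternions, when present, are renormalized to unit norm; a quaternion row
with vanishing norm is a hard error because it has no direction. Two
numerical caveats are worth knowing. First, soft thresholding biases every
surviving coefficient by the threshold, so signals whose energy leaks into
the detail bands (fast oscillations relative to the sampling rate) are
slightly smoothed even when noiseless; the clean-signal preservation test
therefore uses a tone well inside the approximation band. Second, the
transform is periodized; the signal is mirror-padded to a multiple of
$2^{\text{levels}}$ and trimmed after reconstruction to limit wrap-around
artifacts.

**Video frames** are turned into silhouettes by background subtraction: the
background is the per-pixel median (configurable quantile) over the frame
sequence, the foreground is `|frame - background| > mask_threshold`
(threshold in 8-bit units, default 25), cleaned by morphological opening
then closing with a radius-2 disc. The background model uses at most 64
evenly spaced frames; the per-pixel quantile stabilizes well before that.
The model assumes a static camera and a scene in which each pixel is
background most of the time — the synthetic generator's figure walks for
exactly this reason.

**Windowing** (`segment_windows()`) cuts each modality into 4-s windows.
Overlap defaults to 0 (only the window length is a stated operating point;
overlap is configurable). A window's label is the majority vote of its
per-sample labels, ties resolved toward the smaller class id so the rule is
deterministic. Trailing partial windows are discarded; a signal shorter
than one window yields an empty (logged) result rather than an error, so
short recordings degrade gracefully.

## Skeleton extraction

`extract_skeleton()` computes 12 named keypoints (head, shoulders, elbows,
wrists, torso, knees, ankles) from a binary silhouette with a deterministic
geometric procedure — no learned pose estimator:

1. largest connected foreground component (≥ 200 px);
2. Euclidean distance transform of the component;
3. **torso** — the distance-transform-squared weighted centroid. The naive
   "point of maximal distance transform" is unstable: morphological closing
   can fatten the shoulder junction until the global maximum jumps there,
   while the thickness-weighted centroid stays inside the trunk;
4. **head** — the first local maximum, scanning from the top, of the
   row-wise maximum of the distance transform. For a head-on-neck shape
   this is the medial centre of the head; a plain "topmost medial pixel"
   would land on the crown;
5. **shoulders** — left/right silhouette extrema in a row band one fifth of
   body height below the component top, refined inward to the local medial
   axis (maximal distance transform);
6. **wrists** — the farthest foreground point from the torso centre on each
   image side, within the band between the shoulders and the hip line (the
   bottom row of the "thick" region where the distance transform exceeds
   half its maximum);
7. **ankles** — the lowest foreground point on each side below the hip
   line;
8. **elbows/knees** — midpoints of shoulder–wrist and hip–ankle.

Left and right are image-x order: with one fixed camera and no pose
flipping in scope, the leftmost shoulder in the image is "left". Per-point
confidence is the distance-transform value at the point divided by the
component maximum — deterministic, in [0, 1], and it degrades as the
silhouette erodes, which the noise-ladder test exercises.

Keypoints are scored against ground truth with
$D = \sqrt{\sum_n (X_n S_n - Y_n S_n)^2}$ (`point_distance()`); the
per-component scale $S$ defaults to 1 (plain Euclidean pixels) and
otherwise serves resolution normalization. A point is *recognized* when
$D \le 15$ px at the 640×480 operating scale; the synthetic frames default
to 320×240, so the threshold scales to 7.5 px (equivalently, distances are
evaluated with $S = 2$ against 15). `confidence_table()` reports the same
three-column per-point summary (confidence, distance, recognition
accuracy) used in the per-dataset keypoint tables bundled in
`paper_fixtures()`.

## Feature families

**Ambient — Pearson gate.** For each window, `ambient_gate()` computes the
Pearson correlation of every unordered channel pair, averages the absolute
values, and flags an "action performed" when the mean exceeds 0.04. The
absolute value makes the gate sign-agnostic: anti-correlated switches are
co-activity too. The pair correlations, the mean, and the flag together
form the ambient feature block. Note the gate's null behaviour: for
independent channels the correlation is approximately
$N(0, 1/(n-1))$, so with 40–100 samples per window the null flag rate is
substantial; the gate is informative through its *rate contrast* between
idle and active segments, which the generator reproduces through
class-dependent inter-channel coupling. A single-channel stream falls back
to lag-1 autocorrelation (logged).

**Inertial — LPCC.** Each channel of a window is modelled as an
autoregressive process of order $p$ (default 10), solved by
Levinson–Durbin (`lpc_coefficients()`, minimum-phase by construction), and
expanded into $d$ cepstral coefficients (default 12) by the recursion

$$c_x = a_x + \sum_{t=1}^{x-1}\tfrac{t}{x}\,c_t\,a_{x-t} \;(x \le p),
\qquad
c_x = \sum_{t=1}^{x-1}\tfrac{t}{x}\,c_t\,a_{x-t} \;(x > p),$$

with out-of-range $a$ indices contributing zero; the boundary term $x = p$
belongs to the first branch (the standard convention where the two ranges
overlap). The recursion is verified against a literal double-loop oracle to
1e-12 on hundreds of random stable coefficient sets. Zero-energy channels
yield zero blocks rather than errors.

**Vision — SLIF.** `slif_descriptor()` anchors a polar "spider-web"
sampling grid (default 3 rings at 8/16/32 px, 16 spokes) at each of the 12
skeleton points and records binary mask occupancy at every intersection
(point $(x, z)$ at $\text{centre} + (x\cos\frac{2\pi z}{Z},
x\sin\frac{2\pi z}{Z})$, y down), plus a per-anchor occupancy fraction.
Off-image samples read 0; a missing skeleton point zero-fills its block.
The descriptor is translation-equivariant by construction. Per-frame
descriptors are mean-pooled within each 4-s window before fusion.

## Fusion and cross-entropy feature selection

`align_and_fuse()` joins the ambient and motion feature tables on the
window index and assigns each frame's vision features to the motion window
containing its timestamp (mean-pooled). Windows missing a modality get a
zero-filled, flagged span. The fused vector records its (ambient, motion,
vision) spans so the classifier can embed each modality separately.

`cem_optimize()` selects a subset of fused dimensions with the standard
cross-entropy method over Bernoulli masks: sample a population of masks
from per-dimension inclusion probabilities, score them, refit the
probabilities on the elite fraction, smooth, repeat; return the best mask
ever seen, reproducibly from the seed. Probabilities are clipped to
[0.01, 0.99] so no dimension is irrevocably absorbed, and three
consecutive all-identical-score iterations trigger an early stop. Defaults:
population 50, elite 0.2, 30 iterations, smoothing 0.7, initial
probability 0.5.

Two scorers are provided (`mask_score()`), and the difference matters:

- `fisher` — ratio of summed between-class to summed within-class scatter
  over the included dimensions. Fast and deterministic, but as a *subset*
  objective it is maximized by the single most discriminative dimension,
  so it suits comparative scoring (is this mask better than that one?)
  rather than subset recovery.
- `cv_loss` — negative stratified 3-fold error of a nearest-centroid
  classifier on the included dimensions, averaged over three fold splits,
  minus a parsimony penalty of 0.45 × (included/total). Both refinements
  were found necessary for well-posed selection: with a single CV split,
  noise dimensions that happen to fit that split genuinely improve the
  score — the optimum of the objective itself then contains them, and no
  optimizer can recover the informative set; averaging over splits removes
  that artifact. The penalty makes the score strictly prefer the smaller
  of two equally predictive masks; it is sized so that one neutral
  dimension costs more than the fold-split luck it can buy at these
  problem sizes. After the sampling loop, the best mask is polished by
  deterministic backward elimination — greedily dropping any included
  dimension whose removal improves the score. Early iterations can absorb
  a few uninformative dimensions alongside the informative ones (their
  inclusion probability rides to the ceiling before the parsimony pressure
  can act), and the polish removes exactly those; it can only improve the
  returned score. The pipeline uses `cv_loss`.

## The recursive neural network

Each modality span is embedded by an affine+tanh leaf map into an
$n$-dimensional space (default width 64; the pipeline default is 32), and a
single shared composition matrix $W \in \mathbb{R}^{n\times 2n}$ combines
children: $\text{branch} = \tanh(W[\text{left};\text{right}])$. The default
tree is left-deep — compose(compose(ambient, motion), vision) — the
simplest order-stable cascade; a "balanced" alternative
compose(compose(ambient, motion), compose(motion, vision)) reuses the
motion embedding as the shared middle child. Leaves use separate per-modality
maps (their input dimensions differ, so they cannot share $W$); the
composition weights are shared across both tree levels, and both uses
accumulate into one gradient. A final affine+softmax head yields class
probabilities.

Training is plain mini-batch gradient descent on the multiclass
cross-entropy (learning rate 0.01, 200 epochs, batch 32, L2 1e-4 by
default), with manual backpropagation through the structure; features are
standardized with train-set statistics stored in the model. Gradient
correctness for every parameter block, in both tree shapes, is checked
against central finite differences. The seed fixes initialization and
batch order, so identical seeds give identical losses — the determinism
the evaluation contract requires. `kfold_evaluate()` runs stratified
k-fold (default 10) with deterministic fold assignment, pools held-out
predictions into a row-normalized confusion matrix, and reports macro
accuracy — the unweighted mean of the diagonal — because that is the
summary under which the bundled reference tables reproduce their printed
headline accuracies.

## The synthetic generator

`generate_session()` produces seeded sessions whose structure mirrors
indoor ADL corpora: 9 activity classes by default, one label per sample
per modality, segments of at least 8 s.

- *Ambient* (4 channels @ 10 Hz): random-telegraph switch processes with a
  class-dependent shared driver; coupling 0 for class 1 (idle-like) rising
  to 0.9 across the remaining classes, so the Pearson gate's flag rate
  separates idle from active and is monotone in coupling.
- *Inertial* (6 channels @ 25 Hz): per-class two-tone sinusoid mixtures
  (fundamental 0.8 + 0.4·class Hz plus a detuned second harmonic) with
  additive Gaussian noise (sd 0.3) — class-distinct AR spectra for LPCC.
- *Vision* (320×240): an articulated stick figure — torso ellipse, head
  disc, limbs as thick segments (7 px, chosen so radius-2 opening cannot
  sever a limb) — with class-dependent arm/leg swing frequency and
  amplitude, composited over a static textured background. The figure
  walks a slow triangle-wave path across the scene so the median
  background model is valid; ground-truth joints are stored per frame.

The "easy regime" used by the end-to-end tests and the acceptance script
is 9 classes × 3 segments × 16 s (12 windows per class, 108 windows),
frames at 2 Hz — sizes chosen to keep a full desk run in about a minute
while leaving every stage statistically meaningful.

What passing on generator data does *not* show: robustness to
photorealistic clutter, multi-person scenes, camera motion, sensor
dropout patterns of real hardware, or class structure beyond
frequency/coupling contrasts. The generator exists to exercise every
pipeline contract with known ground truth, not to certify real-world
accuracy.

## Numerical and degenerate-input policy

Constant windows give Pearson correlation 0 with a degeneracy flag;
zero-energy channels give zero LPCC blocks; missing skeleton points
zero-fill their SLIF block and score as recognition failures; windows
missing a modality carry zero-filled flagged spans; empty masks, single
classes, dimension mismatches and sub-Nyquist violations raise typed
errors. Ties are always broken deterministically (smaller class id,
first index). All stochastic stages — generation, CEM, fold assignment,
initialization, batch order — are functions of explicit seeds.

## Known limitations

- The skeleton extractor is a silhouette heuristic tuned to upright,
  single-person, roughly frontal poses; it has no notion of occlusion or
  limb crossing.
- The wavelet shrinkage slightly smooths genuinely fast signal content
  (an inherent property of universal thresholding), which matters only
  when the band of interest approaches Nyquist.
- The fisher scorer should not be used for subset *recovery* (see above);
  it remains available for fast comparative scoring.
- CEM with a cv_loss scorer optimizes a penalized objective; the selected
  dimensionality is a consequence of the penalty, not a user-set target.
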