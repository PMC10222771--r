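# momofuse

Multimodal locomotion classification from ambient, inertial and vision
streams.

Smart-home and digital-health studies record activities of daily living
(ADLs) with three kinds of sensors at once: environment-mounted binary
switches/PIR detectors, body-worn inertial units, and a fixed camera.
Each modality sees a different slice of the activity — the ambient
channels see *which objects* are touched, the inertial channels see *how
the body moves*, the camera sees *posture* — and classifying short
activity windows reliably requires fusing all three. momofuse is an R
implementation of that full pipeline for researchers who want a tested,
deterministic, dependency-light reference: every stage is an exported
function, every stochastic step is seeded, and a bundled synthetic
session generator with ground-truth joints exercises the whole chain
without any external dataset.

## The method

For a recording with ambient matrix $A$, inertial matrix $M$ and frame
sequence $F$:

1. **Denoising.** $A$ passes a zero-phase (forward–backward) Butterworth
   low-pass (order 3, 5 Hz); $M$ passes per-channel db4 wavelet shrinkage
   with the universal threshold $\hat\sigma\sqrt{2\log n}$, and orientation
   quaternions are renormalized; $F$ is background-subtracted against the
   per-pixel median and cleaned by morphological opening/closing, giving
   binary silhouettes.
2. **Windowing.** All signals are cut into 4-s windows; window labels are
   per-sample majority votes.
3. **Skeleton model.** A deterministic geometric extractor reads 12 body
   points (head, shoulders, elbows, wrists, torso, knees, ankles) off each
   silhouette via the distance transform. Points are scored against ground
   truth with $D=\sqrt{\sum_n (X_nS_n-Y_nS_n)^2}$ and a point counts as
   recognized when $D \le 15$ px at 640×480 scale.
4. **Features.** Ambient: pairwise Pearson correlations
   $PC = \sum(g_x-\bar g)(h_x-\bar h)\,/\,\sqrt{\sum(g_x-\bar g)^2\sum(h_x-\bar h)^2}$
   per window, with an "action performed" flag when the mean $|PC|$
   exceeds 0.04. Inertial: linear prediction cepstral coefficients,
   $c_x = a_x + \sum_{t<x}\frac{t}{x}c_t a_{x-t}$ ($x\le p$),
   $c_x = \sum_{t<x}\frac{t}{x}c_t a_{x-t}$ ($x>p$), from Levinson–Durbin
   LPC per channel. Vision: spider local image features (SLIF) — binary
   occupancy sampled on polar webs
   $s_{x,z} = (x\cos\frac{2\pi z}{Z},\, x\sin\frac{2\pi z}{Z})$ anchored at
   the skeleton points, mean-pooled per window.
5. **Fusion + selection.** Per-window features are concatenated with
   recorded modality spans; a cross-entropy method over Bernoulli masks
   (sample → score → refit on elites → smooth, then backward-elimination
   polish) selects a reduced feature subset.
6. **Classification.** A recursive neural network embeds each modality
   span with an affine+tanh leaf map and composes them with one shared
   matrix, $\mathrm{branch} = \tanh(W[\text{left};\text{right}])$,
   $W \in \mathbb{R}^{n\times 2n}$, followed by a softmax head; trained by
   mini-batch gradient descent with backpropagation through the tree, and
   evaluated with stratified 10-fold cross-validation, row-normalized
   confusion matrices and macro accuracy (unweighted diagonal mean).

The package also ships verbatim transcriptions of the reference
per-dataset result tables (`paper_fixtures()`) whose macro accuracies are
the published headline numbers, used as arithmetic fixtures by the tests.

## Worked example

Generate a 9-class synthetic session (three 16-s segments per class),
run the full pipeline, and cross-validate:

```r
library(momofuse)

cfg <- pipeline_config(
  generator = generator_config(n_classes = 9, segment_s = 16,
                               segments_per_class = 3, frame_fs = 2,
                               seed = 1))
report <- run_pipeline(cfg)
```

Printed results (about a minute on a laptop):

```
windows: 108   fused dims: 668   selected: 19
mean class accuracy (10-fold): 0.9630
skeleton: mean joint distance 2.20 px (threshold 7.5 px)
<confusion_matrix: 9 classes, 108 windows>
     1    2 3 4 5 6    7    8    9
1 1.00 0.00 0 0 0 0 0.00 0.00 0.00
2 0.08 0.75 0 0 0 0 0.00 0.00 0.17
3 0.00 0.00 1 0 0 0 0.00 0.00 0.00
...
           point confidence  distance accuracy
1           head  0.6379081 0.3356461        1
2  left_shoulder  0.3950884 2.1810490        1
```

Reading this: 108 four-second windows were fused into 668-dimensional
vectors; the cross-entropy selector kept 19 dimensions; stratified
10-fold cross-validation of the RvNN reaches 96.3 % macro accuracy, with
the row-normalized confusion matrix showing which classes blur (class 2
is occasionally mistaken for 1 and 9). The skeleton extractor tracks the
rendered figure's joints to 2.2 px on average at 320×240 — well inside
the scaled 7.5 px recognition threshold — and the per-point table mirrors
the standard confidence/distance/accuracy keypoint summary.

The bundled reference tables reproduce their published summaries
arithmetically:

```r
fx <- paper_fixtures()
round(100 * mean_class_accuracy(fx$hwu_usp), 2)      # 87.67
round(100 * mean_class_accuracy(fx$opportunity), 2)  # 86.71
```

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/momofuse.R", package="momofuse"))')" \
    run-all --seed 1 --out report_dir
```

## Scope

momofuse implements the pipeline against its own synthetic generator and
generic CSV/PNG session layouts; native parsers for specific public
dataset releases, learned pose estimators, 3-D skeletons and multi-person
scenes are out of scope. The feature-optimization stage is implemented as
a standard cross-entropy method over binary masks; see the methods
vignette (`vignettes/multimodal-locomotion.Rmd`) for the design rationale
and known limitations.
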