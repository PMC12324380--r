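---
title: "Scoring and curating cryo-EM 2D class averages with cryograder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and curating cryo-EM 2D class averages with cryograder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryograder)
```

## The problem

Single-particle cryo-EM refines a 3D structure from hundreds of thousands of
noisy projection images ("particles"). After 2D classification, each class
average summarizes one cluster of aligned particles; deciding which classes
are worth keeping is traditionally a manual, subjective step, and strong
classes tend to absorb dissimilar low-signal particles (the attractor
effect), so a single pass of selection is rarely clean. cryograder automates
the step with two coupled components:

1. a **quality scorer** — a residual CNN that maps a class-average image plus
   six physical metadata features to a continuous quality score, and
2. a **selection workflow** — an iterative classify–score–select loop that
   pools particles from good classes, discards hopeless ones, and sends the
   ambiguous middle back for re-classification.

## The score

Scores live on a continuous scale anchored at 1 (best) through 5 (unusable),
mirroring a five-letter expert rubric (A–F, `grade_to_score()`). The model is
a regressor trained with MSE loss rather than a classifier: nothing clamps
its output, so a class worse than anything seen in training can score above
5, and a better-than-everything class below 1. For comparison with
higher-is-better rankers on a 0–1 scale, `score_to_bin()` applies the affine
reversal $b = (5 - s)/4$, clamped to $[0,1]$. The reversal direction is an
interpretation we fixed once: our scale is lower-is-better, the 0–1 ranking
scale is higher-is-better, and the map is trivially switchable if a user
needs the opposite convention.

## Metadata features

Six features are fused with the image, in a fixed order
(`feature_names()`): pixel size (Å/px), FRC resolution estimate (Å — we use
Å rather than spatial frequency, recorded in the manifest), relative class
distribution (fraction of the job's particles in the class), and three mass
features. The mass features derive from a pixel-intensity mass estimator:

1. pixels more than 3 standard deviations above the image mean are particle
   signal, the rest background (`segment_particle()`);
2. the background mean is subtracted from each particle pixel, the result
   summed and multiplied by the pixel size squared
   (`summed_intensity()`) — the background mean is subtracted per particle
   pixel *before* summing, which keeps the estimate invariant to additive
   intensity offsets and linear in gain and pixel area;
3. a through-origin linear calibration (`fit_calibration()`) against
   reference particles of known mass converts the sum to kDa — through the
   origin because zero intensity must mean zero mass, and because a single
   multiplicative calibration factor is exactly a zero-intercept slope.

The CNN does not see the absolute mass but its deviations from the mean,
median, and mode of all class masses in the same job (`mass_features()`):
within one classification job, outlier masses flag junk classes better than
absolute values do. The mode of a handful of continuous masses is undefined
in the textbook sense; we use the half-sample mode, which is robust and
parameter-free, and fall back to the median below three observations. The
whole-image mean and sd (not an annulus) feed the 3σ threshold, matching the
plain reading of the recipe. Because every feature has different units, the
training loop z-scores each one and freezes the statistics in the model
manifest; inference refuses to score if they are missing.

## Preprocessing

The scorer accepts any square image with side ≥ 31 px. At scoring time
images are brought to a canonical 210×210 frame (`canonicalize()`): smaller
images are zero-padded around a centered window (odd differences go
bottom/right — a fixed convention, documented rather than guessed at
runtime), larger ones are Fourier-cropped. Fourier cropping truncates
spatial frequencies above the new Nyquist symmetrically around DC, the
standard cryo-EM downsampling that leaves low-frequency content untouched;
we rescale so the *mean intensity* (DC term) is preserved — preserving total
power instead would inflate the contrast of heavily cropped images, and
mean preservation also keeps the amplitude of any retained sinusoid exact.
Upsampling small images in Fourier space is deliberately not done; padding
preserves the native pixel sampling the FRC and pixel-size features refer
to.

Intensity normalization to mean 0, sd 1 (`normalize_image()`) happens
*after* canonicalization, so padded zeros participate deterministically in
the statistics; the convention is recorded in the manifest so training and
inference can never disagree. A constant image maps to all zeros rather
than dividing by zero.

## Architecture

`build_model()` assembles: a 3×3 stem convolution; a sequence of stages,
each entered through a *pair of 2×2 stride-2 convolutions* (learned
downsampling in place of pooling — each pair acts like a 4×4 weighted
average pool) and continuing with residual blocks (3×3–BN–ReLU–3×3–BN plus
identity skip); batch normalization after every convolution; and adaptive
average pooling to a fixed 6×6 grid, which is what frees the trunk from a
fixed input size. The pooled activations are flattened, concatenated with
the six standardized features (late fusion — the simplest contract that
lets metadata shift the predicted score), and passed through a two-layer
regression head emitting one unbounded scalar.

Two numerical choices deserve a note. First, a pair of stride-2
convolutions divides the side by 4 per stage; with valid-only convolution a
31-px input would underflow after two stages, so each 2×2 stride-2
convolution pads one row/column at the bottom/right when its input side is
odd, making the output side ⌈side/2⌉ for every input — a 31-px image
survives any stage count and the 31-px floor is enforced
explicitly, not by accident of arithmetic. Second, when the trunk's output
grid is smaller than 6×6 the adaptive pooling bins replicate values
(each output bin averages at least one input cell), the same bin
semantics as PyTorch's `AdaptiveAvgPool2d`.

The default configuration (`scorer_config()`) uses a 32-channel stem and
four stages of two residual blocks at 32→64→128→256 channels with a
128-unit head; widths and depth are fully configurable. `scorer_config_small()` (8-channel stem, two stages of
16 and 32, one block each, 32-unit head) is the desk-scale variant used
throughout the tests: full-scale training needs a large expert-labeled
corpus of class averages (tens of thousands of images) that no package can
ship, so everything here trains on synthetic data at sizes a single CPU
core handles in about a minute.

The network itself — convolutions (im2col + GEMM in compiled code), batch
norm, adaptive pooling, Adam, and manual backpropagation — is implemented
in this package. Gradient correctness is pinned by central-difference
checks in the test suite, and a 20-block configuration must still deliver a
nonzero gradient to the stem convolution, which is the point of the
residual skips.

## Training recipe

`train_scorer()` minimizes the MSE between predicted score and numeric
label with Adam at learning rate 1e-4, weight decay 1e-4, batch size 32,
200 epochs (defaults of `training_config()`; the desk-scale tests use 30
epochs at these rates, or a larger learning rate where a test needs
convergence within a few dozen steps on a tiny set). The weight penalty is
the optimizer's classic L2-in-gradient flavor (added to the gradient before
the Adam moments), not decoupled decay; the choice is recorded here and in
the manifest. No learning-rate schedule. Everything is seeded: weight
initialization (He-normal) and per-epoch shuffling both derive from
`config$seed`, so identical configs give bitwise-identical loss traces on
CPU. Mini-batches are required by batch normalization; a trailing batch of
one image cannot produce batch statistics, so it is merged into the
previous batch rather than dropped. `split_dataset()` holds out a seeded
10% by default for validation, and `evaluate_scorer()` always reports the
MSE on both the native 1–5 scale and the 0–1 bin scale (their ratio is
exactly 16 while all values stay inside the anchors), because a headline
validation MSE is ambiguous without stating its scale.

## The selection workflow

`run_workflow()` iterates classify → score → disposition over a pluggable,
stateless backend (`backend(particle_ids, iteration, seed)` returning
classes that exactly partition their input — nothing else about the
classifier is assumed). Round counts come from the extraction-box side as a
proxy for particle size (`plan_iterations()`): 5 rounds below 200 px, 3
for 200–300 px inclusive, 2 above 300 px — the boundary values 200 and
300 belong to the middle tier.

Disposition per class, with the boundary semantics fixed once in one
predicate: score ≤ 2.5 ("good") → 70% of the class's particles are set
aside and the remaining 30% stay in flight; 2.5 < score < 4.5 → the class
stays in flight; score ≥ 4.5 → discarded. The set-aside 70% *joins the
accepted pool* rather than being removed: the workflow's purpose is to
retain well-scoring particles, and pooling is the only reading under which
"all particles passing the cutoff are pooled" makes sense; a config flag
(`pool_setaside = FALSE`) provides the other reading. The split applies per
class (not over the union of good classes) with the count rounded half-up,
and the draw ranks particles by a deterministic per-(seed, round, particle)
hash key: the exact per-class count is honored, reruns and resumed runs
reproduce the same draws byte for byte, and whether a particle is set aside
never depends on which other particles share its class — which is also what
makes pool sizes respond monotonically to cutoff changes.

After the planned rounds, surviving in-flight particles whose last class
scored below 4.5 join the pool (by construction all survivors qualify), the
pool is classified once more, and `final_batches()` splits it into three
*nested* batches at thresholds 2.5 / 3.5 / 4.5 (≤ semantics). Particle
conservation — pooled, in-flight and rejected always partition the initial
set — is asserted after every state change, and the audit log records every
class decision. Snapshots (`write_workflow_snapshot()`) make runs
resumable; resumed runs equal uninterrupted ones exactly because no draw
depends on global RNG state.

## Synthetic data

`generate_stack()` emulates a graded 2D classification job with no external
data: each class is a Gaussian-blob phantom (3–7 blobs, unit-scale
amplitudes) degraded by its grade — a Gaussian low-pass at a cutoff
fraction of Nyquist (0.95, 0.75, 0.55, 0.35, 0.18 for grades 1–5) plus
additive Gaussian noise on a geometric ladder (sd 0.02, 0.08, 0.25, 0.70,
2.0). The ladder is geometric because real class quality spans orders of
magnitude in SNR and an "unusable" class is noise-dominated; it was fixed
once, at the point where the generator's own design requirement — FRC
resolution estimates rank-correlated with grade at ρ ≥ 0.9 over 100
classes — holds. Each class carries two half-set noise realizations whose
Fourier ring correlation gives the resolution estimate at the 0.143
crossing (the community half-set convention), linearly interpolated between rings, saturating at
Nyquist when the curve never crosses. Class distributions are a flat
Dirichlet draw; "true" masses follow a known slope from the clean phantom's
summed intensity, so calibration recovery is testable end to end. Defaults:
64-px boxes at 1.0 Å/px, sizes a CPU trains on in about a minute per 500
classes.

What the generator does *not* emulate: CTF oscillations, beam-induced
motion, particle-picking artifacts, structured backgrounds (ice, carbon
edges), or real projection structure. Passing tests therefore demonstrate
that the implementation learns and ranks a controlled quality gradient and
that the bookkeeping is exact — not that the desk-scale model would match
expert labels on real micrograph-derived classes, which can only be
established against a large expert-labeled corpus.

## Problem sizes used in the checks

The automated checks train the desk-scale model on 500 synthetic classes
(80/20 split) for 30 epochs per seed — ten seeds in the test suite, three
in the acceptance script — and exercise the workflow on a few thousand mock
particles over the full 5-round schedule. These sizes were chosen as the
smallest at which descent, held-out rank recovery (Spearman ≥ 0.8), and all
bookkeeping invariants are stable across seeds.

## Known limitations

- The architecture fixes the structural elements (residual skips, paired
  2×2 stride-2 downsampling, BN, 6×6 adaptive pooling, late metadata
  fusion); channel widths and depth are configurable defaults, not a
  canonical layer table.
- No trained full-scale weights ship with the package; users train on their
  own labeled corpora.
- The classification backend is an interface; adapters for specific
  processing platforms are out of scope, as are reconstruction-based
  validation metrics (FSC against simulated maps, Q-score, B-factor).
- MRC I/O covers modes 0/1/2/6 and writes mode 2; extended headers are
  skipped, not interpreted.
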