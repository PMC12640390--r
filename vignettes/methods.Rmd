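---
title: "Methods: morphokinetic stage annotation and transition timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphokinetic stage annotation and transition timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryostage)
```

## The problem

Time-lapse incubators image each embryo every few minutes through the first
days of in vitro development. The timed sequence of morphological events —
morphokinetics — feeds viability scores used to rank embryos for transfer,
so annotating *which stage* each frame shows and *when* each stage begins
matters clinically. Manual annotation is subjective and slow; a frame-level
classifier automates it but produces noisy per-frame labels, especially
near stage transitions where even experts disagree.

This package provides the full chain: a 17-class stage ontology, frame
classifiers at configurable scale, a run-length denoising algorithm for
per-frame predictions, exact transition-time extraction with quantile error
analysis, and a synthetic time-lapse generator so every step is testable
without clinical data.

## The stage ontology

`stage_levels()` lists the 17 classes in developmental order: `tPB2`
(polar-body appearance), `tPNa`/`tPNf` (pronuclei appearance/fading),
cleavage stages `t2`–`t8` and `t9+`, `tM` (morula), `tSB`/`tB`/`tEB`/`tHB`
(blastulation through hatching), and `Empty`. `Empty` marks wells after the
embryo is removed (typically day 5 for freezing or transfer); it is a
data-quality class, not a developmental event, so it is placed last and
excluded from developmental adjacency. `tHB` is kept in the ontology but
flagged rare — hatched blastocysts are so scarce in annotated datasets that
per-class metrics are unstable — and evaluation functions exclude it by
default (`exclude = "tHB"`).

## Elapsed-time encoding

The fused classifier receives the time since fertilisation as a one-hot
vector over two-hour windows across a maximum assumed incubation of seven
days: `index = floor(minutes / 120)`, vector length `7 * 24 / 2 = 84`.
150 minutes gives window 1, 240 minutes window 2. Times at or beyond seven
days clamp to window 83 with a warning rather than erroring: acquisition
logs occasionally overrun, and clamping is recoverable while preserving
monotonicity.

## Classifier scaffold

Two architectures share a convolutional feature extractor:

* **image-only**: extractor plus one linear classification head;
* **fused**: the pooled feature vector is projected to `fusion_hidden`, a
  linear embedding of the 84-bin time vector forms a second token, and one
  attention-based encoder layer (4 self-attention heads, feed-forward
  block, residual connections) mixes the two tokens. Head 1 reads the raw
  image features, head 2 the fused image token. Training sums the two
  weighted cross-entropy losses so gradient always reaches the backbone
  and the model cannot collapse onto the time input alone; inference uses
  head 2.

The tokenisation is an interpretation — published descriptions of such
fusion layers rarely pin down the token set — and is documented as such: a
2-token sequence (image, time), no positional encoding (the two roles are
distinguished by their projections), and no layer normalisation, which the
tiny fusion width does not need for stable training.

Because no deep-learning runtime is available in this R stack, the engine
is written directly on base-R arrays: im2col 3×3 convolutions, 2×2 max
pooling, the 2-token encoder layer, weighted cross-entropy and Adam, with
analytic backpropagation verified against central finite differences in the
test suite (worst relative error below 1e-4 at every probed parameter).
The `"tiny"` backbone (two conv blocks, 64-dim features, 32 px input) is
the test workhorse; `"reference"` selects a deeper/wider stack at 380 px
and 512-wide fusion standing in for an EfficientNet-class extractor, and is
config-selectable but not exercised in tests — hand-rolled MBConv blocks
would add much code and nothing testable at desk scale.

Preprocessing follows microscopy practice: CLAHE (contrast-limited adaptive
histogram equalisation, 8×8 tiles, clip factor 2) normalises uneven
illumination, the grayscale channel is replicated into R, G, B, and channels
are standardised with the ImageNet constants (means 0.485/0.456/0.406, SDs
0.229/0.224/0.225) so pretrained backbones remain compatible. Training
augmentation applies rotation+shift with probability 0.3, horizontal flip
with 0.5, and noise-or-blur with 0.5, each independently, deterministic per
seed. Class imbalance — cleavage-stage counts span two orders of magnitude
in real data — is handled by inverse-class-frequency weights normalised so
the count-weighted mean weight is 1 (`w_c = (N/K)/n_c`), which rebalances
gradients without changing the loss scale between experiments.

Training uses Adam at an initial learning rate of 0.001, reduce-on-plateau
(patience 3 epochs, factor 0.1, floor 1e-6 — the schedule is monotone), up
to 50 epochs, returning the best-validation-loss checkpoint. Splits are
assigned at the *video* level (70/10/20) to prevent frame leakage between
splits. Frames within 2 frames of an annotated transition are dropped from
training (`exclude_transition_frames()`) because boundary labels are the
least reliable; evaluation keeps all frames.

## Postprocessing

Per-frame argmax labels are denoised in two stages.

**Stage 1 — confidence substitution.** Frames whose top probability does
not exceed 0.8 (strictly) take the label of the most recent frame that did
exceed it. Leading frames with no confident predecessor keep their own
label. The threshold is configurable.

**Stage 2 — interruptive-group removal.** With `P_i` the per-frame label,
changes `Δ(i) = 1` iff `P_i ≠ P_{i−1}` (first frame defined unchanged), and
group ids `G_i = Σ_{k≤i} Δ(k)` partition the video into runs. For a class
`c` with run ids `G_c`, any id strictly inside `[min G_c, max G_c]` not in
`G_c` *interrupts* `c`. Interruptive groups are treated as noise and
relabelled to the enclosing class (relabelled, not deleted, to keep the
output frame-aligned for timing extraction), iterating to a fixpoint with
classes processed in ascending order of first occurrence.

Two design points deserve emphasis, both discovered the hard way:

* **The length guard is essential, not optional.** Absorbing *every*
  interruptive group is only correct when noise is rare and isolated. A
  single isolated flip back to an earlier stage deep inside a later run
  makes the earlier class's id range engulf the whole span; unguarded, the
  algorithm relabels hours of development and corrupts stage onsets by
  10–80 h in simulation. The default therefore absorbs an interruptive
  group only when it is no longer than the shorter of its flanking
  same-class runs — the "compare each group's length with its neighbours"
  criterion. `length_guard = FALSE` restores the unguarded behaviour for
  comparison.
* **Absorption must merge.** A detached run lying between two classes' id
  ranges can satisfy both classes' absorption criteria and flip between
  them forever. Requiring the absorbed group to touch a flanking same-class
  run means every absorption merges runs, the run count strictly
  decreases, and the fixpoint provably terminates.

The smoother is deliberately *not* monotone: a long genuine reversion (for
example reverse cleavage, 3 cells falling back to 2) is two long runs with
no interrupted class and passes through unchanged. Short reversion episodes
flanked by the same stage are indistinguishable from noise at this level
and are absorbed; that is an inherent limit of trend-based smoothing, and
it costs under 1 % of events in the synthetic benchmark.

## Transition timing

`extract_transitions()` emits one event per run — the first run included,
so starting stages are timed — recording only the *resulting* stage (a
jump from `t2` straight to `t4` is a transition to `t4`) and the time of
the first frame bearing the new label, in hours. Errors are signed,
predicted minus true; at the nominal 20-minute frame interval one
misplaced frame contributes 0.33 h. Events are matched by (video, stage)
with a first-occurrence policy for re-entered stages (the standard
morphokinetic convention; `"occurrence"` and `"strict"` policies are
available). Summaries report count, mean, sample SD and the
25/50/75/80/85/90/95/99th percentiles via linear interpolation between
order statistics (R quantile type 7; the choice is documented because no
canonical method exists). Outputs print hours at 2 decimals; internal
arithmetic is full precision.

## The synthetic world

The generator states one fixed world; its defaults are not tuned against
test outcomes.

* **Timelines.** Stage dwell times are log-normal (log-SD 0.25) around
  means anchored to clinical morphokinetics (t2 ≈ day 1, blastocyst ≈ day
  4.5): 2, 21, 3, 11, 2, 11, 1.5, 2, 2.5, 11, 17, 15, 8, 7, 10, 8 hours
  for `tPB2` … `tHB`. These are configuration, not claims — real datasets
  publish no duration distributions, only the ontology and frame interval.
  Frames arrive every 20 minutes. 25 % of videos arrest at a random stage
  (mirroring the substantial non-viable fraction of clinical cohorts); 5 %
  show one reverse-cleavage episode of 1–3 h; all embryos leave the well on
  day 5, after which frames are `Empty` (6 h tail). `tHB` arises naturally
  only when a fast embryo reaches it before removal — which is why it is
  rare.
* **Prediction noise.** Away from boundaries a frame's argmax flips to an
  ordinal-adjacent stage with probability 0.05. Around each true boundary
  the classifier is systematically uncertain: with probability 0.4 the
  perceived boundary is displaced (magnitude geometric with ratio 0.1,
  capped at 3 frames), displaced frames carry reduced confidence
  (0.51–0.9), and no confidence falls below 0.35. The displacement
  interpretation is deliberate: reading the transition error rate as
  per-frame leaked probability mass would put every boundary frame under
  the 0.8 substitution threshold and force every detected transition ≥ 3
  frames late, contradicting the recovery property the generator is
  supposed to exhibit. Boundary-adjacent confusion between the two
  flanking stages is also what real confusion matrices show.
* **Rendering.** Frames are stage-coded geometry in a bright well: one
  large cell with marks for pronuclear stages, `k` fixed-radius
  non-overlapping cells for cleavage stage `tk`, a cluster of tiny cells
  for the morula, a growing cavity for blastocyst stages, an external
  bulge for hatching, an empty well for `Empty`, plus Gaussian pixel
  noise and random rotation. Fixed radii make foreground area nearly
  linear in cell count, so the default 5-class learnability task
  (`tPNf`, `t2`, `t3`, `t4`, `Empty`) is separable by construction.

A green test therefore establishes that the *pipeline* — encoding,
training mechanics, smoothing, timing — behaves as specified on data with
the stated structure. It does not establish photorealism, robustness to
focal drift, fragmentation, multi-embryo wells, or the accuracy figures
reported for real clinical imagery, which require the external dataset and
GPU-scale training.

## Numerical choices and degenerate inputs

* Argmax ties break toward the lower ordinal (the earlier, conservative
  stage), deterministically.
* "Greater than 80 % confidence" is a strict inequality.
* Probability rows must sum to 1 within 1e-6; CSV round-trips renormalise
  after 6-decimal rounding.
* Empty prediction sequences, misaligned vectors, non-monotone times,
  unknown labels and zero class counts raise immediate, named errors.
* All stochastic functions accept a seed and restore the caller's RNG
  state; CLI commands log their seed and re-run byte-identically.

## Known limitations

* The interruptive-group policy (class order, length guard, adjacency
  requirement) is one deterministic resolution of an under-determined
  description; alternatives could differ on pathological inputs. The
  brute-force oracle in the tests pins the chosen semantics on all 3^8
  short sequences.
* The reference-scale backbone is a capacity stand-in, not EfficientNet;
  no pretrained weights ship with the package.
* The synthetic noise model has no focal or illumination drift and its
  flips are always ordinal-adjacent; real classifiers occasionally make
  distant errors.
* Timing evaluation matches by stage identity; embryos that skip a stage
  in prediction but not truth simply yield an unmatched event rather than
  a penalised error, as in per-class event counting.
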