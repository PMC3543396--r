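---
title: "Artifact scoring, gating and registration in ivmclean: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact scoring, gating and registration in ivmclean: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivmclean)
```

## The problem and the model

Two-photon intravital microscopy records fluorescence time-lapse videos
inside living tissue. Cardiac and respiratory cycles, muscle tone and
peristalsis displace the tissue irregularly, so a fraction of frames are
translated, elastically distorted or defocused. These corruptions arrive
as isolated peaks in time, which motivates a *detect-and-discard* model
rather than frame repair: frames are scored for dissimilarity against a
reference, the high scorers are removed, and only then is the sequence
registered and enhanced.

The scoring statistic is the mean squared pixel difference (square
difference score) between frame $I_t$ and its reference $R_t$ on a single
designated *reference channel*:

$$D_t = \frac{1}{HW}\sum_{x,y}\bigl(I_t(x,y) - R_t(x,y)\bigr)^2 .$$

Two modelling assumptions matter:

1. **A temporally stable reference structure exists.** Blood vessels
   labelled by an intravascular dye are the canonical choice: over a
   session of an hour or two they neither move nor remodel appreciably,
   so any large frame-to-frame change on that channel is motion, not
   biology. The package never scores the dynamic (cell) channels.
2. **Artifacts are a minority.** Percentile gating at keep-fraction $P$
   can remove at most $(100-P)\%$ of frames; if more frames than that are
   corrupted the recording is not salvageable by frame rejection.

### Reference policies

* `single`: one user-chosen frame is the reference for the whole video.
  Simple, but the score baseline then measures distance *to that frame*:
  under slow drift the baseline ramps with drift phase, and the choice of
  reference frame visibly changes which frames get rejected.
* `rfg` (rolling reference generation, the default): for every frame the
  reference is the average-intensity projection of the window of $n$
  adjacent frames centred on the frame itself. The rolling mean tracks
  slow drift, so the baseline stays flat and only genuine outliers spike.
  The test suite asserts this as a variance comparison: on a drifting
  synthetic scene, the running-median-detrended good-frame trace has
  strictly lower variance under `rfg` than under `single`.

Two conventions needed fixing where the underlying procedure is
ambiguous, and both are deliberate:

* the scored frame is **included** in its own window ("centred on the
  frame" read literally). Inclusion damps an isolated impulse by a factor
  $\bigl((n-1)/n\bigr)^2$ — the closed form the unit tests check — but
  never changes the ranking of an isolated artifact against clean frames;
* windows **truncate** at the stack boundaries instead of padding:
  padding would have to invent content, truncation only shortens the
  average.

Scores are normalised per pixel (mean, not sum) so that they are
comparable across acquisition resolutions, and all scoring arithmetic is
done in doubles — 8-bit saturation would silently clip exactly the large
deviations the score exists to measure.

## Gating

**Percentile gate.** The threshold is the nearest-rank $P$-th percentile:
the value at rank $\lceil P/100 \cdot T\rceil$ of the ascending sort;
frames scoring at or below it are kept. Nearest rank (rather than an
interpolated quantile) makes the kept count exactly
$\lceil P/100 \cdot T \rceil$ for distinct scores and keeps the rule
deterministic. The default $P = 60$ is the demonstrated headline setting
for heavily corrupted recordings; for cleaner videos a higher $P$ wastes
fewer good frames.

**n-neighbor relative-maximum filter.** The sequence is partitioned into
*consecutive non-overlapping* groups of $n$ (odd, default 3); each group
loses its highest scorer, ties removing the earliest. A trailing partial
group of two or more frames is still filtered; a trailing singleton is
kept. Non-overlapping blocks make the removal count predictable:
$\lfloor T/n\rfloor + [T \bmod n \ge 2]$.

**Double filtering.** One relative-maximum pass removes at most one frame
per group, so two adjacent distorted frames cannot both go. `passes = 2`
re-applies the same gate to the survivors. Between passes, scores are
recomputed on the retained stack when scoring is `rfg` (references built
from a sequence that still contained artifacts are themselves
contaminated) and reused when scoring is `single` (a fixed reference does
not change when frames are removed). On a perfectly clean sequence the
second pass still removes one frame per group — the documented
over-removal cost of double filtering.

When both gates are configured, the percentile gate runs first and the
neighbor filter second on the survivors; the two are complementary (a
low percentile alone rejects too many good frames), and a fixed order
keeps runs reproducible.

## Registration

Four transform families are supported — translation; rigid (translation +
rotation); scaled rotation (+ isotropic scale); affine (full $2\times3$
matrix) — each mapping a frame's coordinates onto its predecessor's.
Alignment anchors on the first frame and proceeds by propagation: frame
$t$ is estimated against the *already aligned* frame $t-1$ on the
reference channel, so the estimate is directly the cumulative model into
the anchor's coordinate system, and it is applied to all channels.
Because estimation errors propagate down the chain, gating artifact
frames *before* alignment is the default pipeline order.

Estimator internals:

* **translation** — FFT phase correlation with parabolic sub-pixel
  refinement. Both images are Hann-windowed first: planted jitter and
  prior warps leave zero-filled borders whose straight edges otherwise
  dominate the correlation and bias the peak toward zero shift (this
  failure mode was observed directly on the jitter fixture and is the
  reason the window is not optional).
* **rigid / scaled rotation / affine** — coarse-to-fine Gauss–Newton
  least squares on the backward warp parameters (the classic pyramid
  intensity-based approach used by stack-registration plug-ins): a
  2–3 level mean-pyramid, with the full-resolution phase-correlation
  shift as the starting point whenever it lowers the initial cost, then
  iterative linearisation of
  $\sum_q\bigl(\mathrm{moving}(Bq)-\mathrm{fixed}(q)\bigr)^2$. Rigid and
  scaled-rotation results are the polar projection of the fitted linear
  part, re-anchored so the image centre maps identically. A first
  implementation matched salient patches by local search and fit the
  model to correspondences; on vessel images it was unreliable (straight
  tube segments suffer the aperture problem, and the quasi-periodic
  network produces wrong locks under shear), so it was replaced — the
  interface contract is unchanged.
* degenerate inputs (zero-variance frames, vanishing overlap, singular
  normal equations) fall back to translation-only with a warning; a
  degenerate frame mid-sequence reuses the previous cumulative model.

Resampling is inverse-mapped bilinear interpolation, zero fill outside
the field, re-quantized to 8 bits by round-half-up. Zero fill was chosen
over edge replication because invented content at the border would leak
into later propagated estimates.

Planted-transform recovery is tested noise-free to ≤ 0.5 px
(translations up to 5 px) and ≤ 2% relative Frobenius error (affine with
0.1 shear), with graceful degradation (≤ 1 px) under σ = 10 intensity
noise.

## Enhancement

* **Channel subtraction** removes bleed-through (e.g. CFP signal in the
  YFP channel under simultaneous excitation): per pixel
  $\mathrm{clip}(T - \alpha S,\,0,\,255)$. The spillover scale $\alpha$
  (default 1) is user-set; estimating it would require single-dye control
  acquisitions, so no estimation procedure is invented.
* **Grouped projections** collapse non-overlapping windows of $w$ frames
  by per-pixel max (extended field of view) or rounded mean (improved
  signal-to-noise), reducing the frame rate by $w$; the output frame
  inherits the origin index of its group's first frame.
* **Kalman stack filter**: a causal per-pixel temporal smoother that
  keeps the frame count — its advantage over projections. The recursion
  is reconstructed from first principles, not ported from any existing
  implementation: the package provides a fixed-gain form $E_t = g\,E_{t-1} + (1-g)\,x_t$ (default
  $g = 0.8$, the conventional setting for this filter family) and an adaptive
  scalar-state variant with measurement noise $R = (\rho\,255)^2$,
  $\rho = 0.05$, initial variance $R$. $g = 0$ is the identity. State is
  real-valued throughout; re-quantization happens once at the end. The
  steady-state variance ratio of the fixed-gain filter on static noise,
  $(1-g)/(1+g)$, is asserted by the tests up to quantization slack.

## Annotation

Timestamps are a pure function of origin index and frame interval:
`origin_index x frame_interval`, formatted `MM:SS.mmm`. Burn-in uses a
built-in 3×5 bitmap font (white glyphs, 1 px black outline, integer
upscaling) so rendering is identical on every platform; pixel-exact
assertions are made only in sidecar mode, which never touches pixels.
Scale bars are `round(length / pixel_size)` pixels wide and refuse to
draw when the pixel size is unknown or the bar exceeds the frame.

## The synthetic scene generator

`generate_scene()` emulates the structure the method relies on, not the
optics: a static vessel network (smoothed random-walk tubes with Gaussian
cross-section) on red, moving Gaussian blobs (cells) on green, an empty
blue channel, i.i.d. Gaussian sensor noise per frame, optional slow
sinusoidal drift, and planted corruptions applied to all channels with
per-frame ground-truth labels:

* **major** artifacts are full-field: translation ≥ 8 px, defocus blur
  σ ≥ 4 px, or elastic warp with ≥ 6 px peak;
* **minor** artifacts are small glitches: 1–3 px translations or
  partial-field warps ≤ 2 px.

The major/minor boundary values are generator parameters; the underlying
classes are qualitative (full-field distortion vs small glitch), so the
thresholds above are this package's own operationalisation.

Everything is reproducible from the seed, and the generator restores the
caller's RNG state. Label bookkeeping is exact: planted corruption counts
equal label counts.

Two presets are used throughout the tests:

* `scene_separable()` — the headline fixture: 39.8% major artifacts,
  shift-type only (8–20 px, random directions), noise σ = 2, no drift,
  and **stratified** artifact placement (one artifact drawn per equal
  time bin). Stratification is what makes the preset's construction
  guarantee hold — every artifact frame scores strictly above every good
  frame. Under uniform placement at this load, some 15-frame scoring
  windows consist almost entirely of artifacts; the rolling reference for
  the good frame inside such a window is built from artifact frames, and
  that frame's score becomes indistinguishable from an artifact's, so
  strict separation is impossible by construction, not by bad luck.
  Bounded local density is also what quasi-periodic respiratory
  interference actually looks like. At $T = 1000$ and $P = 60$,
  $\lceil 0.6 \cdot 1000\rceil = 600$ frames survive and all 398 planted
  artifacts fall in the rejected 400.
* `scene_drift()` — 1000 frames with 4 px sinusoidal drift (period 250)
  plus 10% shift artifacts; the fixture on which rolling references are
  compared against a fixed reference.

What the generator does **not** emulate — and what passing tests
therefore do not establish for real data: realistic point-spread
functions and photon (shot) noise, photobleaching, vessel remodelling,
fast in-plane cell motion on the reference channel, z-drift, and
correlated (non-i.i.d.) noise. The construction guarantee of the
separable preset is a property of that preset, not of arbitrary
recordings; on real videos the score distributions of good and corrupted
frames can overlap, which is exactly why the percentile cutoff is a
user-facing parameter.

## Numerical choices and degenerate inputs

* Intensities are stored as doubles in $[0,255]$; every operation that
  writes pixels re-quantizes by round-half-up with clipping.
* Nearest-rank percentile; earliest-index tie-break in the neighbor
  filter; stable frame order everywhere (gating never reorders).
* Histogram reports use 50 equal-width bins by default; an all-equal
  score series degenerates to a single occupied bin of frequency 1.
* Gauss–Newton stops when the predicted corner displacement changes by
  < 0.01 px (at most 50 iterations per level); pyramid levels halve
  resolution down to a 48 px minimum edge, at most 3 levels.
* Empty stacks are unrepresentable (`T ≥ 1` enforced); selections must
  partition the origin indices they cover; metadata parsing requires the
  frame interval and warns outside the usual 2.5–15 fps acquisition
  range.

## Problem sizes in the test suite

The suites run on sizes chosen to exercise every code path while staying
quick on a single CPU: oracle comparisons on 20-frame 64×64 stacks,
gating oracles on 1000 random score vectors, the headline and drift
fixtures at 1000 frames of 64×64×3, and registration fixtures at 96×96.
The acceptance script (`scripts/acceptance.R`) re-runs the same
computations from scratch and writes each resulting quantity with the
problem size it used.

## Limitations

Frame rejection cannot create good frames: heavily corrupted recordings
lose most of their timeline. Elastic (within-frame, non-uniform) motion
is out of scope — such frames are meant to be *rejected*, not unwarped.
The Kalman filter blurs genuinely fast-moving objects; it is intended
for post-gating residual noise, not for motion repair. Only 8-bit, up to
3-channel, single-plane time series are supported.
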