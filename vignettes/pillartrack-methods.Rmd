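---
title: "Methods: pillar-deflection tracking and contractility metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pillar-deflection tracking and contractility metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pillartrack)
```

## The measurement model

A cardiac microbundle suspended between two elastomeric pillars contracts
periodically; each pillar tip deflects toward the tissue centre by δ(t)
micrometres. Treating each pillar as a linear cantilever, the twitch force
follows Hooke's law

$$F(t) = k\,\delta(t),$$

with the stiffness either measured experimentally (e.g. 2.677 µN/µm for
standard Type-1 strain-gauge devices) or derived from beam theory for a
point load applied at height $a$ along a cantilever of length $L$:

$$k = \frac{6EI}{a^2(3L-a)}, \qquad
I_\text{rect} = \frac{wt^3}{12}, \quad I_\text{circ} = \frac{\pi D^4}{64}.$$

At $a = L$ this reduces to the classical tip-load stiffness $3EI/L^3$, which
the tests pin to machine precision. Units are µm, µN, µN/µm throughout; the
elastic modulus is accepted in kPa and converted internally
(1 kPa = 10⁻³ µN/µm²). Mean tissue stress divides the force by the tissue
cross-section, `width × depth`, where the width is auto-measured on the
first valley frame (Otsu-thresholded midline strip between the pillars'
inner edges — scale-invariant, so global intensity rescaling moves the
estimate by at most a pixel) and the depth is user input.

**Deflection convention.** δ is the *mean of the two pillars' deflections
from rest*. The alternative — the change in inter-pillar distance, which
equals the *sum* of the two deflections for a symmetric contraction —
yields forces exactly twice as high. Both are implemented in
`twitch_force()`; the package reports the mean-pillar convention and a test
asserts the exact factor of two so the choice can never drift silently.

## Segmentation

The first frame is thresholded with a *local Otsu* scheme: the frame is
tiled (tile ≈ 2 × the 25 px default radius, shrunk for small frames), a
256-bin Otsu threshold is computed per tile, tiles with less than 20% of the
global contrast fall back to the global Otsu threshold (so background tiles
do not threshold their own noise), and the tile thresholds are bilinearly
interpolated to a per-pixel threshold surface. The binary map is cleaned by
3×3 opening and closing, hole filling, and removal of border-touching and
sub-0.1%-area components. Because the tissue band is horizontally elongated
while pillar caps are compact, candidates wider than 2.5 × their height are
discarded; of the survivors the two largest with centroid-column separation
exceeding one candidate width become the left/right masks (ordered by
centroid column). Failures raise an error that points at the external-mask
path: a whitespace 0/1 text grid or a binary PNG, where 1 denotes the pillar
domain.

The mask-perturbation protocol (`perturb_mask`) applies a fixed 5×5 square
structuring element — erosion or dilation, once or four times — and the
sensitivity of the tracked peak displacement to these perturbations is part
of the acceptance suite (bound: under 10%).

## Feature detection and tracking

Fiducial markers are Shi-Tomasi corners: the minimum eigenvalue of the
structure tensor (gradients by central differences, accumulated over a 5 px
block), thresholded at `quality_level` × the maximal response inside the
mask, then greedily non-maximum-suppressed at `min_distance`. Tracking is a
pyramidal Lucas-Kanade solver written for this package (no R binding to an
existing implementation exists): per frame pair and per pyramid level,
each marker's displacement solves the local least-squares system on spatial
and temporal gradients within a square window by damped Newton iteration
(up to 20 iterations, 0.01 px tolerance), with the coarse-level flow
doubled and refined at the next finer level. Pyramids use a 5-tap
binomial antialiasing filter and 2× decimation, capped so the coarsest
level is at least 16 px. All interpolation is bilinear. The solver is
vectorised across markers, so cost scales with window area × levels, not
marker count.

Automatic parameter adjustment is a deterministic schedule: defaults
(quality 0.1, min distance 3 px, window 15 px, 3 levels); if fewer than 10
features are found the quality level is halved down to a floor of 0.005;
the window scales with the mask bounding box (reference 40 px box ↔ 15 px
window, capped at 4×, kept odd). Markers whose system is degenerate, whose
flow exceeds the window extent, or which leave the frame are dropped with a
warning — never interpolated — and fewer than 5 survivors per pillar is a
hard error. The whole tracking path is deterministic; there is no seed.

## Beat segmentation, drift, irregularity

Displacement is reduced per pillar to mean directional components and the
mean per-marker displacement norm (so equal-and-opposite marker motion
cancels directionally but not in magnitude). For valley finding the package
uses the *inter-pillar separation deficit* `max(sep) − sep(t)` when both
pillars are tracked: separation is baseline-free and maximal exactly when
the tissue is relaxed, so the signal is valid even for movies that start
mid-beat (where the frame-1-baselined absolute displacement has its minima
at the *contracted* frames). For bare single-signal inputs the mean
absolute displacement is used.

The signal is smoothed by a centred moving average over
`max(3, round(fps/10))` frames. Valley candidates are local minima; their
prominence (lowest barrier toward the neighbouring candidates) must exceed
25% of the *largest candidate prominence* — this reference tracks the beat
amplitude rather than the raw signal range, which baseline drift would
inflate and which would otherwise suppress genuine valleys in drifting
movies. A minimum valley separation of `fps/3` frames (rate cap 3 Hz) is
enforced by keeping the deepest valleys first. The movie start counts as a
valley when it sits within the prominence band of the global minimum; the
movie end never does, so the terminal partial beat is discarded. Fewer than
2 complete beats is a hard error; per-beat splitting additionally requires
3. If the first valley is not frame 1, the movie is truncated to start
there and detection + tracking are re-run.

Drift is flagged when the mean absolute displacement at any valley other
than the baseline exceeds 0.5 px — below typical tracking noise a warning
would be meaningless; the threshold is config-overridable. Correction is
per-beat re-baselining (marker positions at each beat's start valley),
which removes linear drift to within 5% of per-beat amplitude by
construction and is never applied automatically — the user opts in with
`split = TRUE`. Irregular beating is a warning only: period CV above 20%
or any beat peak deviating more than 30% from the median peak. These two
thresholds are this package's own quantification of "irregular"; nothing
further is done with flagged movies.

## Metrics

Within each (re-baselined) beat: the peak is the global maximum; FWHM and
FW80M are the times between the linearly interpolated flank crossings of
50% and 80% of the peak (for a raised-cosine beat of period $P$,
FWHM $= P/2$ exactly; for a symmetric triangle, FW80M $= 0.4\,$FWHM);
contraction and relaxation velocities are the extremal central-difference
derivatives before and after the peak (no smoothing by default — at 30 fps
and a 1 s beat the discretisation error is under 2%). The beating rate is
complete beats divided by the time between first and last valley. Summaries
are means ± SD across beats; a single beat reports SD 0 with an explicit
flag. All metrics are invariant to constant offsets of the displacement
signal. "FW80M" is read as the full duration at 80% of maximum.

## The synthetic generator

`generate_movie()` renders what the tracker actually faces: two square caps
(default 28 px) carrying band-limited speckle texture at 22% contrast
(corner detection needs texture; this mirrors the real applicability
condition that pillar regions show identifiable texture), a dimmer tissue
band stretching linearly between the inner cap edges, and a dark
low-texture background. Motion is pure translation of the caps — rendered
by resampling continuous textures at sub-pixel shifted coordinates with
soft (≈1 px) edges, never integer rolls — following a raised-cosine or
triangular waveform (default 3 px amplitude, 30-frame period, 30 fps, i.e.
1 Hz pacing at a 4 µm/px length scale). Movies span `beats × period` plus
half a period, so the last valley remains an interior minimum and a movie
rendered with B beats yields B analyzable beats. Optional ingredients:
per-beat amplitude multipliers (irregularity), symmetric inward drift
(px/frame, tissue-compaction-like), Gaussian noise as a fraction of dynamic
range (default 2%), 8/16-bit quantisation. One seeded stream makes movies
bit-identical per seed.

Before the generator is allowed to judge the tracker, it is itself
validated: a brute-force SSD template-matching oracle (nested sub-pixel
grid search with bilinear resampling, independent of the optical-flow code)
must agree with the manifest within 0.1 px on noiseless movies.

What the generator does *not* emulate: out-of-plane motion, focus drift,
illumination gradients, pillar rotation, and deforming cap appearance.
Passing tests therefore demonstrate correctness of the algorithmic chain on
in-plane translating textured targets, not robustness to every real-world
artefact.

## Problem sizes and numerical choices

Test and validation movies are 96 × 200 px with 2–4 beats (51–136 frames) —
large enough for two 28 px caps, a 30 px tissue band and multi-pixel
deflections, while keeping the full suite fast on a single CPU. The
acceptance script tracks six movies (five for the noise-accuracy bound at
amplitudes 1.5–5 px, one for the mask-perturbation bound) and reruns
tracking under four perturbed mask sets.

Degenerate inputs are first-class: constant frames fail segmentation with
the external-mask hint; textureless masks fail detection after the
relaxation schedule bottoms out; flat beats fail velocity estimation;
over-erosion raises an empty-mask error; all-zero or non-binary external
masks are rejected. Ties in candidate selection resolve by area, then
lateral separation; marker means are permutation-invariant.

One deliberate deviation from common Python-side conventions: indices are
R-native 1-based (frames 1..F, pixel (row, col) from the top-left), stated
here once and used consistently in all outputs.

## Known limitations

Rotation or shear of the pillar caps is not modelled (translation-only
flow); dense out-of-plane motion can masquerade as drift (the drift warning
is the intended detector); the tissue-width measurement assumes a single
contiguous band at the midline; Type-2 styling shares the Type-1 code path
with polarity checks rather than a separately trained appearance model; and
the AI-based segmentation route of the original software family is out of
scope — external masks are the supported fallback.
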