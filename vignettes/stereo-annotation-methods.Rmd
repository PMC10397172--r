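---
title: "Tracking and depth-correct annotation of stereoscopic surgical video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and depth-correct annotation of stereoscopic surgical video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereoannot)
```

## The problem

Robotic-assisted surgery (RAS) is performed through a stereoscopic console:
the operating surgeon sees the field in depth. Training material should
therefore also be stereoscopic, and the recorded videos — side-by-side
(SBS) composites, left eye in the left half — gain teaching value when an
expert marks up anatomical structures ("annotations" or *marks*) and
sub-intervals worth watching ("sections"). The catch is depth: a virtual
overlay burned into both eyes at the same horizontal position appears at
the screen plane, floating in front of or behind the tissue it labels.
Mismatched depth cues are uncomfortable to fuse and can cause
cybersickness. For the overlay to sit *on* the tissue, the right-eye copy
must be drawn shifted by the tissue's horizontal disparity, and that
disparity must be re-estimated as the element and the endoscope move.

`stereoannot` implements that computational core: keyframe scheduling,
object tracking in the left eye, per-keyframe disparity estimation,
disparity smoothing, depth-correct rendering, section timeline algebra, a
teacher-authoritative synchronized playback protocol, and the evaluation
statistics used for questionnaire studies of such tools.

## Conventions

* Pixel coordinates are 0-based, origin top-left, x rightward, y downward.
  Boxes are `(x, y, w, h)` with half-open extents `[x, x+w) × [y, y+h)`,
  always in *left-eye* coordinates.
* Time is authoritative in seconds; the frame index is `round(t · fps)`.
* Disparity is `d = x_left − x_right` of matched content; the right-eye
  overlay is drawn at `x_left − d`. A `disparity_sign` switch covers
  sources with the opposite convention, and `swap_eyes()` covers
  right-eye-left sources.

## Video container

Stereo video lives behind a small interface (`open_sbs_video()`,
`read_stereo_frame()`, `write_sbs_video()`) with two backends: an
in-memory frame list for small scenes, and a lossless *frame store* — a
directory of per-frame PNGs plus a `meta.json` descriptor — for anything
longer. A lossless container keeps every pipeline stage bit-reproducible:
a write/reopen round trip returns identical pixels, which the tests rely
on. Frames are numeric arrays in `[0, 1]`, grayscale or RGB.

## Annotation processing

Processing turns one user-drawn box at `t_start` into keyframes covering
`[t_start, t_end]`:

1. **Schedule.** Keyframes at `t_start, t_start + Δt, …`, with `t_end`
   always appended, so spacing never exceeds `Δt`. The update interval
   `Δt` controls how often the tracked element is relocated; values
   between 0.1 s and 1 s are reasonable and the default is 0.5 s. Smaller
   `Δt` tracks faster motion at proportionally higher cost.
2. **Track.** A discriminative normalized cross-correlation (NCC) template
   tracker runs on every frame of the span in the left eye: the template
   is fixed at initialization (no drift accumulation) and searched in a
   `search_margin` window (default 32 px) around the previous position.
   The per-frame match confidence is the peak correlation clipped below at
   zero — so the default `confidence_threshold` of 0.5 demands genuine
   correlation, not the ~0 level a random match produces. Below the
   threshold the last good box is held and the keyframe is flagged; a run
   of more than `max_consecutive_failures` (default 5) consecutive flagged
   keyframes truncates the annotation at the last good keyframe and logs
   it. The class of tracker named in the literature for this task (CSRT)
   has no binding in this toolchain; the template tracker fills the same
   contract and is exercised against generated ground truth.
3. **Disparity per keyframe.** The tracked left-eye patch is matched
   against the right eye along the same rows (rectified-rig assumption:
   stereo endoscopes exhibit essentially pure horizontal parallax) over
   shifts in `[−search_range, +search_range]` (default 128 px ≈ 6.7% of a
   1920 px eye) using zero-normalized cross-correlation. Matching uses an
   *interior* template — the box border, eroded by 10% of the short side
   (at most 3 px), is excluded — because border pixels straddle the
   object/background boundary and carry the background's disparity; with
   the full box, a probe whose box exactly covers the object can have its
   integer peak displaced by a whole pixel. With `subpixel` on, the
   integer peak is refined by re-matching against bilinearly resampled
   right-eye patches on a 1/8-px grid followed by a parabolic fit on that
   grid; a plain three-point parabola on the integer scores was measured
   to carry quarter-pixel bias on textured patches, which the fine grid
   removes. A (near-)constant patch is degenerate: disparity `NA`,
   score 0.
4. **Maintain.** The raw disparity track is smoothed so the overlay's
   depth is stable: a window-3 sliding median removes singleton outliers,
   keyframes whose score fell below the confidence threshold inherit
   linearly interpolated disparity from good neighbors, and any remaining
   jump beyond `max_disparity_jump` (default 10 px per keyframe) is
   clamped toward its predecessor. The maximum absolute inter-keyframe
   jump never increases.

Processing is deterministic for fixed inputs (the default path draws no
random numbers), and the processed annotation carries a signature of its
inputs so reprocessing with unchanged inputs returns the stored keyframes
— the stored positions and disparities never need recomputation.

The annotation lifecycle is `unprocessed → processing → processed`
(timeline colors red/yellow/green; section bars are blue). Only processed
annotations are ever rendered; student-facing operations additionally
require the intervention to be `published`.

`submit_job()` / `poll_job()` implement the asynchronous authoring
contract — states `queued → running → done/failed`, monotone progress,
non-blocking polls, resubmission returning the live job. In this package
the registry executes jobs synchronously in-process; the contract, not the
concurrency mechanism, is the tested surface, and a process-level executor
could be substituted without changing callers.

## Rendering

Between keyframes, box center, size and disparity interpolate linearly
(`interpolate_annotation()`); at keyframe times the stored keyframe is
returned exactly. Holding the last keyframe instead would be cheaper but
makes overlays jump at each keyframe, so interpolation is the default and
is isolated behind one function. Each processed annotation is drawn as a
rectangle plus a 5×7 bitmap-font label in the left eye at its box, and in
the right eye shifted by `−d`. The shared pointer is drawn in both eyes at
the screen plane by default (`pointer_disparity` lets it borrow depth).
Viewer comfort controls shift the eyes apart/together symmetrically
(`disparity_offset`, preserving the cyclopean center) and zoom about the
eye center. With nothing to draw and neutral settings, `render_frame()` is
the identity.

Sections may overlap; `compact_sections()` merges them into a sorted,
disjoint union clipped to the video duration, and sections-only playback
renders exactly those frames, so hours of routine footage collapse to the
teaching material. `map_compact_time()` is the strictly increasing
piecewise-linear map from the compacted axis back to source time. Speed
(1×, 2×, 4×, 8×) is implemented by frame decimation at unchanged output
fps — bit-exact and container-independent; other speeds are rejected.

## Synchronized playback

A teacher creates a room (6-character code from a 32-symbol alphabet
without 0/O/1/I) and every control action becomes a sequenced JSON message:
`play`, `pause`, `seek(t)`, `speed(s ∈ {1,2,4,8})`, `mode(full|sections)`,
`pointer(x, y, visible)`. Student state is a pure fold over the messages in
`seq` order; the client buffers out-of-order arrivals and applies them in
sequence, so any delivery order of the same messages yields the same
state, and duplicates are dropped. Students have no API that mutates
shared state — teacher authority is structural, not policed. Position
advances between messages via the local clock only while playing; sessions
log as JSON-lines and replay deterministically. The transport is
pluggable; the in-memory loopback used in tests is the reference.

## Synthetic scenes and what they do (not) show

Patient videos cannot be redistributed, so every stage is validated on
generated SBS scenes: seeded band-limited textures (coarse random grids,
bilinearly interpolated, periodic) for background and patches, patches
following linear or sinusoidal trajectories with constant, linear or
sinusoidal disparity profiles, a drifting background with its own
disparity, flat-gray occluders, and per-eye additive Gaussian noise. The
right eye is the same content with each patch shifted by `−d(t)`, so
ground-truth disparity equals the applied offset *by construction* and
estimator error is measurable exactly. Output is quantized to 8 bits so
in-memory and PNG-stored scenes agree bit-exactly, and generation is fully
determined by the seed.

The demo intervention mirrors the structure of a thoracic-surgery teaching
video — a robotic resection of a mediastinal cyst — with four sections
("Start of the surgical procedure", "Opening of the mediastinal pleura",
"Continuity with the sympathetic chain", "Rib release") and three
annotations ("Subclavian artery", "Cyst", "Sympathetic chain") bound to
three moving patches. The default profile is 30 s at 25 fps, 640×360 per
eye, which keeps an end-to-end run at desk scale; passing
`eye_size = c(1920, 1080)` reproduces the full-HD SBS geometry (3840×1080
composite) for integration runs.

What passing these tests shows: the geometry and bookkeeping are correct,
the estimator recovers known shifts to subpixel accuracy under moderate
noise, and the failure policy triggers when evidence disappears. What they
do not show: robustness to specularities, smoke, non-rigid tissue
deformation, motion blur, or appearance change — the generator's patches
are rigid and their texture is stationary. Real endoscopic footage will
produce more flagged keyframes and earlier truncations; the thresholds
here are acceptance bars for the machinery, not clinical performance
claims.

## Evaluation statistics

For questionnaire studies, `summarize_likert()` gives n, mean, sample sd,
min, max, median and IQR (type-7 quantiles — linear interpolation — chosen
for determinism and documented because IQR values depend on the quartile
convention). `one_sample_t_from_summary()` computes
`t = (m − μ₀)/(s/√n)`, `df = n − 1`, two-sided p — directly from printed
summary statistics, which is how published rating tables can be
recomputed without raw data. `wilcoxon_one_sample()` drops zero
differences, average-ranks ties, and uses exact enumeration of sign
assignments for effective n ≤ 12 (valid under ties) or a tie-corrected
normal approximation otherwise, Z signed so ratings above μ₀ give Z > 0;
no continuity correction is applied, which is documented rather than
configurable.

## Numerical choices and edge cases

* Keyframe times use a 1 ns tolerance when deciding whether `t_end` was
  already reached, so spans that are exact multiples of `Δt` do not get a
  duplicate final keyframe.
* `estimate_disparity()` clamps partially out-of-frame boxes with a
  warning; a fully outside box is an error.
* A perfect (numerically 1.0) integer correlation peak skips subpixel
  refinement: the match is exact and a fit could only perturb it.
* Sections touching end-to-start merge (the union is taken on closed
  intervals at second resolution); serialization rounds times to
  milliseconds, sub-frame at any realistic fps.
* When an annotation re-enters the unprocessed state its keyframes are
  dropped: stale keyframes must never be rendered as if current.
* Room codes from a seeded generator are reproducible for tests;
  unseeded codes use R's global RNG.

## Problem sizes used in the checks

The test suite and the acceptance script validate: integer-shift recovery
over the full ±128 px search range and ~30 fractional shifts (single-frame
560×100 probes); noise-σ=5 MAE over 500 keyframes (25 scenes × 20
frames); a three-scene motion suite (4 s, 320×180, linear ×2 +
sinusoidal) against ground truth; 400–1000 random section sets against a
1 ms grid-membership oracle; the full demo intervention end-to-end; and
100-message protocol replays under adversarial reordering. These sizes
were chosen to exercise each claim while keeping a complete run at desk
scale.

## Known limitations

* The template tracker has no scale/rotation adaptation; boxes keep their
  initial size. Surgical close-ups with strong zoom change will lose IoU.
* Disparity is one scalar per annotation — correct for compact elements,
  an approximation for elongated structures crossing depth gradients.
* The rectified-rig assumption ignores vertical parallax; a miscalibrated
  rig would need a vertical search band.
* The job registry is synchronous; true parallelism would need a
  process-level executor.
* Wire-format messages carry no authentication; the protocol trusts the
  transport, as a classroom deployment behind one broker would.
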