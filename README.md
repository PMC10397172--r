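# stereoannot

Depth-correct annotation of side-by-side stereoscopic surgical video, in R.

Robotic-assisted surgery (RAS) is taught with recordings of real
procedures, and because the operating console is stereoscopic, the
teaching videos are too: 3840×1080 side-by-side (SBS) composites, left eye
in the left half. When a teacher highlights an anatomical structure with a
labeled bounding box, the overlay must appear *at the depth of the
tissue* — otherwise the two eyes receive conflicting depth cues, the
annotation floats off the anatomy, and viewers get uncomfortable. That
requires (i) tracking the annotated element through the video and (ii)
estimating, at every keyframe, the horizontal disparity

> d = x_left − x_right

of the matched content between the two eyes, then drawing the right-eye
copy of the overlay at `x_left − d`. `stereoannot` implements this
pipeline and everything around it:

* **stereo I/O** — open/validate/split/compose SBS video (lossless PNG
  frame store + in-memory backend), red-cyan anaglyph preview;
* **data model** — interventions, named sections, annotations ("marks")
  with keyframes; canonical versioned JSON with field-path validation;
  section timeline algebra (union, compacted-time mapping);
* **processing engine** — keyframe scheduling (default Δt = 0.5 s),
  NCC template tracking with a hold-and-flag failure policy,
  band-restricted block matching with subpixel refinement for disparity
  (search range ±128 px), median + jump-clamp disparity maintenance,
  and an asynchronous job contract;
* **renderer** — burns processed annotations into both eyes at matching
  depth, sections-only playback, speeds 1×/2×/4×/8×, shared pointer,
  viewer disparity/zoom comfort controls;
* **synthetic scenes** — seeded textured stereo scenes with exact
  ground-truth boxes and disparities, so every claim is testable without
  patient data;
* **sync protocol** — room codes, sequenced teacher-authoritative playback
  messages, deterministic client replay;
* **evaluation statistics** — Likert summaries, one-sample t-tests from
  summary statistics, one-sample Wilcoxon signed-rank test.

## Worked example

Generate a 4-second synthetic stereo scene with one moving textured patch
at constant disparity 10 px, annotate it, process the annotation, and
compare with the generator's ground truth:

```r
library(stereoannot)

spec <- scene_spec(
  duration = 4, fps = 25, eye_size = c(320, 180),
  background = list(seed = 2, drift = c(2, 1), disparity = 2, scale = 20),
  patches = list(list(
    id = "vessel", seed = 9, size = c(44, 36),
    trajectory = list(type = "linear", from = c(40, 60), to = c(150, 110)),
    disparity  = list(type = "constant", value = 10))),
  noise_sigma = 2, seed = 1)
scene <- generate_scene(spec)

ann  <- annotation("mark-vessel", "Vessel", t_start = 0, t_end = 4,
                   initial_box = bounding_box(40, 60, 44, 36))
proc <- process_annotation(scene$video, ann, processing_config(search_margin = 20))
proc$state
#> [1] "processed"

kf <- proc$keyframes[[5]]
sprintf("keyframe at t=%.1f s: box (%.0f, %.0f, %.0f, %.0f), d = %.2f px",
        kf$time, kf$box$x, kf$box$y, kf$box$w, kf$box$h, kf$disparity)
#> [1] "keyframe at t=2.0 s: box (95, 85, 44, 36), d = 10.05 px"

evaluate_against_truth(intervention("demo", annotations = list(proc)),
                       scene$truth, patch_map = c("mark-vessel" = "vessel"))
#>          mark  mean_iou disparity_mae flagged_fraction n_keyframes
#> 1 mark-vessel 0.9593228    0.02510674                0           9
```

The annotation was scheduled at the default half-second interval (9
keyframes over 4 s), tracked with mean IoU 0.96 against the known
trajectory, and its disparity recovered to 0.03 px mean absolute error.
Rendering then draws the box and label in the left eye at the keyframe
box and in the right eye shifted by −d:

```r
fr  <- read_stereo_frame(scene$video, 50)
out <- render_frame(fr, list(proc), viewer_settings())
```

The statistics module recomputes one-sample t-tests directly from printed
summary statistics (here: 15 raters, mean 128/15 ≈ 8.533, sd 1.2466 on a
0–10 usefulness item, tested against 7.75):

```r
one_sample_t_from_summary(128/15, 1.2466, 15, 7.75)
#> one-sample t = 2.434, df = 14, two-sided p = 0.02894, mean diff = 0.783
```

A thin CLI over the same functions lives at `inst/cli/stereoannot.R`
(subcommands `probe`, `validate`, `process`, `render`, `synth`, `stats`,
`room`).

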