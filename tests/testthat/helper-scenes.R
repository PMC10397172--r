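# Shared fixture builders. Everything is generated in code at test time;
# the demo intervention (30 s, 640x360 per eye) is expensive, so it is
# built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

demo_fixture <- function() {
  if (is.null(.fixture_cache$demo)) {
    dir <- file.path(tempdir(), "stereoannot-demo-store")
    .fixture_cache$demo <- make_demo_intervention(out_dir = dir)
  }
  .fixture_cache$demo
}

processed_demo_fixture <- function() {
  if (is.null(.fixture_cache$demo_processed)) {
    demo <- demo_fixture()
    .fixture_cache$demo_processed <-
      process_intervention(demo$video, demo$intervention)
  }
  .fixture_cache$demo_processed
}

demo_patch_map <- c("mark-artery" = "subclavian-artery",
                    "mark-cyst" = "cyst",
                    "mark-chain" = "sympathetic-chain")

# A small scene with one patch: quick to generate, matchable texture.
small_scene <- function(duration = 2, fps = 25, eye = c(320, 180),
                        trajectory = list(type = "linear", from = c(40, 60),
                                          to = c(140, 100)),
                        disparity = list(type = "constant", value = 10),
                        size = c(44, 36), noise_sigma = 0, seed = 4,
                        occluders = list(), drift = c(2, 1)) {
  spec <- scene_spec(
    duration = duration, fps = fps, eye_size = eye,
    background = list(seed = 2, drift = drift, disparity = 2, scale = 20),
    patches = list(list(id = "p", seed = 9, size = size,
                        trajectory = trajectory, disparity = disparity)),
    occluders = occluders, noise_sigma = noise_sigma, seed = seed)
  generate_scene(spec)
}

# One noiseless single-frame stereo scene whose only patch is shifted by
# `d` pixels between the eyes; used as a pure-shift disparity probe.
shift_probe_frame <- function(d, eye = c(560, 100), box = c(260, 30, 40, 40),
                              seed = 5) {
  spec <- scene_spec(
    duration = 1 / 25, fps = 25, eye_size = eye,
    background = list(seed = 1, drift = c(0, 0), disparity = 0, scale = 16),
    patches = list(list(id = "p", seed = seed, size = box[3:4],
                        trajectory = list(type = "static", at = box[1:2]),
                        disparity = list(type = "constant", value = d))),
    seed = seed)
  generate_scene(spec)$video |> read_stereo_frame(0)
}

random_sections <- function(k, duration) {
  starts <- runif(k, 0, duration)
  lens <- runif(k, 0.01, duration / 3)
  lapply(seq_len(k), function(i)
    section(paste0("s", i), starts[i], min(starts[i] + lens[i], duration)))
}

# Grid-membership oracle for interval unions: marks a 1 ms grid and reads
# the union back off it.
grid_union <- function(sections, duration, step = 1e-3) {
  grid <- seq(0, duration, by = step)
  covered <- rep(FALSE, length(grid))
  for (s in sections) {
    covered <- covered | (grid >= s$t_start - step / 2 & grid < s$t_end - step / 2)
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  data.frame(start = grid[starts[r$values]],
             end = grid[pmin(ends[r$values] + 1, length(grid))])
}
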