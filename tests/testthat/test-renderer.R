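processed_ann <- function(id = "a", d0 = 4, d1 = 8) {
  kfs <- list(keyframe(1, bounding_box(100, 40, 40, 30), d0, 0.9),
              keyframe(2, bounding_box(120, 50, 40, 30), d1, 0.9))
  annotation(id, "Cyst", 1, 2, bounding_box(100, 40, 40, 30),
             state = "processed", keyframes = kfs)
}

test_that("keyframe interpolation is exact at keyframes and linear between", {
  ann <- processed_ann()
  at <- interpolate_annotation(ann, 1)
  expect_equal(at$box$x, 100); expect_equal(at$disparity, 4)
  at2 <- interpolate_annotation(ann, 2)
  expect_equal(at2$box$x, 120); expect_equal(at2$disparity, 8)
  mid <- interpolate_annotation(ann, 1.5)
  expect_equal(mid$disparity, 6)
  expect_equal(mid$box$x, 110); expect_equal(mid$box$y, 45)
  # absent outside the span
  expect_null(interpolate_annotation(ann, 2.001))
  expect_null(interpolate_annotation(ann, 0.999))
  # unprocessed annotations cannot be interpolated
  raw <- annotation("r", "x", 0, 1, bounding_box(0, 0, 10, 10))
  expect_error(interpolate_annotation(raw, 0.5), class = "stereoannot_unprocessed")
})

blank_frame <- function(t = 1.5, W = 320, H = 180) {
  set.seed(1)
  img <- matrix(runif(H * W), H, W)
  structure(list(left = img, right = img, index = 0L, time = t),
            class = "stereo_frame")
}

test_that("render_frame with nothing to draw is the identity", {
  fr <- blank_frame()
  out <- render_frame(fr, list(), viewer_settings())
  expect_identical(out$left, fr$left)
  expect_identical(out$right, fr$right)
})

test_that("unprocessed annotations leave pixels untouched", {
  fr <- blank_frame()
  raw <- annotation("r", "x", 1, 2, bounding_box(50, 50, 40, 30))
  out <- render_frame(fr, list(raw), viewer_settings())
  expect_identical(out$left, fr$left)
  expect_identical(out$right, fr$right)
  proc <- processed_ann()
  proc$state <- "processing"
  out2 <- render_frame(fr, list(proc), viewer_settings())
  expect_identical(out2$left, fr$left)
})

test_that("the right-eye rectangle is drawn shifted by minus the disparity", {
  fr <- blank_frame(t = 1) # at keyframe: box x=100, d=4
  out <- render_frame(fr, list(processed_ann()), viewer_settings())
  # left eye changed at the box border columns, right eye at x - d
  changed_l <- which(colSums(out$left != fr$left) > 0)
  changed_r <- which(colSums(out$right != fr$right) > 0)
  expect_equal(min(changed_l), 100 + 1) # 0-based box x -> 1-based column
  expect_equal(min(changed_r), 96 + 1)
})

test_that("rendered disparity is recoverable from the pixels", {
  sc <- small_scene(duration = 2)
  ann <- annotation("a", "CYST", 0, 2, bounding_box(40, 60, 44, 36))
  pa <- process_annotation(sc$video, ann, processing_config(search_margin = 16))
  for (t in c(0.5, 1, 1.7)) {
    fr <- read_stereo_frame(sc$video, round(t * 25))
    out <- render_frame(fr, list(pa), viewer_settings())
    at <- interpolate_annotation(pa, fr$time)
    est <- estimate_disparity(out, at$box)
    expect_lt(abs(est$disparity - at$disparity), 1)
  }
})

test_that("pointer, disparity offset and zoom transform the eyes as documented", {
  fr <- blank_frame()
  # pointer drawn in both eyes at the same x (screen plane)
  out <- render_frame(fr, list(), viewer_settings(pointer = c(160, 90)))
  expect_false(identical(out$left, fr$left))
  expect_false(identical(out$right, fr$right))
  expect_equal(which(colSums(out$left != fr$left) > 0),
               which(colSums(out$right != fr$right) > 0))
  # symmetric disparity offset: left shifts +off/2, right -off/2
  off <- render_frame(fr, list(), viewer_settings(disparity_offset = 8))
  expect_equal(off$left[50, 20 + 1:100], fr$left[50, 16 + 1:100])
  expect_equal(off$right[50, 20 + 1:100], fr$right[50, 24 + 1:100])
  # zoom 2 about the center magnifies: center pixel unchanged
  zm <- render_frame(fr, list(), viewer_settings(zoom = 2))
  expect_equal(dim(zm$left), dim(fr$left))
  expect_error(viewer_settings(zoom = 0), class = "stereoannot_bad_zoom")
})

test_that("speed decimation keeps every s-th frame and rejects other speeds", {
  frames <- lapply(1:16, function(i) matrix(i / 16, 4, 8))
  v <- stereo_video_mem(frames, 4)
  iv <- intervention("iv", status = "published")
  expect_equal(length(playback_frame_indices(v, iv, "full", 1)), 16)
  expect_equal(playback_frame_indices(v, iv, "full", 2), seq(0, 15, 2))
  expect_equal(playback_frame_indices(v, iv, "full", 8), c(0, 8))
  expect_error(playback_frame_indices(v, iv, "full", 3),
               class = "stereoannot_bad_speed")
  rep <- render_video(v, iv, "full", speed = 2)
  expect_equal(rep$frames_written, 8)
})

test_that("sections-only rendering emits exactly the union's frames", {
  frames <- lapply(1:40, function(i) matrix(i / 40, 4, 8))
  v <- stereo_video_mem(frames, 10) # 4 s
  iv <- intervention("iv", status = "published",
                     sections = list(section("a", 0.5, 1.0),
                                     section("b", 0.8, 1.5),
                                     section("c", 3.0, 3.4)))
  ivals <- compact_sections(iv$sections, 4)
  want <- sum(round((ivals$end - ivals$start) * 10))
  rep <- render_video(v, iv, "sections", 1)
  expect_equal(rep$frames_written, want)
  # frames come in chronological order with the gap skipped
  idx <- playback_frame_indices(v, iv, "sections", 1)
  expect_true(all(diff(idx) > 0))
  expect_false(any(idx %in% 20:29))
})

test_that("student-facing rendering rejects drafts", {
  frames <- lapply(1:4, function(i) matrix(0.5, 4, 8))
  v <- stereo_video_mem(frames, 4)
  iv <- intervention("iv", status = "draft")
  expect_error(render_video(v, iv, "full", 1),
               class = "stereoannot_draft_intervention")
  expect_silent(render_video(v, iv, "full", 1, audience = "teacher"))
})

test_that("rendered output round-trips through the frame store deterministically", {
  sc <- small_scene(duration = 1)
  ann <- annotation("a", "X", 0, 1, bounding_box(40, 60, 44, 36))
  pa <- process_annotation(sc$video, ann, processing_config(search_margin = 16))
  iv <- intervention("iv", status = "published", annotations = list(pa))
  dir <- withr::local_tempdir()
  r1 <- render_video(sc$video, iv, "full", 1, out_path = file.path(dir, "a"))
  r2 <- render_video(sc$video, iv, "full", 1, out_path = file.path(dir, "b"))
  for (i in c(0, 10, 24))
    expect_identical(read_composite(r1$video, i), read_composite(r2$video, i))
})
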