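test_that("keyframe schedules cover the span with spacing at most dt", {
  expect_equal(schedule_keyframes(10, 12, 0.5), c(10, 10.5, 11, 11.5, 12))
  expect_equal(schedule_keyframes(0, 1, 0.3), c(0, 0.3, 0.6, 0.9, 1))
  expect_equal(schedule_keyframes(5, 5.2, 0.5), c(5, 5.2))
  expect_error(schedule_keyframes(5, 4, 0.5), class = "stereoannot_bad_span")
  expect_error(schedule_keyframes(0, 1, 0), class = "stereoannot_bad_interval")
  # property: count and spacing over random spans
  set.seed(12)
  for (i in 1:50) {
    t0 <- runif(1, 0, 100); len <- runif(1, 0.05, 20); dt <- runif(1, 0.1, 1)
    ts <- schedule_keyframes(t0, t0 + len, dt)
    expect_true(all(diff(ts) > 0))
    expect_true(all(diff(ts) <= dt + 1e-9))
    expect_equal(ts[1], t0)
    expect_equal(ts[length(ts)], t0 + len)
    if (abs(len / dt - round(len / dt)) > 1e-6)
      expect_equal(length(ts), ceiling(len / dt) + 1)
  }
})

test_that("disparity estimation is exact on integer shifts and close on fractional", {
  for (d in c(-60, -12, 0, 7, 33, 101)) {
    fr <- shift_probe_frame(d)
    est <- estimate_disparity(fr, bounding_box(260, 30, 40, 40))
    expect_equal(est$disparity, d)
    expect_gt(est$score, 0.95)
  }
  for (d in c(-20.5, -3.3, 5.25, 12.4, 40.75)) {
    fr <- shift_probe_frame(d)
    est <- estimate_disparity(fr, bounding_box(260, 30, 40, 40))
    expect_lt(abs(est$disparity - d), 0.25)
  }
  # identical eyes: zero shift, near-perfect score
  fr <- shift_probe_frame(0)
  fr$right <- fr$left
  est <- estimate_disparity(fr, bounding_box(260, 30, 40, 40))
  expect_equal(est$disparity, 0)
  expect_gt(est$score, 0.99)
})

test_that("integer-stage estimate matches an exhaustive R-side NCC oracle", {
  fr <- shift_probe_frame(23)
  gl <- fr$left; gr <- fr$right
  b <- c(260, 30, 40, 40)
  templ <- gl[b[2] + 1:b[4], b[1] + 1:b[3]]
  # brute-force NCC over all shifts, plain R
  shifts <- -128:128
  scores <- vapply(shifts, function(s) {
    x <- b[1] - s
    if (x < 0 || x + b[3] > ncol(gr)) return(NA_real_)
    patch <- gr[b[2] + 1:b[4], x + 1:b[3]]
    suppressWarnings(stats::cor(as.vector(templ), as.vector(patch)))
  }, numeric(1))
  oracle_d <- shifts[which.max(scores)]
  est <- estimate_disparity(fr, bounding_box(260, 30, 40, 40),
                            processing_config(subpixel = FALSE))
  expect_equal(est$disparity, oracle_d)
  expect_equal(oracle_d, 23)
})

test_that("degenerate patches and clamped boxes are signalled", {
  fr <- shift_probe_frame(5)
  fr$left[, ] <- 0.5; fr$right[, ] <- 0.5
  est <- estimate_disparity(fr, bounding_box(100, 20, 30, 30))
  expect_true(is.na(est$disparity))
  expect_equal(est$score, 0)
  fr2 <- shift_probe_frame(5)
  expect_warning(estimate_disparity(fr2, bounding_box(-10, 30, 50, 40)),
                 "clamped")
})

test_that("disparity maintenance removes outliers and respects the jump limit", {
  cfg <- processing_config(max_disparity_jump = 10)
  expect_equal(maintain_disparity(c(10, 10, 55, 10, 10), config = cfg),
               c(10, 10, 10, 10, 10))
  expect_equal(maintain_disparity(rep(7, 9), config = cfg), rep(7, 9))
  # low-score keyframes inherit interpolated disparity
  sm <- maintain_disparity(c(4, 99, 8), scores = c(1, 0.1, 1), config = cfg)
  expect_equal(sm[2], 6)
  # single keyframe passes through
  expect_equal(maintain_disparity(5, config = cfg), 5)
})

test_that("disparity maintenance matches a direct reference and never raises the max jump", {
  ref_pipeline <- function(d, lim) {
    n <- length(d)
    max_in <- if (n > 1) max(abs(diff(d))) else 0
    if (n >= 3) {
      dm <- d
      for (i in 2:(n - 1)) dm[i] <- sort(d[(i - 1):(i + 1)])[2]
      d <- dm
    }
    cap <- max(min(lim, max_in), 1e-9)
    for (i in seq_len(n)[-1]) {
      s <- d[i] - d[i - 1]
      if (abs(s) > cap) d[i] <- d[i - 1] + sign(s) * cap
    }
    d
  }
  set.seed(5)
  for (rep in 1:40) {
    n <- sample(3:40, 1)
    d <- cumsum(runif(n, -8, 8))
    cfg <- processing_config(max_disparity_jump = 10)
    got <- maintain_disparity(d, config = cfg)
    expect_equal(got, ref_pipeline(d, 10))
    if (n > 1)
      expect_lte(max(abs(diff(got))), max(abs(diff(d))) + 1e-9)
  }
})

test_that("a static patch tracks to constant boxes at every scheduled keyframe", {
  sc <- small_scene(duration = 4,
                    trajectory = list(type = "static", at = c(100, 80)),
                    drift = c(0, 0))
  ann <- annotation("a", "Static", 0, 4, bounding_box(100, 80, 44, 36))
  tr <- track_annotation(sc$video, ann, processing_config(search_margin = 16))
  expect_equal(nrow(tr), 9) # 4 s span at 0.5 s spacing
  expect_true(all(tr$x == 100 & tr$y == 80))
  expect_false(any(tr$flagged))
})

test_that("moving patches are tracked with high IoU against ground truth", {
  sc <- small_scene(duration = 3)
  ann <- annotation("a", "Cyst", 0, 3, bounding_box(40, 60, 44, 36))
  pa <- process_annotation(sc$video, ann, processing_config(search_margin = 16))
  expect_equal(pa$state, "processed")
  m <- evaluate_against_truth(intervention("iv", annotations = list(pa)),
                              sc$truth, patch_map = c(a = "p"))
  expect_gte(m$mean_iou, 0.7)
  expect_lte(m$disparity_mae, 1)
})

test_that("full occlusion flags keyframes and holds the last good box", {
  sc <- small_scene(duration = 4,
                    trajectory = list(type = "static", at = c(100, 80)),
                    drift = c(0, 0),
                    occluders = list(list(t_start = 1.6, t_end = 2.6,
                                          region = c(80, 60, 90, 80))))
  ann <- annotation("a", "Occluded", 0, 4, bounding_box(100, 80, 44, 36))
  pa <- process_annotation(sc$video, ann, processing_config(search_margin = 16))
  flags <- vapply(pa$keyframes, `[[`, logical(1), "low_confidence")
  expect_gte(sum(flags), 1)
  m <- evaluate_against_truth(intervention("iv", annotations = list(pa)),
                              sc$truth, patch_map = c(a = "p"))
  expect_gte(m$mean_iou, 0.5) # unflagged keyframes still on target
})

test_that("an occlusion longer than the failure budget truncates the annotation", {
  sc <- small_scene(duration = 7,
                    trajectory = list(type = "static", at = c(100, 80)),
                    drift = c(0, 0),
                    occluders = list(list(t_start = 1.8, t_end = 6.9,
                                          region = c(80, 60, 90, 80))))
  ann <- annotation("a", "Lost", 0, 7, bounding_box(100, 80, 44, 36))
  pa <- process_annotation(sc$video, ann, processing_config(search_margin = 16))
  expect_lt(pa$t_end, 7)
  expect_match(attr(pa, "log"), "truncated")
  last <- pa$keyframes[[length(pa$keyframes)]]
  expect_false(last$low_confidence)
})

test_that("processing is deterministic, idempotent, and caches unchanged inputs", {
  sc <- small_scene(duration = 2)
  ann <- annotation("a", "Cyst", 0, 2, bounding_box(40, 60, 44, 36))
  cfg <- processing_config(search_margin = 16)
  p1 <- process_annotation(sc$video, ann, cfg)
  p2 <- process_annotation(sc$video, ann, cfg)
  expect_identical(save_intervention(intervention("i", annotations = list(p1))),
                   save_intervention(intervention("i", annotations = list(p2))))
  # reprocessing the processed annotation with unchanged inputs is a no-op
  t0 <- Sys.time()
  p3 <- process_annotation(sc$video, p1, cfg)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 0.1)
  expect_identical(p3$keyframes, p1$keyframes)
  # first/last keyframes at the span ends
  kt <- vapply(p1$keyframes, `[[`, numeric(1), "time")
  expect_equal(kt[1], 0)
  expect_equal(kt[length(kt)], 2)
})

test_that("bad annotation geometry is rejected before tracking", {
  sc <- small_scene(duration = 1)
  cfg <- processing_config(search_margin = 16)
  out <- annotation("a", "x", 0, 1, bounding_box(300, 170, 44, 36))
  expect_error(track_annotation(sc$video, out, cfg), class = "stereoannot_bad_box")
  long <- annotation("a", "x", 0, 5, bounding_box(40, 60, 44, 36))
  expect_error(track_annotation(sc$video, long, cfg), class = "stereoannot_bad_span")
  expect_error(
    track_annotation(sc$video, annotation("a", "x", 0, 1, bounding_box(40, 60, 44, 36)),
                     processing_config(tracker = "csrt")),
    class = "stereoannot_tracker_unavailable")
})

test_that("the job registry honors the asynchronous contract", {
  sc <- small_scene(duration = 1)
  iv <- intervention("iv", annotations = list(
    annotation("a1", "Cyst", 0, 1, bounding_box(40, 60, 44, 36))))
  reg <- job_registry(sc$video, iv, processing_config(search_margin = 16))
  # poll before submit never blocks and reports queued
  expect_equal(poll_job(reg, "a1")$state, "queued")
  job <- submit_job(reg, "a1")
  expect_equal(job$state, "done")
  expect_equal(job$progress, 1)
  expect_equal(job$result$state, "processed")
  # resubmission is a no-op returning the live job
  job2 <- submit_job(reg, "a1")
  expect_identical(job2$result$keyframes, job$result$keyframes)
  # polls observe the terminal state
  expect_equal(poll_job(reg, "a1")$state, "done")
  expect_error(submit_job(reg, "nope"), class = "stereoannot_unknown_annotation")
  expect_error(poll_job(reg, "nope"), class = "stereoannot_unknown_annotation")
})
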