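make_iv <- function(status = "draft", n_sections = 2, n_annotations = 1) {
  secs <- lapply(seq_len(n_sections), function(i)
    section(paste("Section", i), 10 * i, 10 * i + 5, description = "step"))
  anns <- lapply(seq_len(n_annotations), function(i)
    annotation(paste0("m", i), paste("Mark", i), 5 * i, 5 * i + 3,
               bounding_box(10 * i, 20, 40, 30)))
  intervention("iv-1", date = "2023-01-15", specialty = "Thoracic Surgery",
               organ = "Mediastinum", technique = "Robotic resection",
               video_ref = "store", status = status,
               sections = secs[seq_len(n_sections)], annotations = anns)
}

test_that("intervention documents round-trip through canonical JSON", {
  iv <- make_iv(n_sections = 2, n_annotations = 2)
  txt <- save_intervention(iv)
  iv2 <- load_intervention(txt)
  expect_equal(iv2, iv, ignore_attr = TRUE)
  # canonicalization is a fixed point: save(load(save(x))) == save(x)
  expect_identical(save_intervention(iv2), txt)
  # empty intervention round-trips too
  empty <- intervention("iv-0")
  expect_equal(load_intervention(save_intervention(empty)), empty,
               ignore_attr = TRUE)
})

test_that("processed annotations round-trip with keyframes intact", {
  kfs <- list(keyframe(1, bounding_box(10, 20, 40, 30), 12.5, 0.9),
              keyframe(1.5, bounding_box(12, 21, 40, 30), 12, 0.4, TRUE),
              keyframe(2, bounding_box(14, 22, 40, 30), 11.5, 0.8))
  ann <- annotation("m1", "Cyst", 1, 2, bounding_box(10, 20, 40, 30),
                    state = "processed", keyframes = kfs)
  iv <- intervention("iv-k", annotations = list(ann))
  iv2 <- load_intervention(save_intervention(iv))
  expect_equal(iv2$annotations[[1]]$keyframes, kfs, ignore_attr = TRUE)
  expect_true(iv2$annotations[[1]]$keyframes[[2]]$low_confidence)
})

test_that("schema violations are reported with field paths", {
  iv <- make_iv()
  doc <- jsonlite::parse_json(save_intervention(iv))
  doc$marks[[1]]$t_end <- NULL
  err <- expect_error(validate_intervention(doc),
                      class = "stereoannot_invalid_document")
  expect_match(conditionMessage(err), "marks[1].t_end", fixed = TRUE)
  doc2 <- jsonlite::parse_json(save_intervention(iv))
  doc2$schema_version <- "9.9"
  expect_error(validate_intervention(doc2), "schema_version",
               class = "stereoannot_invalid_document")
  doc3 <- jsonlite::parse_json(save_intervention(iv))
  doc3$sections[[1]]$t_start <- 99; doc3$sections[[1]]$t_end <- 12
  err3 <- expect_error(validate_intervention(doc3),
                       class = "stereoannot_invalid_document")
  expect_match(conditionMessage(err3), "sections[1]", fixed = TRUE)
  # spans beyond the video duration are caught when a duration is known
  expect_gt(length(check_intervention(jsonlite::parse_json(save_intervention(iv)),
                                      duration = 12)), 0)
})

test_that("model constructors enforce their invariants", {
  expect_error(bounding_box(0, 0, 0, 5), class = "stereoannot_bad_box")
  expect_error(section("s", 5, 5), class = "stereoannot_bad_span")
  expect_error(annotation("a", "l", 2, 1, bounding_box(0, 0, 1, 1)),
               class = "stereoannot_bad_span")
  expect_error(keyframe(0, bounding_box(0, 0, 1, 1), 0, 1.2),
               class = "stereoannot_bad_keyframe")
  expect_error(annotation("a", "l", 0, 1, bounding_box(0, 0, 1, 1),
                          state = "processed"),
               class = "stereoannot_bad_keyframes")
  expect_error(intervention("iv", annotations = list(
    annotation("a", "l", 0, 1, bounding_box(0, 0, 1, 1)),
    annotation("a", "l2", 0, 1, bounding_box(0, 0, 1, 1)))),
    class = "stereoannot_dup_id")
})

test_that("timeline colors follow the processing state, sections are blue", {
  expect_equal(annotation_state_color("unprocessed"), "red")
  expect_equal(annotation_state_color("processing"), "yellow")
  expect_equal(annotation_state_color("processed"), "green")
  a <- annotation("a", "l", 0, 1, bounding_box(0, 0, 1, 1))
  expect_equal(annotation_state_color(a), "red")
  expect_equal(annotation_state_color(section("s", 0, 1)), "blue")
})

test_that("compact_sections merges, clips, sorts and is idempotent", {
  # overlapping spans merge into one interval
  out <- compact_sections(list(section("a", 0, 10), section("b", 5, 15)), 100)
  expect_equal(out, data.frame(start = 0, end = 15))
  # disjoint spans stay separate and sorted
  out2 <- compact_sections(list(section("b", 50, 60), section("a", 0, 10)), 100)
  expect_equal(out2$start, c(0, 50))
  # clipping to duration
  out3 <- compact_sections(list(section("a", 90, 200)), 100)
  expect_equal(out3, data.frame(start = 90, end = 100))
  # idempotence: compacting the output changes nothing
  set.seed(42)
  secs <- random_sections(12, 60)
  once <- compact_sections(secs, 60)
  again <- compact_sections(data.frame(t_start = once$start, t_end = once$end), 60)
  expect_equal(again, once)
  # empty input -> empty output
  expect_equal(nrow(compact_sections(list(), 10)), 0)
})

test_that("compact_sections agrees with the 1 ms grid-membership oracle", {
  set.seed(7)
  for (rep in 1:25) {
    secs <- random_sections(sample(1:20, 1), 30)
    got <- compact_sections(secs, 30)
    want <- grid_union(secs, 30)
    expect_equal(nrow(got), nrow(want))
    expect_true(all(abs(got$start - want$start) <= 2e-3))
    expect_true(all(abs(got$end - want$end) <= 2e-3))
    # total compacted duration equals the measure of the union
    expect_lt(abs(sum(got$end - got$start) - sum(want$end - want$start)), 4e-3 * nrow(got))
  }
})

test_that("map_compact_time is the strictly increasing piecewise offset map", {
  expect_equal(map_compact_time(30, data.frame(start = 100, end = 200)), 130)
  ivals <- data.frame(start = c(0, 50), end = c(10, 60))
  expect_equal(map_compact_time(15, ivals), 55)
  expect_error(map_compact_time(25, ivals), class = "stereoannot_bad_time")
  # property: monotone, lands inside some interval
  set.seed(9)
  secs <- random_sections(8, 40)
  ivals2 <- compact_sections(secs, 40)
  total <- sum(ivals2$end - ivals2$start)
  probes <- sort(runif(2000, 0, total - 1e-9))
  mapped <- map_compact_time(probes, ivals2)
  expect_true(all(diff(mapped) > 0))
  inside <- vapply(mapped, function(t)
    any(t >= ivals2$start - 1e-9 & t <= ivals2$end + 1e-9), logical(1))
  expect_true(all(inside))
})

test_that("student-facing operations reject drafts", {
  expect_error(require_published(make_iv("draft")),
               class = "stereoannot_draft_intervention")
  expect_silent(require_published(make_iv("published")))
})

test_that("keyframe CSV export has one row per keyframe", {
  kfs <- list(keyframe(1, bounding_box(10, 20, 40, 30), 12, 0.9),
              keyframe(2, bounding_box(14, 22, 40, 30), 11, 0.8))
  ann <- annotation("m1", "Cyst", 1, 2, bounding_box(10, 20, 40, 30),
                    state = "processed", keyframes = kfs)
  df <- export_keyframes_csv(intervention("iv", annotations = list(ann)))
  expect_equal(nrow(df), 2)
  expect_equal(df$disparity, c(12, 11))
  expect_named(df, c("mark", "time", "x", "y", "w", "h", "disparity",
                     "confidence", "low_confidence"))
})
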