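#' Intervention data model
#'
#' An intervention bundles the metadata of one recorded surgical procedure
#' (date, specialty, organ, technique, publication status), a reference to
#' its SBS video, a set of named sections (sub-intervals with teaching
#' value) and a set of annotations ("marks"): labeled bounding boxes with a
#' time span that are tracked through the video and, once processed, carry a
#' list of keyframes storing the left-eye box and the horizontal disparity
#' at sampled times. Documents serialize to a canonical, versioned JSON form
#' whose keys mirror the relational layout of the backing store (surgery,
#' section, mark, keyframe).
#'
#' @name model
NULL

.schema_version <- "1.0"
.states <- c("unprocessed", "processing", "processed")
.statuses <- c("draft", "published")

#' Bounding box
#'
#' 0-based pixel box `(x, y, w, h)` in left-eye coordinates with half-open
#' extents `[x, x+w) x [y, y+h)`.
#'
#' @param x,y top-left corner, pixels
#' @param w,h width/height, pixels (> 0)
#' @return a `bounding_box`
#' @export
bounding_box <- function(x, y, w, h) {
  if (w <= 0 || h <= 0) .abort("box width and height must be > 0", "bad_box")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h)),
            class = "bounding_box")
}

#' Clamp a box to a frame
#'
#' @param box a `bounding_box`
#' @param width,height frame dimensions in pixels
#' @return the box intersected with `[0, width) x [0, height)`
#' @export
clamp_box <- function(box, width, height) {
  x0 <- max(0, box$x); y0 <- max(0, box$y)
  x1 <- min(width, box$x + box$w); y1 <- min(height, box$y + box$h)
  if (x1 <= x0 || y1 <= y0)
    .abort("box lies entirely outside the frame", "bad_box")
  bounding_box(x0, y0, x1 - x0, y1 - y0)
}

#' Annotation keyframe
#'
#' @param time seconds from video start
#' @param box left-eye `bounding_box`
#' @param disparity signed horizontal disparity in pixels (d = x_left - x_right)
#' @param confidence match confidence in `[0, 1]`
#' @param low_confidence flag set when the tracker or matcher fell below the
#'   confidence threshold at this time
#' @return a `keyframe`
#' @export
keyframe <- function(time, box, disparity, confidence, low_confidence = FALSE) {
  if (confidence < 0 || confidence > 1)
    .abort("confidence must lie in [0, 1]", "bad_keyframe")
  structure(list(time = as.numeric(time), box = box,
                 disparity = as.numeric(disparity),
                 confidence = as.numeric(confidence),
                 low_confidence = isTRUE(low_confidence)),
            class = "keyframe")
}

#' Annotation ("mark")
#'
#' @param id unique identifier
#' @param label short text displayed with the bounding box
#' @param t_start,t_end time span in seconds, `t_start < t_end`
#' @param initial_box left-eye `bounding_box` at `t_start`
#' @param description optional longer text
#' @param update_interval keyframe spacing Delta-t in seconds; values between
#'   0.1 and 1.0 are reasonable, default 0.5
#' @param state one of `"unprocessed"`, `"processing"`, `"processed"`
#' @param keyframes list of `keyframe` (non-empty iff state is processed)
#' @return an `annotation`
#' @export
annotation <- function(id, label, t_start, t_end, initial_box,
                       description = NULL, update_interval = 0.5,
                       state = "unprocessed", keyframes = list()) {
  if (!state %in% .states)
    .abort(sprintf("unknown annotation state '%s'", state), "bad_state")
  if (t_start >= t_end) .abort("annotation requires t_start < t_end", "bad_span")
  if (update_interval <= 0) .abort("update_interval must be > 0", "bad_interval")
  a <- structure(list(id = as.character(id), label = as.character(label),
                      description = description,
                      t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                      update_interval = as.numeric(update_interval),
                      state = state, initial_box = initial_box,
                      keyframes = keyframes),
                 class = "annotation")
  .check_annotation_keyframes(a)
  a
}

.check_annotation_keyframes <- function(a, where = "annotation") {
  errs <- character()
  if (a$state == "processed") {
    if (!length(a$keyframes))
      errs <- c(errs, sprintf("%s.keyframes: processed annotation has no keyframes", where))
    else {
      tt <- vapply(a$keyframes, `[[`, numeric(1), "time")
      if (any(diff(tt) <= 0))
        errs <- c(errs, sprintf("%s.keyframes: times must be strictly increasing", where))
      if (abs(tt[1] - a$t_start) > 1e-6)
        errs <- c(errs, sprintf("%s.keyframes: first keyframe must sit at t_start", where))
      if (abs(tt[length(tt)] - a$t_end) > 1e-6)
        errs <- c(errs, sprintf("%s.keyframes: last keyframe must sit at t_end", where))
    }
  }
  if (length(errs)) .abort(paste(errs, collapse = "; "), "bad_keyframes")
  invisible(a)
}

#' Section
#'
#' A named sub-interval of the video with teaching value.
#'
#' @param name section name
#' @param t_start,t_end span in seconds, `0 <= t_start < t_end`
#' @param description optional text
#' @return a `section`
#' @export
section <- function(name, t_start, t_end, description = NULL) {
  if (t_start < 0 || t_start >= t_end)
    .abort("section requires 0 <= t_start < t_end", "bad_span")
  structure(list(name = as.character(name), description = description,
                 t_start = as.numeric(t_start), t_end = as.numeric(t_end)),
            class = "section")
}

#' Intervention
#'
#' @param id identifier
#' @param date ISO-8601 date of the procedure
#' @param specialty,organ,technique descriptive metadata
#' @param video_ref locator of the SBS video (frame-store directory)
#' @param status `"draft"` (hidden from students) or `"published"`
#' @param sections list of `section`
#' @param annotations list of `annotation`
#' @return an `intervention`
#' @export
intervention <- function(id, date = NA_character_, specialty = NA_character_,
                         organ = NA_character_, technique = NA_character_,
                         video_ref = NA_character_, status = "draft",
                         sections = list(), annotations = list()) {
  if (!status %in% .statuses)
    .abort(sprintf("unknown status '%s'", status), "bad_status")
  ids <- vapply(annotations, `[[`, character(1), "id")
  if (anyDuplicated(ids)) .abort("annotation ids must be unique", "dup_id")
  structure(list(id = as.character(id), date = date, specialty = specialty,
                 organ = organ, technique = technique, status = status,
                 video_ref = video_ref, sections = sections,
                 annotations = annotations),
            class = "intervention")
}

#' @export
print.intervention <- function(x, ...) {
  cat(sprintf("<intervention '%s'> %s, %d section(s), %d annotation(s)\n",
              x$id, x$status, length(x$sections), length(x$annotations)))
  invisible(x)
}

# ---- validation --------------------------------------------------------

.num_field <- function(node, path, field, errs) {
  v <- node[[field]]
  if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v))
    c(errs, sprintf("%s.%s: missing or non-numeric", path, field))
  else errs
}

#' Validate an intervention document
#'
#' Structural validation with field-path diagnostics. Returns a character
#' vector of problems (empty when valid); `validate_intervention()` raises a
#' classed error listing them instead.
#'
#' @param doc a named list as produced by [jsonlite::read_json()], or an
#'   `intervention` object
#' @param duration optional video duration in seconds; when supplied, all
#'   section/annotation spans must lie within `[0, duration]`
#' @return character vector of diagnostics, empty when the document is valid
#' @export
check_intervention <- function(doc, duration = NULL) {
  errs <- character()
  if (inherits(doc, "intervention")) doc <- .iv_to_doc(doc)
  if (!identical(doc$schema_version, .schema_version))
    errs <- c(errs, sprintf("schema_version: expected \"%s\", got %s",
                            .schema_version,
                            if (is.null(doc$schema_version)) "nothing"
                            else paste0('"', doc$schema_version, '"')))
  s <- doc$surgery
  if (is.null(s)) errs <- c(errs, "surgery: missing")
  else {
    if (is.null(s$id)) errs <- c(errs, "surgery.id: missing")
    if (is.null(s$status) || !s$status %in% .statuses)
      errs <- c(errs, "surgery.status: must be \"draft\" or \"published\"")
  }
  for (i in seq_along(doc$sections)) {
    p <- sprintf("sections[%d]", i)
    sec <- doc$sections[[i]]
    if (is.null(sec$name)) errs <- c(errs, paste0(p, ".name: missing"))
    errs <- .num_field(sec, p, "t_start", errs)
    errs <- .num_field(sec, p, "t_end", errs)
    if (is.numeric(sec$t_start) && is.numeric(sec$t_end)) {
      if (sec$t_start < 0 || sec$t_start >= sec$t_end)
        errs <- c(errs, paste0(p, ": requires 0 <= t_start < t_end"))
      if (!is.null(duration) && sec$t_end > duration + 1e-6)
        errs <- c(errs, sprintf("%s.t_end: exceeds video duration %g", p, duration))
    }
  }
  ids <- character()
  for (i in seq_along(doc$marks)) {
    p <- sprintf("marks[%d]", i)
    m <- doc$marks[[i]]
    if (is.null(m$id)) errs <- c(errs, paste0(p, ".id: missing"))
    else ids <- c(ids, m$id)
    if (is.null(m$label)) errs <- c(errs, paste0(p, ".label: missing"))
    errs <- .num_field(m, p, "t_start", errs)
    errs <- .num_field(m, p, "t_end", errs)
    if (is.numeric(m$t_start) && is.numeric(m$t_end) && m$t_start >= m$t_end)
      errs <- c(errs, paste0(p, ": requires t_start < t_end"))
    if (!is.null(duration) && is.numeric(m$t_end) && m$t_end > duration + 1e-6)
      errs <- c(errs, sprintf("%s.t_end: exceeds video duration %g", p, duration))
    if (is.null(m$state) || !m$state %in% .states)
      errs <- c(errs, paste0(p, ".state: must be unprocessed/processing/processed"))
    if (is.null(m$initial_box)) errs <- c(errs, paste0(p, ".initial_box: missing"))
    else for (f in c("x", "y", "w", "h"))
      errs <- .num_field(m$initial_box, paste0(p, ".initial_box"), f, errs)
    if (identical(m$state, "processed") && !length(m$keyframes))
      errs <- c(errs, paste0(p, ".keyframes: processed mark has no keyframes"))
    for (j in seq_along(m$keyframes)) {
      q <- sprintf("%s.keyframes[%d]", p, j)
      k <- m$keyframes[[j]]
      errs <- .num_field(k, q, "time", errs)
      errs <- .num_field(k, q, "disparity", errs)
      errs <- .num_field(k, q, "confidence", errs)
      if (is.numeric(k$confidence) && (k$confidence < 0 || k$confidence > 1))
        errs <- c(errs, paste0(q, ".confidence: outside [0, 1]"))
    }
  }
  if (anyDuplicated(ids)) errs <- c(errs, "marks: duplicate ids")
  errs
}

#' @rdname check_intervention
#' @export
validate_intervention <- function(doc, duration = NULL) {
  errs <- check_intervention(doc, duration)
  if (length(errs))
    .abort(paste0("invalid intervention document:\n  ",
                  paste(errs, collapse = "\n  ")), "invalid_document")
  invisible(TRUE)
}

# ---- JSON serialization ------------------------------------------------

.box_to_doc <- function(b) list(x = b$x, y = b$y, w = b$w, h = b$h)

.kf_to_doc <- function(k) {
  list(time = round(k$time, 3), box = .box_to_doc(k$box),
       disparity = round(k$disparity, 3),
       confidence = round(k$confidence, 4),
       low_confidence = k$low_confidence)
}

.iv_to_doc <- function(iv) {
  list(
    schema_version = .schema_version,
    surgery = list(id = iv$id, date = iv$date, specialty = iv$specialty,
                   organ = iv$organ, technique = iv$technique,
                   status = iv$status, video_ref = iv$video_ref),
    sections = lapply(iv$sections, function(s)
      list(name = s$name, description = s$description,
           t_start = round(s$t_start, 3), t_end = round(s$t_end, 3))),
    marks = lapply(iv$annotations, function(m)
      list(id = m$id, label = m$label, description = m$description,
           t_start = round(m$t_start, 3), t_end = round(m$t_end, 3),
           update_interval = round(m$update_interval, 3), state = m$state,
           initial_box = .box_to_doc(m$initial_box),
           keyframes = lapply(m$keyframes, .kf_to_doc))))
}

.doc_to_iv <- function(doc) {
  s <- doc$surgery
  secs <- lapply(doc$sections, function(x)
    section(x$name, x$t_start, x$t_end, description = x$description))
  anns <- lapply(doc$marks, function(m) {
    kfs <- lapply(m$keyframes, function(k)
      keyframe(k$time, bounding_box(k$box$x, k$box$y, k$box$w, k$box$h),
               k$disparity, k$confidence, isTRUE(k$low_confidence)))
    annotation(m$id, m$label, m$t_start, m$t_end,
               bounding_box(m$initial_box$x, m$initial_box$y,
                            m$initial_box$w, m$initial_box$h),
               description = m$description,
               update_interval = if (is.null(m$update_interval)) 0.5 else m$update_interval,
               state = m$state, keyframes = kfs)
  })
  intervention(s$id, date = s$date %||% NA_character_,
               specialty = s$specialty %||% NA_character_,
               organ = s$organ %||% NA_character_,
               technique = s$technique %||% NA_character_,
               video_ref = s$video_ref %||% NA_character_,
               status = s$status, sections = secs, annotations = anns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load / save intervention documents
#'
#' `save_intervention()` writes the canonical JSON form: fixed key order,
#' times rounded to millisecond precision, disparities to 1/1000 px,
#' confidences to 4 decimals, UTF-8, 2-space indentation. `load_intervention()`
#' validates before constructing the model, raising a classed error with
#' field-path diagnostics on schema violations. `load(save(x))` is the
#' identity on the model, and `save(load(save(x)))` is byte-identical to
#' `save(x)`.
#'
#' @param path file path; for `save_intervention`, `NULL` returns the JSON text
#' @param iv an `intervention`
#' @param duration optional duration (seconds) for span validation
#' @return `load_intervention`: an `intervention`; `save_intervention`: the
#'   path (or JSON text when `path` is `NULL`), invisibly
#' @export
load_intervention <- function(path, duration = NULL) {
  doc <- jsonlite::parse_json(
    if (file.exists(path)) paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                                 collapse = "\n") else path)
  validate_intervention(doc, duration)
  .doc_to_iv(doc)
}

#' @rdname load_intervention
#' @export
save_intervention <- function(iv, path = NULL) {
  txt <- jsonlite::toJSON(.iv_to_doc(iv), auto_unbox = TRUE, pretty = 2,
                          digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(txt)))
  writeLines(as.character(txt), path, useBytes = TRUE)
  invisible(path)
}

#' Timeline bar color of an annotation or section
#'
#' Annotations are shown red while unprocessed, yellow while processing and
#' green once processed; section bars are always blue.
#'
#' @param x an `annotation`, a state string, or a `section`
#' @return a color name
#' @export
annotation_state_color <- function(x) {
  if (inherits(x, "section")) return("blue")
  state <- if (inherits(x, "annotation")) x$state else as.character(x)
  switch(state,
         unprocessed = "red", processing = "yellow", processed = "green",
         .abort(sprintf("unknown annotation state '%s'", state), "bad_state"))
}

# ---- section timeline algebra ------------------------------------------

#' Merge section spans into disjoint playback intervals
#'
#' Sections-only playback shows just the union of the section spans, so a
#' procedure lasting hours can be watched in minutes. Spans are clipped to
#' `[0, duration]`, sorted, and overlapping or touching spans merged.
#'
#' @param sections list of `section` (or a data.frame with t_start/t_end)
#' @param duration video duration in seconds
#' @return data.frame with columns `start`, `end`: sorted, pairwise disjoint
#' @export
compact_sections <- function(sections, duration) {
  if (duration <= 0) .abort("duration must be > 0", "bad_span")
  if (is.data.frame(sections)) {
    s <- sections$t_start %||% sections$start
    e <- sections$t_end %||% sections$end
  } else {
    s <- vapply(sections, `[[`, numeric(1), "t_start")
    e <- vapply(sections, `[[`, numeric(1), "t_end")
  }
  s <- pmax(0, s); e <- pmin(duration, e)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  if (!length(s)) return(data.frame(start = numeric(), end = numeric()))
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  rs <- s[1]; re <- e[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= re + .t_eps) re <- max(re, e[i])
    else { out_s <- c(out_s, rs); out_e <- c(out_e, re); rs <- s[i]; re <- e[i] }
  }
  data.frame(start = c(out_s, rs), end = c(out_e, re))
}

#' Map compacted playback time back to source time
#'
#' Sections-only playback concatenates the compacted intervals; this is the
#' strictly increasing piecewise-linear map from a time on that compacted
#' axis to the corresponding time in the source video.
#'
#' @param t_compact time in seconds on the compacted axis, in
#'   `[0, total compacted length)`
#' @param intervals data.frame from [compact_sections()]
#' @return source time in seconds
#' @export
map_compact_time <- function(t_compact, intervals) {
  lens <- intervals$end - intervals$start
  total <- sum(lens)
  out <- vapply(t_compact, function(t) {
    if (t < 0 || t >= total + .t_eps)
      .abort(sprintf("compacted time %g outside [0, %g)", t, total), "bad_time")
    t <- min(t, total)
    acc <- 0
    for (i in seq_along(lens)) {
      if (t <= acc + lens[i] + .t_eps) return(intervals$start[i] + (t - acc))
      acc <- acc + lens[i]
    }
    intervals$end[length(lens)] # unreachable
  }, numeric(1))
  out
}

#' Export keyframes as CSV
#'
#' One row per keyframe: annotation id, time, box, disparity, confidence,
#' low-confidence flag.
#'
#' @param iv an `intervention`
#' @param path output CSV path, or `NULL` to return the data.frame
#' @return the data.frame, invisibly when written
#' @export
export_keyframes_csv <- function(iv, path = NULL) {
  rows <- do.call(rbind, lapply(iv$annotations, function(m) {
    if (!length(m$keyframes)) return(NULL)
    do.call(rbind, lapply(m$keyframes, function(k)
      data.frame(mark = m$id, time = k$time, x = k$box$x, y = k$box$y,
                 w = k$box$w, h = k$box$h, disparity = k$disparity,
                 confidence = k$confidence, low_confidence = k$low_confidence)))
  }))
  if (is.null(rows))
    rows <- data.frame(mark = character(), time = numeric(), x = numeric(),
                       y = numeric(), w = numeric(), h = numeric(),
                       disparity = numeric(), confidence = numeric(),
                       low_confidence = logical())
  if (is.null(path)) return(rows)
  write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}

#' Assert that an intervention is visible to students
#'
#' Student-facing operations (collaborative rooms, student rendering) accept
#' only published interventions; drafts are an authoring-side concept.
#'
#' @param iv an `intervention`
#' @return `iv`, invisibly
#' @export
require_published <- function(iv) {
  if (!identical(iv$status, "published"))
    .abort(sprintf("intervention '%s' is a draft; students only see published interventions",
                   iv$id), "draft_intervention")
  invisible(iv)
}
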