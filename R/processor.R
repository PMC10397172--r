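#' Annotation processing engine
#'
#' Processing an annotation turns a single user-drawn left-eye bounding box
#' into a list of keyframes covering the annotation's time span: the box is
#' tracked through the left-eye view frame by frame, sampled at the keyframe
#' schedule, the horizontal disparity of the tracked patch is measured
#' against the right eye at every keyframe by band-restricted block
#' matching, and the disparity track is smoothed so the virtual overlay sits
#' at a stable, correct depth.
#'
#' Disparity sign convention: `d = x_left - x_right` of matched content, so
#' content in front of the screen plane (closer to the cameras of a
#' converged rig) has larger d, and the right-eye overlay is drawn at
#' `x_left - d`. Set `disparity_sign = -1` in the config for sources using
#' the opposite convention.
#'
#' @name processor
NULL

#' Processing configuration
#'
#' @param update_interval keyframe spacing Delta-t in seconds; how often the
#'   tracker relocates the annotated element. Values between 0.1 s and 1 s
#'   are reasonable; default 0.5 s.
#' @param search_range maximum absolute horizontal disparity searched, pixels
#' @param confidence_threshold matches scoring below this are flagged low
#'   confidence and do not move the tracker
#' @param max_disparity_jump largest allowed disparity change between
#'   consecutive keyframes, pixels; larger jumps are clamped
#' @param max_consecutive_failures a run of more than this many consecutive
#'   low-confidence keyframes truncates the annotation at the last good one
#' @param subpixel refine the integer disparity peak by a parabolic fit
#' @param tracker `"ncc_template"` (the built-in discriminative template
#'   tracker) — `"csrt"` is accepted for forward compatibility but is not
#'   available in this build
#' @param disparity_sign +1 for `d = x_left - x_right` (default), -1 to flip
#' @param search_margin tracker search window half-size around the previous
#'   position, pixels
#' @return a `processing_config`
#' @export
processing_config <- function(update_interval = 0.5, search_range = 128,
                              confidence_threshold = 0.5,
                              max_disparity_jump = 10,
                              max_consecutive_failures = 5, subpixel = TRUE,
                              tracker = c("ncc_template", "csrt"),
                              disparity_sign = 1, search_margin = 32) {
  tracker <- match.arg(tracker)
  if (update_interval <= 0) .abort("update_interval must be > 0", "bad_interval")
  if (search_range < 1) .abort("search_range must be >= 1", "bad_config")
  if (!disparity_sign %in% c(-1, 1)) .abort("disparity_sign must be +-1", "bad_config")
  structure(list(update_interval = update_interval, search_range = search_range,
                 confidence_threshold = confidence_threshold,
                 max_disparity_jump = max_disparity_jump,
                 max_consecutive_failures = max_consecutive_failures,
                 subpixel = isTRUE(subpixel), tracker = tracker,
                 disparity_sign = disparity_sign, search_margin = search_margin),
            class = "processing_config")
}

#' Keyframe schedule
#'
#' Times `t_start, t_start + dt, ...` with `t_end` always included as the
#' final time, so the whole span is covered with spacing at most `dt`.
#'
#' @param t_start,t_end span in seconds, `t_start < t_end`
#' @param update_interval spacing `dt` in seconds (> 0)
#' @return strictly increasing numeric vector of times
#' @export
schedule_keyframes <- function(t_start, t_end, update_interval) {
  if (update_interval <= 0) .abort("update_interval must be > 0", "bad_interval")
  if (t_start >= t_end) .abort("requires t_start < t_end", "bad_span")
  k <- floor((t_end - t_start) / update_interval + .t_eps)
  times <- t_start + (0:k) * update_interval
  if (times[length(times)] >= t_end - .t_eps) times[length(times)] <- t_end
  else times <- c(times, t_end)
  times
}

# map peak correlation in [-1,1] to a confidence in [0,1]: negative
# correlations carry no match evidence and clip to 0; NA marks a
# degenerate (constant) patch
.score01 <- function(r) if (is.na(r)) 0 else max(r, 0)

# frame index nearest time t, clamped so t = duration maps to the last frame
.frame_at <- function(video, t) {
  min(max(as.integer(round(t * video$fps)), 0L), video$frame_count - 1L)
}

.int_box <- function(box, width, height) {
  b <- clamp_box(box, width, height)
  x0 <- floor(b$x); y0 <- floor(b$y)
  x1 <- ceiling(b$x + b$w); y1 <- ceiling(b$y + b$h)
  list(x = as.integer(x0), y = as.integer(y0),
       w = as.integer(min(x1, width) - x0), h = as.integer(min(y1, height) - y0))
}

.patch <- function(gray, ib) {
  gray[ib$y + seq_len(ib$h), ib$x + seq_len(ib$w), drop = FALSE]
}

# Interior matching region: boxes are drawn around an object, so pixels at
# the border often straddle the object/background boundary and carry a
# different disparity than the object itself. Eroding the border (10% of
# the short side, at most 3 px) before correlation keeps the match on the
# object, the same reason discriminative trackers weight down box edges.
.erode_box <- function(ib) {
  m <- min(3L, as.integer(floor(min(ib$w, ib$h) * 0.1)))
  if (m < 1L || ib$w - 2L * m < 4L || ib$h - 2L * m < 4L) return(ib)
  list(x = ib$x + m, y = ib$y + m, w = ib$w - 2L * m, h = ib$h - 2L * m)
}

#' Horizontal disparity of a left-eye box
#'
#' The left-eye patch under `left_box` is matched against the right-eye
#' image along the same row band, over horizontal shifts in
#' `[-search_range, +search_range]`, using zero-normalized cross-correlation.
#' The disparity is `d = x_left - x_right_best` (times `disparity_sign`);
#' with `subpixel` on, the integer peak is refined by re-matching on a
#' 1/8-pixel grid (bilinearly resampled right-eye patches) followed by a
#' parabolic fit on that grid. The match score is the peak correlation mapped to
#' `[0, 1]` (negative correlations clip to 0, carrying no match evidence);
#' a (near-)constant patch is degenerate and scores 0.
#'
#' @param frame a `stereo_frame`
#' @param left_box left-eye `bounding_box` (clamped to the frame if needed,
#'   with a warning)
#' @param config a [processing_config()]
#' @return list with `disparity` (pixels, `NA` when degenerate) and
#'   `score` in `[0, 1]`
#' @export
estimate_disparity <- function(frame, left_box,
                               config = processing_config()) {
  gl <- .to_gray(frame$left); gr <- .to_gray(frame$right)
  H <- nrow(gl); W <- ncol(gl)
  cb <- clamp_box(left_box, W, H)
  if (abs(cb$x - left_box$x) > 0 || abs(cb$y - left_box$y) > 0 ||
      abs(cb$w - left_box$w) > 0 || abs(cb$h - left_box$h) > 0)
    warning("box partially outside frame; clamped")
  ib <- .erode_box(.int_box(cb, W, H))
  templ <- .patch(gl, ib)
  # candidate right-eye x positions for the template's top-left corner
  x_lo <- max(0L, ib$x - as.integer(config$search_range))
  x_hi <- min(W - ib$w, ib$x + as.integer(config$search_range))
  if (x_lo > x_hi) .abort("search range leaves no candidate positions", "bad_config")
  scores <- ncc_search(gr, templ, x_lo, x_hi, ib$y, ib$y)[1, ]
  if (all(is.na(scores)))
    return(list(disparity = NA_real_, score = 0))
  i <- which.max(scores) # NAs never selected
  x_best <- x_lo + i - 1L
  frac <- 0
  # a (numerically) perfect peak is an exact integer match; refinement
  # could only perturb it
  if (config$subpixel && scores[i] < 1 - 1e-6) {
    # sample the correlation on a 1/8-px grid around the integer peak by
    # matching against bilinearly resampled right-eye patches, then apply
    # a parabolic fit on the fine grid; this avoids the quarter-pixel bias
    # a three-point parabola on integer scores suffers on textured patches
    tv <- as.vector(templ); tv <- tv - mean(tv)
    tnorm <- sqrt(sum(tv^2))
    step <- 1 / 8
    offs <- seq(-0.5, 0.5, by = step)
    fine <- vapply(offs, function(f) {
      x0 <- x_best + floor(f); fr <- f - floor(f)
      if (x0 < 0 || x0 + ib$w + 1 > ncol(gr)) return(NA_real_)
      p0 <- gr[ib$y + seq_len(ib$h), x0 + seq_len(ib$w), drop = FALSE]
      pf <- if (fr == 0) p0 else
        (1 - fr) * p0 + fr * gr[ib$y + seq_len(ib$h), x0 + 1 + seq_len(ib$w),
                                drop = FALSE]
      pv <- as.vector(pf); pv <- pv - mean(pv)
      den <- sqrt(sum(pv^2)) * tnorm
      if (den < 1e-12) NA_real_ else sum(pv * tv) / den
    }, numeric(1))
    if (!all(is.na(fine))) {
      j <- which.max(fine)
      frac <- offs[j]
      if (j > 1 && j < length(fine) && !is.na(fine[j - 1]) && !is.na(fine[j + 1])) {
        den <- fine[j - 1] - 2 * fine[j] + fine[j + 1]
        if (den < -1e-12)
          frac <- frac + step * max(-0.5, min(0.5,
                       0.5 * (fine[j - 1] - fine[j + 1]) / den))
      }
    }
  }
  d <- (ib$x - (x_best + frac)) * config$disparity_sign
  list(disparity = d, score = .score01(scores[i]))
}

#' Track an annotated element through the left-eye view
#'
#' A discriminative normalized cross-correlation template tracker: the
#' template is taken from the left eye at `t_start` under the annotation's
#' initial box and matched in a `search_margin`-pixel window around the
#' previous position on every frame of the span. Positions are sampled at
#' the keyframe schedule. When the match confidence falls below
#' `confidence_threshold` the last good box is held and the keyframe is
#' flagged; a run of more than `max_consecutive_failures` consecutive
#' flagged keyframes truncates the annotation at the last good keyframe.
#'
#' @param video a `stereo_video` covering the annotation span
#' @param ann an `annotation` with an initial box at `t_start`
#' @param config a [processing_config()]
#' @return data.frame with one row per scheduled keyframe: `time`, box
#'   (`x`, `y`, `w`, `h`), `confidence`, `flagged`; attribute `"log"` carries
#'   processing messages (e.g. truncation)
#' @export
track_annotation <- function(video, ann, config = processing_config()) {
  if (config$tracker == "csrt")
    .abort("the csrt tracker is not available in this build; use ncc_template",
           "tracker_unavailable")
  fps <- video$fps
  dur <- video$frame_count / fps
  if (ann$t_start < -.t_eps || ann$t_end > dur + .t_eps)
    .abort("annotation span outside video", "bad_span")
  f0 <- read_stereo_frame(video, .frame_at(video, ann$t_start))
  H <- nrow(.to_gray(f0$left)); W <- ncol(.to_gray(f0$left))
  b <- ann$initial_box
  if (b$x < 0 || b$y < 0 || b$x + b$w > W || b$y + b$h > H)
    .abort("initial box outside frame", "bad_box")
  ib <- .int_box(b, W, H)
  templ <- .patch(.to_gray(f0$left), ib)

  times <- schedule_keyframes(ann$t_start, ann$t_end, config$update_interval)
  kf_idx <- vapply(times, function(t) .frame_at(video, t), integer(1))
  i_start <- .frame_at(video, ann$t_start)
  i_end <- .frame_at(video, ann$t_end)
  m <- as.integer(config$search_margin)

  pos <- c(ib$x, ib$y) # current top-left, integer
  conf <- 1
  state_at <- vector("list", length(times))
  next_kf <- 1L
  for (idx in i_start:i_end) {
    if (idx > i_start) {
      gl <- .to_gray(read_stereo_frame(video, idx)$left)
      x0 <- max(0L, pos[1] - m); x1 <- min(W - ib$w, pos[1] + m)
      y0 <- max(0L, pos[2] - m); y1 <- min(H - ib$h, pos[2] + m)
      sc <- ncc_search(gl, templ, x0, x1, y0, y1)
      if (all(is.na(sc))) {
        conf <- 0
      } else {
        j <- which.max(sc)
        conf <- .score01(sc[j])
        if (conf >= config$confidence_threshold) {
          ij <- arrayInd(j, dim(sc))
          pos <- c(x0 + ij[2] - 1L, y0 + ij[1] - 1L)
        } # else: hold last good position
      }
    }
    while (next_kf <= length(kf_idx) && kf_idx[next_kf] == idx) {
      state_at[[next_kf]] <- list(pos = pos, conf = conf)
      next_kf <- next_kf + 1L
    }
  }
  # any keyframe indices collapsed by rounding inherit the nearest earlier state
  for (k in seq_along(state_at)) if (is.null(state_at[[k]])) state_at[[k]] <- state_at[[k - 1]]

  out <- data.frame(
    time = times,
    x = vapply(state_at, function(s) s$pos[1], numeric(1)),
    y = vapply(state_at, function(s) s$pos[2], numeric(1)),
    w = ib$w, h = ib$h,
    confidence = vapply(state_at, function(s) s$conf, numeric(1)))
  out$flagged <- out$confidence < config$confidence_threshold

  log <- character()
  r <- rle(out$flagged)
  if (any(r$values & r$lengths > config$max_consecutive_failures)) {
    run <- which(r$values & r$lengths > config$max_consecutive_failures)[1]
    cut <- if (run == 1) 0L else sum(r$lengths[seq_len(run - 1)])
    # truncate at the last good keyframe before the failure run
    while (cut > 0L && out$flagged[cut]) cut <- cut - 1L
    if (cut == 0L)
      .abort("tracking failed from the first keyframe on", "tracking_failed")
    log <- sprintf(
      "tracking lost after %d consecutive low-confidence keyframes; annotation truncated at t=%.3f s (%d of %d keyframes kept)",
      r$lengths[run], out$time[cut], cut, nrow(out))
    out <- out[seq_len(cut), , drop = FALSE]
  }
  attr(out, "log") <- log
  out
}

#' Smooth a disparity track
#'
#' Keeps the virtual annotation at a stable depth: a sliding median of
#' window 3 removes singleton outliers, keyframes whose match score fell
#' below the confidence threshold inherit linearly interpolated disparity
#' from their good neighbors, and any remaining jump larger than
#' `max_disparity_jump` between consecutive keyframes is clamped toward its
#' predecessor. Output length equals input length, and the maximum absolute
#' inter-keyframe jump never increases.
#'
#' @param disparities raw per-keyframe disparities (`NA` allowed for
#'   degenerate matches; treated as low score)
#' @param scores per-keyframe match scores in `[0, 1]` (default all good)
#' @param config a [processing_config()]
#' @return numeric vector of smoothed disparities, same length
#' @export
maintain_disparity <- function(disparities, scores = NULL,
                               config = processing_config()) {
  n <- length(disparities)
  if (n < 1) .abort("need at least one keyframe", "bad_input")
  if (is.null(scores)) scores <- rep(1, n)
  d <- as.numeric(disparities)
  good <- scores >= config$confidence_threshold & !is.na(d)
  if (!any(good)) return(rep(NA_real_, n))
  # low-score keyframes inherit interpolated disparity from good neighbors
  if (any(!good)) {
    gi <- which(good)
    d[!good] <- stats::approx(gi, d[gi], xout = which(!good), rule = 2)$y
  }
  max_jump_in <- if (n > 1) max(abs(diff(d))) else 0
  # sliding median, window 3, ends kept
  if (n >= 3) {
    dm <- d
    for (i in 2:(n - 1)) dm[i] <- median(d[(i - 1):(i + 1)])
    d <- dm
  }
  # clamp residual jumps toward the predecessor
  lim <- min(config$max_disparity_jump, max(max_jump_in, 0))
  if (n > 1) for (i in 2:n) {
    step <- d[i] - d[i - 1]
    cap <- max(lim, .t_eps)
    if (abs(step) > cap) d[i] <- d[i - 1] + sign(step) * cap
  }
  d
}

#' Process an annotation end to end
#'
#' Schedule, track, measure per-keyframe disparity, smooth, and attach the
#' resulting keyframes: state moves unprocessed -> processing -> processed.
#' The pipeline is deterministic for fixed inputs, and the result carries a
#' signature of its inputs so reprocessing with unchanged inputs returns the
#' stored keyframes without recomputation.
#'
#' @param video a `stereo_video`
#' @param ann an `annotation`
#' @param config a [processing_config()]; the annotation's own
#'   `update_interval` is used for the schedule
#' @return the processed `annotation` (state `"processed"`, keyframes filled,
#'   attribute `"log"` with processing messages)
#' @export
process_annotation <- function(video, ann, config = processing_config()) {
  sig <- rlang::hash(list(video[c("fps", "frame_count", "composite_width", "height")],
                          if (video$backend == "dir") video$path
                          else rlang::hash(video$frames[[1]]),
                          ann[c("id", "t_start", "t_end", "update_interval")],
                          ann$initial_box, unclass(config)))
  if (ann$state == "processed" && identical(attr(ann, "input_signature"), sig))
    return(ann)
  cfg <- config
  cfg$update_interval <- ann$update_interval
  ann$state <- "processing"
  ann$keyframes <- list()
  result <- tryCatch({
    tr <- track_annotation(video, ann, cfg)
    fps <- video$fps
    raw_d <- numeric(nrow(tr)); raw_s <- numeric(nrow(tr))
    for (i in seq_len(nrow(tr))) {
      fr <- read_stereo_frame(video, .frame_at(video, tr$time[i]))
      est <- estimate_disparity(fr, bounding_box(tr$x[i], tr$y[i], tr$w[i], tr$h[i]), cfg)
      raw_d[i] <- est$disparity; raw_s[i] <- est$score
    }
    sm <- maintain_disparity(raw_d, pmin(raw_s, tr$confidence), cfg)
    flagged <- tr$flagged | raw_s < cfg$confidence_threshold
    kfs <- lapply(seq_len(nrow(tr)), function(i)
      keyframe(tr$time[i], bounding_box(tr$x[i], tr$y[i], tr$w[i], tr$h[i]),
               sm[i], min(raw_s[i], tr$confidence[i]), flagged[i]))
    list(kfs = kfs, t_end = tr$time[nrow(tr)], log = attr(tr, "log"))
  }, error = function(e) e)
  if (inherits(result, "error")) {
    ann$state <- "unprocessed"
    attr(ann, "input_signature") <- NULL
    stop(result)
  }
  ann$t_end <- result$t_end # unchanged unless truncated
  ann$keyframes <- result$kfs
  ann$state <- "processed"
  attr(ann, "input_signature") <- sig
  attr(ann, "log") <- result$log
  ann
}

#' Process every annotation of an intervention
#'
#' @param video a `stereo_video`
#' @param iv an `intervention`
#' @param config a [processing_config()]
#' @return `iv` with all annotations processed
#' @export
process_intervention <- function(video, iv, config = processing_config()) {
  iv$annotations <- lapply(iv$annotations, function(a)
    process_annotation(video, a, config))
  iv
}

# ---- asynchronous job contract ------------------------------------------

#' Processing job registry
#'
#' Annotation processing is long-running, so the authoring front-end submits
#' jobs and polls for their state instead of blocking. The registry executes
#' jobs in-process while honoring that contract: jobs step through
#' queued -> running -> done (or failed), progress is monotone
#' non-decreasing, polling never blocks, and resubmitting an id already
#' known is a no-op returning the live job.
#'
#' @param video a `stereo_video`
#' @param iv an `intervention` whose annotations the registry can process
#' @param config a [processing_config()]
#' @return a `job_registry`
#' @export
job_registry <- function(video, iv, config = processing_config()) {
  reg <- new.env(parent = emptyenv())
  reg$video <- video
  reg$config <- config
  reg$annotations <- setNames(iv$annotations,
                              vapply(iv$annotations, `[[`, character(1), "id"))
  reg$jobs <- new.env(parent = emptyenv())
  class(reg) <- "job_registry"
  reg
}

#' @rdname job_registry
#' @param registry a `job_registry`
#' @param annotation_id id of an annotation known to the registry
#' @return `submit_job`/`poll_job`: a `processing_job` list with fields
#'   `annotation_id`, `state` (queued/running/done/failed), `progress` in
#'   `[0, 1]`, `log`, and `result` (the processed annotation when done)
#' @export
submit_job <- function(registry, annotation_id) {
  if (!annotation_id %in% names(registry$annotations))
    .abort(sprintf("unknown annotation id '%s'", annotation_id), "unknown_annotation")
  if (!is.null(registry$jobs[[annotation_id]]))
    return(registry$jobs[[annotation_id]])
  job <- list(annotation_id = annotation_id, state = "queued", progress = 0,
              log = character(), result = NULL)
  registry$jobs[[annotation_id]] <- job
  job$state <- "running"; job$progress <- 0.1
  registry$jobs[[annotation_id]] <- job
  res <- tryCatch(
    process_annotation(registry$video, registry$annotations[[annotation_id]],
                       registry$config),
    error = function(e) e)
  if (inherits(res, "error")) {
    job$state <- "failed"
    job$log <- c(job$log, conditionMessage(res))
  } else {
    job$state <- "done"; job$progress <- 1
    job$log <- c(job$log, attr(res, "log"))
    job$result <- res
  }
  registry$jobs[[annotation_id]] <- job
  job
}

#' @rdname job_registry
#' @export
poll_job <- function(registry, annotation_id) {
  job <- registry$jobs[[annotation_id]]
  if (is.null(job)) {
    if (!annotation_id %in% names(registry$annotations))
      .abort(sprintf("unknown annotation id '%s'", annotation_id), "unknown_annotation")
    return(list(annotation_id = annotation_id, state = "queued", progress = 0,
                log = character(), result = NULL))
  }
  job
}
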