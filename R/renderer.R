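#' Stereoscopic rendering of annotated video
#'
#' Burns processed annotations into SBS output: each annotation is drawn as
#' a rectangle plus label text in the left eye at its (interpolated) box and
#' in the right eye at the box shifted horizontally by `-d`, so the overlay
#' is perceived at the depth of the annotated tissue. Also implements the
#' viewer comfort adjustments (global disparity offset, zoom), the shared
#' pointer, sections-only compaction and speed decimation.
#'
#' @name renderer
NULL

#' Viewer settings
#'
#' @param disparity_offset global signed disparity adjustment in pixels,
#'   split symmetrically between the eyes (left shifts by `+offset/2`,
#'   right by `-offset/2`) to preserve the cyclopean image center
#' @param zoom scale factor (> 0) about the eye center
#' @param pointer shared pointer as `c(x, y)` in left-eye coordinates, or
#'   `NULL` when hidden
#' @param pointer_disparity pointer depth in pixels; 0 places it at the
#'   screen plane
#' @return a `viewer_settings`
#' @export
viewer_settings <- function(disparity_offset = 0, zoom = 1, pointer = NULL,
                            pointer_disparity = 0) {
  if (zoom <= 0) .abort("zoom must be > 0", "bad_zoom")
  structure(list(disparity_offset = disparity_offset, zoom = zoom,
                 pointer = pointer, pointer_disparity = pointer_disparity),
            class = "viewer_settings")
}

#' Interpolate an annotation at a time
#'
#' At a keyframe time returns that keyframe exactly; between keyframes the
#' box center, size and disparity interpolate linearly; outside the
#' annotation's stored span the annotation is absent (`NULL`).
#'
#' @param ann a processed `annotation`
#' @param t time in seconds
#' @return list with `box` and `disparity`, or `NULL` when absent
#' @export
interpolate_annotation <- function(ann, t) {
  if (ann$state != "processed")
    .abort(sprintf("annotation '%s' is not processed", ann$id), "unprocessed")
  kfs <- ann$keyframes
  tt <- vapply(kfs, `[[`, numeric(1), "time")
  if (t < tt[1] - .t_eps || t > tt[length(tt)] + .t_eps) return(NULL)
  t <- min(max(t, tt[1]), tt[length(tt)])
  i <- findInterval(t, tt, rightmost.closed = TRUE)
  k0 <- kfs[[i]]
  if (i == length(kfs) || abs(tt[i] - t) < .t_eps)
    return(list(box = k0$box, disparity = k0$disparity))
  k1 <- kfs[[i + 1]]
  a <- (t - tt[i]) / (tt[i + 1] - tt[i])
  lerp <- function(u, v) (1 - a) * u + a * v
  cx <- lerp(k0$box$x + k0$box$w / 2, k1$box$x + k1$box$w / 2)
  cy <- lerp(k0$box$y + k0$box$h / 2, k1$box$y + k1$box$h / 2)
  w <- lerp(k0$box$w, k1$box$w); h <- lerp(k0$box$h, k1$box$h)
  list(box = bounding_box(cx - w / 2, cy - h / 2, w, h),
       disparity = lerp(k0$disparity, k1$disparity))
}

# ---- drawing primitives (0-based coordinates, clipped) -------------------

.draw_rect <- function(img, x, y, w, h, value, thickness = 2L) {
  H <- dim(img)[1]; W <- dim(img)[2]
  x0 <- round(x); y0 <- round(y); x1 <- round(x + w); y1 <- round(y + h)
  set_px <- function(img, ys, xs) {
    ys <- ys[ys >= 1 & ys <= H]; xs <- xs[xs >= 1 & xs <= W]
    if (!length(ys) || !length(xs)) return(img)
    if (length(dim(img)) == 2L) img[ys, xs] <- value
    else for (c in 1:3) img[ys, xs, c] <- value[min(c, length(value))]
    img
  }
  for (k in seq_len(thickness) - 1L) {
    xs <- (x0 + 1):(x1)
    img <- set_px(img, y0 + 1 + k, xs)        # top
    img <- set_px(img, y1 - k, xs)            # bottom
    ys <- (y0 + 1):(y1)
    img <- set_px(img, ys, x0 + 1 + k)        # left
    img <- set_px(img, ys, x1 - k)            # right
  }
  img
}

.draw_text <- function(img, text, x, y, value, scale = 1L) {
  bm <- .text_bitmap(text, scale)
  if (!ncol(bm)) return(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  for (r in seq_len(nrow(bm))) for (c in seq_len(ncol(bm))) {
    if (!bm[r, c]) next
    yy <- round(y) + r; xx <- round(x) + c
    if (yy < 1 || yy > H || xx < 1 || xx > W) next
    if (length(dim(img)) == 2L) img[yy, xx] <- value
    else img[yy, xx, ] <- value[pmin(1:3, length(value))]
  }
  img
}

.draw_disc <- function(img, x, y, radius, value) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ys <- max(1, floor(y - radius + 1)):min(H, ceiling(y + radius + 1))
  xs <- max(1, floor(x - radius + 1)):min(W, ceiling(x + radius + 1))
  for (yy in ys) for (xx in xs) {
    if ((yy - 1 - y)^2 + (xx - 1 - x)^2 > radius^2) next
    if (length(dim(img)) == 2L) img[yy, xx] <- value[1]
    else img[yy, xx, ] <- value[pmin(1:3, length(value))]
  }
  img
}

.shift_x <- function(img, dx) {
  dx <- as.integer(round(dx))
  if (dx == 0L) return(img)
  W <- dim(img)[2]
  out <- img; out[] <- 0
  src <- seq_len(W) - dx
  ok <- src >= 1 & src <= W
  if (!any(ok)) return(out)
  if (length(dim(img)) == 2L) out[, which(ok)] <- img[, src[ok]]
  else out[, which(ok), ] <- img[, src[ok], ]
  out
}

.zoom_eye <- function(img, zoom) {
  if (zoom == 1) return(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ys <- pmin(pmax(round(cy + (seq_len(H) - cy) / zoom), 1), H)
  xs <- pmin(pmax(round(cx + (seq_len(W) - cx) / zoom), 1), W)
  if (length(dim(img)) == 2L) img[ys, xs] else img[ys, xs, ]
}

#' Render annotations into one stereo frame
#'
#' Only processed annotations are drawn (unprocessed and in-progress marks
#' never reach rendered output); each is drawn in the left eye at its box
#' and in the right eye at the box shifted by `-d`. The shared pointer is
#' drawn in both eyes, at the screen plane unless a pointer disparity is
#' set. With no annotations, no pointer, zero offset and zoom 1 the frame
#' passes through unchanged.
#'
#' @param frame a `stereo_frame`
#' @param annotations list of `annotation`; each is interpolated at the
#'   frame's `time`
#' @param settings a [viewer_settings()]
#' @param color overlay intensity (grayscale frames) or RGB triple
#' @return the rendered `stereo_frame`
#' @export
render_frame <- function(frame, annotations = list(),
                         settings = viewer_settings(), color = 1) {
  left <- frame$left; right <- frame$right
  for (ann in annotations) {
    if (ann$state != "processed") next
    at <- interpolate_annotation(ann, frame$time)
    if (is.null(at)) next
    b <- at$box; d <- at$disparity
    left <- .draw_rect(left, b$x, b$y, b$w, b$h, color)
    right <- .draw_rect(right, b$x - d, b$y, b$w, b$h, color)
    ty <- b$y - 10
    left <- .draw_text(left, ann$label, b$x, ty, color)
    right <- .draw_text(right, ann$label, b$x - d, ty, color)
  }
  if (!is.null(settings$pointer)) {
    p <- settings$pointer; pd <- settings$pointer_disparity
    left <- .draw_disc(left, p[1], p[2], 5, c(1, 0.1, 0.1))
    right <- .draw_disc(right, p[1] - pd, p[2], 5, c(1, 0.1, 0.1))
  }
  if (settings$disparity_offset != 0) {
    left <- .shift_x(left, round(settings$disparity_offset / 2))
    right <- .shift_x(right, -round(settings$disparity_offset / 2))
  }
  if (settings$zoom != 1) {
    left <- .zoom_eye(left, settings$zoom)
    right <- .zoom_eye(right, settings$zoom)
  }
  structure(list(left = left, right = right, index = frame$index,
                 time = frame$time), class = "stereo_frame")
}

#' Frame indices selected by a playback mode and speed
#'
#' `mode = "full"` plays every frame; `mode = "sections"` plays exactly the
#' frames of the compacted section union in chronological order. Speed `s`
#' keeps every s-th frame of the selection at unchanged output fps.
#'
#' @param video a `stereo_video`
#' @param iv an `intervention` (for its sections)
#' @param mode `"full"` or `"sections"`
#' @param speed playback speed, one of 1, 2, 4, 8
#' @return integer vector of 0-based frame indices
#' @export
playback_frame_indices <- function(video, iv, mode = c("full", "sections"),
                                   speed = 1) {
  mode <- match.arg(mode)
  if (!speed %in% c(1, 2, 4, 8))
    .abort(sprintf("speed %g not supported; use 1, 2, 4 or 8", speed), "bad_speed")
  dur <- video$frame_count / video$fps
  if (mode == "full") {
    idx <- seq_len(video$frame_count) - 1L
  } else {
    ivals <- compact_sections(iv$sections, dur)
    idx <- integer()
    for (i in seq_len(nrow(ivals))) {
      i0 <- as.integer(ceiling(ivals$start[i] * video$fps - .t_eps))
      i1 <- as.integer(ceiling(ivals$end[i] * video$fps - .t_eps)) - 1L
      i1 <- min(i1, video$frame_count - 1L)
      if (i1 >= i0) idx <- c(idx, i0:i1)
    }
  }
  idx[seq(1, length(idx), by = speed)]
}

#' Render an intervention to an output SBS video
#'
#' @param video input `stereo_video`
#' @param iv an `intervention`; must be published unless
#'   `audience = "teacher"`
#' @param mode `"full"` or `"sections"` (sections-only compaction)
#' @param speed 1, 2, 4 or 8 (frame decimation at unchanged fps)
#' @param settings a [viewer_settings()]
#' @param out_path frame-store directory to write, or `NULL` to return an
#'   in-memory video
#' @param audience `"student"` (default; rejects drafts) or `"teacher"`
#' @param anaglyph write red-cyan anaglyph frames instead of SBS
#' @return a rendering report: list with `frames_written`,
#'   `annotations_drawn`, `mode`, `speed`, and `video` (the output handle)
#' @export
render_video <- function(video, iv, mode = c("full", "sections"), speed = 1,
                         settings = viewer_settings(), out_path = NULL,
                         audience = c("student", "teacher"),
                         anaglyph = FALSE) {
  mode <- match.arg(mode); audience <- match.arg(audience)
  if (audience == "student") require_published(iv)
  idx <- playback_frame_indices(video, iv, mode, speed)
  processed <- Filter(function(a) a$state == "processed", iv$annotations)
  drawn <- 0L
  frames <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    fr <- read_stereo_frame(video, idx[k])
    active <- Filter(function(a) !is.null(interpolate_annotation(a, fr$time)),
                     processed)
    drawn <- drawn + length(active)
    out <- render_frame(fr, active, settings)
    frames[[k]] <- if (anaglyph) make_anaglyph(out) else compose_sbs(out)
  }
  outv <- stereo_video_mem(frames, video$fps)
  if (!is.null(out_path)) {
    write_sbs_video(outv, out_path)
    outv <- open_sbs_video(out_path)
  }
  list(frames_written = length(idx), annotations_drawn = drawn,
       mode = mode, speed = speed, video = outv)
}
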