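#' Side-by-side stereoscopic video I/O
#'
#' A stereo video is a sequence of side-by-side (SBS) composite frames: the
#' left-eye image occupies columns `[0, W/2)` of the composite and the
#' right-eye image columns `[W/2, W)`. Frames are numeric arrays in `[0, 1]`,
#' either `H x W` (grayscale) or `H x W x 3` (RGB). Two backends share one
#' interface: an in-memory video ([stereo_video_mem()]) and an on-disk
#' lossless frame store ([write_sbs_video()] / [open_sbs_video()]), a
#' directory holding one PNG per frame plus a `meta.json` descriptor.
#'
#' All pixel coordinates in the package are 0-based with the origin at the
#' top-left corner, x growing rightward and y downward; boxes are
#' `(x, y, w, h)` with half-open extents `[x, x+w) x [y, y+h)`.
#'
#' @name stereo_io
NULL

.meta_name <- "meta.json"
.frame_fmt <- "frame_%06d.png"

.check_composite <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) < 2L)
    .abort("composite frame must be an H x W or H x W x 3 array", "bad_frame")
  if (d[2] %% 2L != 0L)
    .abort(sprintf("composite width %d is odd; not a valid SBS frame", d[2]),
           "odd_width")
  invisible(img)
}

#' Create an in-memory SBS stereo video
#'
#' @param frames list of composite SBS frames (all same dimensions, even width)
#' @param fps frames per second (> 0)
#' @return a `stereo_video` object
#' @export
stereo_video_mem <- function(frames, fps) {
  if (!length(frames)) .abort("video must contain at least one frame", "empty_video")
  if (!is.numeric(fps) || fps <= 0) .abort("fps must be > 0", "bad_fps")
  lapply(frames, .check_composite)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f)[1:2], d[1:2]), logical(1))
  if (!all(ok)) .abort("all frames must share the same dimensions", "bad_frame")
  structure(
    list(backend = "mem", frames = frames, fps = fps,
         frame_count = length(frames),
         composite_width = as.integer(d[2]), height = as.integer(d[1])),
    class = "stereo_video")
}

#' Write an SBS video to a lossless frame store
#'
#' Creates (or replaces) a directory containing `meta.json` and one PNG file
#' per composite frame. PNG is lossless, so a write/reopen round trip is
#' bit-exact at 8-bit depth.
#'
#' @param video a `stereo_video`, or a list of composite frames
#' @param path directory to create
#' @param fps frames per second (required when `video` is a plain list)
#' @return the path, invisibly
#' @export
write_sbs_video <- function(video, path, fps = NULL) {
  if (!inherits(video, "stereo_video")) video <- stereo_video_mem(video, fps)
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)
  for (i in seq_len(video$frame_count)) {
    png::writePNG(read_composite(video, i - 1L),
                  file.path(path, sprintf(.frame_fmt, i - 1L)))
  }
  meta <- list(format = "stereoannot-frames-v1", fps = video$fps,
               frame_count = video$frame_count,
               composite_width = video$composite_width, height = video$height)
  jsonlite::write_json(meta, file.path(path, .meta_name), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Open a side-by-side stereo video
#'
#' Opens a frame-store directory, validates its metadata (even composite
#' width, at least one frame, positive fps, first frame decodable and
#' consistent with the declared dimensions) and returns a handle giving
#' random access to any frame index.
#'
#' @param path frame-store directory
#' @return a `stereo_video` handle
#' @export
open_sbs_video <- function(path) {
  meta_path <- file.path(path, .meta_name)
  if (!dir.exists(path) || !file.exists(meta_path))
    .abort(sprintf("'%s' is not a readable stereo video (missing frame store)", path),
           "unreadable")
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                   error = function(e) .abort("corrupt video metadata", "unreadable"))
  need <- c("fps", "frame_count", "composite_width", "height")
  if (!all(need %in% names(meta))) .abort("corrupt video metadata", "unreadable")
  if (meta$frame_count < 1) .abort("video has zero frames", "empty_video")
  if (meta$fps <= 0) .abort("fps must be > 0", "bad_fps")
  if (meta$composite_width %% 2 != 0)
    .abort(sprintf("composite width %d is odd; not a valid SBS video",
                   meta$composite_width), "odd_width")
  f0 <- file.path(path, sprintf(.frame_fmt, 0L))
  img <- tryCatch(png::readPNG(f0),
                  error = function(e) .abort("first frame unreadable", "unreadable"))
  if (!identical(as.integer(dim(img)[1:2]),
                 as.integer(c(meta$height, meta$composite_width))))
    .abort("frame dimensions disagree with metadata", "unreadable")
  structure(
    list(backend = "dir", path = path, fps = meta$fps,
         frame_count = as.integer(meta$frame_count),
         composite_width = as.integer(meta$composite_width),
         height = as.integer(meta$height)),
    class = "stereo_video")
}

#' @export
print.stereo_video <- function(x, ...) {
  cat(sprintf("<stereo_video [%s]> %d frames @ %g fps, composite %dx%d (per eye %dx%d)\n",
              x$backend, x$frame_count, x$fps, x$composite_width, x$height,
              x$composite_width %/% 2L, x$height))
  invisible(x)
}

#' Read one composite frame
#'
#' @param video a `stereo_video`
#' @param index 0-based frame index
#' @return the composite frame array
#' @export
read_composite <- function(video, index) {
  index <- as.integer(index)
  if (index < 0L || index >= video$frame_count)
    .abort(sprintf("frame index %d out of range [0, %d)", index, video$frame_count),
           "bad_index")
  if (video$backend == "mem") {
    video$frames[[index + 1L]]
  } else {
    img <- png::readPNG(file.path(video$path, sprintf(.frame_fmt, index)))
    if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3] # drop alpha
    img
  }
}

#' Read one frame as a stereo pair
#'
#' @param video a `stereo_video`
#' @param index 0-based frame index
#' @return a `stereo_frame`: left/right eye images, index, time in seconds
#' @export
read_stereo_frame <- function(video, index) {
  sf <- split_frame(read_composite(video, index))
  sf$index <- as.integer(index)
  sf$time <- index / video$fps
  sf
}

#' Split an SBS composite into a stereo frame
#'
#' The left eye is columns `[0, W/2)`, the right eye `[W/2, W)`. No pixel is
#' modified; [compose_sbs()] is the exact inverse.
#'
#' @param composite SBS composite image (even width)
#' @return a `stereo_frame` with `left` and `right` images
#' @export
split_frame <- function(composite) {
  .check_composite(composite)
  w <- dim(composite)[2]
  half <- w %/% 2L
  if (length(dim(composite)) == 2L) {
    left <- composite[, seq_len(half), drop = FALSE]
    right <- composite[, half + seq_len(half), drop = FALSE]
  } else {
    left <- composite[, seq_len(half), , drop = FALSE]
    right <- composite[, half + seq_len(half), , drop = FALSE]
  }
  structure(list(left = left, right = right, index = NA_integer_, time = NA_real_),
            class = "stereo_frame")
}

#' Compose left/right eye images into an SBS composite
#'
#' @param left,right eye images of identical dimensions (or a `stereo_frame`
#'   as `left` with `right` missing)
#' @return the composite image, left eye first
#' @export
compose_sbs <- function(left, right) {
  if (inherits(left, "stereo_frame") && missing(right)) {
    right <- left$right
    left <- left$left
  }
  dl <- dim(left); dr <- dim(right)
  if (!identical(dl, dr))
    .abort("left and right eyes must have identical dimensions", "dim_mismatch")
  if (length(dl) == 2L) {
    out <- cbind(left, right)
  } else {
    out <- array(0, c(dl[1], 2L * dl[2], dl[3]))
    out[, seq_len(dl[2]), ] <- left
    out[, dl[2] + seq_len(dl[2]), ] <- right
  }
  out
}

#' Swap the two eyes of a composite frame
#'
#' For sources recorded right-eye-left. Involution: applying it twice is the
#' identity.
#'
#' @param composite SBS composite image
#' @return composite with the two halves exchanged
#' @export
swap_eyes <- function(composite) {
  sf <- split_frame(composite)
  compose_sbs(sf$right, sf$left)
}

.to_rgb <- function(img) {
  if (length(dim(img)) == 2L) {
    array(rep(img, 3L), c(dim(img), 3L))
  } else img
}

.to_gray <- function(img) {
  if (length(dim(img)) == 2L) img else (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

#' Red-cyan anaglyph of a stereo frame
#'
#' Routes the left eye to the red channel and the right eye to green and
#' blue, allowing depth inspection of SBS footage on an ordinary monitor
#' with red-cyan glasses.
#'
#' @param frame a `stereo_frame` (or an SBS composite, which is split first)
#' @return an `H x W_eye x 3` RGB image
#' @export
make_anaglyph <- function(frame) {
  if (!inherits(frame, "stereo_frame")) frame <- split_frame(frame)
  l <- .to_rgb(frame$left); r <- .to_rgb(frame$right)
  out <- array(0, dim(l))
  out[, , 1] <- l[, , 1]
  out[, , 2] <- r[, , 2]
  out[, , 3] <- r[, , 3]
  out
}

#' Probe a stereo video
#'
#' @param path frame-store directory
#' @return a one-row data.frame: fps, frame count, per-eye resolution, SBS validity
#' @export
probe_sbs_video <- function(path) {
  v <- open_sbs_video(path)
  data.frame(fps = v$fps, frame_count = v$frame_count,
             eye_width = v$composite_width %/% 2L, eye_height = v$height,
             sbs_valid = TRUE)
}
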