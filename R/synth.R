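#' Synthetic stereo scenes with ground truth
#'
#' Surgical stereo footage cannot be redistributed, so every stage of the
#' pipeline is exercised on generated side-by-side scenes instead: seeded
#' band-limited noise textures (smoothed random fields, guaranteeing
#' matchable non-degenerate patches), textured patches following known
#' trajectories with known disparity profiles, a drifting background with
#' its own constant disparity, optional occluders, and additive Gaussian
#' noise applied independently per eye. The right eye shows the same
#' content with each patch shifted by `-d(t)`, so ground-truth disparity
#' equals the applied offset by construction and estimator error is
#' measurable exactly.
#'
#' @name synth
NULL

# Band-limited texture: coarse seeded noise grid sampled bilinearly and
# periodically, so it is defined (and smooth) at any real coordinate.
.texture <- function(seed, cells = 24L, lo = 0.15, hi = 0.85) {
  rng <- .seeded_rng(seed)
  g <- matrix(rng(cells * cells), cells, cells)
  list(g = g * (hi - lo) + lo, n = cells)
}

# local RNG stream that leaves the global seed untouched
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  function(n, normal = FALSE) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    x <- if (normal) rnorm(n) else runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    x
  }
}

# Sample texture at real coordinates (vectors xs, ys in pixels) with
# bilinear interpolation on a periodic coarse grid; `scale` is pixels per
# texture cell.
.sample_texture <- function(tex, xs, ys, scale = 12) {
  n <- tex$n; g <- tex$g
  u <- xs / scale; v <- ys / scale
  u0 <- floor(u); v0 <- floor(v)
  fu <- u - u0; fv <- v - v0
  cu0 <- u0 %% n; rv0 <- v0 %% n
  cu1 <- cu0 + 1; cu1[cu1 == n] <- 0
  rv1 <- rv0 + 1; rv1[rv1 == n] <- 0
  # linear column-major indices into the n x n grid
  g[rv0 + cu0 * n + 1] * (1 - fu) * (1 - fv) +
    g[rv0 + cu1 * n + 1] * fu * (1 - fv) +
    g[rv1 + cu0 * n + 1] * (1 - fu) * fv +
    g[rv1 + cu1 * n + 1] * fu * fv
}

#' Scene specification
#'
#' @param duration seconds (> 0)
#' @param fps frames per second
#' @param eye_size per-eye `c(width, height)` in pixels
#' @param background list: `seed`, `drift` (`c(vx, vy)` px/s), `disparity`
#'   (constant background disparity, px), `scale` (texture cell size, px)
#' @param patches list of patch specs: `id`, `seed`, `size` (`c(w, h)` px),
#'   `trajectory` (see [traj_position()]), `disparity` (see
#'   [disparity_profile()]), `scale`
#' @param occluders list of `list(t_start, t_end, region = c(x, y, w, h))`;
#'   a flat gray rectangle drawn over both eyes during the interval
#' @param noise_sigma additive Gaussian noise sd on the 8-bit scale
#' @param seed master seed for the noise stream
#' @return a `scene_spec`
#' @export
scene_spec <- function(duration = 4, fps = 25, eye_size = c(320, 180),
                       background = list(seed = 1, drift = c(0, 0),
                                         disparity = 2, scale = 16),
                       patches = list(), occluders = list(),
                       noise_sigma = 0, seed = 0) {
  if (duration <= 0) .abort("duration must be > 0", "bad_spec")
  if (fps <= 0) .abort("fps must be > 0", "bad_spec")
  structure(list(duration = duration, fps = fps, eye_size = eye_size,
                 background = background, patches = patches,
                 occluders = occluders, noise_sigma = noise_sigma,
                 seed = seed),
            class = "scene_spec")
}

#' Patch trajectory position
#'
#' Supported trajectories: `list(type = "static", at = c(x, y))`,
#' `list(type = "linear", from = c(x, y), to = c(x, y))` (traversed over the
#' scene duration), and `list(type = "sinusoidal", center = c(x, y),
#' amplitude = c(ax, ay), period = seconds)`.
#'
#' @param traj trajectory spec
#' @param t time in seconds
#' @param duration scene duration in seconds
#' @return `c(x, y)` top-left position in pixels (may be fractional)
#' @export
traj_position <- function(traj, t, duration) {
  switch(traj$type,
    static = traj$at,
    linear = traj$from + (traj$to - traj$from) * (t / duration),
    sinusoidal = traj$center + traj$amplitude * sin(2 * pi * t / traj$period),
    .abort(sprintf("unknown trajectory type '%s'", traj$type), "bad_spec"))
}

#' Disparity profile value
#'
#' Supported profiles: `list(type = "constant", value = d)`,
#' `list(type = "linear", from = d0, to = d1)` and
#' `list(type = "sinusoidal", center = d, amplitude = a, period = s)`.
#'
#' @param prof profile spec
#' @param t time in seconds
#' @param duration scene duration in seconds
#' @return disparity in pixels
#' @export
disparity_profile <- function(prof, t, duration) {
  switch(prof$type,
    constant = prof$value,
    linear = prof$from + (prof$to - prof$from) * (t / duration),
    sinusoidal = prof$center + prof$amplitude * sin(2 * pi * t / prof$period),
    .abort(sprintf("unknown disparity profile '%s'", prof$type), "bad_spec"))
}

# draw one eye at time t; eye = "left" or "right"
.render_eye <- function(spec, t, eye, bg_tex, patch_texs) {
  W <- spec$eye_size[1]; H <- spec$eye_size[2]
  bg <- spec$background
  d_bg <- if (eye == "right") bg$disparity %||% 0 else 0
  # background coordinates are separable (pure translation), so bilinear
  # interpolation reduces to four row/column index gathers
  n <- bg_tex$n; g <- bg_tex$g; scl <- bg$scale %||% 16
  u <- ((seq_len(W) - 1) + bg$drift[1] * t + d_bg) / scl
  v <- ((seq_len(H) - 1) + bg$drift[2] * t) / scl
  u0 <- floor(u); fu <- u - u0; cu0 <- u0 %% n; cu1 <- (cu0 + 1) %% n
  v0 <- floor(v); fv <- v - v0; rv0 <- v0 %% n; rv1 <- (rv0 + 1) %% n
  wu1 <- rep(fu, each = H); wu0 <- 1 - wu1
  img <- (g[rv0 + 1, cu0 + 1] * (1 - fv) + g[rv1 + 1, cu0 + 1] * fv) * wu0 +
         (g[rv0 + 1, cu1 + 1] * (1 - fv) + g[rv1 + 1, cu1 + 1] * fv) * wu1
  for (pi in seq_along(spec$patches)) {
    p <- spec$patches[[pi]]
    pos <- traj_position(p$trajectory, t, spec$duration)
    d <- disparity_profile(p$disparity, t, spec$duration)
    px <- pos[1] - (if (eye == "right") d else 0)
    py <- pos[2]
    w <- p$size[1]; h <- p$size[2]
    # integer pixels inside the half-open extent [p, p+size)
    x0 <- max(0L, as.integer(ceiling(px - .t_eps)))
    x1 <- min(W - 1L, as.integer(ceiling(px + w - .t_eps)) - 1L)
    y0 <- max(0L, as.integer(ceiling(py - .t_eps)))
    y1 <- min(H - 1L, as.integer(ceiling(py + h - .t_eps)) - 1L)
    if (x1 < x0 || y1 < y0) next
    cols <- x0:x1; rows <- y0:y1
    vals <- matrix(.sample_texture(patch_texs[[pi]],
                                   rep(cols - px, each = length(rows)),
                                   rep(rows - py, length(cols)),
                                   p$scale %||% 8),
                   length(rows), length(cols))
    img[rows + 1, cols + 1] <- vals
  }
  for (oc in spec$occluders) {
    if (t < oc$t_start - .t_eps || t > oc$t_end + .t_eps) next
    r <- oc$region
    x0 <- max(1, round(r[1]) + 1); y0 <- max(1, round(r[2]) + 1)
    x1 <- min(W, round(r[1] + r[3])); y1 <- min(H, round(r[2] + r[4]))
    if (x1 >= x0 && y1 >= y0) img[y0:y1, x0:x1] <- 0.5
  }
  img
}

#' Generate a synthetic SBS scene with ground truth
#'
#' Fully determined by the spec (including its seed): the same spec yields
#' bit-identical output. Ground truth records, per frame and patch, the
#' left-eye box, the applied disparity, and whether an occluder covers the
#' patch center.
#'
#' @param spec a [scene_spec()]
#' @param out_dir frame-store directory to write, or `NULL` for an
#'   in-memory video
#' @return list with `video` (a `stereo_video`) and `truth` (data.frame:
#'   `frame`, `time`, `patch`, `x`, `y`, `w`, `h`, `disparity`, `occluded`)
#' @export
generate_scene <- function(spec, out_dir = NULL) {
  W <- spec$eye_size[1]; H <- spec$eye_size[2]
  n_frames <- as.integer(round(spec$duration * spec$fps))
  bg_tex <- .texture(spec$seed + 1000L * (spec$background$seed %||% 1))
  patch_texs <- lapply(seq_along(spec$patches), function(i)
    .texture(spec$seed + 2000L + 1000L * (spec$patches[[i]]$seed %||% i),
             cells = 16L, lo = 0, hi = 1))
  noise_rng <- .seeded_rng(spec$seed + 99L)

  truth <- vector("list", n_frames)
  # long scenes are streamed straight into the frame store rather than
  # accumulated in memory
  streaming <- !is.null(out_dir)
  if (streaming) {
    if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
    dir.create(out_dir, recursive = TRUE)
  }
  frames <- if (streaming) NULL else vector("list", n_frames)
  for (f in seq_len(n_frames) - 1L) {
    t <- f / spec$fps
    left <- .render_eye(spec, t, "left", bg_tex, patch_texs)
    right <- .render_eye(spec, t, "right", bg_tex, patch_texs)
    if (spec$noise_sigma > 0) {
      s <- spec$noise_sigma / 255
      left <- left + matrix(noise_rng(H * W, normal = TRUE) * s, H, W)
      right <- right + matrix(noise_rng(H * W, normal = TRUE) * s, H, W)
      left <- pmin(pmax(left, 0), 1)
      right <- pmin(pmax(right, 0), 1)
    }
    # quantize to 8 bits so in-memory and PNG round trips agree
    left <- round(left * 255) / 255
    right <- round(right * 255) / 255
    comp <- compose_sbs(left, right)
    if (streaming)
      png::writePNG(comp, file.path(out_dir, sprintf(.frame_fmt, f)))
    else frames[[f + 1L]] <- comp
    if (length(spec$patches)) {
      rows <- lapply(seq_along(spec$patches), function(pi) {
        p <- spec$patches[[pi]]
        pos <- traj_position(p$trajectory, t, spec$duration)
        d <- disparity_profile(p$disparity, t, spec$duration)
        cx <- pos[1] + p$size[1] / 2; cy <- pos[2] + p$size[2] / 2
        occ <- any(vapply(spec$occluders, function(oc) {
          r <- oc$region
          t >= oc$t_start - .t_eps && t <= oc$t_end + .t_eps &&
            cx >= r[1] && cx < r[1] + r[3] && cy >= r[2] && cy < r[2] + r[4]
        }, logical(1)))
        data.frame(frame = f, time = t, patch = p$id %||% as.character(pi),
                   x = pos[1], y = pos[2], w = p$size[1], h = p$size[2],
                   disparity = d, occluded = occ)
      })
      truth[[f + 1L]] <- do.call(rbind, rows)
    }
  }
  if (streaming) {
    meta <- list(format = "stereoannot-frames-v1", fps = spec$fps,
                 frame_count = n_frames, composite_width = 2L * W, height = H)
    jsonlite::write_json(meta, file.path(out_dir, .meta_name),
                         auto_unbox = TRUE, digits = NA)
    video <- open_sbs_video(out_dir)
  } else {
    video <- stereo_video_mem(frames, spec$fps)
  }
  truth <- if (length(spec$patches)) do.call(rbind, truth)
           else data.frame(frame = integer(), time = numeric(),
                           patch = character(), x = numeric(), y = numeric(),
                           w = numeric(), h = numeric(),
                           disparity = numeric(), occluded = logical())
  list(video = video, truth = truth)
}

#' Demo intervention: a synthetic mediastinal-cyst teaching video
#'
#' Builds a synthetic stand-in for the thoracic-surgery teaching video used
#' to evaluate the tool: a 30 s, 25 fps scene (640x360 per eye by default)
#' with three textured anatomical stand-in patches, wrapped in an
#' intervention carrying the four teaching sections ("Start of the surgical
#' procedure", "Opening of the mediastinal pleura", "Continuity with the
#' sympathetic chain", "Rib release") and three annotations ("Subclavian
#' artery", "Cyst", "Sympathetic chain"), each bound to one patch with full
#' ground truth.
#'
#' @param out_dir frame-store directory for the video, or `NULL` to keep it
#'   in memory
#' @param eye_size per-eye resolution; the default keeps processing at desk
#'   scale, a `c(1920, 1080)` profile mirrors full-HD sources
#' @param duration,fps scene timing
#' @param seed generator seed
#' @return list with `intervention`, `video`, `truth`, and `spec`
#' @export
make_demo_intervention <- function(out_dir = NULL, eye_size = c(640, 360),
                                   duration = 30, fps = 25, seed = 7) {
  sc <- eye_size[1] / 640 # scale layout to the requested resolution
  spec <- scene_spec(
    duration = duration, fps = fps, eye_size = eye_size,
    background = list(seed = 3, drift = c(1.5, 0.6) * sc, disparity = round(2 * sc),
                      scale = 24 * sc),
    patches = list(
      list(id = "subclavian-artery", seed = 11, size = round(c(70, 46) * sc),
           trajectory = list(type = "linear", from = c(60, 70) * sc,
                             to = c(210, 120) * sc),
           disparity = list(type = "constant", value = 14 * sc), scale = 9 * sc),
      list(id = "cyst", seed = 12, size = round(c(90, 78) * sc),
           trajectory = list(type = "sinusoidal", center = c(300, 150) * sc,
                             amplitude = c(36, 14) * sc, period = 11),
           disparity = list(type = "sinusoidal", center = 18 * sc,
                            amplitude = 4 * sc, period = 13), scale = 11 * sc),
      list(id = "sympathetic-chain", seed = 13, size = round(c(56, 40) * sc),
           trajectory = list(type = "linear", from = c(470, 240) * sc,
                             to = c(380, 190) * sc),
           disparity = list(type = "linear", from = 8 * sc, to = 16 * sc),
           scale = 8 * sc)),
    noise_sigma = 2, seed = seed)
  scene <- generate_scene(spec, out_dir)

  secs <- list(
    section("Start of the surgical procedure", 1, 6,
            "Beginning of the surgery after port placement and docking."),
    section("Opening of the mediastinal pleura", 8, 13,
            "The mediastinal pleura is incised over the cyst."),
    section("Continuity with the sympathetic chain", 15, 20,
            "The cyst appears to depend on the sympathetic chain."),
    section("Rib release", 22, 27,
            "Adhesions from the lower pole of the cyst to the rib are released."))

  mk_ann <- function(id, label, t0, t1, patch_id, descr) {
    tr <- scene$truth[scene$truth$patch == patch_id &
                        abs(scene$truth$time - t0) < 1e-6, ]
    annotation(id, label, t0, t1,
               bounding_box(round(tr$x), round(tr$y), tr$w, tr$h),
               description = descr)
  }
  anns <- list(
    mk_ann("mark-artery", "Subclavian artery", 2, 7, "subclavian-artery",
           "Large caliber artery; injury can cause massive bleeding."),
    mk_ann("mark-cyst", "Cyst", 10, 15, "cyst", "The target lesion."),
    mk_ann("mark-chain", "Sympathetic chain", 18, 24, "sympathetic-chain",
           "Injury at T1 risks Horner's syndrome."))

  iv <- intervention(
    "demo-mediastinal-cyst", date = "2023-01-15", specialty = "Thoracic Surgery",
    organ = "Mediastinum", technique = "Robotic resection of a mediastinal cyst",
    video_ref = if (is.null(out_dir)) "memory" else out_dir,
    status = "draft", sections = secs, annotations = anns)
  list(intervention = iv, video = scene$video, truth = scene$truth, spec = spec)
}

.box_iou <- function(x1, y1, w1, h1, x2, y2, w2, h2) {
  ix <- pmax(0, pmin(x1 + w1, x2 + w2) - pmax(x1, x2))
  iy <- pmax(0, pmin(y1 + h1, y2 + h2) - pmax(y1, y2))
  inter <- ix * iy
  inter / (w1 * h1 + w2 * h2 - inter)
}

#' Compare processed annotations with generator ground truth
#'
#' For each processed annotation, keyframe boxes and disparities are
#' compared with the ground-truth record of the frame nearest each keyframe
#' time. Keyframes flagged low-confidence are excluded from the IoU and
#' disparity errors (they are reported via `flagged_fraction`), as are
#' frames the ground truth marks occluded.
#'
#' @param iv a processed `intervention` whose annotation ids map to truth
#'   patch ids via `patch_map` (default: annotation order = patch order)
#' @param truth ground-truth data.frame from [generate_scene()]
#' @param patch_map named character vector: annotation id -> patch id
#' @return data.frame per annotation: `mark`, `mean_iou`, `disparity_mae`,
#'   `flagged_fraction`, `n_keyframes`
#' @export
evaluate_against_truth <- function(iv, truth, patch_map = NULL) {
  anns <- Filter(function(a) a$state == "processed", iv$annotations)
  if (is.null(patch_map)) {
    pids <- unique(truth$patch)
    if (length(pids) < length(anns))
      .abort("ground truth does not cover all annotations", "fixture_mismatch")
    patch_map <- setNames(pids[seq_along(anns)],
                          vapply(anns, `[[`, character(1), "id"))
  }
  rows <- lapply(anns, function(a) {
    pid <- patch_map[[a$id]]
    if (is.null(pid) || !pid %in% truth$patch)
      .abort(sprintf("no ground truth patch for annotation '%s'", a$id),
             "fixture_mismatch")
    tp <- truth[truth$patch == pid, ]
    ious <- numeric(); derr <- numeric(); flags <- 0L
    for (k in a$keyframes) {
      i <- which.min(abs(tp$time - k$time))
      if (k$low_confidence) { flags <- flags + 1L; next }
      if (tp$occluded[i]) next
      ious <- c(ious, .box_iou(k$box$x, k$box$y, k$box$w, k$box$h,
                               tp$x[i], tp$y[i], tp$w[i], tp$h[i]))
      derr <- c(derr, abs(k$disparity - tp$disparity[i]))
    }
    data.frame(mark = a$id,
               mean_iou = if (length(ious)) mean(ious) else NA_real_,
               disparity_mae = if (length(derr)) mean(derr) else NA_real_,
               flagged_fraction = flags / length(a$keyframes),
               n_keyframes = length(a$keyframes))
  })
  do.call(rbind, rows)
}
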