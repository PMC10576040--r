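# ---------------------------------------------------------------------------
# Synthetic barn-scene generator. Stands in for the (private) surveillance
# dataset: textured ground, dense multi-animal scenes of elliptical cow
# silhouettes at near/far scales, mounting events rendered as overlapping
# silhouette pairs labeled by the exact bounding box of the union of the
# two rendered masks, and day/night lighting regimes. Frames are grouped
# into synthetic "videos" that share a camera distance and lighting, so the
# video-level split protocol is meaningful.
# ---------------------------------------------------------------------------

#' Scene generator configuration
#'
#' Defaults emulate the source data regime: 2560 x 1440 frames, 6-18
#' animals, 1-3 mounting pairs, body length 5-16% of the frame width
#' (near/far camera), minimum silhouette overlap 0.35 for a mounting pair,
#' 30% night frames.
#'
#' @param canvas `(width, height)` in pixels
#' @param n_animals inclusive range of non-mounting animals per scene
#' @param mounting_pairs inclusive range of mounting pairs per scene
#' @param scale range of body length as a fraction of canvas width
#' @param overlap minimum pair silhouette overlap,
#'   `|A intersect B| / min(|A|, |B|)`
#' @param night_prob probability that a scene is a night frame
#' @return a `scene_config` list
#' @export
scene_config <- function(canvas = c(2560L, 1440L),
                         n_animals = c(6L, 18L),
                         mounting_pairs = c(1L, 3L),
                         scale = c(0.05, 0.16),
                         overlap = 0.35,
                         night_prob = 0.3) {
  stopifnot(length(canvas) == 2L, all(canvas >= 32L),
            overlap >= 0, overlap < 1)
  if (scale[1] * canvas[1] < 4)
    stop("canvas too small for the requested scale range")
  structure(list(canvas = as.integer(canvas),
                 n_animals = as.integer(n_animals),
                 mounting_pairs = as.integer(mounting_pairs),
                 scale = scale, overlap = overlap,
                 night_prob = night_prob),
            class = "scene_config")
}

# low-frequency noise field via bilinear upsampling of a coarse grid
noise_field <- function(H, W, coarse = 12L, amp = 1) {
  g <- array(runif(coarse * coarse, -amp, amp),
             c(coarse, coarse, 1L, 1L))
  array(cpp_resize_bilinear(g, H, W), c(H, W))
}

# local mask of a rotated ellipse; returns bounding indices and the mask
ellipse_mask <- function(H, W, cx, cy, a, b, phi) {
  ext <- sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
  eyt <- sqrt((a * sin(phi))^2 + (b * cos(phi))^2)
  j0 <- max(1L, floor(cx - ext)); j1 <- min(W, ceiling(cx + ext))
  i0 <- max(1L, floor(cy - eyt)); i1 <- min(H, ceiling(cy + eyt))
  if (j1 < j0 || i1 < i0) return(NULL)
  xs <- j0:j1; ys <- i0:i1
  dx <- matrix(rep(xs - cx, each = length(ys)), length(ys), length(xs))
  dy <- matrix(rep(ys - cy, times = length(xs)), length(ys), length(xs))
  u <- cos(phi) * dx + sin(phi) * dy
  v <- -sin(phi) * dx + cos(phi) * dy
  list(i0 = i0, i1 = i1, j0 = j0, j1 = j1,
       mask = (u / a)^2 + (v / b)^2 <= 1)
}

# paint a cow silhouette (body + head blob); returns the updated image and
# the combined mask (for label construction)
paint_cow <- function(img, cx, cy, a, phi, tone, want_mask = FALSE) {
  H <- dim(img)[1]; W <- dim(img)[2]
  b <- a * runif(1, 0.38, 0.5)
  col <- tone * runif(3, 0.9, 1.1)
  col <- pmin(pmax(col, 0), 1)
  parts <- list(ellipse_mask(H, W, cx, cy, a, b, phi))
  hx <- cx + (a * 1.05) * cos(phi)
  hy <- cy + (a * 1.05) * sin(phi)
  parts[[2]] <- ellipse_mask(H, W, hx, hy, a * 0.32, b * 0.55, phi)
  full <- if (want_mask) matrix(FALSE, H, W) else NULL
  for (pt in parts) {
    if (is.null(pt)) next
    mk <- pt$mask
    if (!any(mk)) next
    sub <- img[pt$i0:pt$i1, pt$j0:pt$j1, , drop = FALSE]
    patch <- noise_field(nrow(mk), ncol(mk), coarse = 4L, amp = 0.12)
    for (ch in 1:3) {
      pl <- sub[, , ch]
      pl[mk] <- pmin(pmax(col[ch] + patch[mk], 0), 1)
      sub[, , ch] <- pl
    }
    img[pt$i0:pt$i1, pt$j0:pt$j1, ] <- sub
    if (want_mask) {
      fm <- full[pt$i0:pt$i1, pt$j0:pt$j1]
      fm[mk] <- TRUE
      full[pt$i0:pt$i1, pt$j0:pt$j1] <- fm
    }
  }
  list(img = img, mask = full)
}

rand_tone <- function() {
  k <- sample.int(3L, 1L)
  if (k == 1L) runif(1, 0.06, 0.20)        # black
  else if (k == 2L) runif(1, 0.70, 0.90)   # white
  else runif(1, 0.28, 0.45)                # brown
}

#' Generate one synthetic barn scene
#'
#' Renders a textured background, `n_animals` single cow silhouettes and
#' `mounting_pairs` overlapping silhouette pairs; each pair contributes one
#' class-0 label box that exactly bounds the union of its two rendered
#' masks. Night scenes are darkened and desaturated. Deterministic for a
#' fixed RNG state.
#'
#' @param cfg a [scene_config()]
#' @param video_scale optional fixed camera-scale multiplier (shared by
#'   frames of one video); `NULL` draws one per scene
#' @param night optional fixed lighting flag; `NULL` draws from
#'   `cfg$night_prob`
#' @param source_video video identifier tag
#' @param keep_masks attach the rendered union mask of every mounting pair
#'   as attribute `pair_masks` (for auditing label tightness)
#' @return a [labeled_image()]
#' @export
generate_scene <- function(cfg = scene_config(), video_scale = NULL,
                           night = NULL, source_video = "v000",
                           keep_masks = FALSE) {
  W <- cfg$canvas[1]; H <- cfg$canvas[2]
  if (is.null(night)) night <- runif(1) < cfg$night_prob
  if (is.null(video_scale)) video_scale <- runif(1, 0.8, 1.25)

  base <- c(0.47, 0.42, 0.33) * runif(1, 0.85, 1.1)
  img <- array(0, c(H, W, 3L))
  coarse <- noise_field(H, W, coarse = 10L, amp = 0.06)
  fine <- array(runif(H * W, -0.02, 0.02), c(H, W))
  for (ch in 1:3) img[, , ch] <- pmin(pmax(base[ch] + coarse + fine, 0), 1)

  draw_len <- function() {
    runif(1, cfg$scale[1], cfg$scale[2]) * W * video_scale / 2
  }
  margin <- function(a) a * 1.6

  # Placed-animal bookkeeping. Only mounting pairs may overlap deeply:
  # a chance overlap of two non-mounting silhouettes would be visually
  # identical to a labeled event, i.e. an unlabeled positive, so single
  # animals are rejection-sampled to keep separation from everything
  # already placed (clutter and proximity remain, stacking does not).
  placed <- list()
  far_enough <- function(cx, cy, a) {
    for (q in placed) {
      if (sqrt((cx - q[1])^2 + (cy - q[2])^2) < 0.9 * (a + q[3]))
        return(FALSE)
    }
    TRUE
  }

  # mounting pairs first (they own their ground)
  npair <- if (cfg$mounting_pairs[2] > cfg$mounting_pairs[1])
    sample(cfg$mounting_pairs[1]:cfg$mounting_pairs[2], 1L)
    else cfg$mounting_pairs[1]
  boxes <- list()
  pair_masks <- list()
  for (p in seq_len(npair)) {
    a0 <- draw_len()
    cx0 <- runif(1, margin(a0), W - margin(a0))
    cy0 <- runif(1, margin(a0), H - margin(a0))
    for (try in 1:20) {
      if (far_enough(cx0, cy0, 2.2 * a0)) break
      cx0 <- runif(1, margin(a0), W - margin(a0))
      cy0 <- runif(1, margin(a0), H - margin(a0))
    }
    placed[[length(placed) + 1L]] <- c(cx0, cy0, 2.2 * a0)
    phi <- runif(1, 0, 2 * pi)
    t0 <- rand_tone()
    t1 <- rand_tone()
    if (abs(t1 - t0) < 0.2) t1 <- if (t0 < 0.5) t0 + 0.35 else t0 - 0.35
    for (try in 1:8) {
      delta <- a0 * runif(1, 0.45, 0.75) * (1 - 0.08 * try)
      dphi <- phi + runif(1, -0.35, 0.35)
      cx1 <- cx0 + delta * cos(dphi)
      cy1 <- cy0 + delta * sin(dphi)
      r0 <- paint_cow(img, cx0, cy0, a0, phi, t0, want_mask = TRUE)
      r1 <- paint_cow(r0$img, cx1, cy1, a0 * 0.82, phi + runif(1, -0.2, 0.2),
                      t1, want_mask = TRUE)
      ov <- sum(r0$mask & r1$mask) / max(1L, min(sum(r0$mask), sum(r1$mask)))
      if (ov >= cfg$overlap || try == 8L) {
        img <- r1$img
        un <- r0$mask | r1$mask
        if (keep_masks) pair_masks[[length(pair_masks) + 1L]] <- un
        ij <- which(un, arr.ind = TRUE)
        y1 <- min(ij[, 1]) - 1; y2 <- max(ij[, 1])
        x1 <- min(ij[, 2]) - 1; x2 <- max(ij[, 2])
        boxes[[length(boxes) + 1L]] <-
          data.frame(class = 0L, cx = (x1 + x2) / 2 / W,
                     cy = (y1 + y2) / 2 / H, w = (x2 - x1) / W,
                     h = (y2 - y1) / H)
        break
      }
    }
  }

  # single (non-mounting) animals, kept clear of everything placed
  n1 <- if (cfg$n_animals[2] > cfg$n_animals[1])
    sample(cfg$n_animals[1]:cfg$n_animals[2], 1L) else cfg$n_animals[1]
  for (i in seq_len(n1)) {
    a <- draw_len()
    ok <- FALSE
    for (try in 1:30) {
      cx <- runif(1, margin(a), W - margin(a))
      cy <- runif(1, margin(a), H - margin(a))
      if (far_enough(cx, cy, 1.45 * a)) { ok <- TRUE; break }
    }
    if (!ok) next
    placed[[length(placed) + 1L]] <- c(cx, cy, 1.45 * a)
    img <- paint_cow(img, cx, cy, a, runif(1, 0, 2 * pi), rand_tone())$img
  }

  if (night) {
    m <- matrix(img, ncol = 3L)
    gray <- rowMeans(m)
    m <- m * 0.4 + gray * 0.6 * 0.35
    m <- m * 0.6
    m <- m + matrix(runif(length(m), -0.01, 0.01), nrow(m), 3L)
    img <- array(pmin(pmax(m, 0), 1), dim(img))
  }

  bdf <- if (length(boxes)) do.call(rbind, boxes) else empty_boxes()
  out <- labeled_image(img, bdf, source_video = source_video,
                       lighting_tag = if (night) "night" else "day")
  if (keep_masks) attr(out, "pair_masks") <- pair_masks
  out
}

#' Generate an in-memory video-grouped scene set
#'
#' Frames within one synthetic video share the camera scale and lighting.
#'
#' @param cfg a [scene_config()]
#' @param n_videos number of synthetic videos
#' @param frames_per_video frames per video
#' @return list of [labeled_image()], `n_videos * frames_per_video` long
#' @export
generate_scenes <- function(cfg = scene_config(), n_videos = 10L,
                            frames_per_video = 5L) {
  out <- vector("list", n_videos * frames_per_video)
  k <- 0L
  for (v in seq_len(n_videos)) {
    vid <- sprintf("v%03d", v)
    vs <- runif(1, 0.8, 1.25)
    nt <- runif(1) < cfg$night_prob
    for (f in seq_len(frames_per_video)) {
      k <- k + 1L
      out[[k]] <- generate_scene(cfg, video_scale = vs, night = nt,
                                 source_video = vid)
    }
  }
  out
}

#' Generate a dataset on disk (PPM images + YOLO-txt labels + manifest)
#'
#' Layout: `out_dir/images/<video>_<frame>.ppm`,
#' `out_dir/labels/<video>_<frame>.txt`, `out_dir/manifest.json`.
#'
#' @param cfg a [scene_config()]
#' @param n_videos,frames_per_video dataset shape
#' @param out_dir output directory
#' @param overwrite allow writing into an existing non-empty directory
#' @return the manifest (invisibly written as JSON too)
#' @export
generate_dataset <- function(cfg = scene_config(), n_videos = 10L,
                             frames_per_video = 5L, out_dir,
                             overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop("out_dir exists and is not empty; use overwrite = TRUE")
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE,
             showWarnings = FALSE)
  scenes <- generate_scenes(cfg, n_videos, frames_per_video)
  videos <- list()
  for (s in scenes) {
    vid <- s$source_video
    if (is.null(videos[[vid]])) videos[[vid]] <- 0L
    videos[[vid]] <- videos[[vid]] + 1L
    stem <- sprintf("%s_f%03d", vid, videos[[vid]])
    write_ppm(s$image, file.path(out_dir, "images", paste0(stem, ".ppm")))
    write_yolo_labels(s$boxes,
                      file.path(out_dir, "labels", paste0(stem, ".txt")))
  }
  manifest <- list(
    canvas = cfg$canvas,
    n_videos = n_videos,
    frames_per_video = frames_per_video,
    videos = lapply(names(videos), function(v)
      list(video = v, frames = videos[[v]])),
    total_images = length(scenes)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Load a dataset directory written by [generate_dataset()]
#'
#' @param dir dataset directory with `images/` and `labels/`
#' @return list of [labeled_image()]
#' @export
load_dataset <- function(dir) {
  imgs <- sort(list.files(file.path(dir, "images"), pattern = "\\.ppm$",
                          full.names = TRUE))
  if (!length(imgs)) stop("no images found under ", dir)
  lapply(imgs, function(p) {
    stem <- sub("\\.ppm$", "", basename(p))
    lab <- file.path(dir, "labels", paste0(stem, ".txt"))
    labeled_image(read_ppm(p), read_yolo_labels(lab),
                  source_video = sub("_f\\d+$", "", stem))
  })
}
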