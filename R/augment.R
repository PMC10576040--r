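# ---------------------------------------------------------------------------
# Training-set augmentation: 4-image mosaic with per-member affine
# transforms (random rotation, translation, scale -> implicit crop at the
# canvas), HSV-style photometric jitter, and the 50% VERTICAL flip the
# training recipe prescribes (vertical as printed, not the more common
# horizontal). All box bookkeeping keeps class ids and clips boxes to the
# canvas; degenerate remnants (area < 10% of the transformed original or
# any side < 2 px) are dropped.
# ---------------------------------------------------------------------------

# default member-transform ranges (radians, fraction, factor)
mosaic_ranges <- list(rotate = 10 * pi / 180, translate = 0.1,
                      scale = c(0.5, 1.5))

#' Stitch four labeled images into one mosaic canvas
#'
#' A random center partitions the square canvas into four quadrants; each
#' sample is resized into its quadrant, then randomly rotated, scaled and
#' translated about the quadrant center (nearest-neighbor warp, gray fill).
#' Transformed boxes are clipped to the canvas; remnants below 10% of the
#' transformed area or thinner than 2 px are dropped. Deterministic for a
#' fixed RNG state.
#'
#' @param samples list of exactly four [labeled_image()] objects
#' @param out_size canvas side in pixels
#' @param identity use identity member transforms and a centered partition
#'   (for closed-form testing)
#' @return a [labeled_image()] of size `out_size` x `out_size`
#' @export
mosaic4 <- function(samples, out_size = 640L, identity = FALSE) {
  stopifnot(length(samples) == 4L)
  S <- as.integer(out_size)
  xc <- if (identity) S %/% 2L else as.integer(round(runif(1, 0.3, 0.7) * S))
  yc <- if (identity) S %/% 2L else as.integer(round(runif(1, 0.3, 0.7) * S))
  canvas <- array(114 / 255, dim = c(S, S, 3L))
  boxes <- list()
  quads <- list(c(1L, xc, 1L, yc), c(xc + 1L, S, 1L, yc),
                c(1L, xc, yc + 1L, S), c(xc + 1L, S, yc + 1L, S))
  for (q in 1:4) {
    qd <- quads[[q]]
    wq <- qd[2] - qd[1] + 1L
    hq <- qd[4] - qd[3] + 1L
    if (wq < 2L || hq < 2L) next
    smp <- samples[[q]]
    img <- smp$image
    d3 <- dim(img)
    rs <- cpp_resize_bilinear(array(img, c(d3[1], d3[2], 3L, 1L)), hq, wq)
    rs <- array(rs, c(hq, wq, 3L))
    if (identity) {
      th <- 0; sc <- 1; tx <- 0; ty <- 0
    } else {
      th <- runif(1, -mosaic_ranges$rotate, mosaic_ranges$rotate)
      sc <- runif(1, mosaic_ranges$scale[1], mosaic_ranges$scale[2])
      tx <- runif(1, -mosaic_ranges$translate, mosaic_ranges$translate) * wq
      ty <- runif(1, -mosaic_ranges$translate, mosaic_ranges$translate) * hq
    }
    cqx <- (wq + 1) / 2; cqy <- (hq + 1) / 2
    # inverse-map quadrant pixels to source pixels (nearest neighbor)
    patch <- cpp_warp_affine_nn(rs, th, sc, tx, ty, 114 / 255)
    canvas[qd[3]:qd[4], qd[1]:qd[2], ] <- patch
    b <- smp$boxes
    if (nrow(b)) {
      # box corners in quadrant pixels, forward affine, aabb
      for (r in seq_len(nrow(b))) {
        px <- b$cx[r] * wq; py <- b$cy[r] * hq
        hw <- b$w[r] * wq / 2; hh <- b$h[r] * hq / 2
        cs <- rbind(c(px - hw, py - hh), c(px + hw, py - hh),
                    c(px - hw, py + hh), c(px + hw, py + hh))
        dxs <- cs[, 1] - cqx; dys <- cs[, 2] - cqy
        nx <- sc * (cos(th) * dxs - sin(th) * dys) + cqx + tx
        ny <- sc * (sin(th) * dxs + cos(th) * dys) + cqy + ty
        # to canvas coordinates
        nx <- nx + qd[1] - 1; ny <- ny + qd[3] - 1
        x1 <- min(nx); x2 <- max(nx); y1 <- min(ny); y2 <- max(ny)
        area0 <- (x2 - x1) * (y2 - y1)
        # clip to the quadrant: pixels from this member exist nowhere else
        x1c <- max(x1, qd[1] - 1); y1c <- max(y1, qd[3] - 1)
        x2c <- min(x2, qd[2]); y2c <- min(y2, qd[4])
        wpx <- x2c - x1c; hpx <- y2c - y1c
        if (wpx < 2 || hpx < 2) next
        if (wpx * hpx < 0.1 * area0) next
        boxes[[length(boxes) + 1L]] <-
          data.frame(class = b$class[r], cx = (x1c + x2c) / 2 / S,
                     cy = (y1c + y2c) / 2 / S, w = wpx / S, h = hpx / S)
      }
    }
  }
  bdf <- if (length(boxes)) do.call(rbind, boxes) else empty_boxes()
  tags <- vapply(samples, function(s) s$lighting_tag, character(1))
  labeled_image(canvas, bdf,
                source_video = samples[[1]]$source_video,
                lighting_tag = if (mean(tags == "night") > 0.5) "night"
                               else "day")
}

#' Random photometric jitter (brightness, chromaticity, contrast)
#'
#' Applies bounded multiplicative gains in HSV space (hue, saturation,
#' value) plus a contrast gain about mid-gray; output clipped to `[0, 1]`.
#' Zero amplitudes give the identity.
#'
#' @param img numeric (H, W, 3) array in `[0, 1]`
#' @param hgain,sgain,vgain,cgain fractional amplitudes
#' @return jittered image
#' @export
photometric_jitter <- function(img, hgain = 0.015, sgain = 0.7,
                               vgain = 0.4, cgain = 0.2) {
  r <- runif(4, -1, 1) * c(hgain, sgain, vgain, cgain) + 1
  if (all(r == 1)) return(img)
  cpp_hsv_jitter(img, r[1], r[2], r[3], r[4])
}

#' Vertical flip
#'
#' With probability `p`, mirrors the image rows and maps each box center
#' `cy -> 1 - cy` (an involution at `p = 1`).
#'
#' @param sample a [labeled_image()]
#' @param p flip probability (default 0.5); `p = 1` forces the flip
#' @return the (possibly) flipped sample
#' @export
vflip <- function(sample, p = 0.5) {
  if (p < 1 && runif(1) >= p) return(sample)
  img <- sample$image[rev(seq_len(dim(sample$image)[1])), , , drop = FALSE]
  b <- sample$boxes
  if (nrow(b)) b$cy <- 1 - b$cy
  labeled_image(img, b, sample$source_video, sample$lighting_tag)
}

#' Resize a labeled image (boxes are normalized, hence unchanged)
#'
#' @param sample a [labeled_image()]
#' @param h,w target size
#' @return resized sample
#' @export
resize_sample <- function(sample, h, w) {
  d <- dim(sample$image)
  rs <- cpp_resize_bilinear(array(sample$image, c(d[1], d[2], 3L, 1L)),
                            as.integer(h), as.integer(w))
  labeled_image(array(rs, c(h, w, 3L)), sample$boxes,
                sample$source_video, sample$lighting_tag)
}
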