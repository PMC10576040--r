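# ---------------------------------------------------------------------------
# Detection metric stack: IoU, non-maximum suppression, greedy
# confidence-ordered matching (TP/FP/FN), average precision by all-point
# PR-curve integration with a monotone precision envelope, and mAP at a
# single IoU threshold or averaged over 0.5:0.95.
#
# Detections and ground truths are data.frames with columns
#   image, class, cx, cy, w, h [, conf]
# in any consistent length unit (pixels or normalized).
# ---------------------------------------------------------------------------

#' Intersection over union of two boxes
#'
#' @param a,b boxes: `(cx, cy, w, h)` for `form = "center"` or
#'   `(x1, y1, x2, y2)` for `form = "corner"`
#' @param form box parameterization
#' @return IoU in `[0, 1]`; 0 for disjoint boxes
#' @export
iou <- function(a, b, form = c("center", "corner")) {
  form <- match.arg(form)
  if (form == "center") {
    if (a[3] < 0 || a[4] < 0 || b[3] < 0 || b[4] < 0)
      stop("negative box dimensions")
    a <- c(a[1] - a[3] / 2, a[2] - a[4] / 2, a[1] + a[3] / 2, a[2] + a[4] / 2)
    b <- c(b[1] - b[3] / 2, b[2] - b[4] / 2, b[1] + b[3] / 2, b[2] + b[4] / 2)
  } else {
    if (a[3] < a[1] || a[4] < a[2] || b[3] < b[1] || b[4] < b[2])
      stop("negative box dimensions")
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
    inter
  inter / union
}

# IoU of one center-form box against rows of a center-form matrix
iou_vec <- function(box, mat) {
  if (nrow(mat) == 0L) return(numeric(0))
  ax1 <- box[1] - box[3] / 2; ay1 <- box[2] - box[4] / 2
  ax2 <- box[1] + box[3] / 2; ay2 <- box[2] + box[4] / 2
  bx1 <- mat[, 1] - mat[, 3] / 2; by1 <- mat[, 2] - mat[, 4] / 2
  bx2 <- mat[, 1] + mat[, 3] / 2; by2 <- mat[, 2] + mat[, 4] / 2
  iw <- pmax(0, pmin(ax2, bx2) - pmax(ax1, bx1))
  ih <- pmax(0, pmin(ay2, by2) - pmax(ay1, by1))
  inter <- iw * ih
  inter / ((ax2 - ax1) * (ay2 - ay1) +
             (bx2 - bx1) * (by2 - by1) - inter)
}

# deterministic detection ordering: confidence desc, then area desc, stable
det_order <- function(det) {
  order(-det$conf, -(det$w * det$h))
}

#' Non-maximum suppression
#'
#' Drops detections below `conf_threshold`, then greedily keeps the
#' highest-confidence detection and suppresses same-class detections with
#' IoU above `iou_threshold`. Idempotent.
#'
#' @param det detection data.frame (`cx, cy, w, h, conf, class`, optionally
#'   `image` -- suppression is within image)
#' @param iou_threshold suppression IoU (default 0.45)
#' @param conf_threshold minimum confidence (default 0.25)
#' @return the surviving rows, ordered by decreasing confidence
#' @export
nms <- function(det, iou_threshold = 0.45, conf_threshold = 0.25) {
  if (is.null(det) || nrow(det) == 0L) return(det)
  det <- det[det$conf >= conf_threshold, , drop = FALSE]
  if (nrow(det) == 0L) return(det)
  if (!"image" %in% names(det)) det$image <- 1L
  keep_all <- list()
  for (img in unique(det$image)) {
    d <- det[det$image == img, , drop = FALSE]
    d <- d[det_order(d), , drop = FALSE]
    boxes <- as.matrix(d[, c("cx", "cy", "w", "h")])
    alive <- rep(TRUE, nrow(d))
    keep <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      if (!alive[i]) next
      keep[i] <- TRUE
      if (i == nrow(d)) break
      rest <- which(alive & seq_len(nrow(d)) > i & d$class == d$class[i])
      if (length(rest)) {
        ov <- iou_vec(boxes[i, ], boxes[rest, , drop = FALSE])
        alive[rest[ov > iou_threshold]] <- FALSE
      }
    }
    keep_all[[length(keep_all) + 1L]] <- d[keep, , drop = FALSE]
  }
  out <- do.call(rbind, keep_all)
  rownames(out) <- NULL
  out
}

#' Match detections to ground truths at one IoU threshold
#'
#' Detections are visited in decreasing confidence (deterministic
#' tie-break: larger area first); each matches the unmatched ground truth
#' of its class and image with the highest IoU >= threshold (TP), else it
#' is a FP. Unmatched ground truths are FNs.
#'
#' @param dets detection data.frame (`image, class, cx, cy, w, h, conf`)
#' @param gts ground-truth data.frame (`image, class, cx, cy, w, h`)
#' @param iou_threshold matching IoU (default 0.5)
#' @return a `match_result`: list with `tp` (logical, confidence order),
#'   `conf` (sorted confidences), `n_gt`, `fn`, and cumulative `precision` /
#'   `recall` sequences
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  n_gt <- if (is.null(gts)) 0L else nrow(gts)
  if (is.null(dets) || nrow(dets) == 0L) {
    r <- list(tp = logical(0), conf = numeric(0), n_gt = n_gt, fn = n_gt,
              precision = numeric(0), recall = numeric(0),
              iou_threshold = iou_threshold)
    class(r) <- "match_result"
    return(r)
  }
  dets <- dets[det_order(dets), , drop = FALSE]
  tp <- logical(nrow(dets))
  if (n_gt > 0L) {
    gt_used <- logical(n_gt)
    gboxes <- as.matrix(gts[, c("cx", "cy", "w", "h")])
    for (i in seq_len(nrow(dets))) {
      cand <- which(!gt_used & gts$image == dets$image[i] &
                      gts$class == dets$class[i])
      if (!length(cand)) next
      ov <- iou_vec(as.numeric(dets[i, c("cx", "cy", "w", "h")]),
                    gboxes[cand, , drop = FALSE])
      j <- which.max(ov)
      if (ov[j] >= iou_threshold) {
        tp[i] <- TRUE
        gt_used[cand[j]] <- TRUE
      }
    }
  }
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  r <- list(tp = tp, conf = dets$conf, n_gt = n_gt,
            fn = n_gt - sum(tp),
            precision = ctp / (ctp + cfp),
            recall = if (n_gt > 0L) ctp / n_gt else rep(0, length(tp)),
            iou_threshold = iou_threshold)
  class(r) <- "match_result"
  r
}

#' Average precision from a match result
#'
#' All-point integration of the precision-recall curve after applying the
#' monotone-decreasing precision envelope. With zero ground truths the AP
#' is undefined and `NA` is returned.
#'
#' @param match a [match_detections()] result
#' @return AP in `[0, 1]`, or `NA` when undefined
#' @export
average_precision <- function(match) {
  stopifnot(inherits(match, "match_result"))
  if (match$n_gt == 0L) return(NA_real_)
  if (!length(match$tp)) return(0)
  r <- c(0, match$recall)
  p <- c(1, match$precision)
  # monotone envelope: p_env(r) = max precision at recall >= r
  p_env <- rev(cummax(rev(p)))
  sum(diff(r) * p_env[-1])
}

#' Mean average precision
#'
#' mAP over classes present in the ground truth, at a single IoU threshold
#' or averaged over a threshold vector (use `seq(0.5, 0.95, 0.05)` for the
#' ranged metric).
#'
#' @param dets detection data.frame (`image, class, cx, cy, w, h, conf`)
#' @param gts ground-truth data.frame (`image, class, cx, cy, w, h`)
#' @param iou_spec numeric IoU threshold(s); default 0.5
#' @param conf_threshold operating confidence for the reported P/R point
#' @return an `eval_result`: list with `per_class` (AP per class per
#'   threshold), `map` (grand mean), `map_by_threshold`, and the operating
#'   `precision`/`recall` at `conf_threshold` and `iou_spec[1]`
#' @export
mean_average_precision <- function(dets, gts, iou_spec = 0.5,
                                   conf_threshold = 0.25) {
  stopifnot(all(iou_spec > 0 & iou_spec < 1))
  classes <- sort(unique(gts$class))
  if (!length(classes)) stop("no ground-truth classes")
  ap <- matrix(NA_real_, length(classes), length(iou_spec),
               dimnames = list(paste0("class_", classes), NULL))
  for (ci in seq_along(classes)) {
    dc <- dets[dets$class == classes[ci], , drop = FALSE]
    gc_ <- gts[gts$class == classes[ci], , drop = FALSE]
    for (ti in seq_along(iou_spec))
      ap[ci, ti] <- average_precision(
        match_detections(dc, gc_, iou_spec[ti]))
  }
  m0 <- match_detections(dets[dets$conf >= conf_threshold, , drop = FALSE],
                         gts, iou_spec[1])
  tp_n <- sum(m0$tp)
  res <- list(
    per_class = ap,
    map_by_threshold = colMeans(ap),
    map = mean(ap),
    precision = if (length(m0$tp)) tp_n / length(m0$tp) else NA_real_,
    recall = if (m0$n_gt > 0) tp_n / m0$n_gt else NA_real_,
    iou_spec = iou_spec
  )
  class(res) <- "eval_result"
  res
}

#' @export
print.eval_result <- function(x, ...) {
  thr <- paste(format(x$iou_spec, digits = 2), collapse = ",")
  cat(sprintf("mAP@[%s] = %.4f  (P = %.3f, R = %.3f at operating point)\n",
              thr, x$map, x$precision, x$recall))
  invisible(x)
}
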