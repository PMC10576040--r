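# ---------------------------------------------------------------------------
# Target assignment and the three-part detection loss (CIoU box regression,
# IoU-scored objectness BCE, smoothed-label classification BCE), plus the
# cosine-annealed learning-rate schedule and label smoothing.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the published recipe: 640-pixel input, batch 40, 200
#' epochs, initial learning rate 0.01 with cosine annealing, label
#' smoothing, SGD with momentum.
#'
#' @param input_size network input side (multiple of 32)
#' @param batch_size images per optimizer step
#' @param epochs training epochs
#' @param lr0 initial learning rate
#' @param lr_final_fraction final LR as a fraction of `lr0`
#' @param label_smoothing smoothing epsilon in `[0, 0.3]`
#' @param loss_weights named weights `(box, obj, cls)`
#' @param momentum,weight_decay SGD hyperparameters
#' @param warmup_epochs linear LR warmup span
#' @param obj_iou_target score positive objectness by the (clipped) CIoU
#'   of the assigned box (`TRUE`, the long-run default) or by 1
#'   (`FALSE`; converges faster on short runs)
#' @param optimizer `"sgd"` (momentum, the long-run default) or `"adam"`
#'   (recommended for short CPU runs; use `lr0` around 1e-3)
#' @param obj_pos_weight weight multiplier on positive cells in the
#'   objectness BCE (1 = unweighted; larger values counter the extreme
#'   background/foreground imbalance on short runs)
#' @param seed RNG seed for shuffling/augmentation/init
#' @return a `train_config` list
#' @export
train_config <- function(input_size = 640L, batch_size = 40L,
                         epochs = 200L, lr0 = 0.01,
                         lr_final_fraction = 0.01,
                         label_smoothing = 0.1,
                         loss_weights = c(box = 0.05, obj = 1.0, cls = 0.5),
                         momentum = 0.937, weight_decay = 5e-4,
                         warmup_epochs = 3L, obj_iou_target = TRUE,
                         optimizer = c("sgd", "adam"),
                         obj_pos_weight = 1, seed = 0L) {
  if (input_size %% 32L != 0L) stop("input_size must be a multiple of 32")
  if (label_smoothing < 0 || label_smoothing > 0.3)
    stop("label_smoothing must be in [0, 0.3]")
  optimizer <- match.arg(optimizer)
  structure(list(input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0,
                 lr_final_fraction = lr_final_fraction,
                 label_smoothing = label_smoothing,
                 loss_weights = loss_weights, momentum = momentum,
                 weight_decay = weight_decay,
                 warmup_epochs = as.integer(warmup_epochs),
                 obj_iou_target = isTRUE(obj_iou_target),
                 optimizer = optimizer,
                 obj_pos_weight = obj_pos_weight,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = lr_min + 0.5 (lr0 - lr_min) (1 + cos(pi e / epochs))` with
#' `lr_min = lr0 * lr_final_fraction`.
#'
#' @param epoch epoch index in `[0, epochs]`
#' @param cfg a [train_config()]
#' @return learning rate
#' @export
cosine_lr <- function(epoch, cfg) {
  if (any(epoch < 0) || any(epoch > cfg$epochs))
    stop("epoch out of [0, epochs]")
  lr_min <- cfg$lr0 * cfg$lr_final_fraction
  lr_min + 0.5 * (cfg$lr0 - lr_min) * (1 + cos(pi * epoch / cfg$epochs))
}

#' Label smoothing targets
#'
#' @param eps smoothing amount in `[0, 0.3]`
#' @return named vector `c(positive = 1 - eps/2, negative = eps/2)`
#' @export
smooth_labels <- function(eps) {
  if (eps < 0 || eps > 0.3) stop("eps must be in [0, 0.3]")
  c(positive = 1 - eps / 2, negative = eps / 2)
}

#' Assign ground-truth boxes to anchors and cells
#'
#' A ground truth matches anchor `a` at a scale iff
#' `max(w/a_w, a_w/w, h/a_h, a_h/h) < 4`; the box's cell plus up to two
#' nearest neighbor cells (by center fraction) receive positives.
#' Degenerate boxes (zero width/height) are dropped and counted.
#'
#' @param labels list (one per image) of normalized box data.frames
#' @param cfg a [head_config()]
#' @param img_size network input side in pixels
#' @return list with per-scale assignment tables
#'   (`n, a, gi, gj, gx, gy, gw, gh, cls`) and `n_dropped`
#' @export
assign_targets <- function(labels, cfg, img_size) {
  stopifnot(inherits(cfg, "head_config"))
  S <- img_size
  out <- vector("list", 3L)
  dropped <- 0L
  rows <- list()
  for (n in seq_along(labels)) {
    b <- labels[[n]]
    if (is.null(b) || nrow(b) == 0L) next
    bad <- b$w <= 0 | b$h <= 0
    dropped <- dropped + sum(bad)
    b <- b[!bad, , drop = FALSE]
    if (nrow(b)) rows[[length(rows) + 1L]] <- cbind(n = n, b)
  }
  all_b <- if (length(rows)) do.call(rbind, rows) else NULL
  for (si in 1:3) {
    stride <- cfg$strides[si]
    G <- S %/% stride
    acc <- list()
    if (!is.null(all_b)) {
      gw <- all_b$w * S; gh <- all_b$h * S
      gx <- all_b$cx * S / stride; gy <- all_b$cy * S / stride
      for (a in 1:3) {
        aw <- cfg$anchors[[si]][a, 1]; ah <- cfg$anchors[[si]][a, 2]
        r <- pmax(gw / aw, aw / gw, gh / ah, ah / gh)
        sel <- which(r < 4)
        for (i in sel) {
          gi0 <- floor(gx[i]); gj0 <- floor(gy[i])
          cells <- list(c(gi0, gj0))
          fx <- gx[i] - gi0; fy <- gy[i] - gj0
          if (fx < 0.5 && gi0 >= 1) cells <- c(cells, list(c(gi0 - 1, gj0)))
          if (fx >= 0.5 && gi0 < G - 1) cells <- c(cells, list(c(gi0 + 1, gj0)))
          if (fy < 0.5 && gj0 >= 1) cells <- c(cells, list(c(gi0, gj0 - 1)))
          if (fy >= 0.5 && gj0 < G - 1) cells <- c(cells, list(c(gi0, gj0 + 1)))
          cells <- cells[seq_len(min(3L, length(cells)))]
          for (cl in cells) {
            if (cl[1] < 0 || cl[1] >= G || cl[2] < 0 || cl[2] >= G) next
            # the cell must still see the center within the decode range
            if (gx[i] - cl[1] <= -0.5 || gx[i] - cl[1] >= 1.5) next
            if (gy[i] - cl[2] <= -0.5 || gy[i] - cl[2] >= 1.5) next
            acc[[length(acc) + 1L]] <-
              c(all_b$n[i], a, cl[1], cl[2], gx[i] * stride,
                gy[i] * stride, gw[i], gh[i], all_b$class[i])
          }
        }
      }
    }
    tb <- if (length(acc)) {
      m <- do.call(rbind, acc)
      data.frame(n = m[, 1], a = m[, 2], gi = m[, 3], gj = m[, 4],
                 gx = m[, 5], gy = m[, 6], gw = m[, 7], gh = m[, 8],
                 cls = m[, 9])
    } else {
      data.frame(n = integer(0), a = integer(0), gi = integer(0),
                 gj = integer(0), gx = numeric(0), gy = numeric(0),
                 gw = numeric(0), gh = numeric(0), cls = integer(0))
    }
    # deduplicate (a gt center on a cell border can propose a cell twice)
    key <- paste(tb$n, tb$a, tb$gi, tb$gj, tb$gx, tb$gy, tb$gw, tb$gh)
    out[[si]] <- tb[!duplicated(key), , drop = FALSE]
  }
  list(scales = out, n_dropped = dropped)
}

# complete-IoU of paired center-form boxes (rows)
ciou_pairs <- function(p, g) {
  eps <- 1e-9
  px1 <- p[, 1] - p[, 3] / 2; py1 <- p[, 2] - p[, 4] / 2
  px2 <- p[, 1] + p[, 3] / 2; py2 <- p[, 2] + p[, 4] / 2
  gx1 <- g[, 1] - g[, 3] / 2; gy1 <- g[, 2] - g[, 4] / 2
  gx2 <- g[, 1] + g[, 3] / 2; gy2 <- g[, 2] + g[, 4] / 2
  iw <- pmax(0, pmin(px2, gx2) - pmax(px1, gx1))
  ih <- pmax(0, pmin(py2, gy2) - pmax(py1, gy1))
  inter <- iw * ih
  uni <- p[, 3] * p[, 4] + g[, 3] * g[, 4] - inter + eps
  i <- inter / uni
  cw <- pmax(px2, gx2) - pmin(px1, gx1)
  ch <- pmax(py2, gy2) - pmin(py1, gy1)
  c2 <- cw^2 + ch^2 + eps
  rho2 <- (p[, 1] - g[, 1])^2 + (p[, 2] - g[, 2])^2
  v <- (4 / pi^2) * (atan(g[, 3] / pmax(g[, 4], eps)) -
                       atan(p[, 3] / pmax(p[, 4], eps)))^2
  alpha <- v / (1 - i + v + eps)  # treated as a constant in the gradient
  i - rho2 / c2 - alpha * v
}

#' Three-part detection loss with gradients
#'
#' `box = mean(1 - CIoU)` over positives; `obj` = binary cross-entropy of
#' objectness against the (detached) positive IoU over every cell, with
#' per-scale balance weights; `cls` = binary cross-entropy against smoothed
#' labels over positives. Returns the weighted total, the three terms and
#' the gradient arrays with respect to the raw head logits.
#'
#' @param logits list of three head logit arrays
#' @param targets an [assign_targets()] result
#' @param cfg a [head_config()]
#' @param tcfg a [train_config()]
#' @return list `(total, box, obj, cls, grads)`
#' @export
detection_loss <- function(logits, targets, cfg, tcfg) {
  nc <- cfg$num_classes
  per <- 5L + nc
  sl <- smooth_labels(tcfg$label_smoothing)
  balance <- c(4.0, 1.0, 0.4)
  lw <- tcfg$loss_weights
  box_sum <- 0; box_n <- 0L; obj_sum <- 0; cls_sum <- 0; cls_n <- 0L
  grads <- vector("list", 3L)
  clamp <- function(s) pmin(pmax(s, 1e-7), 1 - 1e-7)

  for (si in 1:3) {
    lg <- logits[[si]]
    d <- dim(lg)
    Ho <- d[1]; Wo <- d[2]; N <- d[4]
    stride <- cfg$strides[si]
    g <- array(0, d)
    tobj <- array(0, c(Ho, Wo, 3L, N))
    tb <- targets$scales[[si]]
    if (nrow(tb)) {
      lin <- function(ch) {
        (tb$gj + 1) + Ho * tb$gi + Ho * Wo * (ch - 1) +
          Ho * Wo * d[3] * (tb$n - 1)
      }
      base <- (tb$a - 1L) * per
      itx <- lin(base + 1L); ity <- lin(base + 2L)
      itw <- lin(base + 3L); ith <- lin(base + 4L)
      sx <- sigmoid(lg[itx]); sy <- sigmoid(lg[ity])
      sw <- sigmoid(lg[itw]); sh <- sigmoid(lg[ith])
      aw <- cfg$anchors[[si]][tb$a, 1]; ah <- cfg$anchors[[si]][tb$a, 2]
      px <- (2 * sx - 0.5 + tb$gi) * stride
      py <- (2 * sy - 0.5 + tb$gj) * stride
      pw <- (2 * sw)^2 * aw
      ph <- (2 * sh)^2 * ah
      P <- cbind(px, py, pw, ph)
      G <- cbind(tb$gx, tb$gy, tb$gw, tb$gh)
      ci <- ciou_pairs(P, G)
      # per-scale mean, summed over scales (value and gradient agree)
      box_sum <- box_sum + mean(1 - ci)
      box_n <- box_n + 1L
      # central finite differences of CIoU in the decoded box coordinates
      h <- 1e-3 * stride
      dci <- matrix(0, length(ci), 4L)
      for (k in 1:4) {
        Pp <- P; Pp[, k] <- Pp[, k] + h
        Pm <- P; Pm[, k] <- Pm[, k] - h
        dci[, k] <- (ciou_pairs(Pp, G) - ciou_pairs(Pm, G)) / (2 * h)
      }
      # chain through the decode: d(box)/d(logit)
      dpx <- 2 * sx * (1 - sx) * stride
      dpy <- 2 * sy * (1 - sy) * stride
      dpw <- 8 * sw^2 * (1 - sw) * aw
      dph <- 8 * sh^2 * (1 - sh) * ah
      scale_box <- lw[["box"]] / length(ci)
      g[itx] <- g[itx] - scale_box * dci[, 1] * dpx
      g[ity] <- g[ity] - scale_box * dci[, 2] * dpy
      g[itw] <- g[itw] - scale_box * dci[, 3] * dpw
      g[ith] <- g[ith] - scale_box * dci[, 4] * dph
      # objectness target = clipped CIoU (detached)
      iobj <- tb$gj + 1 + Ho * tb$gi + Ho * Wo * (tb$a - 1) +
        Ho * Wo * 3 * (tb$n - 1)
      tv <- if (isTRUE(tcfg$obj_iou_target)) pmax(ci, 0)
            else rep(1, length(ci))
      # on duplicates keep the larger score
      ord <- order(tv)
      tobj[iobj[ord]] <- tv[ord]
      # classification over positives
      if (nc >= 1L) {
        sc_sum <- 0
        for (cc in seq_len(nc)) {
          icl <- lin(base + 5L + cc)
          s <- clamp(sigmoid(lg[icl]))
          t <- ifelse(tb$cls == cc - 1L, sl[["positive"]], sl[["negative"]])
          sc_sum <- sc_sum + sum(-(t * log(s) + (1 - t) * log(1 - s)))
          g[icl] <- g[icl] + lw[["cls"]] * (s - t) / (nrow(tb) * nc)
        }
        cls_sum <- cls_sum + sc_sum / (nrow(tb) * nc)
        cls_n <- cls_n + 1L
      }
    }
    # objectness over every cell/anchor, optionally up-weighting positives
    pw <- if (is.null(tcfg$obj_pos_weight)) 1 else tcfg$obj_pos_weight
    for (a in 1:3) {
      ch <- (a - 1L) * per + 5L
      s <- clamp(sigmoid(lg[, , ch, ]))
      t <- tobj[, , a, ]
      wgt <- if (pw != 1) 1 + (pw - 1) * (t > 0) else 1
      numel <- Ho * Wo * 3 * N
      obj_sum <- obj_sum + balance[si] *
        sum(-wgt * (t * log(s) + (1 - t) * log(1 - s))) / numel
      g[, , ch, ] <- g[, , ch, ] +
        lw[["obj"]] * balance[si] * wgt * (s - t) / numel
    }
    # recipe convention: the optimized objective is summed over the batch
    # (reported terms stay per-image means)
    grads[[si]] <- g * N
  }
  box <- box_sum
  cls <- cls_sum
  list(total = lw[["box"]] * box + lw[["obj"]] * obj_sum +
         lw[["cls"]] * cls,
       box = box, obj = obj_sum, cls = cls, grads = grads)
}
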