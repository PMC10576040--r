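# ---------------------------------------------------------------------------
# SGD training loop (mosaic-augmented loading, cosine schedule with linear
# warmup, best-mAP checkpointing) and the inference pipeline
# (resize -> forward -> decode -> NMS).
# ---------------------------------------------------------------------------

# stack labeled images (already at the network size) into a batch tensor
stack_batch <- function(samples) {
  d <- dim(samples[[1]]$image)
  x <- array(0, c(d[1], d[2], 3L, length(samples)))
  for (i in seq_along(samples)) x[, , , i] <- samples[[i]]$image
  x
}

# one epoch's worth of augmented canvases: one mosaic per dataset item
# (the item plus three random partners), jittered and possibly flipped
build_epoch_canvases <- function(dataset, size, augment = TRUE) {
  idx <- sample(length(dataset))
  if (!augment) {
    return(lapply(dataset[idx], function(s) resize_sample(s, size, size)))
  }
  lapply(idx, function(i) {
    g4 <- c(i, sample(length(dataset), 3L))
    cv <- mosaic4(dataset[g4], out_size = size)
    cv <- labeled_image(photometric_jitter(cv$image), cv$boxes,
                        cv$source_video, cv$lighting_tag)
    vflip(cv, p = 0.5)
  })
}

#' Train the detector
#'
#' Runs the full recipe: mosaic + photometric + vertical-flip augmented
#' loading (augmentation can be disabled), the three-part detection loss,
#' SGD with momentum (or Adam, see [train_config()]) under a
#' cosine-annealed learning rate with linear warmup, per-epoch mAP@0.5
#' evaluation on a validation split, and retention of the best-mAP
#' weights. Deterministic for a fixed `cfg$seed`.
#'
#' @param model a [build_model()] detector
#' @param dataset list of [labeled_image()] training samples
#' @param cfg a [train_config()]
#' @param val_dataset optional list of validation samples (no
#'   augmentation); when omitted, mAP tracking is skipped
#' @param augment apply the augmentation pipeline (default TRUE)
#' @param eval_every evaluate mAP every this many epochs (last epoch is
#'   always evaluated)
#' @param out_dir optional directory for the checkpoint and metrics CSV
#' @param verbose print per-epoch progress
#' @return list: `model` (weights of the best epoch when validation is
#'   tracked), `history` data.frame, `best_map`, `best_epoch`
#' @export
train <- function(model, dataset, cfg = train_config(),
                  val_dataset = NULL, augment = TRUE, eval_every = 1L,
                  out_dir = NULL, verbose = interactive()) {
  if (!length(dataset)) stop("empty dataset")
  set.seed(cfg$seed)
  S <- cfg$input_size
  hist <- data.frame()
  best_map <- -Inf
  best_state <- NULL
  best_epoch <- NA_integer_

  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch - 1L, cfg)
    if (cfg$warmup_epochs > 0L && epoch <= cfg$warmup_epochs)
      lr <- lr * epoch / (cfg$warmup_epochs + 1L)
    canvases <- build_epoch_canvases(dataset, S, augment)
    batches <- split(seq_along(canvases),
                     ceiling(seq_along(canvases) / cfg$batch_size))
    ep <- c(total = 0, box = 0, obj = 0, cls = 0)
    for (bi in batches) {
      smp <- canvases[bi]
      x <- stack_batch(smp)
      labels <- lapply(smp, function(s) s$boxes)
      tg <- assign_targets(labels, model$cfg, S)
      logits <- model$forward_logits(x, train = TRUE)
      ls <- detection_loss(logits, tg, model$cfg, cfg)
      zero_grads(model)
      model$backward_logits(ls$grads)
      if (identical(cfg$optimizer, "adam"))
        adam_step(model, lr, weight_decay = cfg$weight_decay)
      else sgd_step(model, lr, cfg$momentum, cfg$weight_decay)
      ep <- ep + c(ls$total, ls$box, ls$obj, ls$cls) * length(bi)
    }
    ep <- ep / length(canvases)
    map50 <- NA_real_
    if (!is.null(val_dataset) &&
        (epoch %% eval_every == 0L || epoch == cfg$epochs)) {
      ev <- evaluate_model(model, val_dataset, img_size = S)
      map50 <- ev$map
      if (map50 >= best_map) {
        best_map <- map50
        best_state <- module_state(model)
        best_epoch <- epoch
      }
    }
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   box = ep[["box"]], obj = ep[["obj"]],
                                   cls = ep[["cls"]],
                                   total = ep[["total"]], map50 = map50))
    if (verbose)
      message(sprintf(
        "epoch %3d  lr %.5f  box %.4f  obj %.4f  cls %.4f  mAP50 %s",
        epoch, lr, ep[["box"]], ep[["obj"]], ep[["cls"]],
        ifelse(is.na(map50), "-", sprintf("%.3f", map50))))
  }
  if (!is.null(best_state)) module_load_state(model, best_state)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(list(state = module_state(model), cfg = cfg,
                 head_cfg = model$cfg, width = model$width,
                 num_classes = model$num_classes, best_map = best_map),
            file.path(out_dir, "checkpoint.rds"))
    utils::write.csv(hist, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  list(model = model, history = hist,
       best_map = if (is.finite(best_map)) best_map else NA_real_,
       best_epoch = best_epoch)
}

#' Load a checkpoint written by [train()]
#'
#' @param path `checkpoint.rds` file
#' @return the restored detector
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(num_classes = ck$num_classes, width = ck$width,
                       seed = 0L)
  module_load_state(model, ck$state)
  model$cfg <- ck$head_cfg
  model
}

#' Run the detector on labeled or raw images
#'
#' Resizes each image to `img_size`, runs the network in inference mode,
#' decodes the three head outputs and applies class-aware NMS. Boxes are
#' returned in normalized image coordinates.
#'
#' @param model a trained detector
#' @param samples list of [labeled_image()] (or plain (H, W, 3) arrays)
#' @param conf_threshold minimum confidence (0.001 for evaluation, 0.25
#'   for deployment)
#' @param iou_threshold NMS IoU threshold
#' @param img_size network input side
#' @param chunk images per forward pass
#' @return detection data.frame `(image, class, cx, cy, w, h, conf)`
#' @export
model_detect <- function(model, samples, conf_threshold = 0.25,
                         iou_threshold = 0.45, img_size = 320L,
                         chunk = 8L) {
  samples <- lapply(samples, function(s)
    if (inherits(s, "labeled_image")) s else labeled_image(s))
  out <- list()
  for (start in seq(1L, length(samples), by = chunk)) {
    ids <- start:min(start + chunk - 1L, length(samples))
    rs <- lapply(samples[ids], resize_sample, h = img_size, w = img_size)
    x <- stack_batch(rs)
    logits <- model$forward_logits(x, train = FALSE)
    dets <- decode(logits, model$cfg)
    for (k in seq_along(ids)) {
      dm <- dets[[k]]
      dm <- dm[dm[, "conf"] >= conf_threshold, , drop = FALSE]
      if (!nrow(dm)) next
      # cap the candidate set before the quadratic suppression pass
      if (nrow(dm) > 1000L)
        dm <- dm[order(-dm[, "conf"])[1:1000], , drop = FALSE]
      df <- data.frame(image = ids[k], class = as.integer(dm[, "class"]),
                       cx = dm[, "cx"] / img_size,
                       cy = dm[, "cy"] / img_size,
                       w = dm[, "w"] / img_size,
                       h = dm[, "h"] / img_size, conf = dm[, "conf"])
      kept <- nms(df, iou_threshold, conf_threshold)
      if (nrow(kept) > 300L) kept <- kept[1:300, , drop = FALSE]
      out[[length(out) + 1L]] <- kept
    }
  }
  if (!length(out))
    return(data.frame(image = integer(0), class = integer(0),
                      cx = numeric(0), cy = numeric(0), w = numeric(0),
                      h = numeric(0), conf = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Evaluate a detector on a labeled sample set
#'
#' @param model a trained detector
#' @param samples list of [labeled_image()] with ground-truth boxes
#' @param img_size network input side
#' @param conf_threshold evaluation confidence floor (default 0.001)
#' @param iou_spec metric IoU threshold(s)
#' @return an `eval_result` from [mean_average_precision()]
#' @export
evaluate_model <- function(model, samples, img_size = 320L,
                           conf_threshold = 0.001, iou_spec = 0.5) {
  dets <- model_detect(model, samples, conf_threshold = conf_threshold,
                       img_size = img_size)
  gts <- do.call(rbind, lapply(seq_along(samples), function(i) {
    b <- samples[[i]]$boxes
    if (!nrow(b)) return(NULL)
    cbind(image = i, b)
  }))
  if (is.null(gts)) stop("validation set has no ground-truth boxes")
  mean_average_precision(dets, gts, iou_spec)
}
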