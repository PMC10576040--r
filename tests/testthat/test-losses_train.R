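test_that("the cosine schedule hits its anchor points", {
  cfg <- train_config(epochs = 200L, lr0 = 0.01, lr_final_fraction = 0.01)
  expect_equal(cosine_lr(0, cfg), 0.01)
  expect_equal(cosine_lr(200, cfg), 0.01 * 0.01)
  expect_equal(cosine_lr(100, cfg), (0.01 + 1e-4) / 2)
  # monotone non-increasing over the whole span
  lrs <- vapply(0:200, cosine_lr, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) <= 1e-12))
  expect_error(cosine_lr(201, cfg), "out of")
})

test_that("label smoothing produces complementary targets", {
  expect_equal(smooth_labels(0), c(positive = 1, negative = 0))
  expect_equal(smooth_labels(0.1), c(positive = 0.95, negative = 0.05))
  for (eps in seq(0, 0.3, 0.05))
    expect_equal(sum(smooth_labels(eps)), 1)
  expect_error(smooth_labels(0.5), "0, 0.3")
  expect_error(train_config(label_smoothing = 0.4), "0, 0.3")
})

test_that("target assignment follows the anchor-ratio and neighbor rules", {
  cfg <- head_config(1L)
  # empty labels: zero assignments everywhere
  tg0 <- assign_targets(list(empty_boxes()), cfg, 320L)
  expect_identical(vapply(tg0$scales, nrow, integer(1)), rep(0L, 3))
  # a box exactly equal to an anchor is assigned at that scale
  lab <- list(data.frame(class = 0L, cx = 0.5, cy = 0.5,
                         w = 30 / 320, h = 61 / 320))
  tg <- assign_targets(lab, cfg, 320L)
  expect_gt(nrow(tg$scales[[2]]), 0L)  # anchor (30, 61) lives at stride 16
  # all assigned cells are inside their grids
  for (si in 1:3) {
    G <- 320L %/% cfg$strides[si]
    tb <- tg$scales[[si]]
    expect_true(all(tb$gi >= 0 & tb$gi < G & tb$gj >= 0 & tb$gj < G))
  }
  # degenerate boxes are dropped and counted
  bad <- list(data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0, h = 0.1))
  expect_identical(assign_targets(bad, cfg, 320L)$n_dropped, 1L)
})

test_that("assignment matches a brute-force enumeration on a crafted image", {
  cfg <- head_config(1L)
  S <- 320L
  labs <- list(data.frame(class = 0L,
                          cx = c(0.31, 0.55, 0.83),
                          cy = c(0.42, 0.18, 0.77),
                          w = c(12, 40, 150) / S,
                          h = c(14, 70, 160) / S))
  got <- assign_targets(labs, cfg, S)
  # oracle: loop over every (scale, anchor, cell) triple and apply the
  # published rules directly
  count <- 0L
  b <- labs[[1]]
  for (si in 1:3) {
    stride <- cfg$strides[si]
    G <- S %/% stride
    for (a in 1:3) {
      aw <- cfg$anchors[[si]][a, 1]; ah <- cfg$anchors[[si]][a, 2]
      for (r in seq_len(nrow(b))) {
        w <- b$w[r] * S; h <- b$h[r] * S
        if (max(w / aw, aw / w, h / ah, ah / h) >= 4) next
        gx <- b$cx[r] * S / stride; gy <- b$cy[r] * S / stride
        for (gi in 0:(G - 1)) for (gj in 0:(G - 1)) {
          dx <- gx - gi; dy <- gy - gj
          if (dx <= -0.5 || dx >= 1.5 || dy <= -0.5 || dy >= 1.5) next
          # candidate iff this is the center cell or one of the two
          # nearest neighbors along x and y
          ci <- floor(gx); cj <- floor(gy)
          fx <- gx - ci; fy <- gy - cj
          ok <- (gi == ci && gj == cj) ||
            (gj == cj && ((fx < 0.5 && gi == ci - 1 && gi >= 0) ||
                          (fx >= 0.5 && gi == ci + 1 && gi < G))) ||
            (gi == ci && ((fy < 0.5 && gj == cj - 1 && gj >= 0) ||
                          (fy >= 0.5 && gj == cj + 1 && gj < G)))
          if (ok) count <- count + 1L
        }
      }
    }
  }
  expect_identical(sum(vapply(got$scales, nrow, integer(1))), count)
  # every non-degenerate gt yields at least one assignment here
  expect_gte(nrow(got$scales[[1]]) + nrow(got$scales[[2]]) +
               nrow(got$scales[[3]]), nrow(b))
})

test_that("the three-part loss behaves at its fixed points", {
  set.seed(1)
  cfg <- head_config(1L)
  tcfg <- train_config(input_size = 64L, batch_size = 1L, epochs = 10L,
                       label_smoothing = 0)
  labs <- list(data.frame(class = 0L, cx = 0.5, cy = 0.5,
                          w = 12 / 64, h = 14 / 64))
  tg <- assign_targets(labs, cfg, 64L)
  dims <- lapply(c(8L, 4L, 2L), function(G) c(G, G, 18L, 1L))
  zero_logits <- lapply(dims, function(d) array(0, d))

  # no positives at all: box and cls are zero, obj still defined
  tg_empty <- assign_targets(list(empty_boxes()), cfg, 64L)
  l0 <- detection_loss(zero_logits, tg_empty, cfg, tcfg)
  expect_identical(l0$box, 0)
  expect_identical(l0$cls, 0)
  expect_gt(l0$obj, 0)

  # all terms non-negative on arbitrary logits
  set.seed(2)
  rnd <- lapply(dims, function(d) array(rnorm(prod(d)), d))
  lr <- detection_loss(rnd, tg, cfg, tcfg)
  expect_gte(lr$box, 0); expect_gte(lr$obj, 0); expect_gte(lr$cls, 0)
  expect_gte(lr$total, 0)

  # logits encoding the targets exactly, saturated objectness/class:
  # box -> 0 and cls -> 0
  perfect <- lapply(dims, function(d) array(0, d))
  for (si in 1:3) {
    tb <- tg$scales[[si]]
    if (!nrow(tb)) next
    for (r in seq_len(nrow(tb))) {
      t4 <- encode_box(c(tb$gx[r], tb$gy[r], tb$gw[r], tb$gh[r]),
                       c(tb$gi[r], tb$gj[r]),
                       cfg$anchors[[si]][tb$a[r], ], cfg$strides[si])
      per <- 6L
      base <- (tb$a[r] - 1L) * per
      perfect[[si]][tb$gj[r] + 1, tb$gi[r] + 1, base + 1:4, 1] <- t4
      perfect[[si]][tb$gj[r] + 1, tb$gi[r] + 1, base + 5L, 1] <- 20
      perfect[[si]][tb$gj[r] + 1, tb$gi[r] + 1, base + 6L, 1] <- 20
    }
  }
  lp <- detection_loss(perfect, tg, cfg, tcfg)
  expect_lt(lp$box, 1e-6)
  expect_lt(lp$cls, 1e-6)

  # doubling the box weight doubles the box contribution
  t2 <- tcfg; t2$loss_weights[["box"]] <- 2 * tcfg$loss_weights[["box"]]
  la <- detection_loss(rnd, tg, cfg, tcfg)
  lb <- detection_loss(rnd, tg, cfg, t2)
  expect_equal(lb$total - lb$obj * 1 - lb$cls * tcfg$loss_weights[["cls"]],
               2 * (la$total - la$obj - la$cls * tcfg$loss_weights[["cls"]]),
               tolerance = 1e-9)
})

test_that("loss gradients agree with central finite differences", {
  set.seed(3)
  cfg <- head_config(1L)
  tcfg <- train_config(input_size = 64L, batch_size = 2L, epochs = 10L)
  labs <- list(data.frame(class = 0L, cx = 0.45, cy = 0.55,
                          w = 14 / 64, h = 12 / 64),
               data.frame(class = 0L, cx = 0.7, cy = 0.3,
                          w = 30 / 64, h = 40 / 64))
  tg <- assign_targets(labs, cfg, 64L)
  dims <- lapply(c(8L, 4L, 2L), function(G) c(G, G, 18L, 2L))
  lg <- lapply(dims, function(d) array(rnorm(prod(d), sd = 0.5), d))
  ls <- detection_loss(lg, tg, cfg, tcfg)
  f <- function(l) detection_loss(l, tg, cfg, tcfg)$total
  for (si in 1:3) {
    # restrict to objectness/class channels: the coupling of box logits
    # into the detached IoU objectness target is invisible to the
    # analytic gradient by design
    d <- dim(lg[[si]])
    chs <- as.vector(outer(c(5L, 6L), (0:2) * 6L, `+`))
    pool <- which(slice.index(array(seq_len(prod(d)), d), 3) %in% chs)
    idx <- unique(c(intersect(which(abs(ls$grads[[si]]) > 1e-5),
                              pool)[1:4],
                    sample(pool, 3)))
    idx <- idx[!is.na(idx)]
    for (i in idx) {
      eps <- 1e-4
      lp <- lg; lp[[si]][i] <- lp[[si]][i] + eps
      lm <- lg; lm[[si]][i] <- lm[[si]][i] - eps
      num <- (f(lp) - f(lm)) / (2 * eps) * 2  # batch-sum convention (N = 2)
      expect_equal(ls$grads[[si]][i], num,
                   tolerance = max(1e-4, 5e-3 * abs(num)))
    }
  }
})

test_that("a short training run honors the loop contract", {
  set.seed(20)
  cfg <- tiny_scene_cfg()
  ds <- generate_scenes(cfg, n_videos = 4L, frames_per_video = 4L)
  tr <- ds[1:12]; te <- ds[13:16]
  tc <- train_config(input_size = 160L, batch_size = 4L, epochs = 2L,
                     warmup_epochs = 0L, seed = 42L)
  model <- build_model(seed = 42L)
  out_dir <- withr::local_tempdir()
  res <- train(model, tr, tc, val_dataset = te, out_dir = out_dir,
               verbose = FALSE)
  expect_identical(nrow(res$history), 2L)
  expect_true(file.exists(file.path(out_dir, "checkpoint.rds")))
  expect_true(file.exists(file.path(out_dir, "metrics.csv")))
  expect_true(all(is.finite(res$history$total)))
  # best-mAP retention: best >= last tracked value
  expect_gte(res$best_map, res$history$map50[2])
  # determinism: same seed, same data -> identical epoch-1 loss
  model2 <- build_model(seed = 42L)
  res2 <- train(model2, tr, tc, val_dataset = NULL, verbose = FALSE)
  model3 <- build_model(seed = 42L)
  res3 <- train(model3, tr, tc, val_dataset = NULL, verbose = FALSE)
  expect_identical(res2$history$total[1], res3$history$total[1])
  expect_error(train(model, list(), tc), "empty")
  # checkpoint round-trip preserves behavior
  m4 <- load_checkpoint(file.path(out_dir, "checkpoint.rds"))
  x <- array(runif(160 * 160 * 3), c(160, 160, 3, 1))
  expect_equal(m4$forward_logits(x)[[1]],
               res$model$forward_logits(x)[[1]], tolerance = 1e-6)
})

test_that("200 optimizer steps halve the loss on a trivially easy batch", {
  set.seed(30)
  # single fixed canvas with one large high-contrast target; overfit probe
  cfg <- scene_config(canvas = c(160L, 160L), n_animals = c(0L, 0L),
                      mounting_pairs = c(1L, 1L), scale = c(0.3, 0.4),
                      overlap = 0.3, night_prob = 0)
  s <- generate_scene(cfg)
  s <- resize_sample(s, 96L, 96L)
  model <- build_model(seed = 30L)
  tc <- train_config(input_size = 96L, batch_size = 1L, epochs = 10L)
  x <- mountdetect:::stack_batch(list(s))
  tg <- assign_targets(list(s$boxes), model$cfg, 96L)
  first <- NA_real_; last <- NA_real_
  for (step in 1:200) {
    lg <- model$forward_logits(x, train = TRUE)
    ls <- detection_loss(lg, tg, model$cfg, tc)
    if (step == 1L) first <- ls$total
    last <- ls$total
    mountdetect:::zero_grads(model)
    model$backward_logits(ls$grads)
    mountdetect:::sgd_step(model, 0.01, tc$momentum, tc$weight_decay)
  }
  expect_lt(last, 0.5 * first)
})
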