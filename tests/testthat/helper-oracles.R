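# Independent oracles used across the suite. These deliberately take
# different routes than the package code they check.

# brute-force trainable-parameter count: walk every parameter container in
# the module tree and sum element counts
oracle_param_count <- function(m) {
  n <- sum(vapply(m$params, length, integer(1)))
  for (ch in m$children) n <- n + oracle_param_count(ch)
  as.integer(n)
}

# quadratic greedy matcher: explicit IoU matrix, confidence-desc visiting
oracle_match <- function(dets, gts, thr) {
  if (nrow(dets) == 0L)
    return(list(tp = logical(0), conf = numeric(0), n_gt = nrow(gts)))
  ord <- order(-dets$conf, -(dets$w * dets$h))
  dets <- dets[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(gts))
  tp <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    best <- 0; bj <- 0L
    for (j in seq_len(nrow(gts))) {
      if (used[j] || gts$image[j] != dets$image[i] ||
          gts$class[j] != dets$class[i]) next
      ov <- iou(as.numeric(dets[i, c("cx", "cy", "w", "h")]),
                as.numeric(gts[j, c("cx", "cy", "w", "h")]))
      if (ov > best) { best <- ov; bj <- j }
    }
    if (bj > 0L && best >= thr) { tp[i] <- TRUE; used[bj] <- TRUE }
  }
  list(tp = tp, conf = dets$conf, n_gt = nrow(gts))
}

# AP by enumerating every confidence cutoff and integrating the enveloped
# PR polyline (all-point)
oracle_ap <- function(dets, gts, thr) {
  if (nrow(gts) == 0L) return(NA_real_)
  m <- oracle_match(dets, gts, thr)
  K <- length(m$tp)
  if (K == 0L) return(0)
  P <- R <- numeric(K)
  for (k in seq_len(K)) {
    tpk <- sum(m$tp[seq_len(k)])
    P[k] <- tpk / k
    R[k] <- tpk / m$n_gt
  }
  penv <- numeric(K)
  for (k in seq_len(K)) penv[k] <- max(P[k:K])
  ap <- R[1] * penv[1]
  if (K > 1L)
    for (k in 2:K) ap <- ap + (R[k] - R[k - 1]) * penv[k]
  ap
}

# random small detection/ground-truth scene for metric property tests
random_scene_pair <- function(n_gt_max = 5L, n_det_max = 10L) {
  n_gt <- sample.int(n_gt_max, 1L)
  gts <- data.frame(image = 1L, class = sample(0:1, n_gt, replace = TRUE),
                    cx = runif(n_gt, 0.2, 0.8), cy = runif(n_gt, 0.2, 0.8),
                    w = runif(n_gt, 0.05, 0.3), h = runif(n_gt, 0.05, 0.3))
  n_det <- sample.int(n_det_max, 1L)
  base <- gts[sample.int(n_gt, n_det, replace = TRUE), , drop = FALSE]
  dets <- data.frame(image = 1L, class = base$class,
                     cx = pmin(pmax(base$cx + rnorm(n_det, 0, 0.05), 0), 1),
                     cy = pmin(pmax(base$cy + rnorm(n_det, 0, 0.05), 0), 1),
                     w = pmax(base$w * runif(n_det, 0.7, 1.3), 0.01),
                     h = pmax(base$h * runif(n_det, 0.7, 1.3), 0.01),
                     conf = runif(n_det))
  list(dets = dets, gts = gts)
}

# tiny scene configuration for fast augmentation/generator tests
tiny_scene_cfg <- function() {
  scene_config(canvas = c(256L, 144L), n_animals = c(2L, 5L),
               mounting_pairs = c(1L, 2L), scale = c(0.08, 0.2),
               overlap = 0.3, night_prob = 0.3)
}
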