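test_that("C3ECAGhost has the contracted structure and accounting", {
  set.seed(1)
  m <- make_c3ecaghost(32L, 32L, n_bottlenecks = 3L)
  # branch 1 carries exactly 3 ghost bottlenecks after its lateral CBS
  expect_identical(sum(vapply(m$children[[1]]$children, function(ch)
    ch$type == "residual", logical(1))), 3L)
  expect_identical(module_param_count(m), oracle_param_count(m))
  x <- array(rnorm(16 * 16 * 32 * 2), c(16, 16, 32, 2))
  expect_identical(tensor_dim(m$forward(x)), c(16L, 16L, 32L, 2L))
  expect_error(make_c3ecaghost(32L, 31L), "even")
})

test_that("the neck emits width, 2*width, 4*width maps on matching grids", {
  set.seed(1)
  nk <- build_neck(c(32L, 16L, 512L), width = 64L)
  expect_identical(nk$widths, c(64L, 128L, 256L))
  taps <- list(p3 = array(rnorm(16 * 16 * 32), c(16, 16, 32, 1)),
               p4 = array(rnorm(8 * 8 * 16), c(8, 8, 16, 1)),
               p5 = array(rnorm(4 * 4 * 512), c(4, 4, 512, 1)))
  ns <- nk$forward_taps(taps)
  expect_identical(tensor_dim(ns$n3)[1:3], c(16L, 16L, 64L))
  expect_identical(tensor_dim(ns$n4)[1:3], c(8L, 8L, 128L))
  expect_identical(tensor_dim(ns$n5)[1:3], c(4L, 4L, 256L))
  # all four enhancement positions are C3ECAGhost instances
  expect_identical(sum(vapply(nk$children, function(ch)
    ch$type == "c3ecaghost", logical(1))), 4L)
})

test_that("heads output 3*(5+nc) channels of raw logits", {
  set.seed(1)
  hd <- build_heads(head_config(1L), c(16L, 32L, 64L))
  ns <- list(n3 = array(rnorm(8 * 8 * 16), c(8, 8, 16, 1)),
             n4 = array(rnorm(4 * 4 * 32), c(4, 4, 32, 1)),
             n5 = array(rnorm(2 * 2 * 64), c(2, 2, 64, 1)))
  lg <- hd$forward_taps(ns)
  expect_identical(vapply(lg, function(l) tensor_dim(l)[3], integer(1)),
                   rep(18L, 3))
  # 1x1 conv accounting: in * 18 + 18 per scale
  expect_identical(vapply(hd$children, module_param_count, integer(1)),
                   c(16L, 32L, 64L) * 18L + 18L)
})

test_that("the full 1-class model's parameters round to 2.0 M", {
  set.seed(1)
  model <- build_model(num_classes = 1L)
  total <- module_param_count(model)
  expect_identical(round(total / 1e6, 1), 2.0)
  expect_identical(oracle_param_count(model), total)
})

test_that("zero logits decode to the anchor prior at cell centers", {
  cfg <- head_config(1L)
  lg <- lapply(c(8L, 4L, 2L), function(G) array(0, c(G, G, 18, 1)))
  det <- decode(lg, cfg)[[1]]
  # cell (0,0), anchor (10,13), stride 8: center (4,4), size anchor,
  # confidence 0.5 * 0.5
  r <- det[det[, "cx"] == 4 & det[, "cy"] == 4 & det[, "w"] == 10, ,
           drop = FALSE]
  expect_identical(nrow(r), 1L)
  expect_equal(unname(r[1, c("cy", "h", "conf")]), c(4, 13, 0.25))
  # centers within [-0.5 stride, S + 0.5 stride]; sizes <= 4 * anchor
  expect_true(all(det[, "cx"] >= -4 & det[, "cx"] <= 64 + 4))
  expect_true(all(det[, "w"] <= 4 * 373))
})

test_that("decode is inverted by encode for in-range boxes", {
  set.seed(2)
  cfg <- head_config(1L)
  for (i in 1:20) {
    cell <- c(sample(0:6, 1), sample(0:6, 1))
    anchor <- cfg$anchors[[1]][sample(1:3, 1), ]
    box <- c((cell[1] + runif(1, -0.3, 1.2)) * 8,
             (cell[2] + runif(1, -0.3, 1.2)) * 8,
             anchor[1] * runif(1, 0.3, 3.5), anchor[2] * runif(1, 0.3, 3.5))
    t <- encode_box(box, cell, anchor, 8)
    sx <- 1 / (1 + exp(-t))
    back <- c((2 * sx[1] - 0.5 + cell[1]) * 8,
              (2 * sx[2] - 0.5 + cell[2]) * 8,
              (2 * sx[3])^2 * anchor[1], (2 * sx[4])^2 * anchor[2])
    expect_equal(back, box, tolerance = 1e-5)
  }
})

test_that("batch order permutes outputs identically", {
  set.seed(3)
  model <- build_model(width = 16L, seed = 5)
  x <- array(runif(64 * 64 * 3 * 3), c(64, 64, 3, 3))
  lg <- model$forward_logits(x)
  perm <- c(3L, 1L, 2L)
  lgp <- model$forward_logits(x[, , , perm, drop = FALSE])
  for (si in 1:3)
    expect_equal(lgp[[si]], lg[[si]][, , , perm, drop = FALSE],
                 tolerance = 1e-5)
})
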