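test_that("silu matches its closed form and known values", {
  expect_equal(silu(0), 0)
  expect_equal(1 / (1 + exp(0)), 0.5)
  expect_equal(silu(1), 0.731059, tolerance = 1e-5)
  # smooth, non-monotonic: minimum near x = -1.278 with value ~ -0.278
  grid <- seq(-5, 5, by = 1e-3)
  v <- silu(grid)
  expect_equal(grid[which.min(v)], -1.278, tolerance = 1e-2)
  expect_lt(abs(min(v) - (-0.278)), 1e-3)
})

test_that("block parameter counts reproduce the printed and derived values", {
  set.seed(1)
  cases <- list(
    list(make_cbs(block_descriptor("CBS", 3, 16, stride = 2)), 464L),
    list(make_fused_mbconv(block_descriptor("FusedMBConv", 16, 16,
                                            expansion = 1)), 2336L),
    list(make_fused_mbconv(block_descriptor("FusedMBConv", 16, 24,
                                            stride = 2, expansion = 4)),
         10928L),
    list(make_fused_mbconv(block_descriptor("FusedMBConv", 24, 24,
                                            expansion = 4)), 23280L),
    list(make_mbconv(block_descriptor("MBConv", 32, 16, stride = 2,
                                      expansion = 4)), 7840L),
    list(make_mbconv(block_descriptor("MBConv", 16, 24, stride = 2,
                                      expansion = 6)), 5136L),
    list(make_mbconv(block_descriptor("MBConv", 24, 24, expansion = 6)),
         8832L),  # 26,496 printed for 3 identical blocks
    list(make_se(128, 1 / 4), 8352L),
    list(make_ghost_conv(block_descriptor("GhostConv", 64, 64, kernel = 1,
                                          ghost_ratio = 2)), 2464L),
    list(make_eca(64, 3), 3L),
    list(make_sppf(32, 16, 512, 5), 34336L)
  )
  for (cs in cases) {
    expect_identical(module_param_count(cs[[1]]), cs[[2]])
    expect_identical(oracle_param_count(cs[[1]]), cs[[2]])
  }
})

test_that("parameter accounting equals the brute-force weight walk on random blocks", {
  set.seed(42)
  for (i in 1:50) {
    kind <- sample(c("CBS", "MBConv", "FusedMBConv", "GhostConv",
                     "GhostBottleneck", "SE", "ECA", "SPPF"), 1)
    cin <- sample(c(4L, 8L, 16L, 24L), 1)
    cout <- sample(c(8L, 16L, 32L), 1)
    blk <- switch(kind,
      CBS = make_cbs(block_descriptor("CBS", cin, cout,
                                      stride = sample(1:2, 1))),
      MBConv = make_mbconv(block_descriptor(
        "MBConv", cin, cout, stride = sample(1:2, 1),
        expansion = sample(c(2, 4, 6), 1),
        se_ratio = sample(c(0, 0.25), 1))),
      FusedMBConv = make_fused_mbconv(block_descriptor(
        "FusedMBConv", cin, cout, stride = sample(1:2, 1),
        expansion = sample(c(1, 2, 4), 1))),
      GhostConv = make_ghost_conv(block_descriptor(
        "GhostConv", cin, cout, kernel = 1, ghost_ratio = 2)),
      GhostBottleneck = make_ghost_bottleneck(block_descriptor(
        "GhostBottleneck", cin, cout, stride = sample(1:2, 1),
        expansion = 2)),
      SE = make_se(cin, 0.25),
      ECA = make_eca(cin, 3),
      SPPF = make_sppf(cin, cin %/% 2L, cout))
    expect_identical(module_param_count(blk), oracle_param_count(blk),
                     label = paste("kind", kind, cin, cout))
  }
})

test_that("descriptor invariants are enforced", {
  expect_error(block_descriptor("CBS", 3, 16, kernel = 4), "odd")
  expect_error(block_descriptor("CBS", 3, 16, stride = 3), "stride")
  expect_error(block_descriptor("GhostConv", 16, 15, ghost_ratio = 2),
               "divisible")
  expect_error(make_se(0), "channels")
  expect_error(make_eca(16, 4), "odd")
  expect_error(make_fused_mbconv(block_descriptor("FusedMBConv", 5, 16,
                                                  expansion = 2.5)),
               "integer")
})

test_that("blocks preserve or transform shapes as contracted", {
  set.seed(2)
  x <- array(rnorm(16 * 16 * 16 * 2), c(16, 16, 16, 2))
  cbs1 <- make_cbs(block_descriptor("CBS", 16, 16, stride = 1, kernel = 1))
  expect_identical(tensor_dim(cbs1$forward(x)), c(16L, 16L, 16L, 2L))
  cbs2 <- make_cbs(block_descriptor("CBS", 16, 8, stride = 2))
  expect_identical(tensor_dim(cbs2$forward(x)), c(8L, 8L, 8L, 2L))
  # stride-2 halving from 3-channel input, per the stated 640 -> 320 map
  x640 <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  c0 <- make_cbs(block_descriptor("CBS", 3, 16, stride = 2))
  expect_identical(tensor_dim(c0$forward(x640)), c(32L, 32L, 16L, 1L))
  se <- make_se(16, 0.25)
  expect_identical(tensor_dim(se$forward(x)), dim(x))
  eca <- make_eca(16, 3)
  expect_identical(tensor_dim(eca$forward(x)), dim(x))
  gc_ <- make_ghost_conv(block_descriptor("GhostConv", 16, 24, kernel = 1,
                                          ghost_ratio = 2))
  expect_identical(tensor_dim(gc_$forward(x))[3], 24L)
  gb2 <- make_ghost_bottleneck(block_descriptor("GhostBottleneck", 16, 24,
                                                stride = 2))
  expect_identical(tensor_dim(gb2$forward(x)), c(8L, 8L, 24L, 2L))
  sp <- make_sppf(16, 8, 64)
  expect_identical(tensor_dim(sp$forward(x)), c(16L, 16L, 64L, 2L))
})

test_that("gating blocks map all-zero inputs to all-zero outputs", {
  set.seed(3)
  z <- array(0, c(8, 8, 16, 1))
  expect_true(all(as_array(make_se(16, 0.25)$forward(z)) == 0))
  expect_true(all(as_array(make_eca(16, 3)$forward(z)) == 0))
})

test_that("stride-1 equal-width blocks are residual", {
  set.seed(4)
  # with the final BN scale zeroed, the inner path vanishes and the
  # shortcut returns the input unchanged
  for (builder in list(
    function() make_fused_mbconv(block_descriptor("FusedMBConv", 16, 16,
                                                  expansion = 4)),
    function() make_mbconv(block_descriptor("MBConv", 16, 16,
                                            expansion = 4)),
    function() make_ghost_bottleneck(block_descriptor(
      "GhostBottleneck", 16, 16, expansion = 2)))) {
    blk <- builder()
    expect_identical(blk$type, "residual")
    inner <- blk$children[[1]]
    # zero every BN scale/shift: the inner path then maps any input to 0
    # (concat branches included), leaving only the shortcut
    bns <- Filter(function(m) m$type == "bn",
                  mountdetect:::collect_param_modules(inner))
    for (bn in bns) {
      bn$params$gamma[] <- 0
      bn$params$beta[] <- 0
    }
    x <- array(rnorm(8 * 8 * 16), c(8, 8, 16, 1))
    expect_equal(as_array(blk$forward(x)), x, tolerance = 1e-5)
  }
})

test_that("ghost accounting reproduces the analytic counts and ratios", {
  acct <- ghost_accounting(c = 64, n = 64, s = 2, k = 3, d = 3)
  expect_identical(acct$p1, 36864)
  expect_identical(acct$p2, 18720)
  r <- ghost_ratios(acct)
  expect_equal(r[["p_ratio"]], 36864 / 18720)
  expect_equal(r[["p_ratio"]], 1.9692, tolerance = 1e-4)
  # k = d makes the spatial factor cancel: p_ratio == q_ratio
  for (hw in list(c(1, 1), c(20, 20), c(7, 13))) {
    a <- ghost_accounting(64, 64, 2, 3, 3, hw[1], hw[2])
    rr <- ghost_ratios(a)
    expect_equal(rr[["p_ratio"]], rr[["q_ratio"]])
  }
  # p_ratio in [1, s] (equal to c at k = d for small c, so exactly 1 at
  # c = 1), increasing toward s with c
  for (s in c(2L, 3L, 4L)) {
    prev <- 1
    for (cc in c(1, 4, 16, 64, 256, 1024)) {
      rr <- ghost_ratios(ghost_accounting(cc, 12 * s, s, 3, 3))
      expect_gte(rr[["p_ratio"]], 1)
      expect_lte(rr[["p_ratio"]], s)
      expect_gte(rr[["p_ratio"]], prev)
      prev <- rr[["p_ratio"]]
    }
  }
  # c -> infinity limit: ratio -> s
  r6 <- ghost_ratios(ghost_accounting(1e6, 3 * 12, 3, 3, 3))
  expect_equal(r6[["p_ratio"]], 3, tolerance = 1e-3)
})

test_that("ghost convolution block ratio is consistent with the formulas", {
  set.seed(5)
  # constructed block (with its BN terms) lands close to the analytic 1/s
  blk <- make_ghost_conv(block_descriptor("GhostConv", 64, 64, kernel = 3,
                                          ghost_ratio = 2, cheap_kernel = 3))
  trad <- 64 * 64 * 9
  ratio <- trad / module_param_count(blk)
  expect_gte(ratio, 1.9)
  expect_lte(ratio, 2.0)
})
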