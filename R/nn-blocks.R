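# ---------------------------------------------------------------------------
# Building blocks of the lightweight detector: CBS units, squeeze-and-
# excitation, inverted residual blocks (MBConv / Fused-MBConv), Ghost
# convolution and Ghost bottlenecks, efficient channel attention (ECA), and
# fast spatial pyramid pooling (SPPF) -- plus the exact trainable-parameter
# accounting and the analytic Ghost parameter/FLOP ratios.
# ---------------------------------------------------------------------------

#' SiLU activation
#'
#' `silu(x) = x * sigmoid(x)`, the smooth non-monotonic activation used in
#' every convolution unit of the model.
#'
#' @param x numeric vector/array
#' @return numeric of the same shape
#' @export
silu <- function(x) x * fast_sigmoid(x)

#' Block descriptor
#'
#' Declarative description of one building block; validated against the
#' block-family invariants (odd kernels, stride 1 or 2, Ghost divisibility).
#'
#' @param kind one of `"CBS"`, `"SE"`, `"MBConv"`, `"FusedMBConv"`,
#'   `"GhostConv"`, `"GhostBottleneck"`, `"ECA"`, `"SPPF"`
#' @param in_channels,out_channels positive integers
#' @param stride 1 or 2
#' @param kernel odd positive integer (primary kernel)
#' @param expansion expansion ratio for the inverted residual blocks
#' @param se_ratio squeeze-and-excitation reduction ratio; 0 disables SE
#' @param ghost_ratio Ghost ratio `s` (integer >= 2)
#' @param cheap_kernel odd kernel `d` of the Ghost cheap operation
#' @return a `block_descriptor` list
#' @export
block_descriptor <- function(kind, in_channels, out_channels, stride = 1L,
                             kernel = 3L, expansion = 1, se_ratio = 0,
                             ghost_ratio = 2L, cheap_kernel = 3L) {
  kinds <- c("CBS", "SE", "MBConv", "FusedMBConv", "GhostConv",
             "GhostBottleneck", "ECA", "SPPF")
  kind <- match.arg(kind, kinds)
  if (in_channels < 1L || out_channels < 1L) stop("channels must be positive")
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  if (kernel %% 2L == 0L) stop("kernel must be odd")
  if (cheap_kernel %% 2L == 0L) stop("cheap_kernel must be odd")
  if (se_ratio < 0) stop("se_ratio must be non-negative")
  if (kind == "GhostConv") {
    if (ghost_ratio < 2L) stop("ghost_ratio s must be an integer >= 2")
    if (out_channels %% ghost_ratio != 0L)
      stop("out_channels must be divisible by ghost_ratio s")
  }
  structure(list(kind = kind, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 stride = as.integer(stride), kernel = as.integer(kernel),
                 expansion = expansion, se_ratio = se_ratio,
                 ghost_ratio = as.integer(ghost_ratio),
                 cheap_kernel = as.integer(cheap_kernel)),
            class = "block_descriptor")
}

# Conv + BN + SiLU, the basic unit. Convolutions followed by a norm layer
# are bias-free (required to reproduce the printed per-layer counts).
cbs <- function(cin, cout, k = 1L, stride = 1L, groups = 1L, act = TRUE) {
  layers <- list(nn_conv(cin, cout, k, stride, groups = groups),
                 nn_bn(cout))
  if (act) layers <- c(layers, list(nn_silu_act()))
  m <- do.call(nn_seq, layers)
  m$type <- "cbs"
  m$cout <- cout
  m
}

#' Construct a CBS block (convolution + batch norm + SiLU)
#'
#' @param desc a [block_descriptor()] with `kind = "CBS"`
#' @return an `nn_module`
#' @export
make_cbs <- function(desc) {
  stopifnot(inherits(desc, "block_descriptor"), desc$kind == "CBS")
  cbs(desc$in_channels, desc$out_channels, desc$kernel, desc$stride)
}

#' Construct a squeeze-and-excitation gate
#'
#' Global average pool, linear reduce (with bias), SiLU, linear expand
#' (with bias), sigmoid, channelwise multiply with the input.
#'
#' @param channels number of feature channels
#' @param se_ratio hidden width ratio; hidden = max(1, round(channels * se_ratio))
#' @return an `nn_module`
#' @export
make_se <- function(channels, se_ratio = 0.25) {
  if (channels < 1L) stop("channels must be >= 1")
  hidden <- max(1L, as.integer(round(channels * se_ratio)))
  m <- new_module("se")
  fc1 <- nn_conv(channels, hidden, 1L, bias = TRUE)
  a1 <- nn_silu_act()
  fc2 <- nn_conv(hidden, channels, 1L, bias = TRUE)
  gate <- nn_sigmoid_act()
  m$children <- list(fc1, a1, fc2, gate)
  m$forward <- function(x, train = FALSE) {
    x <- as_ft(x)
    d <- cpp_fdim(x)
    v <- cpp_gap_fwd(x)
    vt <- cpp_d2f(array(v, c(1L, 1L, d[3], d[4])))
    g <- gate$forward(fc2$forward(a1$forward(fc1$forward(vt, train),
                                             train), train), train)
    gv <- as.vector(as_array(g))
    if (train) m$cache <- list(x = x, g = gv, d = d)
    cpp_bcast_mul(x, gv)
  }
  m$backward <- function(gy) {
    x <- m$cache$x
    d <- m$cache$d
    gx <- cpp_bcast_mul(gy, m$cache$g)
    gg <- cpp_d2f(array(cpp_plane_dot(gy, x), c(1L, 1L, d[3], d[4])))
    gv <- fc1$backward(a1$backward(fc2$backward(gate$backward(gg))))
    # adjoint of the global average pool: spread gv / (H*W)
    cpp_bcast_addscaled(gx, as.vector(as_array(gv)))
  }
  m
}

# residual wrapper: y = inner(x) + x
residual <- function(inner) {
  m <- new_module("residual")
  m$children <- list(inner)
  m$forward <- function(x, train = FALSE) {
    x <- as_ft(x)
    cpp_add(inner$forward(x, train), x)
  }
  m$backward <- function(gy) cpp_add(inner$backward(gy), gy)
  m
}

#' Construct a Fused-MBConv block
#'
#' Expansion 1: a single 3x3 Conv+BN+SiLU. Expansion e > 1: 3x3 Conv+BN+SiLU
#' expanding to `e * in` channels, then a linear 1x1 Conv+BN projection.
#' An identity shortcut is added iff stride 1 and in = out. Optional SE
#' (before the projection) when `se_ratio > 0`.
#'
#' @param desc a [block_descriptor()] with `kind = "FusedMBConv"`
#' @return an `nn_module`
#' @export
make_fused_mbconv <- function(desc) {
  stopifnot(inherits(desc, "block_descriptor"), desc$kind == "FusedMBConv")
  cin <- desc$in_channels; cout <- desc$out_channels
  e <- desc$expansion
  mid <- cin * e
  if (mid != as.integer(mid)) stop("expansion * in_channels must be integer")
  mid <- as.integer(mid)
  if (e < 1) stop("expansion must be >= 1")
  if (e == 1) {
    inner <- cbs(cin, cout, 3L, desc$stride)
  } else {
    layers <- list(cbs(cin, mid, 3L, desc$stride))
    if (desc$se_ratio > 0)
      layers <- c(layers, list(make_se(mid, desc$se_ratio)))
    layers <- c(layers, list(cbs(mid, cout, 1L, 1L, act = FALSE)))
    inner <- do.call(nn_seq, layers)
  }
  inner$type <- "fused_mbconv"
  if (desc$stride == 1L && cin == cout) residual(inner) else inner
}

#' Construct an MBConv (inverted residual) block
#'
#' 1x1 Conv+BN+SiLU expand, 3x3 depthwise Conv+BN+SiLU (carrying the
#' stride), optional SE, then a linear 1x1 Conv+BN projection; identity
#' shortcut iff stride 1 and in = out.
#'
#' @param desc a [block_descriptor()] with `kind = "MBConv"`
#' @return an `nn_module`
#' @export
make_mbconv <- function(desc) {
  stopifnot(inherits(desc, "block_descriptor"), desc$kind == "MBConv")
  cin <- desc$in_channels; cout <- desc$out_channels
  e <- desc$expansion
  mid <- cin * e
  if (mid != as.integer(mid)) stop("expansion * in_channels must be integer")
  mid <- as.integer(mid)
  layers <- list(cbs(cin, mid, 1L, 1L),
                 cbs(mid, mid, 3L, desc$stride, groups = mid))
  if (desc$se_ratio > 0)
    layers <- c(layers, list(make_se(mid, desc$se_ratio)))
  layers <- c(layers, list(cbs(mid, cout, 1L, 1L, act = FALSE)))
  inner <- do.call(nn_seq, layers)
  inner$type <- "mbconv"
  if (desc$stride == 1L && cin == cout) residual(inner) else inner
}

#' Construct a Ghost convolution
#'
#' A primary k x k convolution produces `out/s` intrinsic maps; a cheap
#' depthwise d x d operation derives the remaining `(s-1) * out/s` ghost
#' maps; the output is their concatenation (primary maps first).
#'
#' @param desc a [block_descriptor()] with `kind = "GhostConv"`
#' @param act apply SiLU after each stage (`FALSE` for the linear
#'   projection inside a Ghost bottleneck)
#' @return an `nn_module`
#' @export
make_ghost_conv <- function(desc, act = TRUE) {
  stopifnot(inherits(desc, "block_descriptor"), desc$kind == "GhostConv")
  cin <- desc$in_channels; cout <- desc$out_channels
  s <- desc$ghost_ratio
  if (cout %% s != 0L) stop("out_channels must be divisible by ghost_ratio s")
  mprim <- cout %/% s
  nghost <- cout - mprim
  primary <- cbs(cin, mprim, desc$kernel, desc$stride, act = act)
  cheap <- cbs(mprim, nghost, desc$cheap_kernel, 1L, groups = mprim,
               act = act)
  m <- new_module("ghost_conv")
  m$children <- list(primary, cheap)
  m$mprim <- mprim; m$nghost <- nghost
  m$forward <- function(x, train = FALSE) {
    p <- primary$forward(x, train)
    g <- cheap$forward(p, train)
    concat_channels(list(p, g))
  }
  m$backward <- function(gy) {
    gs <- split_channels(gy, c(m$mprim, m$nghost))
    primary$backward(cpp_add(gs[[1]], cheap$backward(gs[[2]])))
  }
  m
}

#' Construct a Ghost bottleneck
#'
#' GhostConv expand (to `expansion * in` hidden channels), a 3x3 depthwise
#' Conv+BN when stride 2, then a linear GhostConv projection. Shortcut:
#' identity when stride 1 and in = out, otherwise a depthwise + pointwise
#' downsample path.
#'
#' @param desc a [block_descriptor()] with `kind = "GhostBottleneck"`
#' @return an `nn_module`
#' @export
make_ghost_bottleneck <- function(desc) {
  stopifnot(inherits(desc, "block_descriptor"),
            desc$kind == "GhostBottleneck")
  cin <- desc$in_channels; cout <- desc$out_channels
  e <- if (desc$expansion >= 1) desc$expansion else 2
  hidden <- as.integer(cin * e)
  s <- desc$ghost_ratio; d <- desc$cheap_kernel
  gd <- function(ci, co) block_descriptor("GhostConv", ci, co,
                                          kernel = 1L, ghost_ratio = s,
                                          cheap_kernel = d)
  gc1 <- make_ghost_conv(gd(cin, hidden), act = TRUE)
  gc2 <- make_ghost_conv(gd(hidden, cout), act = FALSE)
  main_layers <- list(gc1)
  if (desc$stride == 2L)
    main_layers <- c(main_layers,
                     list(cbs(hidden, hidden, 3L, 2L, groups = hidden,
                              act = FALSE)))
  main_layers <- c(main_layers, list(gc2))
  main <- do.call(nn_seq, main_layers)
  main$type <- "ghost_bottleneck_main"
  if (desc$stride == 1L && cin == cout) return(residual(main))
  short <- nn_seq(cbs(cin, cin, 3L, desc$stride, groups = cin, act = FALSE),
                  cbs(cin, cout, 1L, 1L, act = FALSE))
  m <- new_module("ghost_bottleneck")
  m$children <- list(main, short)
  m$forward <- function(x, train = FALSE) {
    x <- as_ft(x)
    cpp_add(main$forward(x, train), short$forward(x, train))
  }
  m$backward <- function(gy) cpp_add(main$backward(gy), short$backward(gy))
  m
}

#' Construct an efficient channel attention (ECA) gate
#'
#' Global average pooling followed by a shared 1-D convolution of width `k`
#' across the channel axis (no bias, no dimensionality reduction) and a
#' sigmoid channelwise gate. Exactly `k` trainable parameters.
#'
#' @param channels number of feature channels (for documentation only; the
#'   1-D kernel is shared by all channels)
#' @param k odd 1-D kernel width (default 3)
#' @return an `nn_module`
#' @export
make_eca <- function(channels, k = 3L) {
  if (k %% 2L == 0L) stop("ECA kernel must be odd")
  m <- new_module("eca")
  m$k <- as.integer(k)
  m$params$w <- stats::rnorm(k, sd = 0.1)
  m$grads$w <- numeric(k)
  m$param_count <- as.integer(k)
  half <- (k - 1L) %/% 2L
  conv1d <- function(v, w) {
    # v: C x N matrix, zero-padded correlation along the channel axis
    C <- nrow(v)
    z <- matrix(0, C, ncol(v))
    for (j in seq_len(k)) {
      off <- j - 1L - half
      src <- seq_len(C) + off
      ok <- src >= 1L & src <= C
      z[ok, ] <- z[ok, ] + w[j] * v[src[ok], , drop = FALSE]
    }
    z
  }
  m$forward <- function(x, train = FALSE) {
    x <- as_ft(x)
    d <- cpp_fdim(x)
    v <- matrix(cpp_gap_fwd(x), d[3], d[4])
    z <- conv1d(v, m$params$w)
    g <- fast_sigmoid(z)
    if (train) m$cache <- list(x = x, v = v, g = g)
    cpp_bcast_mul(x, as.vector(g))
  }
  m$backward <- function(gy) {
    x <- m$cache$x; v <- m$cache$v; g <- m$cache$g
    gx <- cpp_bcast_mul(gy, as.vector(g))
    gg <- matrix(cpp_plane_dot(gy, x), nrow(v), ncol(v))
    gz <- gg * g * (1 - g)
    C <- nrow(v)
    for (j in seq_len(m$k)) {
      off <- j - 1L - half
      src <- seq_len(C) + off
      ok <- src >= 1L & src <= C
      m$grads$w[j] <- m$grads$w[j] +
        sum(gz[ok, , drop = FALSE] * v[src[ok], , drop = FALSE])
    }
    gv <- conv1d(gz, rev(m$params$w))
    # adjoint of the global average pool: spread gv / (H*W)
    cpp_bcast_addscaled(gx, as.vector(gv))
  }
  m
}

#' Construct a fast spatial pyramid pooling (SPPF) block
#'
#' 1x1 CBS to `hidden` channels, three cascaded stride-1 max pools, channel
#' concatenation of the four maps, and a final 1x1 CBS to `out_ch`.
#'
#' @param in_ch,hidden,out_ch channel widths
#' @param pool_k odd pooling kernel (default 5)
#' @return an `nn_module`
#' @export
make_sppf <- function(in_ch, hidden, out_ch, pool_k = 5L) {
  if (pool_k %% 2L == 0L) stop("pool_k must be odd")
  cv1 <- cbs(in_ch, hidden, 1L, 1L)
  p1 <- nn_maxpool(pool_k); p2 <- nn_maxpool(pool_k); p3 <- nn_maxpool(pool_k)
  cv2 <- cbs(4L * hidden, out_ch, 1L, 1L)
  m <- new_module("sppf")
  m$children <- list(cv1, p1, p2, p3, cv2)
  m$hidden <- hidden
  m$forward <- function(x, train = FALSE) {
    a <- cv1$forward(x, train)
    b <- p1$forward(a, train)
    cc <- p2$forward(b, train)
    d <- p3$forward(cc, train)
    cv2$forward(concat_channels(list(a, b, cc, d)), train)
  }
  m$backward <- function(gy) {
    g <- cv2$backward(gy)
    gs <- split_channels(g, rep(m$hidden, 4L))
    gd <- p3$backward(gs[[4]])
    gc_ <- p2$backward(cpp_add(gs[[3]], gd))
    gb <- p1$backward(cpp_add(gs[[2]], gc_))
    cv1$backward(cpp_add(gs[[1]], gb))
  }
  m
}

#' Parameter accounting report
#'
#' Walks a module's top-level children and reports a per-layer table plus
#' the total, under the fixed accounting convention (bias-free convs where
#' followed by BN, 2 per normalized channel, zero for activations, pooling
#' and running statistics).
#'
#' @param block an `nn_module`
#' @param names optional character vector naming the per-layer rows
#' @return a `param_report`: list with `per_layer` (data.frame: index, name,
#'   params) and `total`
#' @export
count_params <- function(block, names = NULL) {
  kids <- block$children
  if (length(kids) == 0L) kids <- list(block)
  counts <- vapply(kids, module_param_count, integer(1))
  nm <- if (!is.null(names)) names
        else vapply(kids, function(k) k$type, character(1))
  rep <- list(per_layer = data.frame(index = seq_along(counts), name = nm,
                                     params = counts,
                                     stringsAsFactors = FALSE),
              total = as.integer(sum(counts)))
  class(rep) <- "param_report"
  rep
}

#' @export
print.param_report <- function(x, ...) {
  df <- x$per_layer
  cat(sprintf("%-5s %-24s %12s\n", "Layer", "Name", "Params"))
  for (i in seq_len(nrow(df)))
    cat(sprintf("%-5d %-24s %12s\n", df$index[i], df$name[i],
                format(df$params[i], big.mark = ",")))
  cat(sprintf("%-5s %-24s %12s\n", "", "Total",
              format(x$total, big.mark = ",")))
  invisible(x)
}

#' Analytic Ghost convolution accounting
#'
#' Exact parameter and multiply-accumulate counts of a traditional
#' convolution versus its Ghost decomposition:
#' `p1 = n c k^2`, `p2 = (n/s) c k^2 + (s-1)(n/s) d^2`,
#' `q1 = n h' w' c k^2`, `q2 = (n/s) h' w' c k^2 + (s-1)(n/s) h' w' d^2`.
#'
#' @param c input channels
#' @param n output maps
#' @param s ghost ratio (integer >= 2, divides n)
#' @param k primary kernel
#' @param d cheap-operation kernel
#' @param h_out,w_out output spatial dims (for the MAC counts)
#' @return a `ghost_accounting` list with p1, p2, q1, q2 and the inputs
#' @export
ghost_accounting <- function(c, n, s, k = 3L, d = 3L, h_out = 1L,
                             w_out = 1L) {
  if (s < 2L) stop("s must be >= 2")
  if (n %% s != 0L) stop("n must be divisible by s")
  p1 <- n * c * k * k
  p2 <- (n / s) * c * k * k + (s - 1) * (n / s) * d * d
  q1 <- n * h_out * w_out * c * k * k
  q2 <- (n / s) * h_out * w_out * c * k * k +
    (s - 1) * (n / s) * h_out * w_out * d * d
  structure(list(c = c, n = n, s = s, k = k, d = d, h_out = h_out,
                 w_out = w_out, p1 = p1, p2 = p2, q1 = q1, q2 = q2),
            class = "ghost_accounting")
}

#' Ghost parameter and computation ratios
#'
#' Returns the exact ratios `p1/p2` and `q1/q2`; both approach `s` as the
#' input channel count grows (with `k = d`).
#'
#' @param acct a [ghost_accounting()] object
#' @return named numeric vector `c(p_ratio, q_ratio)`
#' @export
ghost_ratios <- function(acct) {
  stopifnot(inherits(acct, "ghost_accounting"))
  c(p_ratio = acct$p1 / acct$p2, q_ratio = acct$q1 / acct$q2)
}
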