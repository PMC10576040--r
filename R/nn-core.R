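#' @useDynLib mountdetect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head tail write.csv
NULL

# ---------------------------------------------------------------------------
# Minimal define-by-module network engine.
#
# A module is an environment holding parameter arrays, gradient accumulators,
# child modules, and two closures: forward(x, train) and backward(gy).
# Activations flow as single-precision "ftensors" (raw vectors with an
# (H, W, C, N) `fdim` attribute); parameters and user-facing arrays are
# doubles. All heavy kernels live in src/ops.cpp. Backward passes
# accumulate into m$grads by reference, so a whole model is trained by
# walking its primitive modules.
# ---------------------------------------------------------------------------

# logistic function; C++ path for large double arrays
fast_sigmoid <- function(x) {
  if (length(x) > 4096L) cpp_sigmoid(x) else 1 / (1 + exp(-x))
}

# coerce to an ftensor (single-precision raw tensor with an fdim attribute)
as_ft <- function(x) {
  if (is.raw(x)) return(x)
  if (is.null(dim(x))) stop("expected an array input")
  cpp_d2f(x)
}

#' Shape of a tensor (double array or internal single-precision tensor)
#'
#' @param x array or ftensor
#' @return integer (H, W, C, N)
#' @export
tensor_dim <- function(x) {
  if (is.raw(x)) cpp_fdim(x) else {
    d <- dim(x)
    if (length(d) == 3L) c(d, 1L) else d
  }
}

#' Convert an internal single-precision tensor to a double array
#'
#' @param x ftensor (or already an array, returned unchanged)
#' @return numeric (H, W, C, N) array
#' @export
as_array <- function(x) {
  if (is.raw(x)) cpp_f2d(x) else x
}

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$children <- list()
  m$params <- list()
  m$grads <- list()
  m$buffers <- list()
  m$cache <- NULL
  m$param_count <- 0L
  class(m) <- "nn_module"
  m
}

#' @export
print.nn_module <- function(x, ...) {
  cat(sprintf("<nn_module %s: %s trainable parameters>\n",
              x$type, format(module_param_count(x), big.mark = ",")))
  invisible(x)
}

as_t4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array input")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a (H, W, C, N) array")
  x
}

#' Count trainable parameters of a module tree
#'
#' Follows the accounting convention used throughout: convolution weights
#' contribute kernel^2 * in_channels * out_channels / groups, biases only
#' where declared, each normalization layer contributes 2 * channels
#' (scale + shift), and running statistics and activations contribute 0.
#'
#' @param m an `nn_module`
#' @return integer parameter count
#' @export
module_param_count <- function(m) {
  n <- m$param_count
  for (ch in m$children) n <- n + module_param_count(ch)
  as.integer(n)
}

# flat list of every module (depth-first) that owns parameters
collect_param_modules <- function(m, acc = list()) {
  if (length(m$params) > 0L) acc[[length(acc) + 1L]] <- m
  for (ch in m$children) acc <- collect_param_modules(ch, acc)
  acc
}

zero_grads <- function(model) {
  for (m in collect_param_modules(model))
    for (nm in names(m$params)) m$grads[[nm]][] <- 0
  invisible(NULL)
}

# --- primitive layers -------------------------------------------------------

kaiming_init <- function(k, cin_g, cout) {
  fan_in <- k * k * cin_g
  array(stats::rnorm(k * k * cin_g * cout, sd = sqrt(2 / fan_in)),
        dim = c(k, k, cin_g, cout))
}

nn_conv <- function(cin, cout, k = 1L, stride = 1L, pad = k %/% 2L,
                    groups = 1L, bias = FALSE) {
  if (k %% 2L == 0L) stop("convolution kernel must be odd")
  if (cin %% groups != 0L || cout %% groups != 0L)
    stop("channels not divisible by groups")
  m <- new_module("conv")
  m$cin <- cin; m$cout <- cout; m$k <- k; m$stride <- stride
  m$pad <- pad; m$groups <- groups; m$bias <- bias
  m$params$w <- kaiming_init(k, cin %/% groups, cout)
  m$grads$w <- array(0, dim(m$params$w))
  if (bias) {
    m$params$b <- numeric(cout)
    m$grads$b <- numeric(cout)
  }
  m$param_count <- as.integer(k * k * (cin %/% groups) * cout + if (bias) cout else 0L)
  m$forward <- function(x, train = FALSE) {
    x <- as_ft(x)
    if (train) m$cache <- x
    cpp_conv2d_fwd(x, m$params$w, if (bias) m$params$b else NULL,
                   m$stride, m$pad, m$groups)
  }
  m$backward <- function(gy) {
    r <- cpp_conv2d_bwd(m$cache, m$params$w, gy, m$stride, m$pad,
                        m$groups, m$bias)
    m$grads$w <- m$grads$w + r$gw
    if (m$bias) m$grads$b <- m$grads$b + r$gb
    r$gx
  }
  m
}

nn_bn <- function(C, eps = 1e-3, momentum = 0.03) {
  m <- new_module("bn")
  m$C <- C; m$eps <- eps; m$momentum <- momentum
  m$params$gamma <- rep(1, C)
  m$params$beta <- rep(0, C)
  m$grads$gamma <- numeric(C)
  m$grads$beta <- numeric(C)
  m$buffers$run_mean <- rep(0, C)
  m$buffers$run_var <- rep(1, C)
  m$param_count <- as.integer(2L * C)
  m$forward <- function(x, train = FALSE) {
    x <- as_ft(x)
    r <- cpp_bn_fwd(x, m$params$gamma, m$params$beta, m$buffers$run_mean,
                    m$buffers$run_var, m$eps, m$momentum, train)
    if (train) {
      m$buffers$run_mean <- r$run_mean
      m$buffers$run_var <- r$run_var
      m$cache <- list(x = x, mean = r$mean, invstd = r$invstd)
    }
    r$y
  }
  m$backward <- function(gy) {
    r <- cpp_bn_bwd(m$cache$x, gy, m$params$gamma, m$cache$mean,
                    m$cache$invstd)
    m$grads$gamma <- m$grads$gamma + r$ggamma
    m$grads$beta <- m$grads$beta + r$gbeta
    r$gx
  }
  m
}

nn_silu_act <- function() {
  m <- new_module("silu")
  m$forward <- function(x, train = FALSE) {
    x <- as_ft(x)
    if (train) m$cache <- x
    cpp_silu_fwd(x)
  }
  m$backward <- function(gy) cpp_silu_bwd(m$cache, gy)
  m
}

nn_sigmoid_act <- function() {
  m <- new_module("sigmoid")
  m$forward <- function(x, train = FALSE) {
    y <- cpp_sigmoid_fwd(as_ft(x))
    if (train) m$cache <- y
    y
  }
  m$backward <- function(gy) cpp_sigmoid_bwd(m$cache, gy)
  m
}

nn_seq <- function(...) {
  m <- new_module("seq")
  m$children <- list(...)
  m$forward <- function(x, train = FALSE) {
    for (ch in m$children) x <- ch$forward(x, train)
    x
  }
  m$backward <- function(gy) {
    for (ch in rev(m$children)) gy <- ch$backward(gy)
    gy
  }
  m
}

nn_maxpool <- function(k, stride = 1L, pad = k %/% 2L) {
  m <- new_module("maxpool")
  m$k <- k; m$stride <- stride; m$pad <- pad
  m$forward <- function(x, train = FALSE) {
    x <- as_ft(x)
    r <- cpp_maxpool_fwd(x, m$k, m$stride, m$pad)
    if (train) m$cache <- list(argmax = r$argmax, xdim = cpp_fdim(x))
    r$y
  }
  m$backward <- function(gy)
    cpp_maxpool_bwd(gy, m$cache$argmax, m$cache$xdim)
  m
}

nn_upsample2 <- function() {
  m <- new_module("upsample2")
  m$forward <- function(x, train = FALSE) cpp_upsample2_fwd(as_ft(x))
  m$backward <- function(gy) cpp_upsample2_bwd(gy)
  m
}

# channel concatenation of a fixed number of inputs
concat_channels <- function(xs) {
  cpp_concat_channels(lapply(xs, as_ft))
}

split_channels <- function(g, Cs) {
  out <- vector("list", length(Cs))
  at <- 0L
  for (i in seq_along(Cs)) {
    out[[i]] <- cpp_slice_channels(g, at + 1L, at + Cs[i])
    at <- at + Cs[i]
  }
  out
}

# --- optimizers -------------------------------------------------------------

# SGD with momentum; weight decay on convolution weights only.
sgd_step <- function(model, lr, momentum = 0.937, weight_decay = 5e-4) {
  for (m in collect_param_modules(model)) {
    if (is.null(m$vel)) {
      m$vel <- lapply(m$params, function(p) {
        v <- p; v[] <- 0; v
      })
    }
    for (nm in names(m$params)) {
      g <- m$grads[[nm]]
      if (m$type == "conv" && nm == "w" && weight_decay > 0)
        g <- g + weight_decay * m$params[[nm]]
      m$vel[[nm]] <- momentum * m$vel[[nm]] + g
      m$params[[nm]] <- m$params[[nm]] - lr * m$vel[[nm]]
    }
  }
  invisible(NULL)
}

# Adam with decoupled weight decay on convolution weights.
adam_step <- function(model, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 5e-4) {
  for (m in collect_param_modules(model)) {
    if (is.null(m$adam_m)) {
      zero <- function(p) { v <- p; v[] <- 0; v }
      m$adam_m <- lapply(m$params, zero)
      m$adam_v <- lapply(m$params, zero)
      m$adam_t <- 0L
    }
    m$adam_t <- m$adam_t + 1L
    bc1 <- 1 - beta1^m$adam_t
    bc2 <- 1 - beta2^m$adam_t
    for (nm in names(m$params)) {
      g <- m$grads[[nm]]
      m$adam_m[[nm]] <- beta1 * m$adam_m[[nm]] + (1 - beta1) * g
      m$adam_v[[nm]] <- beta2 * m$adam_v[[nm]] + (1 - beta2) * g * g
      step <- lr * (m$adam_m[[nm]] / bc1) /
        (sqrt(m$adam_v[[nm]] / bc2) + eps)
      if (m$type == "conv" && nm == "w" && weight_decay > 0)
        step <- step + lr * weight_decay * m$params[[nm]]
      m$params[[nm]] <- m$params[[nm]] - step
    }
  }
  invisible(NULL)
}

# --- (de)serialization ------------------------------------------------------

# Flatten all parameters and buffers into a named numeric list (depth-first
# order is construction order, which is deterministic for a given config).
module_state <- function(m, prefix = "m") {
  out <- list()
  if (length(m$params))
    for (nm in names(m$params))
      out[[paste0(prefix, ".", nm)]] <- m$params[[nm]]
  if (length(m$buffers))
    for (nm in names(m$buffers))
      out[[paste0(prefix, ".buf.", nm)]] <- m$buffers[[nm]]
  for (i in seq_along(m$children))
    out <- c(out, module_state(m$children[[i]], paste0(prefix, ".", i)))
  out
}

module_load_state <- function(m, state, prefix = "m") {
  if (length(m$params))
    for (nm in names(m$params)) {
      key <- paste0(prefix, ".", nm)
      v <- state[[key]]
      if (is.null(v)) stop("missing parameter in checkpoint: ", key)
      d <- dim(m$params[[nm]])
      if (!is.null(d)) dim(v) <- d
      m$params[[nm]] <- v
    }
  if (length(m$buffers))
    for (nm in names(m$buffers)) {
      key <- paste0(prefix, ".buf.", nm)
      if (!is.null(state[[key]])) m$buffers[[nm]] <- state[[key]]
    }
  for (i in seq_along(m$children))
    module_load_state(m$children[[i]], state, paste0(prefix, ".", i))
  invisible(m)
}
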