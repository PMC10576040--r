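# ---------------------------------------------------------------------------
# The 13-stage lightweight backbone. Stage kinds, strides, channel widths,
# repeat counts and expected per-stage trainable-parameter counts are fixed
# by the published structural table; expansion ratios are the unique
# small-integer solution reproducing every printed count. The printed
# stride 2 at stage 11 is overridden to 1 by default (a 64x total stride
# would contradict the stated 20x20 top grid at 640 input); `strict = TRUE`
# keeps the printed stride.
# ---------------------------------------------------------------------------

#' Default backbone stage table
#'
#' Returns the declarative 13-stage specification: block kind, stride,
#' output channels, repeat count, expansion ratio, SPPF hidden width and
#' the expected trainable-parameter count of every stage.
#'
#' @param strict keep the printed stride 2 at stage 11 instead of the
#'   default override to stride 1 (parameter counts are identical)
#' @return a data.frame with one row per stage
#' @export
default_spec <- function(strict = FALSE) {
  df <- data.frame(
    index = 1:13,
    kind = c("CBS", rep("FusedMBConv", 5L), rep("MBConv", 6L), "SPPF"),
    stride = c(2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L,
               if (strict) 2L else 1L, 1L, 1L),
    in_channels = c(3L, 16L, 16L, 24L, 24L, 32L, 32L, 16L, 16L, 24L,
                    24L, 32L, 32L),
    out_channels = c(16L, 16L, 24L, 24L, 32L, 32L, 16L, 16L, 24L, 24L,
                     32L, 32L, 512L),
    repeats = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 3L, 1L, 5L, 1L),
    expansion = c(NA, 1, 4, 4, 4, 4, 4, 4, 6, 6, 4, 4, NA),
    hidden = c(rep(NA_integer_, 12L), 16L),
    expected_params = c(464L, 2336L, 10928L, 23280L, 24064L, 41280L,
                        7840L, 5824L, 5136L, 26496L, 6688L, 49600L,
                        34336L),
    stringsAsFactors = FALSE
  )
  validate_stage_spec(df)
  df
}

validate_stage_spec <- function(spec) {
  need <- c("index", "kind", "stride", "in_channels", "out_channels",
            "repeats", "expansion", "expected_params")
  if (!all(need %in% names(spec))) stop("stage spec is missing columns")
  n <- nrow(spec)
  if (n < 1L) stop("empty stage spec")
  for (i in seq_len(n)[-1]) {
    if (spec$in_channels[i] != spec$out_channels[i - 1L])
      stop(sprintf("channel chain broken at stage %d: in %d != previous out %d",
                   i, spec$in_channels[i], spec$out_channels[i - 1L]))
  }
  if (spec$in_channels[1L] != 3L) stop("stage 1 must take 3 (RGB) channels")
  rep2 <- which(spec$repeats >= 2L)
  if (any(spec$in_channels[rep2] != spec$out_channels[rep2]))
    stop("repeated stages must keep in = out channels")
  invisible(spec)
}

build_stage <- function(row) {
  blocks <- vector("list", row$repeats)
  for (r in seq_len(row$repeats)) {
    stride <- if (r == 1L) row$stride else 1L
    cin <- if (r == 1L) row$in_channels else row$out_channels
    blocks[[r]] <- switch(
      row$kind,
      CBS = make_cbs(block_descriptor("CBS", cin, row$out_channels,
                                      stride = stride, kernel = 3L)),
      FusedMBConv = make_fused_mbconv(block_descriptor(
        "FusedMBConv", cin, row$out_channels, stride = stride,
        expansion = row$expansion)),
      MBConv = make_mbconv(block_descriptor(
        "MBConv", cin, row$out_channels, stride = stride,
        expansion = row$expansion)),
      SPPF = make_sppf(row$in_channels, row$hidden, row$out_channels),
      stop("unknown stage kind: ", row$kind)
    )
  }
  st <- do.call(nn_seq, blocks)
  st$type <- paste0("stage_", row$kind)
  st
}

#' Build the backbone network
#'
#' Constructs every stage, audits the stage-wise trainable-parameter counts
#' against the spec's `expected_params` (an error names the first
#' mismatching stage), and records the three feature-tap points: the last
#' stage at stride 8, at stride 16, and the final stage (stride 32).
#'
#' @param spec a stage table as returned by [default_spec()]
#' @return an `nn_module` of type `"backbone"`
#' @export
build_backbone <- function(spec = default_spec()) {
  validate_stage_spec(spec)
  stages <- lapply(seq_len(nrow(spec)), function(i) build_stage(spec[i, ]))
  for (i in seq_along(stages)) {
    exp_i <- spec$expected_params[i]
    if (!is.na(exp_i)) {
      got <- module_param_count(stages[[i]])
      if (got != exp_i)
        stop(sprintf("stage %d parameter count %d != expected %d",
                     i, got, exp_i))
    }
  }
  m <- new_module("backbone")
  m$children <- stages
  m$spec <- spec
  # tap after the last stage at each cumulative stride
  cum <- cumprod(ifelse(spec$stride == 2L, 2L, 1L))
  m$tap_idx <- c(p3 = max(which(cum == 8L)), p4 = max(which(cum == 16L)),
                 p5 = nrow(spec))
  m$forward <- function(x, train = FALSE) m$forward_taps(x, train)$p5
  m$forward_taps <- function(x, train = FALSE) {
    x <- as_ft(if (is.raw(x)) x else as_t4(x))
    d <- cpp_fdim(x)
    if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
      stop("input spatial dims must be a multiple of 32")
    taps <- list()
    for (i in seq_along(m$children)) {
      x <- m$children[[i]]$forward(x, train)
      if (i == m$tap_idx[["p3"]]) taps$p3 <- x
      if (i == m$tap_idx[["p4"]]) taps$p4 <- x
    }
    taps$p5 <- x
    taps
  }
  m$backward_taps <- function(g3, g4, g5) {
    g <- g5
    for (i in rev(seq_along(m$children))) {
      g <- m$children[[i]]$backward(g)
      if (i - 1L == m$tap_idx[["p4"]]) g <- cpp_add(g, g4)
      if (i - 1L == m$tap_idx[["p3"]]) g <- cpp_add(g, g3)
    }
    g
  }
  m
}

#' Audit a backbone against its expected per-stage parameter counts
#'
#' @param backbone a module from [build_backbone()]
#' @return a `param_report` whose `per_layer` table carries `expected` and
#'   `pass` columns; failures are reported, not raised
#' @export
validate_against_table2 <- function(backbone) {
  spec <- backbone$spec
  counts <- vapply(backbone$children, module_param_count, integer(1))
  rep <- list(per_layer = data.frame(
    index = spec$index,
    name = paste0(spec$kind, ifelse(spec$repeats > 1L,
                                    paste0(" x", spec$repeats), "")),
    params = counts,
    expected = spec$expected_params,
    pass = counts == spec$expected_params,
    stringsAsFactors = FALSE
  ), total = as.integer(sum(counts)))
  class(rep) <- c("backbone_audit", "param_report")
  rep
}

#' Run the backbone and collect the feature pyramid
#'
#' @param backbone a module from [build_backbone()]
#' @param image_batch (H, W, 3, N) array, H and W multiples of 32
#' @return list with `p3`, `p4`, `p5` feature maps at strides 8/16/32
#' @export
forward_features <- function(backbone, image_batch) {
  taps <- backbone$forward_taps(as_t4(image_batch), train = FALSE)
  lapply(taps, as_array)
}

# --- spec (de)serialization -------------------------------------------------

#' Write a backbone stage table as a YAML-style config
#'
#' @param spec stage table
#' @param path output file
#' @export
write_backbone_spec <- function(spec, path) {
  lines <- c("stages:")
  for (i in seq_len(nrow(spec))) {
    r <- spec[i, ]
    lines <- c(lines, sprintf("  - index: %d", r$index),
               sprintf("    kind: %s", r$kind),
               sprintf("    stride: %d", r$stride),
               sprintf("    in_channels: %d", r$in_channels),
               sprintf("    out_channels: %d", r$out_channels),
               sprintf("    repeats: %d", r$repeats),
               sprintf("    expansion: %s",
                       if (is.na(r$expansion)) "~" else format(r$expansion)),
               sprintf("    hidden: %s",
                       if (is.na(r$hidden)) "~" else format(r$hidden)),
               sprintf("    expected_params: %d", r$expected_params))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a backbone stage table written by [write_backbone_spec()]
#'
#' @param path config file
#' @return stage table data.frame
#' @export
read_backbone_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lines <- lines[lines != "stages:"]
  starts <- grep("^\\s*- ", lines)
  stages <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (s in seq_along(starts)) {
    chunk <- lines[bounds[s]:(bounds[s + 1L] - 1L)]
    chunk <- sub("^\\s*-\\s*", "", chunk)
    chunk <- sub("^\\s*", "", chunk)
    kv <- strsplit(chunk, ":\\s*")
    vals <- setNames(vapply(kv, function(p) p[2], character(1)),
                     vapply(kv, function(p) p[1], character(1)))
    num <- function(x) if (identical(x, "~")) NA_real_ else as.numeric(x)
    stages[[s]] <- data.frame(
      index = as.integer(vals[["index"]]), kind = vals[["kind"]],
      stride = as.integer(vals[["stride"]]),
      in_channels = as.integer(vals[["in_channels"]]),
      out_channels = as.integer(vals[["out_channels"]]),
      repeats = as.integer(vals[["repeats"]]),
      expansion = num(vals[["expansion"]]),
      hidden = as.integer(num(vals[["hidden"]])),
      expected_params = as.integer(vals[["expected_params"]]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, stages)
}
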