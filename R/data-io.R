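# ---------------------------------------------------------------------------
# Dataset IO: YOLO-txt labels, portable pixmap (PPM) images, video-grouped
# train/test splitting, COCO-JSON export, dataset manifests.
#
# Images are numeric (H, W, 3) arrays with values in [0, 1] in memory and
# 8-bit PPM on disk (no compressed-codec package is available offline, so
# the uncompressed portable pixmap takes the place of JPEG/PNG).
# ---------------------------------------------------------------------------

#' A labeled image
#'
#' @param image numeric (H, W, 3) array, values in `[0, 1]`
#' @param boxes data.frame with columns `class, cx, cy, w, h`, normalized
#' @param source_video video identifier the frame came from
#' @param lighting_tag `"day"` or `"night"`
#' @return a `labeled_image` list
#' @export
labeled_image <- function(image, boxes = empty_boxes(),
                          source_video = "v000",
                          lighting_tag = c("day", "night")) {
  lighting_tag <- match.arg(lighting_tag)
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  boxes <- validate_boxes(boxes)
  structure(list(image = image, boxes = boxes,
                 source_video = source_video,
                 lighting_tag = lighting_tag),
            class = "labeled_image")
}

#' @rdname labeled_image
#' @export
empty_boxes <- function() {
  data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
             w = numeric(0), h = numeric(0))
}

validate_boxes <- function(boxes) {
  need <- c("class", "cx", "cy", "w", "h")
  stopifnot(all(need %in% names(boxes)))
  if (nrow(boxes) && (any(boxes$w <= 0) || any(boxes$h <= 0)))
    stop("boxes must have positive width and height")
  boxes[, need, drop = FALSE]
}

#' Read YOLO-txt labels
#'
#' Each row is `class cx cy w h` (normalized floats). Malformed rows raise
#' an error naming the line numbers; out-of-range values are clipped into
#' the unit square with a warning.
#'
#' @param path label file; a missing or empty file yields zero boxes
#' @return box data.frame (`class, cx, cy, w, h`)
#' @export
read_yolo_labels <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L) return(empty_boxes())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_boxes())
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, function(p)
    length(p) != 5L || anyNA(suppressWarnings(as.numeric(p))), logical(1)))
  if (length(bad))
    stop("malformed label rows at line(s): ", paste(bad, collapse = ", "))
  m <- do.call(rbind, lapply(parts, as.numeric))
  df <- data.frame(class = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                   w = m[, 4], h = m[, 5])
  clip_cols <- c("cx", "cy", "w", "h")
  rng <- as.matrix(df[, clip_cols])
  if (any(rng < 0) || any(rng > 1)) {
    warning("out-of-range label values clipped to [0, 1]")
    df$cx <- pmin(pmax(df$cx, 0), 1)
    df$cy <- pmin(pmax(df$cy, 0), 1)
    df$w <- pmin(pmax(df$w, 1e-6), 1)
    df$h <- pmin(pmax(df$h, 1e-6), 1)
  }
  df
}

#' Write YOLO-txt labels
#'
#' @param boxes box data.frame (`class, cx, cy, w, h`)
#' @param path output file
#' @export
write_yolo_labels <- function(boxes, path) {
  if (is.null(boxes) || nrow(boxes) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(sprintf("%d %.6f %.6f %.6f %.6f", boxes$class, boxes$cx,
                     boxes$cy, boxes$w, boxes$h), path)
  invisible(path)
}

#' Split videos into train and test sets
#'
#' Video-level 8:2 protocol: the first `floor(ratio * N)` videos form the
#' training set, the remainder the test set; no video appears in both, so
#' image-level leakage is impossible by construction.
#'
#' @param videos vector of video identifiers (kept in given order)
#' @param ratio training fraction in (0, 1); default 0.8
#' @return list with `train` and `test` video vectors
#' @export
split_by_video <- function(videos, ratio = 0.8) {
  if (!length(videos)) stop("empty video list")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  n_train <- floor(ratio * length(videos))
  list(train = videos[seq_len(n_train)],
       test = videos[setdiff(seq_along(videos), seq_len(n_train))])
}

# --- portable pixmap IO -----------------------------------------------------

#' Write an image as a binary PPM (P6)
#'
#' @param image numeric (H, W, 3) array in `[0, 1]`
#' @param path output file
#' @export
write_ppm <- function(image, path) {
  d <- dim(image)
  stopifnot(length(d) == 3L, d[3] == 3L)
  px <- as.integer(round(pmin(pmax(image, 0), 1) * 255))
  # PPM is row-major, channel-interleaved
  arr <- aperm(array(px, d), c(3, 2, 1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P6", paste(d[2], d[1]), "255"), con, sep = "\n")
  writeBin(as.raw(arr), con)
  invisible(path)
}

#' Read a PPM image (P6 binary or P3 ASCII)
#'
#' @param path input file
#' @return numeric (H, W, 3) array in `[0, 1]`
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || ch == "") stop("unexpected end of PPM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
        next
      }
      if (grepl("\\s", ch)) {
        if (nzchar(tok)) return(tok)
      } else tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P6", "P3")) stop("not a PPM file: ", path)
  W <- as.integer(read_token())
  H <- as.integer(read_token())
  mx <- as.integer(read_token())
  npx <- 3L * W * H
  if (magic == "P6") {
    raw <- readBin(con, "raw", n = npx)
    v <- as.integer(raw)
  } else {
    v <- scan(con, what = integer(), n = npx, quiet = TRUE)
  }
  arr <- array(v, dim = c(3L, W, H))
  aperm(arr, c(3, 2, 1)) / mx
}

# --- COCO-JSON export -------------------------------------------------------

#' Export a dataset or detection set as COCO-JSON
#'
#' @param items named list: for each image id, a list with `width`,
#'   `height` and a box data.frame (`class, cx, cy, w, h`, optionally
#'   `conf`) in normalized units
#' @param path output JSON file
#' @param category_names class-id to name mapping (0-based ids)
#' @return the path, invisibly
#' @export
write_coco_json <- function(items, path,
                            category_names = c("mounting")) {
  images <- list(); anns <- list(); aid <- 0L
  for (i in seq_along(items)) {
    it <- items[[i]]
    images[[i]] <- list(id = i, file_name = names(items)[i],
                        width = it$width, height = it$height)
    b <- it$boxes
    if (!is.null(b) && nrow(b)) {
      for (j in seq_len(nrow(b))) {
        aid <- aid + 1L
        x <- (b$cx[j] - b$w[j] / 2) * it$width
        y <- (b$cy[j] - b$h[j] / 2) * it$height
        ann <- list(id = aid, image_id = i,
                    category_id = as.integer(b$class[j]) + 1L,
                    bbox = c(x, y, b$w[j] * it$width, b$h[j] * it$height),
                    area = b$w[j] * it$width * b$h[j] * it$height,
                    iscrowd = 0L)
        if (!is.null(b$conf)) ann$score <- b$conf[j]
        anns[[aid]] <- ann
      }
    }
  }
  cats <- lapply(seq_along(category_names), function(k)
    list(id = k, name = category_names[k]))
  jsonlite::write_json(list(images = images, annotations = anns,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}
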