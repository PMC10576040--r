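test_that("YOLO label IO round-trips and enforces its policies", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.2 0.1", path)
  b <- read_yolo_labels(path)
  expect_identical(nrow(b), 1L)
  expect_equal(unlist(b[1, ], use.names = FALSE), c(0, 0.5, 0.5, 0.2, 0.1))
  # 100 random boxes round-trip at 1e-6
  set.seed(1)
  boxes <- data.frame(class = sample(0:2, 100, replace = TRUE),
                      cx = runif(100), cy = runif(100),
                      w = runif(100, 0.01, 1), h = runif(100, 0.01, 1))
  write_yolo_labels(boxes, path)
  back <- read_yolo_labels(path)
  expect_equal(back, boxes, tolerance = 1e-6)
  # out-of-range clipped with a warning
  writeLines("0 1.2 0.5 0.2 0.1", path)
  expect_warning(cl <- read_yolo_labels(path), "clipped")
  expect_equal(cl$cx, 1.0)
  # malformed rows reported with line numbers
  writeLines(c("0 0.5 0.5 0.2 0.1", "banana", "0 0.1"), path)
  expect_error(read_yolo_labels(path), "2, 3")
  # empty file: zero boxes
  writeLines(character(0), path)
  expect_identical(nrow(read_yolo_labels(path)), 0L)
})

test_that("PPM images round-trip at 8-bit precision", {
  set.seed(2)
  img <- array(runif(20 * 30 * 3), c(20, 30, 3))
  path <- withr::local_tempfile(fileext = ".ppm")
  write_ppm(img, path)
  back <- read_ppm(path)
  expect_identical(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
})

test_that("video split is an exact ordered partition", {
  vids <- sprintf("v%03d", 1:144)
  sp <- split_by_video(vids, 0.8)
  expect_identical(length(sp$train), 115L)
  expect_identical(length(sp$test), 29L)
  expect_identical(sort(c(sp$train, sp$test)), sort(vids))
  expect_identical(intersect(sp$train, sp$test), character(0))
  sp10 <- split_by_video(letters[1:10], 0.8)
  expect_identical(lengths(sp10), c(train = 8L, test = 2L))
  expect_error(split_by_video(character(0)), "empty")
  expect_error(split_by_video(letters, 1.2), "ratio")
})

test_that("identity mosaic places each box at its quadrant closed form", {
  set.seed(3)
  mk <- function(cx, cy) {
    img <- array(runif(40 * 40 * 3), c(40, 40, 3))
    labeled_image(img, data.frame(class = 0L, cx = cx, cy = cy,
                                  w = 0.2, h = 0.2))
  }
  samples <- list(mk(0.5, 0.5), mk(0.25, 0.5), mk(0.5, 0.25), mk(0.75, 0.75))
  mz <- mosaic4(samples, out_size = 200L, identity = TRUE)
  expect_identical(dim(mz$image), c(200L, 200L, 3L))
  b <- mz$boxes[order(mz$boxes$cx, mz$boxes$cy), ]
  # quadrant side is 100 px; sample k box center maps to
  # (offx + cx*100)/200, (offy + cy*100)/200
  expected <- data.frame(
    cx = c(0 + 0.5, 1 + 0.25, 0 + 0.5, 1 + 0.75) / 2,
    cy = c(0 + 0.5, 0 + 0.5, 1 + 0.25, 1 + 0.75) / 2)
  expected <- expected[order(expected$cx, expected$cy), ]
  expect_equal(b$cx, expected$cx, tolerance = 0.02)
  expect_equal(b$cy, expected$cy, tolerance = 0.02)
  expect_equal(b$w, rep(0.1, 4), tolerance = 0.02)
})

test_that("mosaic is deterministic under a fixed seed and clips boxes", {
  set.seed(4)
  cfg <- tiny_scene_cfg()
  samples <- lapply(1:4, function(i) generate_scene(cfg))
  set.seed(10)
  m1 <- mosaic4(samples, 160L)
  set.seed(10)
  m2 <- mosaic4(samples, 160L)
  expect_identical(m1$image, m2$image)
  expect_equal(m1$boxes, m2$boxes)
  expect_true(all(m1$boxes$cx - m1$boxes$w / 2 >= -1e-9))
  expect_true(all(m1$boxes$cx + m1$boxes$w / 2 <= 1 + 1e-9))
})

test_that("vertical flip is an involution and maps cy -> 1 - cy", {
  set.seed(5)
  s <- generate_scene(tiny_scene_cfg())
  f1 <- vflip(s, p = 1)
  expect_equal(f1$boxes$cy, 1 - s$boxes$cy)
  expect_equal(f1$boxes$class, s$boxes$class)
  f2 <- vflip(f1, p = 1)
  expect_identical(f2$image, s$image)
  expect_equal(f2$boxes, s$boxes)
})

test_that("photometric jitter with zero amplitudes is the identity", {
  set.seed(6)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(photometric_jitter(img, 0, 0, 0, 0), img)
  out <- photometric_jitter(img)
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(dim(out), dim(img))
})

test_that("generated scenes honor their configuration and label tightly", {
  cfg <- scene_config(canvas = c(256L, 144L), n_animals = c(2L, 4L),
                      mounting_pairs = c(2L, 2L), scale = c(0.1, 0.2),
                      overlap = 0.3)
  set.seed(7)
  sc <- generate_scene(cfg)
  expect_identical(nrow(sc$boxes), 2L)
  expect_true(all(sc$boxes$class == 0L))
  set.seed(7)
  sc2 <- generate_scene(cfg)
  expect_identical(sc2$image, sc$image)
  expect_error(scene_config(canvas = c(40L, 40L), scale = c(0.01, 0.02)),
               "too small")
})

test_that("synthetic labels bound the rendered silhouettes (IoU >= 0.9)", {
  # recompute a brute-force box from the rendered pair masks, row/column
  # scan, and compare with the emitted label
  cfg <- scene_config(canvas = c(256L, 144L), n_animals = c(1L, 3L),
                      mounting_pairs = c(1L, 2L), scale = c(0.12, 0.22),
                      overlap = 0.3, night_prob = 0)
  set.seed(8)
  for (rep in 1:8) {
    sc <- generate_scene(cfg, keep_masks = TRUE)
    masks <- attr(sc, "pair_masks")
    expect_identical(length(masks), nrow(sc$boxes))
    for (k in seq_along(masks)) {
      rows <- which(rowSums(masks[[k]]) > 0)
      cols <- which(colSums(masks[[k]]) > 0)
      box_px <- c(min(cols) - 1, min(rows) - 1, max(cols), max(rows))
      b <- sc$boxes[k, ]
      lab_px <- c((b$cx - b$w / 2) * 256, (b$cy - b$h / 2) * 144,
                  (b$cx + b$w / 2) * 256, (b$cy + b$h / 2) * 144)
      expect_gte(iou(box_px, lab_px, form = "corner"), 0.9)
    }
    # every label box contains at least two silhouette centers worth of
    # mask pixels (a pair, not a single animal)
    expect_true(all(sc$boxes$w > 0 & sc$boxes$h > 0))
  }
})

test_that("generate_dataset writes a consistent video-grouped layout", {
  dir <- withr::local_tempdir()
  cfg <- tiny_scene_cfg()
  set.seed(9)
  man <- generate_dataset(cfg, n_videos = 10L, frames_per_video = 5L,
                          out_dir = dir, overwrite = TRUE)
  expect_identical(man$total_images, 50L)
  imgs <- list.files(file.path(dir, "images"), pattern = "\\.ppm$")
  labs <- list.files(file.path(dir, "labels"), pattern = "\\.txt$")
  expect_identical(length(imgs), 50L)
  expect_identical(length(labs), 50L)
  expect_identical(sum(vapply(man$videos, function(v) v$frames,
                              integer(1))), 50L)
  # compatible with the split protocol
  vids <- vapply(man$videos, function(v) v$video, character(1))
  sp <- split_by_video(vids, 0.8)
  expect_identical(lengths(sp), c(train = 8L, test = 2L))
  # refuses to clobber without the flag
  expect_error(generate_dataset(cfg, 1L, 1L, out_dir = dir), "overwrite")
  # loads back with boxes intact
  ds <- load_dataset(dir)
  expect_identical(length(ds), 50L)
  expect_true(all(vapply(ds, function(s) inherits(s, "labeled_image"),
                         logical(1))))
})
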