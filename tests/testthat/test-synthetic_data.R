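test_that("timelines are ordered, deterministic and end Empty", {
  cfg <- timeline_config(reversion_probability = 0, arrest_probability = 0)
  tl <- sample_timeline(cfg, seed = 1)
  expect_identical(tl$time_minutes[1:3], c(0, 20, 40))
  expect_identical(tl$frame_index, seq_len(nrow(tl)) - 1L)
  # without reversion or arrest, ordinals are monotone up to Empty
  ords <- stage_ordinal(tl$label)
  dev <- ords[tl$label != "Empty"]
  expect_true(all(diff(dev) >= 0))
  expect_true(all(diff(dev) <= 1))  # no stage skipped
  # removal day: everything after day 5 is Empty
  expect_true(all((tl$label == "Empty") == (tl$time_minutes >= 5 * 24 * 60)))
  expect_identical(sample_timeline(cfg, seed = 1), tl)
  expect_false(identical(sample_timeline(cfg, seed = 2), tl))
})

test_that("reversion and arrest episodes appear at the configured rates", {
  cfg_rev <- timeline_config(reversion_probability = 1,
                             arrest_probability = 0)
  tl <- sample_timeline(cfg_rev, seed = 3)
  ords <- stage_ordinal(tl$label)
  dev <- ords[tl$label != "Empty"]
  expect_true(any(diff(dev) < 0))  # one reverse-cleavage episode
  cfg_arr <- timeline_config(reversion_probability = 0,
                             arrest_probability = 1)
  tl2 <- sample_timeline(cfg_arr, seed = 4)
  # arrested embryos dwell in their last stage until removal
  last_dev <- tail(as.character(tl2$label[tl2$label != "Empty"]), 1)
  expect_false(last_dev %in% c("tHB"))
})

test_that("rendered frames encode the stage geometry", {
  f1 <- render_frame("t4", size = 64L, seed = 5)
  expect_identical(render_frame("t4", size = 64L, seed = 5), f1)
  expect_false(identical(render_frame("t4", size = 64L, seed = 6), f1))
  expect_true(all(f1 >= 0 & f1 <= 1))
  expect_identical(count_blobs(f1), 4L)
  expect_identical(count_blobs(render_frame("t2", 64L, seed = 2)), 2L)
  expect_identical(count_blobs(render_frame("t3", 64L, seed = 2)), 3L)
  # Empty wells have far less foreground than cleavage stages
  area <- function(img) mean(img > 0.55)
  expect_gt(area(render_frame("t2", 64L, seed = 1)),
            area(render_frame("Empty", 64L, seed = 1)) + 0.02)
  expect_error(render_frame("t4", size = 16L), "at least 32")
})

test_that("zero noise reproduces the truth with full confidence", {
  tl <- sample_timeline(timeline_config(), seed = 6)
  nz <- noise_config(baseline_error_rate = 0, transition_error_rate = 0)
  s <- simulate_predictions(tl, nz, seed = 1)
  expect_identical(as.character(s$top_label), as.character(tl$label))
  expect_true(all(s$confidence == 1))
})

test_that("baseline flips are adjacent and occur at the configured rate", {
  # constant-stage timeline: no boundaries, so every flip is a baseline flip
  n <- 6000L
  tl <- data.frame(frame_index = seq_len(n) - 1L,
                   time_minutes = (seq_len(n) - 1L) * 20,
                   label = factor("t8", levels = stage_levels()))
  s <- simulate_predictions(tl, noise_config(), seed = 8)
  flipped <- as.character(s$top_label) != "t8"
  rate <- mean(flipped)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  expect_true(all(is_adjacent(s$top_label[flipped], "t8")))
  expect_true(all(s$confidence >= 0.35))
  # probability rows are well formed by construction of the sequence class
  expect_s3_class(s, "prediction_sequence")
})

test_that("datasets are written with a 70/10/20 video-level split", {
  dir <- file.path(tempdir(), "embryoset")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  cfg <- timeline_config(frame_interval_minutes = 60)  # small, fast videos
  res <- generate_dataset(10L, dir, config = cfg, size = 32L, seed = 3)
  expect_identical(
    as.integer(table(res$split$split)[c("train", "val", "test")]),
    c(7L, 1L, 2L))
  expect_setequal(res$split$video_id, unique(res$annotations$video_id))
  ann <- read_annotations(file.path(dir, "annotations.csv"))
  expect_identical(nrow(ann), nrow(res$annotations))
  preds <- read_predictions(file.path(dir, "predictions.csv"))
  expect_length(preds, 10L)
  # frames exist and read back as [0,1] grayscale
  v1 <- ann[ann$video_id == ann$video_id[1], ]
  img <- read_frame(file.path(dir, "videos", v1$video_id[1], "00000.png"))
  expect_true(is.matrix(img) && all(img >= 0 & img <= 1))
  ds <- load_image_dataset(dir)
  expect_length(ds$images, nrow(ann))
  expect_identical(sort(unique(ds$split)), c("test", "train", "val"))
  expect_error(generate_dataset(5L, dir), "at least 10")
})

test_that("largest-remainder split is exact for n = 100 and covers n = 11", {
  ns <- asNamespace("embryostage")
  expect_identical(ns$largest_remainder_split(100),
                   c(train = 70L, val = 10L, test = 20L))
  s11 <- ns$largest_remainder_split(11)
  expect_identical(sum(s11), 11L)
  expect_identical(s11[["train"]], 8L)
})
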