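test_that("label lines parse with and without trailing confidence", {
  p <- parse_yolo_seg_line("0 0.0 0.0 1.0 0.0 1.0 1.0", 100, 50)
  expect_equal(p$class_id, 0L)
  expect_true(is.na(p$confidence))
  expect_equal(unclass(p$polygon), rbind(c(0, 0), c(100, 0), c(100, 50)),
               ignore_attr = TRUE)

  q <- parse_yolo_seg_line("0 0.0 0.0 0.5 0.0 0.5 0.5 0.0 0.5 0.962", 10, 10)
  expect_equal(q$confidence, 0.962)
  expect_equal(unclass(q$polygon),
               rbind(c(0, 0), c(5, 0), c(5, 5), c(0, 5)), ignore_attr = TRUE)

  # forcing the dialect overrides parity auto-detection
  r <- parse_yolo_seg_line("0 0.0 0.0 1.0 0.0 1.0 1.0", 10, 10,
                           confidence = "never")
  expect_true(is.na(r$confidence))
  expect_error(parse_yolo_seg_line("0 0.0 0.0 1.0 0.0 1.0 1.0 0.9", 10, 10,
                                   confidence = "never"), "odd coordinate")
})

test_that("malformed label lines raise format errors", {
  expect_error(parse_yolo_seg_line("0 0.1 0.1 0.9 0.1 0.9", 10, 10),
               "format error")
  expect_error(parse_yolo_seg_line("0 0.1 0.1 0.9 0.1", 10, 10),
               "fewer than 3")
  expect_error(parse_yolo_seg_line("0 0.1 0.1 1.5 0.1 0.9 0.9", 10, 10),
               "outside \\[0, 1\\]")
  expect_error(parse_yolo_seg_line("0 a b c d e f", 10, 10), "non-numeric")
})

test_that("manifests load chronologically and tolerate missing label files", {
  dir <- withr::local_tempdir()
  lab <- file.path(dir, sprintf("f%02d.txt", 1:3))
  writeLines("0 0.1 0.1 0.9 0.1 0.5 0.9", lab[1])
  writeLines(c("0 0.1 0.1 0.9 0.1 0.5 0.9", "0 0.2 0.2 0.8 0.2 0.5 0.8"), lab[2])
  # third label file intentionally absent
  man <- make_manifest(basename(lab), start = "2023-05-13 00:00:00",
                       interval = 300, width = 100, height = 80)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE, quote = FALSE)

  expect_warning(loaded <- load_manifest(man_path), "missing")
  expect_length(loaded$frames, 3)
  expect_equal(vapply(loaded$frames, function(f) length(f$instances), integer(1)),
               c(1L, 2L, 0L))
  dts <- diff(as.numeric(loaded$manifest$timestamp))
  expect_equal(dts, c(300, 300))

  # duplicate frame ids
  man2 <- man; man2$frame_id <- c("a", "a", "b")
  utils::write.csv(man2, man_path, row.names = FALSE, quote = FALSE)
  expect_error(load_manifest(man_path), "duplicate")

  # out-of-order timestamps
  man3 <- man; man3$timestamp <- rev(man3$timestamp)
  utils::write.csv(man3, man_path, row.names = FALSE, quote = FALSE)
  expect_error(load_manifest(man_path), "increasing")

  # unparsable timestamp
  man4 <- man; man4$timestamp[2] <- "13/05/2023 midnightish"
  utils::write.csv(man4, man_path, row.names = FALSE, quote = FALSE)
  expect_error(load_manifest(man_path), "timestamp")
})

test_that("min_confidence filters instances at ingest", {
  dir <- withr::local_tempdir()
  lab <- file.path(dir, "f1.txt")
  writeLines(c("0 0.1 0.1 0.9 0.1 0.5 0.9 0.95",
               "0 0.2 0.2 0.8 0.2 0.5 0.8 0.30"), lab)
  man <- make_manifest("f1.txt", start = "2023-05-13 00:00:00",
                       width = 100, height = 80)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE, quote = FALSE)
  loaded <- load_manifest(man_path, min_confidence = 0.5)
  expect_length(loaded$frames[[1]]$instances, 1)
  expect_equal(loaded$frames[[1]]$instances[[1]]$confidence, 0.95)
})

test_that("track CSV round-trips with six-decimal coordinates and empty gaps", {
  dir <- withr::local_tempdir()
  ts <- as.POSIXct("2023-05-13 00:00:00", tz = "UTC") + c(0, 300)
  track <- data.frame(frame_id = c("f1", "f2"), timestamp = ts,
                      x = c(0, 100), y = c(0, 80), n_pigs = c(7L, 7L),
                      D = c(NA, 100))
  p <- file.path(dir, "track.csv")
  write_track_csv(track, p)
  lines <- readLines(p)
  expect_equal(lines[1], "frame_id,timestamp,x,y,n_pigs,D")
  expect_match(lines[3], "100\\.000000$")
  expect_match(lines[2], ",$")  # empty D on the first frame
  back <- read_track_csv(p)
  expect_equal(back$x, track$x)
  expect_equal(back$D, c(NA, 100))

  # single-frame and empty tracks
  write_track_csv(track[1, ], p)
  expect_length(readLines(p), 2)
  write_track_csv(track[0, ], p)
  expect_equal(readLines(p), "frame_id,timestamp,x,y,n_pigs,D")
})

test_that("generated scenes round-trip through the label format", {
  cfg <- pen_config(width = 640, height = 480, n_pigs = 3, duration = 4L,
                    body_length = 90, seed = 21L)
  scene <- simulate_group_walk(cfg)
  dir <- withr::local_tempdir()
  write_scene(scene, dir)
  loaded <- load_manifest(file.path(dir, "manifest.csv"))
  expect_length(loaded$frames, 4)
  for (t in 1:4) {
    insts <- loaded$frames[[t]]$instances
    expect_length(insts, 3)
    for (i in 1:3) {
      orig <- unclass(scene$polygons[[t]][[i]])
      back <- unclass(insts[[i]]$polygon)
      expect_equal(dim(back), dim(orig))
      expect_lt(max(abs(back - orig)), 0.01)  # normalization quantization only
    }
  }
})
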