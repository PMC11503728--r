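test_that("pig contours are valid closed polygons with 30-50 vertices", {
  set.seed(1)
  for (pose in c("lying", "sitting", "standing")) {
    for (rep in 1:10) {
      p <- generate_pig_polygon(c(500, 400), pose, body_length = 200,
                                heading = stats::runif(1, 0, 2 * pi))
      n <- nrow(p)
      expect_gte(n, 30); expect_lte(n, 50)
      expect_s3_class(p, "polygon2d")   # construction validates the geometry
      expect_gt(polygon_area(p), 0)
    }
  }
})

test_that("pig contours are deterministic given the RNG state", {
  set.seed(42); a <- generate_pig_polygon(c(100, 100), "lying", 120, 0.7)
  set.seed(42); b <- generate_pig_polygon(c(100, 100), "lying", 120, 0.7)
  expect_identical(a, b)
})

test_that("standing contours centre on the requested point; leg lobes stay thin", {
  set.seed(7)
  ell_area <- function(L) pi * (L / 2) * (L / 2 / 2.5)
  for (rep in 1:10) {
    st <- generate_pig_polygon(c(600, 300), "standing", 240,
                               stats::runif(1, 0, 2 * pi))
    ctr <- centroid_signed_area(st)
    expect_lt(sqrt(sum((ctr - c(600, 300))^2)), 0.02 * 240)
    # lying adds at most 4 lobes of ~<= 5% body area each
    ly <- generate_pig_polygon(c(600, 300), "lying", 240,
                               stats::runif(1, 0, 2 * pi))
    expect_lt(polygon_area(ly), 1.25 * ell_area(240))
    expect_gt(polygon_area(ly), 0.85 * ell_area(240))
  }
})

test_that("lying contours pull the vertex mean toward the legs more than the mass centroid", {
  set.seed(123)
  for (rep in 1:10) {
    ctr <- c(600, 400)
    p <- generate_pig_polygon(ctr, "lying", 400, stats::runif(1, 0, 2 * pi))
    leg <- attr(p, "leg_dir")
    expect_equal(sqrt(sum(leg^2)), 1, tolerance = 1e-9)
    proj_mean <- sum((centroid_mean(p) - ctr) * leg)
    proj_sm <- sum((centroid_spatial_moment(p, 1200, 800) - ctr) * leg)
    expect_gt(proj_mean, proj_sm)
    expect_gt(proj_mean, 0)  # and the pull is indeed toward the leg side
  }
})

test_that("a rest-locked walk with zero jitter never moves", {
  cfg <- pen_config(width = 800, height = 600, n_pigs = 3, duration = 20L,
                    body_length = 80, seed = 5L, dispersion = 0)
  beh <- behavior_state(p_rest_to_move = 0, rest_jitter = 0)
  sc <- simulate_group_walk(cfg, beh)
  expect_true(all(sc$frames$state == "rest"))
  expect_equal(length(unique(sc$frames$gx)), 1)
  expect_equal(sc$daily$total_D, 0)
})

test_that("scenes are reproducible and keep pigs inside the pen", {
  cfg <- pen_config(width = 1000, height = 700, n_pigs = 5, duration = 30L,
                    body_length = 100, seed = 99L)
  a <- simulate_group_walk(cfg)
  b <- simulate_group_walk(cfg)
  expect_identical(a$frames, b$frames)
  expect_identical(a$centers, b$centers)
  expect_identical(a$polygons, b$polygons)
  expect_true(all(a$centers$x >= 0 & a$centers$x <= 1000))
  expect_true(all(a$centers$y >= 0 & a$centers$y <= 700))
})

test_that("the ground-truth daily total equals the latent path summed by the formula", {
  cfg <- pen_config(width = 900, height = 500, n_pigs = 2, duration = 40L,
                    body_length = 60, seed = 3L)
  sc <- simulate_group_walk(cfg)
  g <- frame_geometry(900, 500)
  manual <- sum(vapply(2:40, function(t)
    normalized_distance(c(sc$frames$gx[t - 1], sc$frames$gy[t - 1]),
                        c(sc$frames$gx[t], sc$frames$gy[t]), g), numeric(1)))
  expect_equal(sum(sc$daily$total_D), manual, tolerance = 1e-12)
  expect_equal(sum(sc$hourly$total_D), manual, tolerance = 1e-12)
})

test_that("written scenes produce one label file per frame and a spanning manifest", {
  cfg <- pen_config(width = 640, height = 480, n_pigs = 3, duration = 288L,
                    body_length = 60, seed = 17L)
  sc <- simulate_group_walk(cfg)
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  labels <- list.files(file.path(dir, "labels"))
  expect_length(labels, 288)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  span <- diff(range(as.POSIXct(man$timestamp, tz = "UTC")))
  expect_equal(as.numeric(span, units = "mins"), 23 * 60 + 55)
  gt <- utils::read.csv(file.path(dir, "ground_truth_daily.csv"))
  expect_equal(gt$total_D, sc$daily$total_D, tolerance = 1e-6)
})

test_that("dropout removes detections but keeps frames", {
  cfg <- pen_config(width = 640, height = 480, n_pigs = 4, duration = 30L,
                    body_length = 60, seed = 11L, dropout = 0.4)
  sc <- simulate_group_walk(cfg)
  expect_true(any(!sc$centers$detected))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  loaded <- suppressWarnings(load_manifest(file.path(dir, "manifest.csv")))
  n_inst <- vapply(loaded$frames, function(f) length(f$instances), integer(1))
  expect_length(n_inst, 30)
  expect_equal(sum(n_inst), sum(sc$centers$detected))
})

test_that("scheduled activity peaks surface in the latent hourly profile", {
  # expectation over seeds: the two largest mean bins sit at the peaks
  prof <- matrix(0, nrow = 24, ncol = 6)
  for (s in 1:6) {
    sc <- simulate_group_walk(pen_config(width = 1000, height = 700,
                                         n_pigs = 2, duration = 288L,
                                         body_length = 60, seed = 400 + s))
    prof[, s] <- sc$hourly$total_D
  }
  top2 <- sort(order(-rowMeans(prof))[1:2] - 1)
  expect_equal(top2, c(9, 21))
})
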