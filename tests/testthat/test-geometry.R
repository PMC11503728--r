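test_that("polygon validation rejects degenerate input and dedups duplicates", {
  expect_error(as_polygon(rbind(c(0, 0), c(1, 1), c(2, 2))), "zero area")
  expect_error(as_polygon(rbind(c(0, 0), c(0, 0), c(0, 0), c(1, 1))), "zero area|fewer")
  expect_error(as_polygon(rbind(c(0, 0), c(1, 0))), "fewer than 3")
  expect_error(as_polygon(rbind(c(0, 0), c(Inf, 0), c(1, 1))), "finite")
  # duplicates survive in the stored vertices (vertex-weighted ops need them)
  p <- as_polygon(rbind(c(0, 0), c(1, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(nrow(p), 5)
  expect_equal(polygon_area(p), 1)
})

test_that("rasterization matches the per-pixel even-odd oracle", {
  sq <- rbind(c(-0.5, -0.5), c(1.5, -0.5), c(1.5, 1.5), c(-0.5, 1.5))
  m <- rasterize_polygon(sq, 4, 4)
  expect_identical(m$intensity, oracle_rasterize(sq, 4, 4))
  expect_equal(sum(m$intensity), 4)  # pixels (0,0),(1,0),(0,1),(1,1)
  expect_equal(m$intensity[1:2, 1:2], matrix(1L, 2, 2))

  set.seed(101)
  for (rep in 1:10) {
    poly <- random_polygon(n = sample(5:14, 1), center = c(10, 9),
                           rmin = 2, rmax = 8)
    got <- rasterize_polygon(poly, 24, 20)$intensity
    expect_identical(got, oracle_rasterize(poly, 24, 20))
  }
})

test_that("rasterization handles full cover, clipping and degenerate shapes", {
  full <- rbind(c(-2, -2), c(9, -2), c(9, 7), c(-2, 7))
  m <- rasterize_polygon(full, 6, 5)
  expect_equal(sum(m$intensity), 6 * 5)
  expect_equal(spatial_moments(m)$m00, 30)
  expect_error(rasterize_polygon(rbind(c(0, 0), c(1, 1), c(2, 2)), 4, 4),
               "zero area")
  # polygon entirely outside the frame -> empty mask, centroid errors
  off <- rbind(c(100, 100), c(110, 100), c(110, 110), c(100, 110))
  expect_equal(sum(rasterize_polygon(off, 10, 10)$intensity), 0)
  expect_error(centroid_spatial_moment(off, 10, 10), "empty mask")
})

test_that("spatial moments follow the definition on simple masks", {
  m <- matrix(0L, nrow = 8, ncol = 8)
  m[6, 4] <- 1L  # pixel (x = 3, y = 5)
  expect_equal(spatial_moments(m), list(m00 = 1, m10 = 3, m01 = 5))
  m2 <- matrix(0L, 4, 4); m2[1:2, 1:2] <- 1L
  expect_equal(spatial_moments(m2), list(m00 = 4, m10 = 2, m01 = 2))
  expect_equal(spatial_moments(matrix(0L, 3, 3)),
               list(m00 = 0, m10 = 0, m01 = 0))
  expect_error(spatial_moments(matrix(c(0, 2, 0, 0), 2, 2)), "0 or 1")
})

test_that("spatial-moment centre equals the mask-moment route exactly", {
  set.seed(77)
  for (rep in 1:8) {
    poly <- random_polygon(n = 10, center = c(15, 12), rmin = 3, rmax = 10)
    mom <- spatial_moments(rasterize_polygon(poly, 32, 28))
    direct <- centroid_spatial_moment(poly, 32, 28)
    expect_equal(direct[["x"]], mom$m10 / mom$m00, tolerance = 1e-12)
    expect_equal(direct[["y"]], mom$m01 / mom$m00, tolerance = 1e-12)
  }
})

test_that("mean-coordinate centre averages raw vertices, duplicates included", {
  expect_equal(centroid_mean(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
               c(x = 0.5, y = 0.5))
  expect_equal(centroid_mean(rbind(c(0, 0), c(3, 0), c(0, 3))), c(x = 1, y = 1))
  rep4 <- rbind(c(0, 0), c(1, 0), c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(0, 1))
  expect_equal(centroid_mean(rep4), c(x = 5 / 7, y = 5 / 7))
})

test_that("iterative least-squares centre converges to the vertex mean", {
  expect_equal(centroid_least_squares(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                                      tol = 1e-9),
               c(x = 0.5, y = 0.5), tolerance = 1e-9, ignore_attr = TRUE)
  same <- matrix(rep(c(2, 3), 4), ncol = 2, byrow = TRUE)
  expect_equal(centroid_least_squares(same, validate = FALSE),
               c(x = 2, y = 3), tolerance = 1e-9, ignore_attr = TRUE)
  set.seed(5)
  for (rep in 1:20) {
    poly <- random_polygon(n = sample(4:40, 1), center = stats::runif(2, -50, 50),
                           rmin = 1, rmax = 30)
    expect_equal(centroid_least_squares(poly, tol = 1e-10), centroid_mean(poly),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(centroid_least_squares(random_polygon(), max_iter = 2L),
               "did not converge")
})

test_that("signed-area centroid matches decomposition oracle and ignores orientation", {
  expect_equal(centroid_signed_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
               c(x = 0.5, y = 0.5))
  # L-shape = 2x2 square minus 1x1 corner: (4*(1,1) - 1*(1.5,1.5)) / 3 = 5/6
  L <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2))
  expect_equal(centroid_signed_area(L), c(x = 5 / 6, y = 5 / 6))
  set.seed(9)
  for (rep in 1:10) {
    poly <- random_polygon(n = 9)
    expect_equal(centroid_signed_area(poly),
                 centroid_signed_area(poly[nrow(poly):1, ]))
  }
})

test_that("all four centres lie inside convex polygons and are translation-equivariant", {
  set.seed(31)
  for (rep in 1:10) {
    poly <- random_convex_polygon(n = 25, center = c(40, 35), radius = 14)
    centres <- list(
      centroid_mean(poly),
      centroid_least_squares(poly),
      centroid_signed_area(poly),
      centroid_spatial_moment(poly, 80, 70)
    )
    # inside test: a convex polygon contains a point iff all cross products
    # with the edge directions share a sign
    v <- poly; n <- nrow(v)
    vn <- v[c(2:n, 1), ]
    for (ctr in centres) {
      cr <- (vn[, 1] - v[, 1]) * (ctr[["y"]] - v[, 2]) -
            (vn[, 2] - v[, 2]) * (ctr[["x"]] - v[, 1])
      expect_true(all(cr >= -1e-9) || all(cr <= 1e-9))
    }
    # translation equivariance (integer shift so the raster shifts rigidly)
    sh <- c(7, 5)
    poly2 <- sweep(poly, 2, sh, "+")
    expect_equal(centroid_mean(poly2), centroid_mean(poly) + sh,
                 ignore_attr = TRUE)
    expect_equal(centroid_signed_area(poly2), centroid_signed_area(poly) + sh,
                 ignore_attr = TRUE)
    expect_equal(centroid_spatial_moment(poly2, 100, 90),
                 centroid_spatial_moment(poly, 80, 70) + sh,
                 tolerance = 1e-12, ignore_attr = TRUE)
    # exact scale equivariance of the two continuum centroids
    s <- 2.5
    expect_equal(centroid_mean(poly * s), centroid_mean(poly) * s,
                 ignore_attr = TRUE)
    expect_equal(centroid_signed_area(poly * s), centroid_signed_area(poly) * s,
                 ignore_attr = TRUE)
  }
})

test_that("raster centroid converges to the signed-area centroid as scale grows", {
  set.seed(13)
  for (rep in 1:5) {
    base <- random_polygon(n = 14, center = c(24, 24), rmin = 6, rmax = 18)
    ref <- centroid_signed_area(base)
    gaps <- vapply(c(1, 4, 16), function(s) {
      big <- base * s
      got <- centroid_spatial_moment(big, ceiling(50 * s), ceiling(50 * s))
      sqrt(sum((got - ref * s)^2)) / s
    }, numeric(1))
    expect_true(all(diff(gaps) <= 1e-6))  # non-increasing normalized gap
    expect_lt(gaps[3], 0.5)
  }
})
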