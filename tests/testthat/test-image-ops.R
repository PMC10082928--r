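test_that("max projection reduces to identity and constant cases", {
  one <- matrix(runif(36), 6, 6)
  st <- image_stack(array(one, dim = c(6, 6, 1)))
  expect_equal(plain_matrix(max_z_project(st)), one)

  st2 <- image_stack(array(c(rep(5, 16), rep(7, 16)), dim = c(4, 4, 2)))
  expect_true(all(max_z_project(st2) == 7))

  expect_error(image_stack(array(numeric(0), dim = c(4, 4, 0))), "slice")
})

test_that("max projection equals the elementwise-max oracle on random stacks", {
  withr::with_seed(11, {
    vox <- array(runif(4 * 8 * 8, 0, 1000), dim = c(8, 8, 4))
    st <- image_stack(vox)
    expect_equal(plain_matrix(max_z_project(st)), oracle_max_project(vox))
  })
})

test_that("rolling-ball subtraction flattens constants and keeps isolated peaks", {
  expect_true(all(rolling_ball_subtract(matrix(123.4, 9, 9), 3) == 0))

  img <- matrix(0, 9, 9)
  img[5, 5] <- 1000
  out <- rolling_ball_subtract(img, 3)
  bg <- oracle_rolling_ball_background(img, 3)
  expect_equal(unclass(out), pmax(img - bg, 0), ignore_attr = TRUE)
  # the peak survives essentially intact (background at the peak ~ 0)
  expect_gt(out[5, 5], 999)

  expect_error(rolling_ball_subtract(matrix(0, 5, 5), 9), "extent")
  expect_error(rolling_ball_subtract(matrix(0, 5, 5), 0), ">= 1")
})

test_that("rolling-ball background matches the morphology oracle on random images", {
  withr::with_seed(21, {
    for (i in 1:25) {
      m <- matrix(runif(16 * 16, 0, 5000), 16, 16)
      out <- rolling_ball_subtract(m, 3)
      bg <- attr(out, "background")
      expect_equal(bg, oracle_rolling_ball_background(m, 3))
      expect_true(all(out <= m + 1e-9))
      expect_true(all(out >= 0))
    }
  })
})

test_that("rolling-ball background commutes with constant offsets", {
  withr::with_seed(31, {
    m <- matrix(runif(64, 0, 1000), 8, 8)
    b0 <- attr(rolling_ball_subtract(m, 3), "background")
    b1 <- attr(rolling_ball_subtract(m + 250, 3), "background")
    expect_equal(b1, b0 + 250)
    expect_equal(plain_matrix(rolling_ball_subtract(m + 250, 3)),
                 plain_matrix(rolling_ball_subtract(m, 3)))
  })
})

test_that("find_maxima honours the prominence definition on designed images", {
  expect_equal(nrow(find_maxima(matrix(7, 10, 10), 100)), 0L)

  # two peaks joined by a ridge: the saddle caps the second peak's prominence
  img <- matrix(0, 10, 10)
  img[3, 3] <- 2000
  img[8, 8] <- 1000
  img[3, 4:8] <- 400
  img[4:7, 8] <- 400
  got <- find_maxima(img, 1700)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$y, got$x), c(2, 2))
  expect_equal(got$prominence_value, 2000)

  # at prominence 500 the second peak appears (prominence 1000 - 400 = 600)
  got2 <- find_maxima(img, 500)
  expect_equal(nrow(got2), 2L)
  expect_equal(got2$prominence_value[2], 600)

  expect_error(find_maxima(matrix(c(1, NA, 2, 3), 2, 2), 1), "non-finite")
  expect_error(find_maxima(img, 0), "> 0")
})

test_that("plateaus emit a single centroid candidate and borders are flagged", {
  img <- matrix(0, 9, 9)
  img[4:6, 4:6] <- 500  # 3x3 plateau centred at (4, 4) 0-based
  got <- find_maxima(img, 100)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$y, got$x), c(4, 4))

  img2 <- matrix(0, 9, 9)
  img2[1, 5] <- 800  # border peak (y = 0)
  img2[6, 5] <- 700
  got2 <- find_maxima(img2, 100)
  expect_true(got2$on_border[got2$y == 0])
  expect_false(got2$on_border[got2$y == 5])
  got3 <- find_maxima(img2, 100, exclude_edges = TRUE)
  expect_equal(got3$y, 5)
})

test_that("find_maxima agrees with the saddle-descent oracle on random images", {
  withr::with_seed(41, {
    for (i in 1:30) {
      m <- random_test_image(12, 12)
      for (prom in c(0.1, 0.4)) {
        got <- find_maxima(m, prom)
        want <- oracle_find_maxima(m, prom)
        expect_equal(nrow(got), nrow(want))
        expect_equal(got$y, want$y)
        expect_equal(got$x, want$x)
        expect_equal(got$prominence_value, want$prominence_value)
      }
    }
  })
})

test_that("candidate count is monotone non-increasing in prominence", {
  withr::with_seed(51, {
    for (i in 1:10) {
      m <- random_test_image()
      counts <- vapply(c(0.05, 0.2, 0.5, 0.9),
                       function(p) nrow(find_maxima(m, p)), numeric(1))
      expect_true(all(diff(counts) <= 0))
    }
  })
})

test_that("spot ROI measurement returns mean, sum and 0.09 um^2 area", {
  img <- matrix(0, 9, 9)
  img[4:6, 4:6] <- 500
  got <- spot_roi_mean(img, y = 4, x = 4)
  expect_equal(got$mean_grey, 500)
  expect_equal(got$raw_integrated_density, 4500)
  expect_equal(got$area_px, 9L)
  expect_equal(got$area_um2, 0.09)
  expect_false(got$clipped)

  withr::with_seed(5, {
    r <- matrix(runif(81, 0, 100), 9, 9)
    g <- spot_roi_mean(r, y = 3, x = 6)
    expect_equal(g$mean_grey, sum(r[3:5, 6:8]) / 9)
    expect_equal(g$raw_integrated_density, g$mean_grey * 9)
  })

  edge <- spot_roi_mean(img, y = 0, x = 0)
  expect_true(edge$clipped)
  expect_equal(edge$area_px, 4L)
  expect_error(spot_roi_mean(img, y = 20, x = 0), "bounds")
})

test_that("polygon measurement matches direct rasterisation", {
  img <- matrix(7, 20, 20)
  sq <- cbind(x = c(4.5, 14.5, 14.5, 4.5), y = c(4.5, 4.5, 14.5, 14.5))
  got <- mean_grey_in_polygon(img, sq)
  expect_equal(got$mean_grey, 7)
  expect_equal(got$area_px, 100L)
  expect_equal(got$area_um2, got$area_px * 0.1^2)

  # triangle over a gradient: compare against a convex barycentric oracle
  grad <- outer(0:19, 0:19, function(y, x) y + 2 * x)
  tri <- cbind(x = c(2.2, 16.8, 3.4), y = c(1.7, 4.2, 17.3))
  g <- expand.grid(y = 0:19, x = 0:19)
  keep <- oracle_in_convex_polygon(g$x, g$y, tri[, 1], tri[, 2])
  want_mean <- mean(grad[cbind(g$y[keep] + 1, g$x[keep] + 1)])
  got_tri <- mean_grey_in_polygon(grad, tri)
  expect_equal(got_tri$mean_grey, want_mean)
  expect_equal(got_tri$area_px, sum(keep))

  tiny <- cbind(x = c(0.1, 0.2, 0.15), y = c(0.6, 0.62, 0.61))
  expect_error(mean_grey_in_polygon(img, tiny), "no pixel centres")
  expect_error(mean_grey_in_polygon(img, sq[1:2, ]), "3 vertices")
})
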