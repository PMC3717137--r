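test_that("ndvi has the standard value, symmetry and zero-denominator handling", {
  expect_equal(ndvi(0.05, 0.45), 0.8)
  expect_equal(ndvi(0.45, 0.05), -0.8)
  expect_equal(ndvi(0.3, 0.3), 0)
  expect_true(is.na(ndvi(0, 0)))
  expect_true(all(abs(ndvi(runif(50), runif(50))) <= 1))
})

test_that("compositing retains near-mean-brightness candidates and picks median NDVI", {
  # brightnesses 0.1, 0.2, 0.9 -> mean 0.4, tolerance 0.28: only 0.2 retained
  cands <- tibble::tibble(
    red = c(0.05, 0.15, 0.85), nir = c(0.15, 0.25, 0.95))
  pick <- composite_best_pixel(cands)
  expect_equal(nrow(pick), 1)
  expect_equal(pick$red, 0.15)

  # single candidate returns itself
  one <- tibble::tibble(red = 0.2, nir = 0.5)
  expect_equal(composite_best_pixel(one), one)

  # even retained count -> lower-middle NDVI order statistic; constant
  # brightness (red + nir = 0.7) so all four are retained, NDVIs 0.2..0.8
  nd <- c(0.2, 0.4, 0.6, 0.8)
  even <- tibble::tibble(red = 0.35 * (1 - nd), nir = 0.35 * (1 + nd))
  expect_equal(ndvi(even$red, even$nir), nd, tolerance = 1e-12)
  pick2 <- composite_best_pixel(even)
  expect_equal(ndvi(pick2$red, pick2$nir), 0.4, tolerance = 1e-12)

  # empty and all-invalid sets give zero rows
  expect_equal(nrow(composite_best_pixel(even[0, ])), 0)
  inval <- dplyr::mutate(even, valid = FALSE)
  expect_equal(nrow(composite_best_pixel(inval)), 0)
})

test_that("compositing matches a brute-force rule enumeration on random stacks", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    cands <- tibble::tibble(red = runif(n, 0, 0.6), nir = runif(n, 0, 0.6),
                            swir = runif(n, 0, 0.6))
    pick <- composite_best_pixel(cands)
    # oracle: direct transliteration of the rule
    bright <- rowMeans(cbind(cands$red, cands$nir, cands$swir))
    keep <- abs(bright - mean(bright)) <= 0.7 * mean(bright)
    ret <- cands[keep, ]
    if (nrow(ret) == 0) {
      expect_equal(nrow(pick), 0)
    } else {
      nd <- (ret$nir - ret$red) / (ret$nir + ret$red)
      expected <- ret[order(nd)[floor((sum(keep) + 1) / 2)], ]
      expect_equal(pick, expected)
      # chosen observation is always a member of the retained set
      expect_true(any(pick$red == ret$red & pick$nir == ret$nir))
    }
  }
})

test_that("cross-sensor calibration recovers exact linear transforms and backfills", {
  set.seed(62)
  fine_v <- matrix(runif(400, 0, 0.5), 20, 20)
  coarse_v <- (fine_v - 0.1) / 2          # fine = 2 * coarse + 0.1
  gaps <- matrix(FALSE, 20, 20); gaps[3:6, 3:6] <- TRUE
  fine_v[gaps] <- NA
  fine <- raster_grid(fine_v, pixel_size = 100)
  coarse <- raster_grid(coarse_v, pixel_size = 100)
  out <- cross_sensor_calibrate(fine, coarse)
  expect_equal(out$gain, 2, tolerance = 1e-9)
  expect_equal(out$offset, 0.1, tolerance = 1e-9)
  expect_equal(out$fill_fraction, 16 / 400)
  expect_false(anyNA(out$filled$values))
  # filled values equal the transformed coarse values
  expect_equal(out$filled$values[gaps], 2 * coarse_v[gaps] + 0.1,
               tolerance = 1e-9)

  # identical sensors: identity transform, nothing to fill
  id <- cross_sensor_calibrate(raster_grid(coarse_v, pixel_size = 100), coarse)
  expect_equal(id$gain, 1, tolerance = 1e-9)
  expect_equal(id$offset, 0, tolerance = 1e-9)
  expect_equal(id$filled$values, coarse_v)

  small <- raster_grid(matrix(runif(25), 5, 5), pixel_size = 100)
  expect_error(cross_sensor_calibrate(small, small, min_overlap = 100),
               "co-occurring")
})

test_that("slope/aspect: flat plane, analytic incline and Horn stencil oracle", {
  flat <- slope_aspect(raster_grid(matrix(5, 6, 6), pixel_size = 10))
  inner <- flat$slope$values[2:5, 2:5]
  expect_true(all(inner == 0))
  expect_true(all(is.na(flat$aspect$values[2:5, 2:5])))

  # dem = 0.1 * x: slope atan(0.1) everywhere, downslope due west (270 deg)
  nc <- 8; nr <- 6; ps <- 10
  xs <- matrix((seq_len(nc) - 0.5) * ps, nr, nc, byrow = TRUE)
  inc <- slope_aspect(raster_grid(0.1 * xs, pixel_size = ps))
  expect_equal(inc$slope$values[3, 4], atan(0.1) * 180 / pi, tolerance = 1e-9)
  expect_equal(inc$slope$values[3, 4], 5.710593, tolerance = 1e-5)
  expect_equal(inc$aspect$values[3, 4], 270)

  set.seed(63)
  dem <- raster_grid(matrix(rnorm(100, 500, 40), 10, 10), pixel_size = 30)
  sa <- slope_aspect(dem)
  for (r in c(2, 5, 9)) for (c in c(2, 6, 9)) {
    o <- oracle_horn_cell(dem$values, r, c, 30)
    expect_equal(sa$slope$values[r, c], o[["slope"]], tolerance = 1e-10)
    expect_equal(sa$aspect$values[r, c], o[["aspect"]], tolerance = 1e-10)
  }
  expect_error(slope_aspect(raster_grid(matrix(1, 2, 2), pixel_size = 1)),
               "3x3")
})

test_that("slope is shift-invariant and aspect flips under DEM negation", {
  set.seed(64)
  z <- matrix(rnorm(64, 100, 20), 8, 8)
  a <- slope_aspect(raster_grid(z, pixel_size = 25))
  b <- slope_aspect(raster_grid(z + 1234, pixel_size = 25))
  expect_equal(a$slope$values, b$slope$values, tolerance = 1e-10)
  neg <- slope_aspect(raster_grid(-z, pixel_size = 25))
  inner <- 2:7
  d <- (a$aspect$values[inner, inner] - neg$aspect$values[inner, inner]) %% 360
  expect_true(all(abs(d - 180) < 1e-8))
})

test_that("median smoothing matches a brute-force sliding window and removes spikes", {
  set.seed(65)
  v <- matrix(rnorm(300), 15, 20)
  v[4, 5] <- NA
  r <- raster_grid(v, pixel_size = 100)
  sm <- median_smooth(r, 5)
  expect_equal(sm$values, oracle_median_filter(v, 5), tolerance = 1e-12)

  # constants are fixed points
  const <- raster_grid(matrix(7, 9, 9), pixel_size = 1)
  expect_equal(median_smooth(const, 5)$values, const$values)

  # an isolated spike in a constant field disappears
  spike <- matrix(3, 11, 11); spike[6, 6] <- 500
  out <- median_smooth(raster_grid(spike, pixel_size = 1), 5)
  expect_true(all(out$values == 3))

  # idempotent on a monotone ramp away from the truncated edge windows
  ramp <- raster_grid(matrix(seq_len(12), 12, 12), pixel_size = 1)
  once <- median_smooth(ramp, 3)
  twice <- median_smooth(once, 3)
  expect_equal(twice$values[3:10, 3:10], once$values[3:10, 3:10])

  expect_error(median_smooth(r, 4), "odd")
})

test_that("seasonality counts strictly-dry months", {
  expect_equal(seasonality_index(rep(200, 12)), 0)
  expect_equal(seasonality_index(rep(50, 12)), 12)
  expect_equal(seasonality_index(c(50, 99, 100, 101, 150, rep(200, 7))), 2)
  expect_error(seasonality_index(rep(100, 11)), "12")
  expect_error(seasonality_index(c(rep(100, 11), -5)), "negative")
})
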