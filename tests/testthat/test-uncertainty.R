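test_that("homoskedastic residuals give a near-constant RMSE curve", {
  set.seed(81)
  pred <- runif(3000, 10, 150)
  obs <- pred + rnorm(3000, sd = 5)
  em <- fit_rmse_polynomial(pred, obs)
  evals <- predict_rmse(em, seq(20, 140, by = 10))
  expect_true(all(abs(evals - 5) < 1))
  # zero residuals -> zero polynomial
  em0 <- fit_rmse_polynomial(pred, pred)
  expect_equal(predict_rmse(em0, c(20, 80, 140)), c(0, 0, 0), tolerance = 1e-8)
})

test_that("proportional residual noise yields an increasing RMSE curve", {
  set.seed(82)
  pred <- runif(4000, 10, 150)
  obs <- pred + rnorm(4000, sd = 0.15 * pred)
  em <- fit_rmse_polynomial(pred, obs)
  evals <- predict_rmse(em, c(20, 60, 100, 140))
  expect_true(all(diff(evals) > 0))
  expect_equal(evals, 0.15 * c(20, 60, 100, 140), tolerance = 0.15)
  # the polynomial reproduces the per-bin RMSE it was fitted to
  at_bins <- predict_rmse(em, em$bins$center)
  expect_lt(sqrt(weighted.mean((at_bins - em$bins$rmse)^2, em$bins$n)),
            0.1 * mean(em$bins$rmse))
})

test_that("sparse bins are merged and too few bins raise", {
  set.seed(83)
  pred <- c(runif(200, 10, 50), 120)     # a lone residual far out
  obs <- pred + rnorm(201, sd = 4)
  em <- fit_rmse_polynomial(pred, obs, bin_width = 10)
  expect_true(all(em$bins$n >= 5))
  expect_error(fit_rmse_polynomial(runif(30, 0, 5), runif(30, 0, 5),
                                   bin_width = 10), "4 populated bins")
})

test_that("quantile bands recover closed-form slopes under scaled-normal errors", {
  set.seed(84)
  pred <- runif(4000, 10, 150)
  obs <- pred - 0.1 * pred * rnorm(4000)   # residual = 0.1 * pred * eps
  qb <- quantile_residual_bands(pred, obs)
  z95 <- qnorm(0.95)
  expect_equal(qb$slope[qb$quantile == 0.95], 0.1 * z95, tolerance = 0.012)
  expect_equal(qb$slope[qb$quantile == 0.05], -0.1 * z95, tolerance = 0.012)
  expect_lt(abs(qb$slope[qb$quantile == 0.5]), 0.01)
  expect_lt(abs(qb$intercept[qb$quantile == 0.5]), 1.5)

  # symmetric homoskedastic errors: flat bands, median near zero
  obs2 <- pred + rnorm(4000, sd = 6)
  qb2 <- quantile_residual_bands(pred, obs2)
  expect_true(all(abs(qb2$slope) < 0.02))
  expect_lt(abs(qb2$intercept[qb2$quantile == 0.5]), 0.6)

  expect_error(quantile_residual_bands(pred[1:10], obs[1:10]), "50")
  expect_error(quantile_residual_bands(pred, obs, quantiles = c(0, 0.5)),
               "inside")
})

test_that("error propagation is root-sum-square off LiDAR and LiDAR-only on transects", {
  tmpl <- raster_grid(matrix(0, 6, 6), pixel_size = 100)
  acd <- raster_like(tmpl, matrix(30, 6, 6))
  mask <- raster_like(tmpl, matrix(rep(c(1, 0, 0), 12), 6, 6))
  # model with lidar error 3 and constant upscaling rmse 4 at ACD 30
  em <- structure(list(rmse_poly = c(4, 0, 0, 0),
                       lidar_error_fn = function(a) 0.1 * a,
                       bins = NULL, bin_width = 10, range = c(0, 100)),
                  class = "error_model")
  err <- propagate_error_map(acd, mask, em)
  on <- mask$values > 0
  expect_true(all(err$values[on] == 3))            # 0.1 * 30
  expect_true(all(err$values[!on] == 5))           # sqrt(3^2 + 4^2)
  # degenerate: no upscaling error -> LiDAR error everywhere
  em0 <- em; em0$rmse_poly <- c(0, 0, 0, 0)
  err0 <- propagate_error_map(acd, mask, em0)
  expect_true(all(err0$values == 3))
  # rss dominance: off-LiDAR error never below LiDAR error at equal ACD
  expect_true(all(err$values[!on] >= err$values[on]))
  # nodata propagates
  acd2 <- acd; acd2$values[2, 2] <- NA
  expect_true(is.na(propagate_error_map(acd2, mask, em)$values[2, 2]))
})

test_that("propagated error is monotone in each component", {
  acd <- raster_grid(matrix(seq(10, 150, length.out = 36), 6, 6), pixel_size = 100)
  mask <- raster_grid(matrix(0, 6, 6), pixel_size = 100)
  base <- structure(list(rmse_poly = c(2, 0.05, 0, 0),
                         lidar_error_fn = function(a) 0.1 * a),
                    class = "error_model")
  bigger_l <- base; bigger_l$lidar_error_fn <- function(a) 0.15 * a
  bigger_m <- base; bigger_m$rmse_poly <- c(4, 0.08, 0, 0)
  e0 <- propagate_error_map(acd, mask, base)$values
  expect_true(all(propagate_error_map(acd, mask, bigger_l)$values >= e0))
  expect_true(all(propagate_error_map(acd, mask, bigger_m)$values >= e0))
})

test_that("interval coverage is nominal when the error model is well-specified", {
  set.seed(85)
  # calibration sample for the error model
  pred_cal <- runif(6000, 10, 150)
  sd_fun <- function(p) 3 + 0.08 * p
  obs_cal <- pred_cal + rnorm(6000, sd = sd_fun(pred_cal))
  em <- fit_rmse_polynomial(pred_cal, obs_cal, lidar_error_rate = 0)
  # fresh field, all off-LiDAR so eps = fitted rmse curve
  pred <- raster_grid(matrix(runif(10000, 10, 150), 100, 100), pixel_size = 100)
  truth <- pred$values + rnorm(10000, sd = sd_fun(pred$values))
  mask <- raster_grid(matrix(0, 100, 100), pixel_size = 100)
  eps <- propagate_error_map(pred, mask, em)$values
  cover <- mean(abs(truth - pred$values) <= 1.96 * eps)
  expect_lt(abs(cover - 0.95), 0.03)
})

test_that("ecoregion bias reports match brute-force zonal statistics", {
  set.seed(86)
  nat <- raster_grid(matrix(runif(400, 20, 120), 20, 20), pixel_size = 100)
  lid <- raster_grid(nat$values + rnorm(400, 2, 5), pixel_size = 100)
  regions <- tibble::tibble(region = c("a", "b"),
                            row0 = c(2, 12), row1 = c(8, 18),
                            col0 = c(3, 11), col1 = c(9, 19))
  rep_ <- ecoregion_bias_report(nat, lid, regions, min_cells = 10)
  for (i in 1:2) {
    sub_n <- nat$values[regions$row0[i]:regions$row1[i],
                        regions$col0[i]:regions$col1[i]]
    sub_l <- lid$values[regions$row0[i]:regions$row1[i],
                        regions$col0[i]:regions$col1[i]]
    expect_equal(rep_$bias[i], mean(sub_n - sub_l), tolerance = 1e-12)
    expect_equal(rep_$rmse[i], sqrt(mean((sub_n - sub_l)^2)), tolerance = 1e-12)
    expect_equal(rep_$n_cells[i], length(sub_n))
  }
  # identical maps: zero bias and rmse everywhere
  id <- ecoregion_bias_report(nat, nat, regions, min_cells = 10)
  expect_true(all(id$bias == 0) && all(id$rmse == 0))
  # constant shift propagates exactly
  shifted <- raster_like(nat, nat$values + 7)
  sh <- ecoregion_bias_report(shifted, nat, regions, min_cells = 10)
  expect_equal(sh$bias, c(7, 7), tolerance = 1e-12)
  expect_s3_class(autoplot(rep_), "ggplot")
  expect_warning(
    expect_warning(ecoregion_bias_report(nat, lid, regions, min_cells = 1e5),
                   "valid cells"),
    "valid cells")
})
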