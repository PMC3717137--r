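test_that("stratification partitions the landscape into joint bins", {
  stack <- make_test_stack()
  # single variable, 3 bins
  s1 <- build_strata(stack["pv"], bins = list(pv = c(0, 1/3, 2/3, 1)))
  expect_lte(nrow(s1$classes), 3)
  expect_false(anyNA(s1$class_map$values))

  # two variables, 3 x 4 fully populated combinations
  nr <- 12; nc <- 12
  tmpl <- raster_grid(matrix(0, nr, nc), pixel_size = 100)
  a <- raster_like(tmpl, matrix(rep(c(0.1, 0.4, 0.7), each = 48), nr, nc))
  b <- raster_like(tmpl, matrix(rep(c(1, 3, 5, 7), times = 36), nr, nc))
  s2 <- build_strata(list(va = a, vb = b),
                     bins = list(va = c(0, 0.3, 0.6, 0.9),
                                 vb = c(0, 2, 4, 6, 8)))
  expect_equal(nrow(s2$classes), 12)
  expect_equal(sum(s2$classes$area_cells), nr * nc)

  # identical cells collapse to one class
  s3 <- build_strata(list(va = raster_like(tmpl, matrix(0.5, nr, nc))),
                     bins = list(va = c(0, 1)))
  expect_equal(nrow(s3$classes), 1)

  # out-of-range values are clamped into end bins and counted
  s4 <- build_strata(list(va = raster_like(tmpl, matrix(c(-5, rep(0.5, 143)), nr, nc))),
                     bins = list(va = c(0, 1)))
  expect_equal(s4$n_clamped, 1)
  expect_equal(nrow(s4$classes), 1)

  expect_error(build_strata(stack, bins = list(pv = c(0.5, 0.5))), "increasing")
  expect_error(build_strata(stack, bins = list(nosuch = c(0, 1))), "no covariate")
})

test_that("stratified mapping reproduces per-class medians (group-by oracle)", {
  set.seed(71)
  stack <- make_test_stack()
  bins <- list(elevation = seq(100, 310, by = 30), pv = seq(0, 1, by = 0.25))
  strata <- build_strata(stack, bins = bins)
  # ACD an exact function of the binned covariates
  cls <- strata$class_map$values
  acd_by_class <- 10 + 7 * (seq_len(max(cls)) %% 13)
  lidar_acd <- raster_like(stack$pv, matrix(acd_by_class[cls], nrow(cls), ncol(cls)))
  mask <- raster_like(stack$pv, matrix(rbinom(400, 1, 0.5), 20, 20))
  out <- stratified_acd_map(strata, lidar_acd, mask, stack$pv)
  covered <- !out$strata_table$fallback[cls]
  # brute-force oracle: per-class median of sampled cells
  df <- data.frame(cls = as.vector(cls), acd = as.vector(lidar_acd$values),
                   s = as.vector(mask$values) > 0)
  med <- tapply(df$acd[df$s], df$cls[df$s], median)
  for (k in unique(as.vector(cls))) {
    if (!is.na(med[as.character(k)])) {
      cells <- out$acd_map$values[cls == k]
      tab <- out$strata_table[out$strata_table$class_id == k, ]
      if (!tab$fallback) expect_equal(unique(cells), unname(med[as.character(k)]))
    }
  }
  # mapped values that aren't fallback equal their class median exactly
  expect_true(all(is.finite(out$acd_map$values)))
})

test_that("classes under 1% coverage fall back to PV-bin medians", {
  nr <- 20; nc <- 20
  tmpl <- raster_grid(matrix(0, nr, nc), pixel_size = 100)
  # two classes split by elevation; class 2 has 0.5% coverage (1 of 200 cells)
  elev <- raster_like(tmpl, matrix(rep(c(100, 400), each = 200), nr, nc))
  pv <- raster_like(tmpl, matrix(0.85, nr, nc))
  strata <- build_strata(list(elevation = elev, pv = pv),
                         bins = list(elevation = c(0, 250, 500),
                                     pv = seq(0, 1, 0.1)))
  acd_vals <- matrix(c(rep(40, 200), rep(120, 200)), nr, nc)
  lidar_acd <- raster_like(tmpl, acd_vals)
  mask_vals <- matrix(0, nr, nc)
  mask_vals[, 1:5] <- 1                 # class 1 fully covered (cols 1-5 in its half)
  mask_vals[, 11:20] <- 0
  mask_vals[3, 14] <- 1                 # exactly one sampled cell in class 2
  mask <- raster_like(tmpl, mask_vals)
  out <- stratified_acd_map(strata, lidar_acd, mask, pv)
  tab <- out$strata_table
  cls2 <- tab$class_id[tab$coverage < 0.01]
  expect_length(cls2, 1)
  expect_true(tab$fallback[tab$class_id == cls2])
  # fallback value: median over ALL sampled cells in the 0.8-0.9 PV bin,
  # i.e. 100 cells at 40 plus one at 120 -> 40
  fb_cells <- out$acd_map$values[strata$class_map$values == cls2]
  expect_true(all(fb_cells == 40))
  # with full coverage and one class the map is the global median
  strata1 <- build_strata(list(pv = pv), bins = list(pv = c(0, 1)))
  full <- raster_like(tmpl, matrix(1, nr, nc))
  out1 <- stratified_acd_map(strata1, lidar_acd, full, pv)
  expect_true(all(out1$acd_map$values == median(acd_vals)))
})

test_that("ensemble training strides the ordered sample and is seed-deterministic", {
  set.seed(72)
  b <- generate_landscape(landscape_config(grid_rows = 30, grid_cols = 34, seed = 6))
  lidar_acd <- b$true_acd
  mask <- sample_transects(b, spacing = 5, swath = 1)
  n_cells <- sum(mask$values > 0)
  m <- train_ensemble(b$covariates, lidar_acd, mask, stride = 2,
                      n_trees = 50, seed = 11)
  expect_equal(m$report$n_ingested, ceiling(n_cells / 2))
  expect_equal(m$report$n_sampled, n_cells)

  p1 <- predict_ensemble(m, b$covariates)
  m2 <- train_ensemble(b$covariates, lidar_acd, mask, stride = 2,
                       n_trees = 50, seed = 11)
  p2 <- predict_ensemble(m2, b$covariates)
  expect_identical(p1$values, p2$values)

  # predictions bounded by the training range (tree averaging)
  expect_gte(min(p1$values), m$train_range[1])
  expect_lte(max(p1$values), m$train_range[2])

  expect_error(train_ensemble(b$covariates, lidar_acd, mask, stride = 50),
               "training cells")
})

test_that("a deterministic covariate-driven field is learnable and memorised", {
  b <- generate_landscape(landscape_config(grid_rows = 25, grid_cols = 25,
                                           noise_cv = 0, seed = 14))
  full <- raster_like(b$true_acd, matrix(1, 25, 25))
  m <- train_ensemble(b$covariates, b$true_acd, full, stride = 1,
                      n_trees = 200, seed = 3)
  pred <- predict_ensemble(m, b$covariates)
  ss_res <- sum((pred$values - b$true_acd$values)^2)
  ss_tot <- sum((b$true_acd$values - mean(b$true_acd$values))^2)
  expect_gt(1 - ss_res / ss_tot, 0.95)

  # overwrite mode pins sampled cells to the LiDAR estimate exactly
  over <- predict_ensemble(m, b$covariates, lidar_acd = b$true_acd,
                           lidar_mask = full, overwrite_lidar = TRUE)
  expect_identical(over$values, b$true_acd$values)
  expect_error(predict_ensemble(m, b$covariates[1:3]), "feature")
})

test_that("both upscalers are mass-plausible and the forest beats stratification on smooth fields", {
  b <- generate_landscape(landscape_config(grid_rows = 40, grid_cols = 50,
                                           noise_cv = 0.05, seed = 25))
  mask <- sample_transects(b, spacing = 10, swath = 1)
  lidar_acd <- b$true_acd
  strata <- build_strata(b$covariates)
  sm <- stratified_acd_map(strata, lidar_acd, mask, b$covariates$pv)
  m <- train_ensemble(b$covariates, lidar_acd, mask, stride = 1,
                      n_trees = 150, seed = 4)
  pm <- predict_ensemble(m, b$covariates)
  obs <- lidar_acd$values[mask$values > 0]
  for (map in list(sm$acd_map, pm)) {
    mu <- mean(map$values, na.rm = TRUE)
    expect_gte(mu, min(obs)); expect_lte(mu, max(obs))
  }
  # mapped stratification values are medians of sampled cells, so they live
  # inside the sampled-cell range (midpoints for even counts included)
  mapped <- unique(sm$acd_map$values[is.finite(sm$acd_map$values)])
  expect_true(all(mapped >= min(obs) & mapped <= max(obs)))
  rmse <- function(x) sqrt(mean((x - b$true_acd$values)^2, na.rm = TRUE))
  expect_lt(rmse(pm$values), rmse(sm$acd_map$values))
})
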