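# Satellite covariate engineering: compositing, cross-sensor backfill,
# terrain derivatives, climate smoothing and seasonality.

#' Normalized Difference Vegetation Index
#'
#' @param red,nir reflectances in [0, 1] (vectors or matrices of equal shape).
#' @return `(nir - red) / (nir + red)`, `NA` where the denominator is zero.
#' @export
ndvi <- function(red, nir) {
  denom <- nir + red
  out <- (nir - red) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Select the best observation from a stack of candidates
#'
#' Cloud-free compositing rule for a single location: compute per-candidate
#' brightness (mean reflectance across bands), retain candidates whose
#' brightness lies within 70% of the mean brightness, then return the
#' retained candidate with the median NDVI (lower-middle order statistic for
#' even counts, for determinism).
#'
#' @param candidates tibble, one row per candidate observation, with columns
#'   `red`, `nir`, any further band columns, and optionally `valid`
#'   (logical).
#' @param brightness_tol fractional tolerance around the mean brightness
#'   (default 0.70). Set `mode = "plusminus"` to read it as a +/- band
#'   around 1 (i.e. retain brightness in `[(1-tol), (1+tol)] * mean`).
#' @param mode `"absolute"` (default; |b - mean| <= tol * mean) or
#'   `"plusminus"`.
#' @return The selected row as a one-row tibble, or a zero-row tibble when
#'   no candidate is valid.
#' @export
composite_best_pixel <- function(candidates, brightness_tol = 0.70,
                                 mode = c("absolute", "plusminus")) {
  mode <- match.arg(mode)
  candidates <- tibble::as_tibble(candidates)
  if ("valid" %in% names(candidates)) {
    candidates <- dplyr::filter(candidates, .data$valid)
  }
  if (nrow(candidates) == 0L) return(candidates)
  band_cols <- setdiff(names(candidates), c("valid", "candidate_id"))
  band_cols <- band_cols[purrr::map_lgl(candidates[band_cols], is.numeric)]
  bright <- rowMeans(as.matrix(candidates[band_cols]))
  mb <- mean(bright)
  # "absolute": |b - mean| <= tol * mean (tol = 0.70).
  # "plusminus": brightness within tol..1 of the mean read as a +/-(1 - tol)
  # band, i.e. |b - mean| <= (1 - tol) * mean.
  tol <- if (mode == "absolute") brightness_tol * mb else (1 - brightness_tol) * mb
  keep <- abs(bright - mb) <= tol
  retained <- candidates[keep, , drop = FALSE]
  if (nrow(retained) == 0L) return(retained)
  nd <- ndvi(retained$red, retained$nir)
  ord <- order(nd)
  pick <- ord[floor((length(ord) + 1) / 2)]  # lower-middle for even counts
  retained[pick, , drop = FALSE]
}

#' Composite a full grid of candidate stacks
#'
#' Applies [composite_best_pixel()] at every location of a nested candidate
#' table.
#'
#' @param candidate_tbl tibble with columns `row`, `col` and a list-column
#'   `candidates` of per-location candidate tibbles.
#' @param ... passed to [composite_best_pixel()].
#' @return A tibble with `row`, `col` and the selected observation's band
#'   columns (`NA` rows where nothing valid existed).
#' @export
composite_grid <- function(candidate_tbl, ...) {
  picks <- purrr::map(candidate_tbl$candidates, composite_best_pixel, ...)
  template <- picks[purrr::map_int(picks, nrow) > 0][[1]]
  na_row <- template[1, , drop = FALSE]
  na_row[1, ] <- NA
  picks <- purrr::map(picks, ~ if (nrow(.x) == 0L) na_row else .x)
  dplyr::bind_cols(candidate_tbl[c("row", "col")], dplyr::bind_rows(picks))
}

#' Cross-sensor linear calibration and gap backfill
#'
#' Fits `fine ~ gain * coarse + offset` by least squares over co-occurring
#' valid pixels, then fills the fine sensor's gaps with transformed coarse
#' values — the standard treatment when a persistent-cloud region has
#' coarse-sensor coverage only.
#'
#' @param fine,coarse co-registered `raster_grid`s of the same band from the
#'   two sensors (`NA` = gap).
#' @param min_overlap minimum co-occurring valid pixels required
#'   (default 100).
#' @return A list: `filled` (raster), `gain`, `offset`, `n_overlap`,
#'   `fill_fraction` (fraction of all cells backfilled).
#' @export
cross_sensor_calibrate <- function(fine, coarse, min_overlap = 100) {
  check_aligned(fine, coarse, "sensor grids")
  f <- fine$values; c_ <- coarse$values
  both <- is.finite(f) & is.finite(c_)
  if (sum(both) < min_overlap)
    stop(sprintf("only %d co-occurring pixels; need >= %d", sum(both), min_overlap),
         call. = FALSE)
  fit <- stats::lm(f[both] ~ c_[both])
  offset <- unname(stats::coef(fit)[1]); gain <- unname(stats::coef(fit)[2])
  gaps <- !is.finite(f) & is.finite(c_)
  f[gaps] <- gain * c_[gaps] + offset
  list(
    filled = raster_like(fine, f),
    gain = gain, offset = offset,
    n_overlap = sum(both),
    fill_fraction = sum(gaps) / length(f)
  )
}

#' Slope and aspect from a DEM (Horn 3x3 method)
#'
#' Finite-difference gradients over the 8 neighbours (Horn weighting), slope
#' as arctan of the gradient magnitude in degrees, aspect as the downslope
#' bearing in degrees clockwise from north in [0, 360). Cells with gradient
#' magnitude below `flat_tol` get `NA` aspect; the one-cell border (and any
#' cell with a missing neighbour) is `NA` for both.
#'
#' @param dem a `raster_grid` of elevation (m), at least 3x3.
#' @param flat_tol gradient magnitude (m/m) below which a cell is flat.
#' @return A list of two `raster_grid`s: `slope` (deg), `aspect` (deg).
#' @export
slope_aspect <- function(dem, flat_tol = 1e-8) {
  stopifnot(is_raster_grid(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("DEM must be at least 3x3", call. = FALSE)
  ps <- dem$pixel_size
  slope <- matrix(NA_real_, nr, nc)
  aspect <- matrix(NA_real_, nr, nc)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  # neighbour blocks around the interior (row 1 = north)
  nw <- z[ri - 1, ci - 1]; n_ <- z[ri - 1, ci]; ne <- z[ri - 1, ci + 1]
  w_ <- z[ri, ci - 1];                         e_ <- z[ri, ci + 1]
  sw <- z[ri + 1, ci - 1]; s_ <- z[ri + 1, ci]; se <- z[ri + 1, ci + 1]
  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * ps)  # dz/dx, east
  gy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * ps)  # dz/dy, north
  gmag <- sqrt(gx^2 + gy^2)
  sl <- atan(gmag) * 180 / pi
  # aspect: bearing of steepest descent (-gx, -gy), clockwise from north
  asp <- (atan2(-gx, -gy) * 180 / pi) %% 360
  asp[gmag < flat_tol] <- NA_real_
  sl[!is.finite(gmag)] <- NA_real_
  slope[ri, ci] <- sl
  aspect[ri, ci] <- asp
  list(slope = raster_like(dem, slope), aspect = raster_like(dem, aspect))
}

#' Terrain derivatives at two resolutions
#'
#' Computes slope/aspect on the native DEM and again on a pixel-averaged
#' coarser DEM, mirroring the use of both a fine and a ~1-km terrain signal
#' as upscaling covariates.
#'
#' @param dem a `raster_grid`.
#' @param coarse_factor block size for the coarse variant.
#' @return List with `fine` and `coarse`, each a list of `slope`, `aspect`.
#' @export
terrain_two_scales <- function(dem, coarse_factor = 10) {
  list(
    fine = slope_aspect(dem),
    coarse = slope_aspect(aggregate_to_hectare(dem, coarse_factor))
  )
}

#' Median filter of a raster
#'
#' Per-cell median of valid values in a `window` x `window` neighbourhood,
#' truncated at edges. Used to smooth coarse, noisy climate surfaces before
#' mapping.
#'
#' @param raster a `raster_grid`.
#' @param window odd integer window edge (default 5).
#' @return Smoothed `raster_grid`.
#' @export
median_smooth <- function(raster, window = 5) {
  stopifnot(is_raster_grid(raster))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  h <- window %/% 2L
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    r0 <- max(1L, r - h); r1 <- min(nr, r + h)
    for (c in seq_len(nc)) {
      c0 <- max(1L, c - h); c1 <- min(nc, c + h)
      block <- v[r0:r1, c0:c1]
      block <- block[is.finite(block)]
      if (length(block)) out[r, c] <- stats::median(block)
    }
  }
  raster_like(raster, out)
}

#' Dry-season length from monthly rainfall
#'
#' Counts the months with rainfall strictly below the dry-month threshold.
#'
#' @param monthly_rain numeric vector of exactly 12 monthly totals (mm).
#' @param threshold dry-month cutoff (mm, default 100); a month exactly at
#'   the threshold is not dry.
#' @return Integer count in [0, 12] (months yr^-1).
#' @export
seasonality_index <- function(monthly_rain, threshold = 100) {
  if (length(monthly_rain) != 12L)
    stop("`monthly_rain` must have exactly 12 values", call. = FALSE)
  if (any(monthly_rain < 0)) stop("rainfall cannot be negative", call. = FALSE)
  sum(monthly_rain < threshold)
}
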