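# Canopy-height derivation and aggregation.

#' Canopy height model from surface and terrain models
#'
#' CHM = DSM - DTM, with negative differences (surface below modelled ground,
#' a common artefact over bare or mis-triangulated terrain) clamped to zero.
#' Nodata in either input propagates.
#'
#' @param dsm,dtm co-registered `raster_grid`s (m elevation).
#' @return A `raster_grid` of canopy height (m) with attribute
#'   `clamped_cells`: the count of negative cells set to 0.
#' @export
compute_chm <- function(dsm, dtm) {
  check_aligned(dsm, dtm, "DSM and DTM")
  chm <- dsm$values - dtm$values
  clamped <- sum(chm < 0, na.rm = TRUE)
  chm[chm < 0] <- 0
  out <- raster_like(dsm, chm)
  attr(out, "clamped_cells") <- clamped
  out
}

#' Mean top-of-canopy height over a plot footprint
#'
#' Averages every CHM pixel whose centre falls inside the footprint polygon
#' (half-open boundary rule, see [point_in_polygon()]). This is the TCH
#' statistic paired with plot carbon estimates in LiDAR calibration.
#'
#' @param chm a fine-resolution `raster_grid` of canopy height (m).
#' @param footprint polygon tibble with columns `x`, `y` in the raster CRS.
#' @return A single number: mean height (m) of selected pixels, with
#'   attribute `n_pixels`.
#' @export
plot_tch <- function(chm, footprint) {
  stopifnot(is_raster_grid(chm))
  cc <- cell_centers(chm)
  # restrict the point-in-polygon test to the footprint's bounding box
  ps <- chm$pixel_size
  inbox <- cc$x >= min(footprint$x) - ps & cc$x <= max(footprint$x) + ps &
    cc$y >= min(footprint$y) - ps & cc$y <= max(footprint$y) + ps
  idx <- which(inbox)
  if (length(idx) == 0L) stop("footprint does not overlap the grid", call. = FALSE)
  sel <- idx[point_in_polygon(cc$x[idx], cc$y[idx], footprint)]
  vals <- chm$values[sel]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L)
    stop("no valid pixel centres fall inside the footprint", call. = FALSE)
  out <- mean(vals)
  attr(out, "n_pixels") <- length(vals)
  out
}

#' Aggregate a fine raster to coarser blocks by averaging
#'
#' Non-overlapping factor-by-factor blocks are reduced to the mean of their
#' valid pixels; blocks where fewer than `min_valid_frac` of pixels are valid
#' become nodata. Used to bring ~1 m canopy height (and any other fine
#' product) to the 1-ha analysis grid.
#'
#' @param fine a `raster_grid` whose dimensions are divisible by `factor`.
#' @param factor integer block edge (e.g. 10 for 10 m -> 100 m pixels).
#' @param min_valid_frac minimum fraction of valid pixels per block
#'   (default 0.5).
#' @return A `raster_grid` with dimensions `dim(fine)/factor` and pixel size
#'   `factor * fine$pixel_size`.
#' @export
aggregate_to_hectare <- function(fine, factor, min_valid_frac = 0.5) {
  stopifnot(is_raster_grid(fine))
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be a positive integer", call. = FALSE)
  if (factor == 1L) return(fine)
  v <- fine$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr %% factor != 0L || nc %% factor != 0L)
    stop("fine grid dimensions must be divisible by `factor`", call. = FALSE)
  NR <- nr %/% factor; NC <- nc %/% factor
  br <- (seq_len(nr) - 1L) %/% factor + 1L
  bc <- (seq_len(nc) - 1L) %/% factor + 1L
  grp <- matrix(br, nr, nc) + NR * matrix(bc - 1L, nr, nc, byrow = TRUE)
  ok <- is.finite(v)
  sums <- tapply(ifelse(ok, v, 0), grp, sum)
  cnts <- tapply(as.numeric(ok), grp, sum)
  means <- as.numeric(sums) / as.numeric(cnts)
  means[as.numeric(cnts) < min_valid_frac * factor^2] <- NA_real_
  out <- matrix(NA_real_, NR, NC)
  out[as.integer(names(sums))] <- means
  raster_grid(out, pixel_size = fine$pixel_size * factor,
              xmin = fine$xmin, ymin = fine$ymin, crs = fine$crs)
}
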