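# Planar polygon helpers. All coordinates are in the raster CRS (metres).
# Polygons are tibbles/data.frames with numeric columns x, y, vertices in
# order, ring implicitly closed.

#' Axis-aligned square footprint polygon
#'
#' Convenience constructor for plot footprints: a square of the given area
#' centred at (x, y).
#'
#' @param x,y centre coordinates (m).
#' @param area_ha footprint area in hectares.
#' @return A tibble of 4 vertices with columns `x`, `y`.
#' @export
square_footprint <- function(x, y, area_ha) {
  stopifnot(area_ha > 0)
  half <- sqrt(area_ha * 1e4) / 2
  tibble::tibble(
    x = c(x - half, x + half, x + half, x - half),
    y = c(y - half, y - half, y + half, y + half)
  )
}

#' Shoelace area of a polygon (m^2)
#' @keywords internal
#' @noRd
polygon_area <- function(poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting with the half-open edge convention: a point exactly on a
#' bottom or left edge counts as inside, on a top or right edge as outside,
#' so abutting footprints partition pixel centres without double counting.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly polygon as a data frame with columns `x`, `y`.
#' @return Logical vector, `TRUE` where the point falls inside.
#' @export
point_in_polygon <- function(px, py, poly) {
  vx <- poly$x; vy <- poly$y
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    # edge (j -> i); half-open in y: crossing counted when exactly one
    # endpoint is strictly above the test point
    cross <- (vy[i] > py) != (vy[j] > py)
    if (any(cross)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside[cross] <- xor(inside[cross], px[cross] < xint[cross])
    }
    j <- i
  }
  inside
}

#' Rectangular region table to polygon list
#'
#' Converts a regions tibble (one row per rectangle, cell-index bounds) into
#' labelled polygons in map coordinates.
#'
#' @param regions tibble with columns `region`, `row0`, `row1`, `col0`, `col1`
#'   (inclusive 1-based cell indices on `grid`).
#' @param grid the `raster_grid` the indices refer to.
#' @return A named list of vertex tibbles, one per region.
#' @export
regions_to_polygons <- function(regions, grid) {
  stopifnot(is_raster_grid(grid))
  ps <- grid$pixel_size
  nr <- nrow(grid$values)
  purrr::map(split(regions, regions$region), function(r) {
    x0 <- grid$xmin + (r$col0 - 1) * ps
    x1 <- grid$xmin + r$col1 * ps
    # row 1 is north: convert row index range to y range
    y1 <- grid$ymin + (nr - r$row0 + 1) * ps
    y0 <- grid$ymin + (nr - r$row1) * ps
    tibble::tibble(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  })
}

#' Write footprints or regions as GeoJSON
#'
#' @param polys named list of vertex tibbles (columns `x`, `y`).
#' @param path output path.
#' @param id_field property name for the polygon label.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polys, path, id_field = "id") {
  features <- purrr::imap(polys, function(p, nm) {
    ring <- cbind(p$x, p$y)
    ring <- rbind(ring, ring[1, , drop = FALSE])
    props <- list(); props[[id_field]] <- nm
    list(
      type = "Feature",
      properties = props,
      geometry = list(type = "Polygon",
                      coordinates = list(apply(ring, 1, as.list)))
    )
  })
  gj <- list(type = "FeatureCollection", features = unname(features))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of polygons.
#' @param id_field property used as the polygon label.
#' @return Named list of vertex tibbles.
#' @export
read_polygons_geojson <- function(path, id_field = "id") {
  gj <- jsonlite::read_json(path)
  polys <- purrr::map(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, purrr::map(ring, ~ c(.x[[1]], .x[[2]])))
    # drop closing vertex
    xy <- xy[-nrow(xy), , drop = FALSE]
    tibble::tibble(x = xy[, 1], y = xy[, 2])
  })
  names(polys) <- purrr::map_chr(gj$features, ~ as.character(.x$properties[[id_field]]))
  polys
}
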