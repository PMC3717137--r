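#' Gridded raster container
#'
#' A minimal single-band raster: a numeric matrix plus an affine georeference
#' (origin of the lower-left corner, square pixels) and a free-text CRS tag.
#' Row 1 is the northernmost row; pixels are centre-registered, so the centre
#' of cell \code{[r, c]} sits at
#' \code{x = xmin + (c - 0.5) * pixel_size},
#' \code{y = ymin + (nrow - r + 0.5) * pixel_size}.
#' Missing cells are `NA` internally; file I/O maps them to a nodata sentinel.
#'
#' @param values numeric matrix (row 1 = north).
#' @param pixel_size pixel edge length in metres. Must be positive.
#' @param xmin,ymin coordinates of the grid's lower-left corner (m).
#' @param crs character tag carried through operations, never interpreted.
#' @return A `raster_grid` object.
#' @examples
#' r <- raster_grid(matrix(1:12, 3, 4), pixel_size = 100)
#' dim(r)
#' @export
raster_grid <- function(values, pixel_size = 100, xmin = 0, ymin = 0,
                        crs = "local-metric") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  structure(
    list(values = values, pixel_size = pixel_size,
         xmin = xmin, ymin = ymin, crs = crs),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, %g m pixels, origin (%g, %g), crs: %s\n",
              nrow(v), ncol(v), x$pixel_size, x$xmin, x$ymin, x$crs))
  ok <- is.finite(v)
  if (any(ok)) {
    cat(sprintf("  values: [%.4g, %.4g], mean %.4g; %d NA cells\n",
                min(v[ok]), max(v[ok]), mean(v[ok]), sum(!ok)))
  } else {
    cat("  all cells NA\n")
  }
  invisible(x)
}

#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Replace the cell values of a raster, keeping its georeference
#'
#' @param x a `raster_grid` template.
#' @param values a matrix with the same dimensions as `x`.
#' @return A `raster_grid` with `x`'s transform and the new values.
#' @export
raster_like <- function(x, values) {
  stopifnot(is_raster_grid(x))
  values <- as.matrix(values)
  if (!all(dim(values) == dim(x$values)))
    stop("replacement values have wrong dimensions", call. = FALSE)
  raster_grid(values, x$pixel_size, x$xmin, x$ymin, x$crs)
}

#' X/Y coordinates of all pixel centres
#'
#' @param x a `raster_grid`.
#' @return A list with matrices `x` and `y`, same shape as the grid.
#' @keywords internal
#' @export
cell_centers <- function(x) {
  stopifnot(is_raster_grid(x))
  nr <- nrow(x$values); nc <- ncol(x$values); ps <- x$pixel_size
  cx <- x$xmin + (seq_len(nc) - 0.5) * ps
  cy <- x$ymin + (nr - seq_len(nr) + 0.5) * ps
  list(x = matrix(cx, nr, nc, byrow = TRUE),
       y = matrix(cy, nr, nc, byrow = FALSE))
}

#' Tidy view of a raster
#'
#' One row per cell with row/col indices, centre coordinates and the value.
#'
#' @param x a `raster_grid`.
#' @param ... ignored.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @method as_tibble raster_grid
#' @export
as_tibble.raster_grid <- function(x, ...) {
  cc <- cell_centers(x)
  nr <- nrow(x$values); nc <- ncol(x$values)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = as.vector(cc$x),
    y = as.vector(cc$y),
    value = as.vector(x$values)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster as a filled map
#'
#' @param object a `raster_grid`.
#' @param name legend title for the fill scale.
#' @param ... ignored.
#' @return A ggplot object.
#' @method autoplot raster_grid
#' @export
autoplot.raster_grid <- function(object, name = "value", ...) {
  df <- as_tibble.raster_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = name, na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}

#' Check that two rasters share shape and georeference
#' @keywords internal
#' @noRd
check_aligned <- function(a, b, what = "rasters") {
  stopifnot(is_raster_grid(a), is_raster_grid(b))
  if (!all(dim(a$values) == dim(b$values)) ||
      a$pixel_size != b$pixel_size ||
      a$xmin != b$xmin || a$ymin != b$ymin) {
    stop(sprintf("%s are not co-registered (shape or transform differs)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

# ---- text I/O: ESRI ASCII grid --------------------------------------------

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text, single-band format readable by any GIS. `NA` cells are written
#' as the `nodata` sentinel.
#'
#' @param x a `raster_grid`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, nodata = -9999) {
  stopifnot(is_raster_grid(x))
  v <- x$values
  v[!is.finite(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", x$xmin),
    sprintf("yllcorner %.10g", x$ymin),
    sprintf("cellsize %.10g", x$pixel_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(v, 1L, function(row) paste(format(row, trim = TRUE, digits = 10),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] or any GIS.
#' @param crs CRS tag to attach (the format itself carries none).
#' @return A `raster_grid`; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path, crs = "local-metric") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) stop("grid body does not match header dims", call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, pixel_size = hdr$cellsize,
              xmin = hdr$xllcorner, ymin = hdr$yllcorner, crs = crs)
}
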