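# Shared fixtures, all generated in code.

# small aligned covariate stack with a deterministic structure
make_test_stack <- function(nr = 20, nc = 20, pixel = 100) {
  tmpl <- raster_grid(matrix(0, nr, nc), pixel_size = pixel)
  rowm <- matrix(seq_len(nr), nr, nc)
  colm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  list(
    elevation = raster_like(tmpl, 100 + 10 * rowm),
    slope = raster_like(tmpl, (rowm + colm) %% 7),
    map = raster_like(tmpl, 1500 + 20 * colm),
    pv = raster_like(tmpl, (colm - 1) / (nc - 1))
  )
}

# independent brute-force oracle: median filter by explicit window scan
oracle_median_filter <- function(m, window) {
  h <- window %/% 2
  out <- m * NA_real_
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    rr <- max(1, r - h):min(nrow(m), r + h)
    cc <- max(1, c - h):min(ncol(m), c + h)
    vals <- m[rr, cc]
    vals <- vals[is.finite(vals)]
    if (length(vals)) out[r, c] <- median(vals)
  }
  out
}

# independent Horn stencil oracle for one interior cell
oracle_horn_cell <- function(z, r, c, ps) {
  gx <- ((z[r - 1, c + 1] + 2 * z[r, c + 1] + z[r + 1, c + 1]) -
           (z[r - 1, c - 1] + 2 * z[r, c - 1] + z[r + 1, c - 1])) / (8 * ps)
  gy <- ((z[r - 1, c - 1] + 2 * z[r - 1, c] + z[r - 1, c + 1]) -
           (z[r + 1, c - 1] + 2 * z[r + 1, c] + z[r + 1, c + 1])) / (8 * ps)
  c(slope = atan(sqrt(gx^2 + gy^2)) * 180 / pi,
    aspect = (atan2(-gx, -gy) * 180 / pi) %% 360)
}

# winding-number point-in-polygon (different algorithm from the package's
# even-odd ray casting), for strictly interior/exterior points
oracle_winding_inside <- function(px, py, poly) {
  vx <- c(poly$x, poly$x[1]); vy <- c(poly$y, poly$y[1])
  vapply(seq_along(px), function(i) {
    wn <- 0
    for (k in seq_len(length(vx) - 1)) {
      cross <- (vx[k + 1] - vx[k]) * (py[i] - vy[k]) -
        (px[i] - vx[k]) * (vy[k + 1] - vy[k])
      if (vy[k] <= py[i]) {
        if (vy[k + 1] > py[i] && cross > 0) wn <- wn + 1
      } else {
        if (vy[k + 1] <= py[i] && cross < 0) wn <- wn - 1
      }
    }
    wn != 0
  }, logical(1))
}
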