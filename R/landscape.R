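# Synthetic study landscapes with known generating parameters.
#
# The generator emulates the data structure of a national LiDAR-assisted
# carbon mapping campaign: a 1-ha covariate stack (terrain, climate,
# fractional cover), a true ACD field tied to the covariates through a known
# model with heteroskedastic noise, a fine-resolution canopy height model
# consistent with the generating height-carbon power law, systematic
# north-south sampling transects, and set-aside validation blocks.

#' Configuration for a synthetic landscape
#'
#' @param grid_rows,grid_cols landscape dimensions in 1-ha cells (>= 10).
#' @param pixel_size edge of a 1-ha cell in metres (default 100).
#' @param fine_factor fine CHM pixels per cell edge (default 10, i.e. 10 m
#'   CHM pixels).
#' @param gen_a,gen_b generating power-law coefficients of
#'   `ACD = gen_a * TCH^gen_b` (defaults 0.359 and 1.7676, the fitted
#'   national model for Panama).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   ACD noise (default 0.15).
#' @param covariate_effects named numeric vector of linear effects on the
#'   noise-free ACD surface; names must be covariates the generator
#'   produces. Defaults give a smooth, spatially structured carbon field in
#'   roughly 0-130 Mg C ha^-1.
#' @param acd_base intercept of the noise-free ACD surface (Mg C ha^-1).
#' @param seed RNG seed; the bundle is bit-reproducible for a fixed seed.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(grid_rows = 50, grid_cols = 50,
                             pixel_size = 100, fine_factor = 10,
                             gen_a = 0.359, gen_b = 1.7676,
                             noise_cv = 0.15,
                             covariate_effects = c(elevation = -0.04,
                                                   slope = -0.8,
                                                   map = 0.02,
                                                   pv = 60),
                             acd_base = 20,
                             seed = 1L) {
  if (grid_rows < 10 || grid_cols < 10)
    stop("grid must be at least 10 x 10 cells", call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  if (gen_a <= 0 || gen_b <= 0) stop("generating coefficients must be positive",
                                     call. = FALSE)
  known <- c("elevation", "slope", "aspect", "map", "seasonality",
             "pv", "npv", "bare")
  bad <- setdiff(names(covariate_effects), known)
  if (length(bad))
    stop("unknown covariates in `covariate_effects`: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         pixel_size = pixel_size, fine_factor = as.integer(fine_factor),
         gen_a = gen_a, gen_b = gen_b, noise_cv = noise_cv,
         covariate_effects = covariate_effects, acd_base = acd_base,
         seed = as.integer(seed)),
    class = "landscape_config"
  )
}

# Smooth Gaussian random field: iid normal deviates smoothed by a separable
# Gaussian kernel (two 1-D passes with reflected edges), then standardised.
smooth_field <- function(nr, nc, scale_cells = 6) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  # reflection padding needs the half-width to fit inside the grid edge
  half <- max(1L, min(ceiling(2 * scale_cells), min(nr, nc) - 1L))
  kx <- stats::dnorm(seq(-half, half), sd = scale_cells)
  kx <- kx / sum(kx)
  pad_reflect <- function(v, h) c(rev(v[seq_len(h)]), v, rev(v[(length(v) - h + 1):length(v)]))
  smooth_vec <- function(v) {
    vp <- pad_reflect(v, half)
    stats::filter(vp, kx, sides = 2)[(half + 1):(half + length(v))]
  }
  z <- apply(z, 2, smooth_vec)
  z <- t(apply(z, 1, smooth_vec))
  (z - mean(z)) / stats::sd(z)
}

#' Generate a complete synthetic landscape
#'
#' Produces the covariate stack, the true carbon field, a consistent
#' fine-resolution canopy height model, a systematic transect mask and
#' validation blocks. The true ACD is
#' `max(0, acd_base + sum(effects * covariates)) * noise`, with unit-mean
#' lognormal noise of coefficient of variation `noise_cv`. The CHM is built
#' so that each cell's mean height back-transforms through the generating
#' power law to exactly the cell's true ACD: fine pixels carry zero-mean
#' within-cell texture around `(ACD / gen_a)^(1/gen_b)`.
#'
#' @param config a [landscape_config()].
#' @return A `landscape_bundle`: list with `covariates` (named list of
#'   `raster_grid`s: elevation, slope, aspect, map, seasonality, pv, npv,
#'   bare), `true_acd`, `acd_det` (noise-free surface), `chm` (fine grid),
#'   `transect_mask` (logical-valued raster), `validation_regions` (tibble of
#'   labelled rectangles), and `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  nr <- config$grid_rows; nc <- config$grid_cols; ps <- config$pixel_size

  grid_tmpl <- raster_grid(matrix(0, nr, nc), pixel_size = ps)

  # -- terrain: a ridge running roughly E-W plus smooth noise ---------------
  rowfrac <- matrix((seq_len(nr) - 0.5) / nr, nr, nc)
  ridge <- 800 * exp(-((rowfrac - 0.45) / 0.2)^2)
  elevation <- pmax(ridge + 150 * smooth_field(nr, nc, scale_cells = 5) + 100, 0)
  dem <- raster_like(grid_tmpl, elevation)
  terr <- slope_aspect(dem)
  slope <- terr$slope$values
  aspect <- terr$aspect$values
  # fill the undefined border/flat cells so every cell has usable covariates
  slope[!is.finite(slope)] <- 0
  aspect[!is.finite(aspect)] <- 0

  # -- climate: rainfall increasing with elevation, seasonality opposite ----
  map_mm <- pmax(1500 + 1.2 * elevation + 200 * smooth_field(nr, nc, 8), 800)
  seasonality <- round(pmin(pmax(6 - 0.004 * elevation +
                                   1.2 * smooth_field(nr, nc, 8), 0), 8))

  # -- fractional cover: PV from a logistic of a smooth field, remainder
  #    split between NPV and bare --------------------------------------------
  pv_raw <- stats::plogis(1.2 + 1.5 * smooth_field(nr, nc, 6) -
                            0.5 * (slope / 10))
  pv <- pmin(pmax(pv_raw, 0.001), 0.999)
  split <- stats::plogis(0.4 * smooth_field(nr, nc, 4))
  npv <- (1 - pv) * split
  bare <- 1 - pv - npv

  covs <- list(
    elevation = elevation, slope = slope, aspect = aspect,
    map = map_mm, seasonality = seasonality,
    pv = pv, npv = npv, bare = bare
  )

  # -- noise-free ACD surface ------------------------------------------------
  det <- matrix(config$acd_base, nr, nc)
  for (nm in names(config$covariate_effects)) {
    det <- det + config$covariate_effects[[nm]] * covs[[nm]]
  }
  det <- pmax(det, 0)

  # -- multiplicative unit-mean lognormal noise ------------------------------
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- matrix(stats::rlnorm(nr * nc, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nr, nc)
  } else {
    noise <- matrix(1, nr, nc)
  }
  true_acd <- det * noise

  # -- CHM: fine pixels whose block mean inverts the power law exactly ------
  f <- config$fine_factor
  tch <- (true_acd / config$gen_a)^(1 / config$gen_b)
  chm_vals <- matrix(0, nr * f, nc * f)
  texture <- matrix(stats::rnorm(nr * f * nc * f), nr * f, nc * f)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      rows <- ((r - 1) * f + 1):(r * f); cols <- ((c - 1) * f + 1):(c * f)
      t_cell <- texture[rows, cols]
      t_cell <- t_cell - mean(t_cell)          # exactly zero-mean texture
      amp <- 0.15 * tch[r, c]
      if (amp > 0) {
        t_cell <- t_cell * amp / max(abs(t_cell), 1)  # bounded, stays >= 0
      } else {
        t_cell[] <- 0
      }
      chm_vals[rows, cols] <- tch[r, c] + t_cell
    }
  }
  chm <- raster_grid(chm_vals, pixel_size = ps / f)

  bundle <- structure(
    list(
      covariates = purrr::map(covs, ~ raster_like(grid_tmpl, .x)),
      acd_det = raster_like(grid_tmpl, det),
      true_acd = raster_like(grid_tmpl, true_acd),
      chm = chm,
      transect_mask = NULL,
      validation_regions = NULL,
      config = config
    ),
    class = "landscape_bundle"
  )
  bundle$transect_mask <- sample_transects(bundle, spacing = 25, swath = 1)
  bundle$validation_regions <- make_validation_regions(bundle)
  bundle
}

#' @export
print.landscape_bundle <- function(x, ...) {
  cat(sprintf("<landscape_bundle> %d x %d ha cells, %d covariates, seed %d\n",
              x$config$grid_rows, x$config$grid_cols,
              length(x$covariates), x$config$seed))
  cat(sprintf("  true ACD: mean %.1f Mg C/ha; transect coverage %.1f%%\n",
              mean(x$true_acd$values),
              100 * mean(x$transect_mask$values)))
  invisible(x)
}

#' Systematic north-south sampling transects
#'
#' Parallel vertical strips of `swath` columns every `spacing` columns,
#' emulating systematically aligned flight lines on a true-north azimuth.
#' The default spacing/swath of 25/1 gives ~4% coverage, the national
#' LiDAR share the design emulates.
#'
#' @param bundle a `landscape_bundle` (only its grid shape is used).
#' @param spacing period between strip starts, in cells. Must exceed `swath`
#'   unless full coverage is intended.
#' @param swath strip width in cells (>= 1).
#' @return A `raster_grid` of 0/1 values (1 = sampled).
#' @export
sample_transects <- function(bundle, spacing = 25, swath = 1) {
  if (spacing <= 0) stop("`spacing` must be positive", call. = FALSE)
  if (swath < 1) stop("`swath` must be >= 1", call. = FALSE)
  if (swath > spacing) stop("`swath` cannot exceed `spacing`", call. = FALSE)
  tmpl <- bundle$true_acd
  nc <- ncol(tmpl$values)
  sampled_cols <- ((seq_len(nc) - 1L) %% spacing) < swath
  mask <- matrix(as.numeric(sampled_cols), nrow(tmpl$values), nc, byrow = TRUE)
  raster_like(tmpl, mask)
}

# Six rectangular validation blocks in the inter-transect gaps, away from
# sampled columns, mirroring set-aside validation polygons.
make_validation_regions <- function(bundle, n_regions = 6) {
  nr <- nrow(bundle$true_acd$values); nc <- ncol(bundle$true_acd$values)
  mask_cols <- which(bundle$transect_mask$values[1, ] == 1)
  free_cols <- setdiff(seq_len(nc), mask_cols)
  # split the landscape into a 3 x 2 lattice of candidate blocks
  row_breaks <- round(seq(1, nr + 1, length.out = 4))
  col_breaks <- round(seq(1, nc + 1, length.out = 3))
  blocks <- tidyr::expand_grid(rb = 1:3, cb = 1:2)
  regions <- purrr::pmap_dfr(blocks, function(rb, cb) {
    r0 <- row_breaks[rb]; r1 <- row_breaks[rb + 1] - 1
    c0 <- col_breaks[cb]; c1 <- col_breaks[cb + 1] - 1
    # shrink to the central half and snap to unsampled columns
    rr <- round(c(r0 + (r1 - r0) * 0.25, r0 + (r1 - r0) * 0.75))
    cc <- round(c(c0 + (c1 - c0) * 0.25, c0 + (c1 - c0) * 0.75))
    cols <- intersect(seq(cc[1], cc[2]), free_cols)
    tibble::tibble(region = sprintf("ecoregion_%d", (rb - 1) * 2 + cb),
                   row0 = rr[1], row1 = rr[2],
                   col0 = min(cols), col1 = max(cols))
  })
  regions
}

#' Synthetic wood-density reference table
#'
#' A small fixed taxon list with species- and genus-level densities drawn
#' from the realistic tropical range, used when generating and re-analysing
#' synthetic inventories.
#'
#' @return A [wood_density_table()].
#' @export
synthetic_wood_density_table <- function() {
  species <- tibble::tibble(
    species = sprintf("Taxon%02d sp%d", rep(1:8, each = 2), rep(1:2, 8)),
    density = round(seq(0.32, 0.92, length.out = 16), 3)
  )
  genus <- tibble::tibble(
    genus = sprintf("Taxon%02d", 1:8),
    density = round(seq(0.38, 0.85, length.out = 8), 3)
  )
  wood_density_table(species = species, genus = genus, regional_default = 0.56)
}

# Generating height-diameter curve shared by the stem simulator and the
# closure analysis: ln H = 0.60 + 0.62 ln D  (H ~ 25 m at D = 40 cm).
generating_hd_model <- function() {
  structure(list(c0 = 0.60, c1 = 0.62, provenance = "local-fit",
                 n = NA_integer_, resid_sd = 0),
            class = "height_diameter_model")
}

#' Simulate field inventory plots on a landscape
#'
#' Places square plots uniformly at random (seeded), then fills each with a
#' stem list whose allometric carbon closes on the cell's true ACD: diameters
#' are drawn from a truncated power law at or above 10 cm, heights follow the
#' generating height-diameter curve, taxa are drawn from the synthetic
#' wood-density table, and the final stem's diameter is solved so the plot
#' total matches the target carbon.
#'
#' @param bundle a `landscape_bundle`.
#' @param n_plots number of plots (> 0).
#' @param areas plot areas in ha, recycled over plots (default 0.1-1.0 range
#'   typical of inventory networks).
#' @param seed RNG seed for placement and stem draws.
#' @param carbon_fraction,form passed through to match the allometry used in
#'   re-analysis.
#' @return A tibble, one row per plot: `plot_id`, `area_ha`, `row`, `col`,
#'   `x`, `y` (centre), `true_acd`, a `footprint` list-column of vertex
#'   tibbles, and a `stems` list-column
#'   (`stem_id`, `dbh`, `height`, `taxon`).
#' @export
generate_plot_inventories <- function(bundle, n_plots,
                                      areas = c(0.1, 0.25, 0.36, 1.0),
                                      seed = bundle$config$seed + 1000L,
                                      carbon_fraction = 0.48,
                                      form = "moist") {
  if (n_plots <= 0) stop("`n_plots` must be positive", call. = FALSE)
  if (any(areas < 0.01 | areas > 1.0))
    stop("plot areas must lie in [0.01, 1.0] ha", call. = FALSE)
  set.seed(seed)
  acd <- bundle$true_acd$values
  nr <- nrow(acd); nc <- ncol(acd); ps <- bundle$true_acd$pixel_size
  wd <- synthetic_wood_density_table()
  hd <- generating_hd_model()
  taxa <- c(wd$species$species, "Unlisted indet.")
  dens <- c(wd$species$density, wd$regional_default)

  rows <- sample.int(nr, n_plots, replace = TRUE)
  cols <- sample.int(nc, n_plots, replace = TRUE)
  area_vec <- rep_len(areas, n_plots)

  plots <- purrr::map_dfr(seq_len(n_plots), function(i) {
    r <- rows[i]; c <- cols[i]; area <- area_vec[i]
    half <- sqrt(area * 1e4) / 2
    # centre the footprint inside its cell, jittered but fully contained
    cx <- bundle$true_acd$xmin + (c - 0.5) * ps
    cy <- bundle$true_acd$ymin + (nr - r + 0.5) * ps
    jit <- (ps / 2 - half)
    if (jit > 0) {
      cx <- cx + stats::runif(1, -jit, jit)
      cy <- cy + stats::runif(1, -jit, jit)
    }
    target_c <- acd[r, c] * area  # Mg C to accumulate in the plot
    stems <- simulate_stem_list(target_c, hd, taxa, dens,
                                carbon_fraction, form)
    tibble::tibble(
      plot_id = sprintf("plot_%03d", i), area_ha = area,
      row = r, col = c, x = cx, y = cy,
      true_acd = acd[r, c],
      footprint = list(square_footprint(cx, cy, area)),
      stems = list(stems)
    )
  })
  plots
}

# Draw stems until cumulative carbon reaches the target, then solve the last
# stem's diameter so the plot total closes exactly. Carbon of one stem under
# the moist form with the generating H(D):
#   c(D) = cf * 0.0509 * rho * D^2 * H(D) / 1000,  H(D) = exp(c0) D^c1
# so c(D) = K * rho * D^(2 + c1), invertible in D.
simulate_stem_list <- function(target_c, hd, taxa, dens,
                               carbon_fraction, form) {
  empty <- tibble::tibble(stem_id = integer(), dbh = numeric(),
                          height = numeric(), taxon = character())
  if (target_c <= 1e-9) return(empty)
  K <- carbon_fraction * 0.0509 * exp(hd$c0) / 1000
  expo <- 2 + hd$c1
  dbh <- numeric(); taxon <- character(); rho <- numeric()
  acc <- 0
  while (acc < target_c && length(dbh) < 5000) {
    # truncated Pareto-like diameters >= 10 cm (alpha ~ 2.3 tail)
    d <- 10 * stats::runif(1)^(-1 / 2.3)
    d <- min(d, 180)
    ti <- sample.int(length(taxa), 1)
    ci <- K * dens[ti] * d^expo
    if (acc + ci > target_c) {
      # close the plot: solve the diameter giving exactly the remainder
      d_fit <- ((target_c - acc) / (K * dens[ti]))^(1 / expo)
      if (d_fit >= 10) {
        dbh <- c(dbh, d_fit); taxon <- c(taxon, taxa[ti]); rho <- c(rho, dens[ti])
        acc <- target_c
      }
      break
    }
    dbh <- c(dbh, d); taxon <- c(taxon, taxa[ti]); rho <- c(rho, dens[ti])
    acc <- acc + ci
  }
  if (length(dbh) == 0L) return(empty)
  tibble::tibble(
    stem_id = seq_along(dbh),
    dbh = dbh,
    height = exp(hd$c0 + hd$c1 * log(dbh)),
    taxon = taxon
  )
}

#' Write a landscape bundle to disk
#'
#' Covariates, true ACD, CHM and the transect mask go to ESRI ASCII grids;
#' validation regions to GeoJSON; the config to YAML.
#'
#' @param bundle a `landscape_bundle`.
#' @param dir output directory (created if needed).
#' @return Tibble of written paths, invisibly.
#' @export
write_landscape <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    purrr::imap_chr(bundle$covariates, function(r, nm) {
      p <- file.path(dir, paste0(nm, ".asc")); write_ascii_grid(r, p); p
    }),
    true_acd = { p <- file.path(dir, "true_acd.asc")
                 write_ascii_grid(bundle$true_acd, p); p },
    chm = { p <- file.path(dir, "chm.asc")
            write_ascii_grid(bundle$chm, p); p },
    transect_mask = { p <- file.path(dir, "transect_mask.asc")
                      write_ascii_grid(bundle$transect_mask, p); p }
  )
  rp <- file.path(dir, "validation_regions.geojson")
  write_polygons_geojson(
    regions_to_polygons(bundle$validation_regions, bundle$true_acd), rp,
    id_field = "region")
  cfgp <- file.path(dir, "config.yml")
  cfg <- unclass(bundle$config)
  cfg$covariate_effects <- as.list(cfg$covariate_effects)
  yaml::write_yaml(cfg, cfgp)
  invisible(tibble::tibble(artifact = c(names(paths), "validation_regions", "config"),
                           path = c(unname(paths), rp, cfgp)))
}

#' Write plot inventories as CSV stem tables plus GeoJSON footprints
#'
#' @param plots tibble from [generate_plot_inventories()].
#' @param dir output directory.
#' @return Tibble of written paths, invisibly.
#' @export
write_plot_inventories <- function(plots, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stems <- tidyr::unnest(
    dplyr::select(plots, "plot_id", "stems"), "stems")
  stems_path <- file.path(dir, "stems.csv")
  utils::write.csv(stems, stems_path, row.names = FALSE)
  plots_path <- file.path(dir, "plots.csv")
  utils::write.csv(dplyr::select(plots, "plot_id", "area_ha", "x", "y"),
                   plots_path, row.names = FALSE)
  fp <- file.path(dir, "footprints.geojson")
  polys <- purrr::set_names(plots$footprint, plots$plot_id)
  write_polygons_geojson(polys, fp, id_field = "plot_id")
  invisible(tibble::tibble(artifact = c("stems", "plots", "footprints"),
                           path = c(stems_path, plots_path, fp)))
}
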