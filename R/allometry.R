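# Plot-level aboveground carbon from tree lists.
#
# Units throughout: dbh cm, height m, wood density g cm^-3, stem biomass kg
# dry mass, plot-level carbon Mg C ha^-1.

#' Wood density lookup table
#'
#' Taxon-to-density map with a species level, a genus level, and a regional
#' default used when neither resolves — the fallback cascade used for
#' Neotropical inventories (Central American regional default 0.56 g cm^-3).
#'
#' @param species tibble/data.frame with columns `species`, `density`.
#' @param genus tibble/data.frame with columns `genus`, `density`.
#' @param regional_default density used when the taxon is unknown (g cm^-3).
#' @return A `wood_density_table`.
#' @export
wood_density_table <- function(species = NULL, genus = NULL,
                               regional_default = 0.56) {
  species <- if (is.null(species)) {
    tibble::tibble(species = character(), density = numeric())
  } else tibble::as_tibble(species)
  genus <- if (is.null(genus)) {
    tibble::tibble(genus = character(), density = numeric())
  } else tibble::as_tibble(genus)
  dens <- c(species$density, genus$density, regional_default)
  if (any(dens <= 0.1 | dens >= 1.5))
    stop("wood densities must lie in (0.1, 1.5) g cm^-3", call. = FALSE)
  structure(list(species = species, genus = genus,
                 regional_default = regional_default),
            class = "wood_density_table")
}

#' Resolve wood density for taxa
#'
#' Species match first, then genus (the first word of the taxon string), then
#' the regional default. Vectorised over `taxon`.
#'
#' @param taxon character vector of taxon names ("Genus species", "Genus", or
#'   `NA` for unknown).
#' @param table a [wood_density_table()].
#' @return A tibble with columns `taxon`, `density` (g cm^-3) and
#'   `resolution` (`"species"`, `"genus"` or `"regional"`).
#' @examples
#' wd <- wood_density_table(
#'   species = data.frame(species = "Ocotea insularis", density = 0.62))
#' wood_density_lookup(c("Ocotea insularis", "Nothotaxon sp."), wd)
#' @export
wood_density_lookup <- function(taxon, table) {
  stopifnot(inherits(table, "wood_density_table"))
  taxon <- as.character(taxon)
  genus_of <- sub("\\s.*$", "", taxon)
  sp_d <- table$species$density[match(taxon, table$species$species)]
  ge_d <- table$genus$density[match(genus_of, table$genus$genus)]
  density <- dplyr::coalesce(sp_d, ge_d, table$regional_default)
  resolution <- dplyr::case_when(
    !is.na(sp_d) ~ "species",
    !is.na(ge_d) ~ "genus",
    TRUE ~ "regional"
  )
  tibble::tibble(taxon = taxon, density = density, resolution = resolution)
}

#' Fit a height-diameter model
#'
#' Log-log linear fit `ln H = c0 + c1 ln D` by least squares — the default
#' functional form for local height models in tropical inventories.
#'
#' @param pairs tibble/data.frame with columns `dbh` (cm) and `height` (m).
#' @return A `height_diameter_model` with fields `c0`, `c1`,
#'   `provenance = "local-fit"` and a residual summary.
#' @export
fit_height_diameter <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) < 5L) stop("need at least 5 (dbh, height) pairs", call. = FALSE)
  if (any(pairs$dbh <= 0) || any(pairs$height <= 0))
    stop("dbh and height must be positive", call. = FALSE)
  fit <- stats::lm(log(height) ~ log(dbh), data = pairs)
  co <- unname(stats::coef(fit))
  structure(
    list(c0 = co[1], c1 = co[2], provenance = "local-fit",
         n = nrow(pairs),
         resid_sd = stats::sd(stats::residuals(fit))),
    class = "height_diameter_model"
  )
}

#' LiDAR-constrained height-diameter model
#'
#' Fits the same log-log form through per-plot pairs of maximum measured
#' diameter and maximum LiDAR canopy height. Constraining heights to what the
#' LiDAR actually observed caps systematic height over-prediction where no
#' direct tree-height measurements exist. With a single plot the exponent is
#' held at a supplied regional value and only the intercept is solved.
#'
#' @param pairs tibble with columns `max_dbh` (cm), `lidar_max_height` (m),
#'   one row per plot.
#' @param fallback_exponent exponent used when only one pair is supplied.
#' @return A `height_diameter_model` with `provenance = "lidar-constrained"`.
#' @export
fit_hd_lidar_constrained <- function(pairs, fallback_exponent = 0.6) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) < 1L) stop("need at least one (max_dbh, max_height) pair", call. = FALSE)
  if (any(pairs$max_dbh <= 0) || any(pairs$lidar_max_height <= 0))
    stop("diameters and heights must be positive", call. = FALSE)
  if (nrow(pairs) == 1L) {
    c1 <- fallback_exponent
    c0 <- log(pairs$lidar_max_height) - c1 * log(pairs$max_dbh)
    rsd <- 0
  } else {
    fit <- stats::lm(log(lidar_max_height) ~ log(max_dbh), data = pairs)
    co <- unname(stats::coef(fit))
    c0 <- co[1]; c1 <- co[2]
    rsd <- stats::sd(stats::residuals(fit))
  }
  structure(
    list(c0 = c0, c1 = c1, provenance = "lidar-constrained",
         n = nrow(pairs), resid_sd = rsd),
    class = "height_diameter_model"
  )
}

#' Predict tree height from diameter
#'
#' @param model a `height_diameter_model`.
#' @param dbh diameters (cm).
#' @return Heights (m).
#' @export
predict_height <- function(model, dbh) {
  stopifnot(inherits(model, "height_diameter_model"))
  exp(model$c0 + model$c1 * log(dbh))
}

#' @export
print.height_diameter_model <- function(x, ...) {
  cat(sprintf("<height_diameter_model> ln H = %.4f + %.4f ln D (%s, n = %d)\n",
              x$c0, x$c1, x$provenance, x$n))
  invisible(x)
}

# Chave-style pantropical biomass forms with D (cm), H (m), rho (g cm^-3).
agb_forms <- list(
  moist = function(rho, d, h) 0.0509 * rho * d^2 * h,
  dry   = function(rho, d, h) 0.112 * (rho * d^2 * h)^0.916,
  wet   = function(rho, d, h) 0.0776 * (rho * d^2 * h)^0.940
)

#' Aboveground dry biomass of single stems
#'
#' Pantropical allometry with diameter, height and wood density inputs.
#' Heights absent from the record are predicted from the height-diameter
#' model; densities are resolved through the lookup cascade when the record
#' carries none.
#'
#' @param stems tibble with columns `dbh` (cm) and optionally `height` (m),
#'   `taxon`, `wood_density` (g cm^-3).
#' @param hd a `height_diameter_model`, used for stems without height.
#' @param table a [wood_density_table()], used for stems without density.
#' @param form allometric variant: `"moist"` (default, AGB = 0.0509 rho D^2 H),
#'   `"dry"` or `"wet"`.
#' @return The input tibble with columns `height`, `wood_density` filled and
#'   `agb_kg` appended.
#' @export
stem_biomass <- function(stems, hd = NULL, table = wood_density_table(),
                         form = c("moist", "dry", "wet")) {
  form <- match.arg(form)
  stems <- tibble::as_tibble(stems)
  if (nrow(stems) == 0L) return(dplyr::mutate(stems, agb_kg = numeric(0)))
  if (any(stems$dbh <= 0)) stop("all dbh must be positive", call. = FALSE)
  if (!"height" %in% names(stems)) stems$height <- NA_real_
  if (!"wood_density" %in% names(stems)) stems$wood_density <- NA_real_
  if (!"taxon" %in% names(stems)) stems$taxon <- NA_character_
  need_h <- is.na(stems$height)
  if (any(need_h)) {
    if (is.null(hd)) stop("stems lack heights and no height-diameter model given",
                          call. = FALSE)
    stems$height[need_h] <- predict_height(hd, stems$dbh[need_h])
  }
  need_rho <- is.na(stems$wood_density)
  if (any(need_rho)) {
    stems$wood_density[need_rho] <-
      wood_density_lookup(stems$taxon[need_rho], table)$density
  }
  stems$agb_kg <- agb_forms[[form]](stems$wood_density, stems$dbh, stems$height)
  stems
}

#' Plot-level aboveground carbon density
#'
#' Sums stem biomass over stems at or above the diameter cutoff, converts to
#' carbon with the dry-mass carbon fraction, and normalises by plot area:
#' ACD = cf * sum(AGB >= cutoff) / area, in Mg C ha^-1.
#'
#' @param plots tibble with one row per plot: `plot_id`, `area_ha`, and a
#'   list-column `stems` of stem tibbles (as accepted by [stem_biomass()]).
#' @param hd height-diameter model for stems without heights.
#' @param table wood density table for stems without densities.
#' @param carbon_fraction carbon per unit dry biomass (default 0.48).
#' @param min_dbh diameter cutoff in cm; smaller stems are excluded
#'   (default 10).
#' @param form allometric variant passed to [stem_biomass()].
#' @return The input tibble with columns `n_stems` (>= cutoff), `agb_mg`
#'   (Mg dry mass in the plot) and `acd` (Mg C ha^-1) appended.
#' @examples
#' plots <- tibble::tibble(
#'   plot_id = "p1", area_ha = 0.1,
#'   stems = list(data.frame(dbh = 20, height = 15, wood_density = 0.56)))
#' plot_acd(plots)$acd  # ~0.821 Mg C ha^-1
#' @export
plot_acd <- function(plots, hd = NULL, table = wood_density_table(),
                     carbon_fraction = 0.48, min_dbh = 10,
                     form = "moist") {
  plots <- tibble::as_tibble(plots)
  if (any(plots$area_ha <= 0)) stop("plot areas must be positive", call. = FALSE)
  per_plot <- purrr::map2(plots$stems, plots$area_ha, function(st, area) {
    st <- tibble::as_tibble(st)
    st <- st[!is.na(st$dbh) & st$dbh >= min_dbh, , drop = FALSE]
    if (nrow(st) == 0L) return(c(n = 0, agb_mg = 0))
    st <- stem_biomass(st, hd = hd, table = table, form = form)
    c(n = nrow(st), agb_mg = sum(st$agb_kg) / 1000)
  })
  plots$n_stems <- purrr::map_dbl(per_plot, "n")
  plots$agb_mg <- purrr::map_dbl(per_plot, "agb_mg")
  plots$acd <- carbon_fraction * plots$agb_mg / plots$area_ha
  plots
}
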