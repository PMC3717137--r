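# Landscape-scale extension of LiDAR carbon estimates: covariate
# stratification with class medians, and random-forest regression with
# position features.

default_strata_bins <- function(stack) {
  rng <- function(nm) range(stack[[nm]]$values, na.rm = TRUE)
  edges <- list()
  mk <- function(nm, step) {
    r <- rng(nm)
    lo <- floor(r[1] / step) * step
    hi <- ceiling(r[2] / step) * step
    if (hi <= lo) hi <- lo + step
    seq(lo, hi, by = step)
  }
  if ("elevation" %in% names(stack)) edges$elevation <- mk("elevation", 250)
  if ("slope" %in% names(stack)) edges$slope <- mk("slope", 5)
  if ("map" %in% names(stack)) edges$map <- mk("map", 250)
  if ("seasonality" %in% names(stack)) {
    r <- rng("seasonality")
    edges$seasonality <- seq(floor(r[1]) - 0.5, ceiling(r[2]) + 0.5, by = 1)
  }
  for (nm in intersect(c("pv", "npv", "bare"), names(stack)))
    edges[[nm]] <- seq(0, 1, by = 0.1)
  edges
}

#' Stratify a landscape into unique covariate classes
#'
#' Each cell is assigned the joint bin of its covariate values; every
#' distinct joint bin present on the landscape is one class. Values outside
#' the outermost edges are clamped into the end bins (and counted).
#'
#' @param stack named list of aligned `raster_grid` covariates.
#' @param bins named list of strictly increasing bin-edge vectors, one per
#'   stratification variable; `NULL` uses coarse default steps (250 m
#'   elevation, 5 deg slope, 250 mm rainfall, integer seasonality, 10%
#'   cover fractions).
#' @return A `strata` object: `class_map` (`raster_grid` of class ids),
#'   `classes` (tibble: `class_id`, one `bin_<var>` column per variable,
#'   `area_cells`), `bins`, `n_clamped`.
#' @export
build_strata <- function(stack, bins = NULL) {
  if (is.null(bins)) bins <- default_strata_bins(stack)
  for (nm in names(bins)) {
    if (!nm %in% names(stack)) stop("no covariate named ", nm, call. = FALSE)
    if (any(diff(bins[[nm]]) <= 0))
      stop("bin edges for ", nm, " must be strictly increasing", call. = FALSE)
  }
  tmpl <- stack[[names(bins)[1]]]
  n_clamped <- 0L
  bin_idx <- purrr::imap(bins, function(edges, nm) {
    v <- as.vector(stack[[nm]]$values)
    below <- v < edges[1]; above <- v > edges[length(edges)]
    n_clamped <<- n_clamped + sum(below | above, na.rm = TRUE)
    i <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
    i
  })
  key_df <- tibble::as_tibble(purrr::set_names(bin_idx, paste0("bin_", names(bins))))
  key <- do.call(paste, c(key_df, sep = "|"))
  classes <- dplyr::count(dplyr::mutate(key_df, .key = key), .data$.key,
                          dplyr::across(dplyr::starts_with("bin_")),
                          name = "area_cells")
  classes <- dplyr::arrange(classes, .data$.key)
  classes$class_id <- seq_len(nrow(classes))
  class_map <- matrix(classes$class_id[match(key, classes$.key)],
                      nrow(tmpl$values), ncol(tmpl$values))
  structure(
    list(class_map = raster_like(tmpl, class_map),
         classes = dplyr::select(classes, "class_id",
                                 dplyr::starts_with("bin_"), "area_cells"),
         bins = bins, n_clamped = n_clamped),
    class = "strata"
  )
}

#' @export
print.strata <- function(x, ...) {
  cat(sprintf("<strata> %d classes over %d variables (%s); %d clamped cells\n",
              nrow(x$classes), length(x$bins),
              paste(names(x$bins), collapse = ", "), x$n_clamped))
  invisible(x)
}

#' Map carbon by class medians with a PV-only fallback
#'
#' Classes whose LiDAR coverage (sampled cells / class cells) is at least
#' `min_coverage` receive the median ACD of their sampled cells. Classes
#' below the threshold fall back to bins of photosynthetic-vegetation
#' fraction alone — the covariate most strongly related to carbon — whose
#' medians are computed over all sampled cells in each PV bin.
#'
#' @param strata a `strata` object from [build_strata()].
#' @param lidar_acd `raster_grid` of LiDAR-estimated ACD (values needed only
#'   where sampled).
#' @param lidar_mask `raster_grid` of 0/1 sampling indicator.
#' @param pv `raster_grid` of PV fraction (for the fallback).
#' @param min_coverage coverage threshold (default 0.01, i.e. 1%).
#' @param pv_edges PV fallback bin edges (default the stratification's PV
#'   edges, else 10% steps).
#' @return A list: `acd_map` (`raster_grid`), `strata_table` (tibble with
#'   per-class `median_acd`, `n_lidar`, `coverage`, `fallback` flag),
#'   `n_unresolved` (cells in fallback bins with no sampled cells; mapped
#'   nodata).
#' @export
stratified_acd_map <- function(strata, lidar_acd, lidar_mask, pv,
                               min_coverage = 0.01, pv_edges = NULL) {
  check_aligned(strata$class_map, lidar_acd, "strata and LiDAR ACD")
  check_aligned(lidar_acd, lidar_mask, "LiDAR ACD and mask")
  if (is.null(pv_edges))
    pv_edges <- if ("pv" %in% names(strata$bins)) strata$bins$pv else seq(0, 1, 0.1)

  cls <- as.vector(strata$class_map$values)
  acd <- as.vector(lidar_acd$values)
  sampled <- as.vector(lidar_mask$values) > 0 & is.finite(acd)
  pvv <- as.vector(pv$values)

  cells <- tibble::tibble(cls = cls, acd = acd, sampled = sampled,
                          pv_bin = findInterval(pvv, pv_edges,
                                                rightmost.closed = TRUE,
                                                all.inside = TRUE))
  per_class <- dplyr::summarise(
    dplyr::group_by(cells, .data$cls),
    area = dplyr::n(),
    n_lidar = sum(.data$sampled),
    median_acd = stats::median(.data$acd[.data$sampled]),
    .groups = "drop"
  )
  per_class$coverage <- per_class$n_lidar / per_class$area
  per_class$fallback <- per_class$coverage < min_coverage

  pv_medians <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(cells, .data$sampled), .data$pv_bin),
    pv_median = stats::median(.data$acd), .groups = "drop"
  )

  value_by_class <- per_class$median_acd
  value_by_class[per_class$fallback] <- NA_real_
  mapped <- value_by_class[match(cells$cls, per_class$cls)]
  use_fb <- is.na(mapped)
  mapped[use_fb] <- pv_medians$pv_median[match(cells$pv_bin[use_fb],
                                               pv_medians$pv_bin)]
  n_unresolved <- sum(is.na(mapped))

  out_map <- raster_like(lidar_acd,
                         matrix(mapped, nrow(lidar_acd$values),
                                ncol(lidar_acd$values)))
  table <- dplyr::left_join(strata$classes,
                            dplyr::rename(per_class, class_id = "cls"),
                            by = "class_id")
  list(acd_map = out_map,
       strata_table = dplyr::select(table, "class_id",
                                    dplyr::starts_with("bin_"),
                                    "area_cells", "n_lidar", "coverage",
                                    "median_acd", "fallback"),
       n_unresolved = n_unresolved)
}

# Assemble the model frame: covariates plus raw row/col position features.
stack_to_frame <- function(stack) {
  tmpl <- stack[[1]]
  nr <- nrow(tmpl$values); nc <- ncol(tmpl$values)
  df <- tibble::as_tibble(purrr::map(stack, ~ as.vector(.x$values)))
  df$pos_row <- rep(seq_len(nr), times = nc)
  df$pos_col <- rep(seq_len(nc), each = nr)
  df
}

#' Train a random-forest upscaler on strided LiDAR cells
#'
#' Takes an ordered sample of every `stride`-th sampled cell (row-major
#' order) — systematic thinning of the dense transect sample — and fits a
#' regression forest of ACD on the covariates plus raw row/col position.
#' Position features exploit the systematic spatial coverage of the
#' transects and damp large-scale spatial autocorrelation of errors.
#'
#' @param stack named list of aligned covariate `raster_grid`s.
#' @param lidar_acd `raster_grid` of LiDAR ACD.
#' @param lidar_mask `raster_grid` 0/1 sampling indicator.
#' @param stride ingest every `stride`-th sampled cell (default 10).
#' @param n_trees forest size (default 500).
#' @param min_leaf minimum terminal node size (default 5).
#' @param seed RNG seed for the forest.
#' @return A `carbon_ensemble`: the fitted forest, feature names, and an
#'   ingestion report (`n_sampled`, `n_ingested`, `stride`).
#' @export
train_ensemble <- function(stack, lidar_acd, lidar_mask, stride = 10,
                           n_trees = 500, min_leaf = 5, seed = 1L) {
  check_aligned(stack[[1]], lidar_acd, "stack and LiDAR ACD")
  if (stride < 1) stop("`stride` must be >= 1", call. = FALSE)
  df <- stack_to_frame(stack)
  acd <- as.vector(lidar_acd$values)
  sampled_idx <- which(as.vector(lidar_mask$values) > 0 & is.finite(acd))
  take <- sampled_idx[seq(1, length(sampled_idx), by = stride)]
  if (length(take) < 100)
    stop(sprintf("only %d training cells after striding; need >= 100",
                 length(take)), call. = FALSE)
  x <- as.data.frame(df[take, , drop = FALSE])
  y <- acd[take]
  set.seed(seed)
  forest <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                       nodesize = min_leaf)
  structure(
    list(forest = forest, features = names(x), seed = seed,
         report = tibble::tibble(n_sampled = length(sampled_idx),
                                 n_ingested = length(take),
                                 stride = stride, n_trees = n_trees),
         train_range = range(y)),
    class = "carbon_ensemble"
  )
}

#' @export
print.carbon_ensemble <- function(x, ...) {
  cat(sprintf("<carbon_ensemble> %d trees on %d/%d sampled cells (stride %d)\n",
              x$report$n_trees, x$report$n_ingested, x$report$n_sampled,
              x$report$stride))
  invisible(x)
}

#' @method glance carbon_ensemble
#' @export
glance.carbon_ensemble <- function(x, ...) {
  dplyr::mutate(x$report,
                oob_mse = x$forest$mse[length(x$forest$mse)],
                oob_rsq = x$forest$rsq[length(x$forest$rsq)])
}

#' Predict a full-coverage carbon map from a trained ensemble
#'
#' @param model a `carbon_ensemble`.
#' @param stack covariate stack with the same variables used in training.
#' @param lidar_acd,lidar_mask optional; when both are given and
#'   `overwrite_lidar = TRUE`, directly sampled cells keep their LiDAR ACD
#'   instead of the model prediction.
#' @param overwrite_lidar replace predictions with direct LiDAR estimates on
#'   sampled cells (default `FALSE`).
#' @return A `raster_grid` of predicted ACD (Mg C ha^-1).
#' @export
predict_ensemble <- function(model, stack, lidar_acd = NULL,
                             lidar_mask = NULL, overwrite_lidar = FALSE) {
  df <- stack_to_frame(stack)
  if (!setequal(names(df), model$features))
    stop("covariate stack does not match the trained feature set", call. = FALSE)
  pred <- stats::predict(model$forest, as.data.frame(df[model$features]))
  tmpl <- stack[[1]]
  out <- matrix(pred, nrow(tmpl$values), ncol(tmpl$values))
  if (overwrite_lidar) {
    if (is.null(lidar_acd) || is.null(lidar_mask))
      stop("`overwrite_lidar` needs `lidar_acd` and `lidar_mask`", call. = FALSE)
    keep <- lidar_mask$values > 0 & is.finite(lidar_acd$values)
    out[keep] <- lidar_acd$values[keep]
  }
  raster_like(tmpl, out)
}
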