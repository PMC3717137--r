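# Heteroskedastic error modelling, per-pixel propagation and ecoregion bias
# validation.

#' Fit a cubic RMSE-versus-predicted error model
#'
#' Residuals (predicted - observed) are binned by predicted ACD; the RMSE of
#' each bin is computed; a 3rd-order polynomial is least-squares fitted
#' through (bin centre, bin RMSE), weighted by bin count. Sparse bins
#' (fewer than `min_bin_n` residuals) are merged with their neighbours.
#' Evaluations are clamped at zero.
#'
#' @param predicted,observed paired ACD values (Mg C ha^-1).
#' @param bin_width bin width in Mg C ha^-1 (default 10).
#' @param min_bin_n minimum residuals per bin before merging (default 5).
#' @param lidar_error_rate proportional LiDAR-tier error rate stored on the
#'   model (default 0.10, i.e. 10% of ACD — the 1-ha LiDAR calibration
#'   error level).
#' @param lidar_error_fn optional function `ACD -> error` overriding the
#'   proportional rule (e.g. a fitted heteroskedastic curve).
#' @return An `error_model`: `rmse_poly` (coefficients, increasing powers),
#'   `bins` tibble (`center`, `rmse`, `n`), `bin_width`, `lidar_error_fn`,
#'   `range` of predicted values fitted.
#' @export
fit_rmse_polynomial <- function(predicted, observed, bin_width = 10,
                                min_bin_n = 5, lidar_error_rate = 0.10,
                                lidar_error_fn = NULL) {
  stopifnot(length(predicted) == length(observed))
  ok <- is.finite(predicted) & is.finite(observed)
  predicted <- predicted[ok]; observed <- observed[ok]
  resid <- predicted - observed
  edges <- seq(floor(min(predicted) / bin_width) * bin_width,
               ceiling(max(predicted) / bin_width) * bin_width + bin_width,
               by = bin_width)
  bin <- findInterval(predicted, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  bins <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, resid = resid,
                                   pred = predicted), .data$bin),
    center = mean(.data$pred),
    rmse = sqrt(mean(.data$resid^2)),
    n = dplyr::n(), .groups = "drop"
  )
  bins <- dplyr::arrange(bins, .data$center)
  # merge sparse bins into their nearest (preceding, else following) bin
  while (any(bins$n < min_bin_n) && nrow(bins) > 1L) {
    i <- which(bins$n < min_bin_n)[1]
    j <- if (i > 1L) i - 1L else i + 1L
    ntot <- bins$n[i] + bins$n[j]
    bins$center[j] <- (bins$center[i] * bins$n[i] + bins$center[j] * bins$n[j]) / ntot
    bins$rmse[j] <- sqrt((bins$rmse[i]^2 * bins$n[i] +
                            bins$rmse[j]^2 * bins$n[j]) / ntot)
    bins$n[j] <- ntot
    bins <- bins[-i, , drop = FALSE]
  }
  if (nrow(bins) < 4L)
    stop("need at least 4 populated bins to fit a cubic", call. = FALSE)
  fit <- stats::lm(rmse ~ poly(center, 3, raw = TRUE), data = bins,
                   weights = bins$n)
  if (is.null(lidar_error_fn)) {
    rate <- lidar_error_rate
    lidar_error_fn <- function(acd) rate * acd
  }
  structure(
    list(rmse_poly = unname(stats::coef(fit)),
         bins = bins, bin_width = bin_width,
         lidar_error_fn = lidar_error_fn,
         range = range(predicted)),
    class = "error_model"
  )
}

#' Evaluate an error model's upscaling-tier RMSE curve
#'
#' @param model an `error_model`.
#' @param acd predicted ACD values (vector or matrix).
#' @return RMSE estimates (Mg C ha^-1), clamped at zero.
#' @export
predict_rmse <- function(model, acd) {
  co <- model$rmse_poly
  out <- co[1] + co[2] * acd + co[3] * acd^2 + co[4] * acd^3
  pmax(out, 0)
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model> RMSE(x) = %.3g + %.3g x + %.3g x^2 + %.3g x^3 (%d bins)\n",
              x$rmse_poly[1], x$rmse_poly[2], x$rmse_poly[3], x$rmse_poly[4],
              nrow(x$bins)))
  invisible(x)
}

#' @method tidy error_model
#' @export
tidy.error_model <- function(x, ...) {
  tibble::tibble(term = paste0("acd^", 0:3), estimate = x$rmse_poly)
}

#' Linear quantile regression of residuals on predictions
#'
#' Fits `residual ~ intercept + slope * predicted` at each requested
#' quantile by minimising the pinball (check) loss with Nelder-Mead,
#' initialised at the least-squares line. Characterises how mapping error
#' spreads with carbon stock.
#'
#' @param predicted,observed paired ACD values (>= 50 pairs).
#' @param quantiles probabilities strictly inside (0, 1)
#'   (default 0.05, 0.5, 0.95).
#' @return Tibble: `quantile`, `intercept`, `slope`, `loss`.
#' @export
quantile_residual_bands <- function(predicted, observed,
                                    quantiles = c(0.05, 0.5, 0.95)) {
  stopifnot(length(predicted) == length(observed))
  if (length(predicted) < 50L) stop("need at least 50 pairs", call. = FALSE)
  if (any(quantiles <= 0 | quantiles >= 1))
    stop("quantiles must lie strictly inside (0, 1)", call. = FALSE)
  resid <- predicted - observed
  ls <- stats::lm(resid ~ predicted)
  purrr::map_dfr(quantiles, function(tau) {
    pinball <- function(par) {
      u <- resid - (par[1] + par[2] * predicted)
      sum(u * (tau - (u < 0)))
    }
    opt <- stats::optim(unname(stats::coef(ls)), pinball,
                        method = "Nelder-Mead",
                        control = list(maxit = 5e3, reltol = 1e-8))
    tibble::tibble(quantile = tau, intercept = opt$par[1],
                   slope = opt$par[2], loss = opt$value)
  })
}

#' Propagate LiDAR and upscaling errors to a per-pixel uncertainty map
#'
#' Directly LiDAR-sampled cells carry only the LiDAR-to-carbon error;
#' upscaled cells carry the root-sum-square of the LiDAR error and the
#' upscaling RMSE, the two sources being treated as independent:
#' `eps = sqrt(eps_lidar^2 + eps_model^2)`.
#'
#' @param acd_map `raster_grid` of mapped ACD.
#' @param lidar_mask `raster_grid` 0/1; 1 = directly LiDAR-mapped.
#' @param model an `error_model`.
#' @return `raster_grid` of per-cell error (Mg C ha^-1); nodata ACD stays
#'   nodata.
#' @export
propagate_error_map <- function(acd_map, lidar_mask, model) {
  check_aligned(acd_map, lidar_mask, "ACD map and LiDAR mask")
  acd <- acd_map$values
  eps_l <- model$lidar_error_fn(acd)
  eps_m <- predict_rmse(model, acd)
  eps <- sqrt(eps_l^2 + eps_m^2)
  on_lidar <- lidar_mask$values > 0
  eps[on_lidar] <- eps_l[on_lidar]
  eps[!is.finite(acd)] <- NA_real_
  raster_like(acd_map, eps)
}

#' Compare a national-scale map against LiDAR truth by region
#'
#' Zonal validation: within each labelled region, the mean bias
#' (national minus LiDAR), RMSE, cell count, and distribution summaries of
#' both maps.
#'
#' @param national,lidar_acd aligned `raster_grid`s.
#' @param regions tibble of rectangles (`region`, `row0`, `row1`, `col0`,
#'   `col1`) as produced by the landscape simulator, or a named list of
#'   polygons (columns `x`, `y`) in map coordinates.
#' @param min_cells regions with fewer valid overlapping cells raise a
#'   warning (default 100).
#' @return A `bias_report` tibble: `region`, `n_cells`, `bias`, `rmse`,
#'   `mean_national`, `mean_lidar`, `median_national`, `median_lidar`.
#' @export
ecoregion_bias_report <- function(national, lidar_acd, regions,
                                  min_cells = 100) {
  check_aligned(national, lidar_acd, "maps")
  nr <- nrow(national$values)
  if (!is.data.frame(regions)) {
    # polygons -> cell-index rectangles via their bounding boxes
    cc <- cell_centers(national)
    regions <- purrr::imap_dfr(regions, function(p, nm) {
      inside <- matrix(point_in_polygon(as.vector(cc$x), as.vector(cc$y), p),
                       nr, ncol(national$values))
      idx <- which(inside, arr.ind = TRUE)
      if (nrow(idx) == 0L) stop("region ", nm, " overlaps no cells", call. = FALSE)
      tibble::tibble(region = nm, row0 = min(idx[, 1]), row1 = max(idx[, 1]),
                     col0 = min(idx[, 2]), col1 = max(idx[, 2]))
    })
  }
  out <- purrr::pmap_dfr(regions, function(region, row0, row1, col0, col1, ...) {
    nat <- national$values[row0:row1, col0:col1]
    lid <- lidar_acd$values[row0:row1, col0:col1]
    ok <- is.finite(nat) & is.finite(lid)
    if (!any(ok)) stop("region ", region, " has no valid overlap", call. = FALSE)
    if (sum(ok) < min_cells)
      warning(sprintf("region %s has only %d valid cells", region, sum(ok)),
              call. = FALSE)
    d <- nat[ok] - lid[ok]
    tibble::tibble(
      region = region, n_cells = sum(ok),
      bias = mean(d), rmse = sqrt(mean(d^2)),
      mean_national = mean(nat[ok]), mean_lidar = mean(lid[ok]),
      median_national = stats::median(nat[ok]),
      median_lidar = stats::median(lid[ok])
    )
  })
  class(out) <- c("bias_report", class(out))
  out
}

#' Plot a bias report
#'
#' @param object a `bias_report`.
#' @param ... ignored.
#' @return A ggplot bar chart of per-region bias.
#' @method autoplot bias_report
#' @export
autoplot.bias_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$region, y = .data$bias)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(bias~(Mg~C~ha^-1))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
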