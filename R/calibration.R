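# Calibration of the TCH -> ACD power law by maximum likelihood with a
# mean-dependent error term.
#
# Model: ACD_i ~ Normal(mu_i, sigma_i^2), mu_i = a * TCH_i^b,
#        sigma_i = sigma0 * mu_i^k.
# k = 0 recovers constant (arithmetic) error, k = 1 proportional error; both
# are nested, and k is estimated from the data. Fitting on untransformed
# values avoids log back-transformation bias and permits ACD = 0
# observations (grasslands).

power_law_nll <- function(par, tch, acd, sigma_floor = 1e-8) {
  a <- exp(par[1]); b <- exp(par[2]); sigma0 <- exp(par[3]); k <- par[4]
  mu <- a * tch^b
  sigma <- pmax(sigma0 * mu^k, sigma_floor)
  if (any(!is.finite(sigma)) || any(!is.finite(mu))) return(1e12)
  out <- -sum(stats::dnorm(acd, mean = mu, sd = sigma, log = TRUE))
  if (!is.finite(out)) 1e12 else out
}

#' Fit the TCH-to-ACD power law by maximum likelihood
#'
#' Maximises the Gaussian likelihood with mean `a * TCH^b` and standard
#' deviation `sigma0 * mean^k` over all four parameters, starting from
#' ordinary least squares on (ln TCH, ln ACD). The heteroskedastic error
#' model makes the fit equivalent in spirit to a log-log regression while
#' staying on the original carbon scale.
#'
#' @param tch plot-mean top-of-canopy heights (m), all positive.
#' @param acd plot carbon densities (Mg C ha^-1), non-negative.
#' @param k_bounds box for the error-variance exponent (default c(0, 3)).
#' @return A `power_law_fit` with elements `a`, `b`, `sigma0`, `k`, a
#'   `report` tibble (n, adj_r2, rmse, bias, loglik, convergence) and the
#'   data used.
#' @export
fit_power_law_ml <- function(tch, acd, k_bounds = c(0, 3)) {
  tch <- as.numeric(tch); acd <- as.numeric(acd)
  n <- length(tch)
  if (n < 10L) stop("need at least 10 calibration plots", call. = FALSE)
  if (length(acd) != n) stop("`tch` and `acd` lengths differ", call. = FALSE)
  if (any(tch <= 0)) stop("all TCH values must be positive", call. = FALSE)
  if (any(acd < 0)) stop("ACD values must be non-negative", call. = FALSE)
  if (stats::sd(tch) == 0) stop("degenerate data: all TCH equal", call. = FALSE)

  # log-log OLS initialisation (positive ACD only)
  pos <- acd > 0
  init_fit <- stats::lm(log(acd[pos]) ~ log(tch[pos]))
  a0 <- exp(unname(stats::coef(init_fit)[1]))
  b0 <- unname(stats::coef(init_fit)[2])
  mu0 <- a0 * tch^b0
  resid0 <- acd - mu0
  rmse0 <- sqrt(mean(resid0^2))

  if (rmse0 < 1e-9 * max(acd)) {
    # exact power-law data: ML degenerates (sigma -> 0); the OLS solution is
    # already the maximiser of the mean model
    model <- new_power_law_fit(a0, b0, sigma0 = 0, k = 0, tch = tch, acd = acd,
                               loglik = Inf, convergence = 0L,
                               message = "noise-free data, OLS solution exact")
    return(model)
  }

  sig0 <- max(stats::sd(resid0 / pmax(mu0, 1)), 1e-3)
  par0 <- c(log(a0), log(max(b0, 1e-3)), log(sig0), 1)
  opt <- stats::optim(par0, power_law_nll, tch = tch, acd = acd,
                      method = "L-BFGS-B",
                      lower = c(-20, -20, -20, k_bounds[1]),
                      upper = c(20, 5, 20, k_bounds[2]),
                      control = list(maxit = 1e4, factr = 1e2))
  if (opt$convergence != 0) {
    # fall back: profile over a grid of fixed k with Nelder-Mead on the rest
    ks <- seq(k_bounds[1], k_bounds[2], length.out = 31)
    prof <- purrr::map(ks, function(kk) {
      stats::optim(par0[1:3], function(p) power_law_nll(c(p, kk), tch, acd),
                   method = "Nelder-Mead",
                   control = list(maxit = 5e3, reltol = 1e-10))
    })
    best <- which.min(purrr::map_dbl(prof, "value"))
    opt <- list(par = c(prof[[best]]$par, ks[best]),
                value = prof[[best]]$value,
                convergence = prof[[best]]$convergence,
                message = "profiled grid over k")
  }
  new_power_law_fit(exp(opt$par[1]), exp(opt$par[2]), exp(opt$par[3]),
                    opt$par[4], tch = tch, acd = acd,
                    loglik = -opt$value, convergence = opt$convergence,
                    message = if (is.null(opt$message)) "" else opt$message)
}

new_power_law_fit <- function(a, b, sigma0, k, tch, acd, loglik,
                              convergence, message = "") {
  mu <- a * tch^b
  structure(
    list(a = a, b = b, sigma0 = sigma0, k = k,
         data = tibble::tibble(tch = tch, acd = acd, fitted = mu),
         loglik = loglik, convergence = convergence, message = message,
         report = fit_report(mu, acd)),
    class = "power_law_fit"
  )
}

# adjusted R^2 (p = 2 mean-model parameters) and original-scale RMSE/bias
fit_report <- function(predicted, observed) {
  n <- length(observed)
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- 1 - ss_res / ss_tot
  tibble::tibble(
    n = n,
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2 - 1),
    rmse = sqrt(mean((observed - predicted)^2)),
    bias = mean(predicted - observed)
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> ACD = %.4g * TCH^%.4g\n", x$a, x$b))
  cat(sprintf("  error sd = %.4g * mu^%.3g; n = %d, adj R2 = %.3f, RMSE = %.2f Mg C/ha\n",
              x$sigma0, x$k, x$report$n, x$report$adj_r2, x$report$rmse))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "sigma0", "k"),
    estimate = c(x$a, x$b, x$sigma0, x$k)
  )
}

#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  dplyr::mutate(x$report, loglik = x$loglik, convergence = x$convergence)
}

#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  grid <- tibble::tibble(tch = seq(min(object$data$tch), max(object$data$tch),
                                   length.out = 200))
  grid$acd <- object$a * grid$tch^object$b
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$tch, y = .data$acd)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "top-of-canopy height (m)",
                  y = expression(ACD~(Mg~C~ha^-1))) +
    ggplot2::theme_minimal()
}

#' Predict carbon density from canopy height
#'
#' Applies the fitted power law `a * TCH^b` elementwise. TCH = 0 maps to 0;
#' nodata propagates; negative TCH is an error.
#'
#' @param model a `power_law_fit` (or any list with `a` and `b`).
#' @param tch a `raster_grid` or numeric vector of heights (m).
#' @return Same shape as `tch`, in Mg C ha^-1.
#' @export
predict_acd <- function(model, tch) {
  f <- function(v) {
    if (any(v < 0, na.rm = TRUE)) stop("TCH must be non-negative", call. = FALSE)
    model$a * v^model$b
  }
  if (is_raster_grid(tch)) raster_like(tch, f(tch$values)) else f(tch)
}

#' Validation statistics on held-out plots
#'
#' Evaluates a fitted power law on plots never used in calibration: RMSE and
#' bias of predicted versus observed ACD on the original scale, and the
#' adjusted R-squared of observed regressed on predicted.
#'
#' @param model a `power_law_fit`.
#' @param plots tibble with columns `tch`, `acd`, and optionally `plot_id`.
#' @param calibration_ids plot ids used in calibration; if `plots` carries
#'   `plot_id`, overlap raises an error (set-aside contract).
#' @return A one-row tibble: `n`, `adj_r2`, `rmse`, `bias`.
#' @export
validation_stats <- function(model, plots, calibration_ids = NULL) {
  plots <- tibble::as_tibble(plots)
  if (nrow(plots) == 0L) stop("validation set is empty", call. = FALSE)
  if (!is.null(calibration_ids) && "plot_id" %in% names(plots) &&
      any(plots$plot_id %in% calibration_ids))
    stop("validation plots overlap the calibration set", call. = FALSE)
  pred <- predict_acd(model, plots$tch)
  out <- fit_report(pred, plots$acd)
  # report the adjusted R^2 of observed regressed on predicted (one slope +
  # intercept), the usual validation-scatter statistic
  if (stats::sd(pred) > 0) {
    out$adj_r2 <- suppressWarnings(
      summary(stats::lm(plots$acd ~ pred))$adj.r.squared)
  }
  out
}
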