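# Penalized smooth-effect models -----------------------------------------

#' Fit a univariate penalized smooth effect
#'
#' Fits `y ~ s(x)` with a cubic regression spline capped at `basis_dim`
#' basis functions, Gaussian errors, identity link (no response
#' transformation), and smoothness selected by restricted maximum
#' likelihood (REML), via [mgcv::gam()].  The deliberately small basis cap
#' keeps fitted effects interpretable as broad trends (an effective degrees
#' of freedom near 1 indicates an essentially linear effect).
#'
#' @param x,y Numeric predictor and response (>= 10 finite observations).
#' @param basis_dim Maximum number of basis functions (default 4).
#' @param predictor,response Names used in summaries and printing.
#' @return An object of class `smooth_fit`: list with the fitted `model`,
#'   `edf` (effective degrees of freedom of the smooth), `null_dev_prop`
#'   (proportion of null deviance explained, `1 - RSS/TSS` under the
#'   Gaussian identity model), the data range, and the names.
#' @export
fit_smooth <- function(x, y, basis_dim = 4L, predictor = "x",
                       response = "y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10L) stop("need at least 10 finite observations")
  if (length(unique(x)) < basis_dim)
    stop("predictor has too few distinct values for the requested basis")
  dat <- data.frame(x = x, y = y)
  if (stats::var(y) == 0) {
    # a constant response carries no signal; REML cannot estimate a scale,
    # so return the exact flat fit directly
    model <- lm(y ~ 1, data = dat)
    edf <- 0; dev_expl <- 0
  } else {
    model <- mgcv::gam(y ~ s(x, k = basis_dim, bs = "cr"), data = dat,
                       family = gaussian(), method = "REML")
    sm <- summary(model)
    edf <- unname(sm$edf); dev_expl <- unname(sm$dev.expl)
  }
  structure(list(model = model,
                 basis_dim = as.integer(basis_dim),
                 edf = edf,
                 null_dev_prop = dev_expl,
                 x_range = range(x), n = length(x),
                 predictor = predictor, response = response),
            class = "smooth_fit")
}

#' Evaluate a smooth fit on a predictor grid
#'
#' @param fit A [fit_smooth()] object.
#' @param grid_n Number of evenly spaced evaluation points spanning the
#'   observed predictor range (default 200).
#' @param conf.level Level of the pointwise uncertainty band.
#' @return Data frame with `x`, `fitted`, `se`, `lower`, `upper`.
#' @export
evaluate_smooth <- function(fit, grid_n = 200L, conf.level = 0.95) {
  stopifnot(inherits(fit, "smooth_fit"))
  xs <- seq(fit$x_range[1L], fit$x_range[2L], length.out = grid_n)
  pr <- predict(fit$model, newdata = data.frame(x = xs), se.fit = TRUE)
  z <- qnorm(1 - (1 - conf.level) / 2)
  data.frame(x = xs, fitted = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
             lower = as.numeric(pr$fit - z * pr$se.fit),
             upper = as.numeric(pr$fit + z * pr$se.fit))
}

#' Summary statistics of a fitted smooth effect
#'
#' Evaluates the fitted curve on `grid_n` evenly spaced predictor values and
#' reports: the predictor values at which the curve is maximized and
#' minimized; the mean of the signed finite-difference slopes (the average
#' effect of a unit change of the predictor on the response); and the mean
#' of the absolute slopes (the sensitivity of the response regardless of
#' direction).  `mean_abs_rate >= |mean_rate|` always holds.
#'
#' @inheritParams evaluate_smooth
#' @return An object of class `fit_summary`: list with `argmax_x`,
#'   `argmin_x`, `mean_rate`, `mean_abs_rate`, `edf`, `null_dev_prop`,
#'   `grid_n`, and the predictor/response names.
#' @export
summarize_fit <- function(fit, grid_n = 200L) {
  ev <- evaluate_smooth(fit, grid_n)
  slopes <- diff(ev$fitted) / diff(ev$x)
  structure(list(predictor = fit$predictor, response = fit$response,
                 argmax_x = ev$x[which.max(ev$fitted)],
                 argmin_x = ev$x[which.min(ev$fitted)],
                 mean_rate = mean(slopes),
                 mean_abs_rate = mean(abs(slopes)),
                 edf = fit$edf, null_dev_prop = fit$null_dev_prop,
                 grid_n = as.integer(grid_n)),
            class = "fit_summary")
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf("smooth fit %s ~ s(%s, k = %d): edf = %.2f, dev.expl = %.3f, n = %d\n",
              x$response, x$predictor, x$basis_dim, x$edf,
              x$null_dev_prop, x$n))
  invisible(x)
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf(paste0("smooth-effect summary (%s ~ %s): argmax = %.3f, ",
                     "argmin = %.3f,\n  mean rate = %.3f, ",
                     "mean |rate| = %.3f, edf = %.2f, dev.expl = %.3f\n"),
              x$response, x$predictor, x$argmax_x, x$argmin_x,
              x$mean_rate, x$mean_abs_rate, x$edf, x$null_dev_prop))
  invisible(x)
}
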