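# Trend regressions: binned latitudinal gradients of EHI and record-level
# covariate relationships (e.g. EHI vs soil organic carbon).  Simple OLS is
# implemented in closed form (normal equations) so tests can check it
# against lm() as an independent route.

# Closed-form simple linear regression y ~ x (optionally weighted) with R^2
# and a two-sided t-test p-value on the slope.
ols_fit <- function(x, y, x_label = "x", y_label = "y", weights = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (is.null(weights)) weights <- rep(1, length(x))
  x <- x[ok]; y <- y[ok]; w <- weights[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete (x, y) pairs", call. = FALSE)
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  if (sxx == 0) stop("predictor has zero variance", call. = FALSE)
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  sst <- sum(w * (y - yb)^2)
  r2 <- if (sst == 0) 1 else 1 - sum(w * resid^2) / sst
  slope_se <- sqrt(sum(w * resid^2) / (n - 2) / sxx)
  p_value <- if (slope_se == 0) 0 else
    2 * stats::pt(-abs(slope / slope_se), df = n - 2)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 p_value = p_value, n = n, slope_se = slope_se,
                 predictor = x_label, response = y_label),
            class = "bce_trend")
}

#' @export
print.bce_trend <- function(x, ...) {
  cat(sprintf("Trend %s ~ %s: slope = %.4g, R2 = %.3f, p = %.3g, n = %d\n",
              x$response, x$predictor, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Latitudinal EHI trend on 1-degree bins
#'
#' Bins records into 1-degree bands of absolute latitude, averages the
#' response within each band, and fits OLS of the band means against the
#' band mean absolute latitude, weighting each band by its record count
#' (band means have variance proportional to 1/count, so count weights give
#' a calibrated slope confidence interval).  Using the within-band mean
#' rather than the nominal band center makes the fit exact for a noiseless
#' linear gradient.
#'
#' @param records data.frame with `latitude` and the response column.
#' @param ecotone optional ecotone filter.
#' @param response response column (default "ehi").
#' @param bin_width band width in degrees (default 1).
#' @return `bce_trend` with slope per degree of |latitude|, plus `bins`
#'   attribute (band table).
#' @export
latitudinal_trend <- function(records, ecotone = NULL, response = "ehi",
                              bin_width = 1) {
  if (!is.null(ecotone)) records <- records[records$ecotone == ecotone, ]
  al <- abs(records$latitude)
  y <- records[[response]]
  ok <- is.finite(al) & is.finite(y)
  al <- al[ok]; y <- y[ok]
  bin <- floor(al / bin_width)
  ub <- sort(unique(bin))
  if (length(ub) < 3) stop("need at least 3 latitude bins with data",
                           call. = FALSE)
  bx <- vapply(ub, function(b) mean(al[bin == b]), numeric(1))
  by <- vapply(ub, function(b) mean(y[bin == b]), numeric(1))
  bn <- vapply(ub, function(b) sum(bin == b), numeric(1))
  fit <- ols_fit(bx, by, x_label = "abs_latitude", y_label = response,
                 weights = bn)
  attr(fit, "bins") <- data.frame(bin_center = (ub + 0.5) * bin_width,
                                  mean_abs_latitude = bx, mean_response = by,
                                  n = as.integer(table(bin)))
  fit
}

#' Record-level covariate trend
#'
#' Simple OLS of one column against another over complete pairs, e.g. soil
#' organic carbon against EHI.
#'
#' @param records data.frame.
#' @param x_label,y_label predictor and response column names.
#' @return `bce_trend`.
#' @export
covariate_trend <- function(records, x_label, y_label) {
  for (cl in c(x_label, y_label))
    if (!cl %in% names(records))
      stop(sprintf("column '%s' not found", cl), call. = FALSE)
  ols_fit(records[[x_label]], records[[y_label]],
          x_label = x_label, y_label = y_label)
}
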