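# Random-intercept linear mixed model fitted by profile REML.
#
# Model: y = X beta + b_g + e, with one random intercept per group,
# b_g ~ N(0, sigma_b^2), e ~ N(0, sigma_e^2).  With the variance ratio
# lambda = sigma_b^2 / sigma_e^2 fixed, V_g = I + lambda * J has the
# closed-form inverse I - lambda/(1 + lambda n_g) * J per group, so beta and
# sigma_e^2 profile out and REML reduces to a bounded 1-D search over
# log(lambda).  This is the "EHIc" bioclimatic-baseline model: EHI regressed
# on climate covariates and pressures with a continent-level random
# intercept.

# Profiled REML criterion pieces for a given lambda.
reml_profile <- function(lambda, X, y, group_idx) {
  p <- ncol(X)
  n <- length(y)
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  ytVy <- 0
  logdetV <- 0
  for (rows in group_idx) {
    ng <- length(rows)
    w <- lambda / (1 + lambda * ng)
    Xg <- X[rows, , drop = FALSE]
    yg <- y[rows]
    cx <- colSums(Xg)
    cy <- sum(yg)
    XtVX <- XtVX + crossprod(Xg) - w * tcrossprod(cx)
    XtVy <- XtVy + crossprod(Xg, yg) - w * cx * cy
    ytVy <- ytVy + sum(yg^2) - w * cy^2
    logdetV <- logdetV + log1p(lambda * ng)
  }
  beta <- solve(XtVX, XtVy)
  rss <- as.numeric(ytVy - 2 * sum(beta * XtVy) + t(beta) %*% XtVX %*% beta)
  rss <- max(rss, 1e-300)
  crit <- logdetV + determinant(XtVX, logarithm = TRUE)$modulus[1] +
    (n - p) * log(rss)
  list(criterion = crit, beta = beta, rss = rss, XtVX = XtVX)
}

#' Fit a random-intercept mixed model by profile REML
#'
#' @param records data.frame.
#' @param fixed character vector of fixed-effect column names (an intercept
#'   is always included).
#' @param group grouping column name (e.g. "continent").
#' @param response response column name (default "ehi").
#' @param tol convergence tolerance of the 1-D REML search (default 1e-8).
#' @return object of class `bce_mixed`: `beta` (named), `random_intercepts`
#'   (named per group, empirical Bayes), `sigma_b`, `sigma_e`, `fitted`
#'   (X beta + b per record, NA where predictors missing), `log_reml`,
#'   `n`, `groups`.
#' @export
fit_random_intercept <- function(records, fixed, group, response = "ehi",
                                 tol = 1e-8) {
  cols <- c(fixed, group, response)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dat <- records[stats::complete.cases(records[, cols]), cols, drop = FALSE]
  y <- dat[[response]]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(dat[, fixed, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  g <- factor(dat[[group]])
  group_idx <- split(seq_along(y), g)
  if (length(group_idx) < 2L) {
    warning("single group: model reduces to ordinary least squares",
            call. = FALSE)
    lambda_hat <- 0
  } else {
    obj <- function(loglam) reml_profile(exp(loglam), X, y,
                                         group_idx)$criterion
    opt <- stats::optimize(obj, interval = c(-30, 15), tol = tol)
    # boundary check: sigma_b = 0 (lambda -> 0)
    lambda_hat <- if (reml_profile(1e-12, X, y, group_idx)$criterion <=
                        opt$objective + tol) 0 else exp(opt$minimum)
  }
  prof <- reml_profile(max(lambda_hat, 1e-12), X, y, group_idx)
  n <- length(y)
  p <- ncol(X)
  sigma_e2 <- prof$rss / (n - p)
  sigma_b2 <- lambda_hat * sigma_e2
  beta <- drop(prof$beta)
  names(beta) <- colnames(X)
  # empirical-Bayes (BLUP) group intercepts shrink the group-mean residual
  marg_resid <- y - drop(X %*% beta)
  b <- vapply(group_idx, function(rows) {
    ng <- length(rows)
    lambda_hat * ng / (1 + lambda_hat * ng) * mean(marg_resid[rows])
  }, numeric(1))
  fitted_rec <- rep(NA_real_, nrow(records))
  ok <- stats::complete.cases(records[, cols])
  Xall <- cbind(1, as.matrix(records[ok, fixed, drop = FALSE]))
  g_all <- as.character(records[[group]][ok])
  b_term <- ifelse(g_all %in% names(b), b[g_all], 0)
  fitted_rec[ok] <- drop(Xall %*% beta) + b_term
  log_reml <- -0.5 * (prof$criterion + (n - p) * (1 + log(2 * pi / (n - p))))
  structure(list(beta = beta, random_intercepts = b,
                 sigma_b = sqrt(sigma_b2), sigma_e = sqrt(sigma_e2),
                 fitted = fitted_rec, residuals = y - (drop(X %*% beta) +
                   b[as.character(g)]),
                 log_reml = log_reml, n = n,
                 groups = names(group_idx), fixed = fixed,
                 response = response, group = group),
            class = "bce_mixed")
}

#' @export
print.bce_mixed <- function(x, ...) {
  cat(sprintf("Random-intercept model (%s | %s), REML, n = %d\n",
              x$response, x$group, x$n))
  cat("  fixed effects:\n")
  print(round(x$beta, 5))
  cat(sprintf("  sigma_b = %.5g, sigma_e = %.5g\n", x$sigma_b, x$sigma_e))
  invisible(x)
}
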