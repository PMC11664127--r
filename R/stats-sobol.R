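# Variance-based global sensitivity analysis: first-order Sobol indices
# S_i = V[E(Y | X_i)] / V(Y), paired-matrix (radial) design with bootstrap
# standard errors and normal-approximation 0.05 quantiles.

#' First-order Sobol indices by the paired-matrix estimator
#'
#' Draws two independent base matrices A and B from `sampler`, evaluates the
#' model on A, B and on each hybrid AB_i (A with column i taken from B), and
#' estimates `V_i = mean(y_B * (y_ABi - y_A))` (the Saltelli-2010 first-order
#' estimator), normalized by the pooled output variance.  Standard errors
#' come from a nonparametric bootstrap over base-sample rows; `q05 = s1 -
#' 1.645 * se` is the 0.05 quantile under a normal approximation.
#'
#' @param model function: numeric matrix (rows = evaluations, one column per
#'   input) -> numeric vector of outputs.  Must be deterministic.
#' @param sampler function: integer n -> n x k numeric matrix of independent
#'   input draws (named columns label the indices).
#' @param n_base number of base samples (>= 64).
#' @param n_boot bootstrap replicates for SE (default 100).
#' @param seed integer seed.
#' @return object of class `bce_sobol`: data.frame-like list with
#'   `indices` (variable, s1, se, q05), `n_base`, `n_boot`, `seed`,
#'   `var_y`.
#' @export
sobol_first_order <- function(model, sampler, n_base, n_boot = 100L,
                              seed = 1L) {
  if (n_base < 64) stop("`n_base` must be at least 64", call. = FALSE)
  res <- with_seed(seed, {
    A <- sampler(n_base)
    B <- sampler(n_base)
    k <- ncol(A)
    yA <- model(A)
    yB <- model(B)
    check_finite <- function(y, X, label) {
      bad <- which(!is.finite(y))
      if (length(bad))
        stop(sprintf("model returned non-finite value for %s row %d: [%s]",
                     label, bad[1],
                     paste(signif(X[bad[1], ], 4), collapse = ", ")),
             call. = FALSE)
    }
    check_finite(yA, A, "A")
    check_finite(yB, B, "B")
    yAB <- matrix(NA_real_, n_base, k)
    for (i in seq_len(k)) {
      ABi <- A
      ABi[, i] <- B[, i]
      yAB[, i] <- model(ABi)
      check_finite(yAB[, i], ABi, paste0("AB_", i))
    }
    # center the outputs: the Saltelli-2010 estimator is offset-invariant in
    # expectation but not in finite samples
    mu <- mean(c(yA, yB))
    yA <- yA - mu
    yB <- yB - mu
    yAB <- yAB - mu
    est <- function(rows) {
      vy <- stats::var(c(yA[rows], yB[rows]))
      colMeans(yB[rows] * (yAB[rows, , drop = FALSE] - yA[rows])) / vy
    }
    s1 <- est(seq_len(n_base))
    boot <- matrix(NA_real_, n_boot, k)
    for (b in seq_len(n_boot)) {
      rows <- sample.int(n_base, n_base, replace = TRUE)
      boot[b, ] <- est(rows)
    }
    se <- apply(boot, 2, stats::sd)
    list(s1 = s1, se = se, var_y = stats::var(c(yA, yB)),
         labels = colnames(A))
  })
  labels <- res$labels
  if (is.null(labels)) labels <- paste0("X", seq_along(res$s1))
  structure(
    list(indices = data.frame(variable = labels, s1 = unname(res$s1),
                              se = unname(res$se),
                              q05 = unname(res$s1 - 1.645 * res$se)),
         n_base = as.integer(n_base), n_boot = as.integer(n_boot),
         seed = as.integer(seed), var_y = res$var_y),
    class = "bce_sobol")
}

#' @export
print.bce_sobol <- function(x, ...) {
  cat(sprintf("First-order Sobol indices (n_base = %d, %d bootstrap reps)\n",
              x$n_base, x$n_boot))
  print(transform(x$indices, s1 = round(s1, 4), se = round(se, 4),
                  q05 = round(q05, 4)), row.names = FALSE)
  invisible(x)
}

#' Empirical-marginal input sampler for the EHI pipeline
#'
#' Builds a sampler that draws each input independently from its empirical
#' marginal in a scored pixel table (rank correlations between inputs are
#' deliberately ignored: a documented limitation of the independence
#' assumption in the variance decomposition).
#'
#' @param records scored pixel table (see [score_indicators()]).
#' @param columns input columns to resample.
#' @return function(n) -> n x length(columns) matrix.
#' @export
empirical_sampler <- function(records, columns) {
  pools <- lapply(columns, function(cl) {
    v <- records[[cl]]
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      stop(sprintf("no observed values to resample for '%s'", cl),
           call. = FALSE)
    v
  })
  names(pools) <- columns
  function(n) {
    m <- vapply(pools, function(v) v[sample.int(length(v), n, replace = TRUE)],
                numeric(n))
    colnames(m) <- columns
    m
  }
}

#' EHI pipeline closure for sensitivity analysis
#'
#' Returns the deterministic map from the normalized indicator inputs to
#' EHI for one ecotone: B is the mean of the six fitness indicators
#' (mangrove) or area alone (salt marsh, seagrass); P is the mean of the
#' normalized pressure compounds (species excluded for salt marsh); EHI =
#' B * (1 - P * T).
#'
#' @param ecotone ecotone label.
#' @return list with `fn` (matrix -> EHI vector) and `inputs` (column names
#'   the closure expects).
#' @export
ehi_model_closure <- function(ecotone) {
  ecotone <- match_ecotone(ecotone)
  fit_cols <- if (ecotone == "mangrove") paste0("n_", fitness_columns())
              else "n_area"
  p_cols <- c("p_climate", "p_land", "p_marine",
              if (ecotone != "salt_marsh") "p_species")
  inputs <- c(fit_cols, p_cols, "t")
  fn <- function(X) {
    b <- rowMeans(X[, fit_cols, drop = FALSE])
    p <- rowMeans(X[, p_cols, drop = FALSE])
    compute_ehi(b, p, X[, "t"])
  }
  list(fn = fn, inputs = inputs)
}
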