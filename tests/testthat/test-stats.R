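unif_sampler <- function(k, lo = 0, hi = 1) {
  function(n) {
    m <- matrix(runif(n * k, lo, hi), ncol = k)
    colnames(m) <- paste0("X", seq_len(k))
    m
  }
}

test_that("sobol indices recover the additive-model closed form", {
  model <- function(X) X[, 1] + 2 * X[, 2] + 3 * X[, 3]
  res <- sobol_first_order(model, unif_sampler(3), n_base = 4096, seed = 2)
  # analytic: V_i = c(1,4,9)/12, V = 14/12
  expect_lt(max(abs(res$indices$s1 - c(1, 4, 9) / 14)), 0.03)
  expect_equal(res$indices$q05, res$indices$s1 - 1.645 * res$indices$se)
})

test_that("a single-input model concentrates all sensitivity", {
  model <- function(X) 5 * X[, 1] - 2
  res <- sobol_first_order(model, unif_sampler(3), n_base = 2048, seed = 3)
  expect_equal(res$indices$s1[1], 1, tolerance = 0.05)
  expect_true(all(abs(res$indices$s1[2:3]) < 0.05))
})

test_that("sobol estimates are invariant to affine output rescaling", {
  model <- function(X) X[, 1] + 2 * X[, 2]
  scaled <- function(X) 100 * model(X) + 7
  r1 <- sobol_first_order(model, unif_sampler(2), n_base = 1024, seed = 5)
  r2 <- sobol_first_order(scaled, unif_sampler(2), n_base = 1024, seed = 5)
  expect_equal(r1$indices$s1, r2$indices$s1, tolerance = 1e-6)
})

test_that("sobol recovers the Ishigami closed-form indices", {
  a <- 7; b <- 0.1
  model <- function(X) sin(X[, 1]) + a * sin(X[, 2])^2 +
    b * X[, 3]^4 * sin(X[, 1])
  # analytic decomposition: V1 = (1 + b pi^4 / 5)^2 / 2, V2 = a^2 / 8,
  # V = V1 + V2 + b^2 pi^8 * (1/18 - 1/50)  [interaction remainder]
  v1 <- (1 + b * pi^4 / 5)^2 / 2
  v2 <- a^2 / 8
  v <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 1 / 2
  truth <- c(v1 / v, v2 / v, 0)
  expect_equal(truth[1], 0.3139, tolerance = 1e-3)
  expect_equal(truth[2], 0.4424, tolerance = 1e-3)
  res <- sobol_first_order(model, unif_sampler(3, -pi, pi),
                           n_base = 8192, seed = 11)
  expect_lt(max(abs(res$indices$s1 - truth)), 0.03)
})

test_that("sobol validates inputs and is seed-deterministic", {
  model <- function(X) X[, 1]
  expect_error(sobol_first_order(model, unif_sampler(1), n_base = 32),
               "64")
  bad <- function(X) ifelse(X[, 1] > 0.5, NaN, X[, 1])
  expect_error(sobol_first_order(bad, unif_sampler(1), n_base = 128,
                                 seed = 1), "non-finite")
  r1 <- sobol_first_order(model, unif_sampler(2), n_base = 256, seed = 9)
  r2 <- sobol_first_order(model, unif_sampler(2), n_base = 256, seed = 9)
  expect_identical(r1$indices, r2$indices)
})

test_that("latitudinal trend is exact on a noiseless gradient", {
  set.seed(4)
  lat <- runif(500, -38.5, 29.5)
  rec <- data.frame(latitude = lat, ehi = 0.8 - 0.007 * abs(lat),
                    ecotone = "mangrove")
  fit <- latitudinal_trend(rec, ecotone = "mangrove")
  expect_equal(fit$slope, -0.007, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  flat <- data.frame(latitude = lat, ehi = 0.5, ecotone = "mangrove")
  expect_equal(latitudinal_trend(flat)$slope, 0, tolerance = 1e-12)

  expect_error(latitudinal_trend(rec[abs(rec$latitude) < 2, ]), "3 latitude")
})

test_that("covariate trend matches lm() to high precision", {
  rec <- data.frame(ehi = c(0.1, 0.3, 0.45, 0.6, 0.8),
                    soc = c(120, 260, 300, 470, 610))
  fit <- covariate_trend(rec, "ehi", "soc")
  ref <- stats::lm(soc ~ ehi, data = rec)
  expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-12)
  expect_equal(fit$r_squared, summary(ref)$r.squared, tolerance = 1e-12)
  expect_equal(fit$p_value, summary(ref)$coefficients[2, 4],
               tolerance = 1e-12)
  expect_error(covariate_trend(rec, "ehi", "nope"), "nope")

  # exact noiseless proportionality
  prop <- data.frame(x = 1:10 / 10, y = 689.16 * (1:10 / 10))
  f2 <- covariate_trend(prop, "x", "y")
  expect_equal(f2$slope, 689.16, tolerance = 1e-10)
  expect_equal(f2$r_squared, 1, tolerance = 1e-12)
})

test_that("covariate trend recovers a slope under calibrated noise", {
  # noise sd chosen so R^2 ~ 0.37: var(signal)/ (var(signal)+sd^2) = 0.37
  set.seed(12)
  n <- 1000
  x <- runif(n)
  signal <- 689.16 * x
  sd_noise <- sqrt(stats::var(signal) * (1 - 0.37) / 0.37)
  y <- signal + rnorm(n, 0, sd_noise)
  fit <- covariate_trend(data.frame(x = x, y = y), "x", "y")
  expect_equal(fit$slope, 689.16, tolerance = 0.10 * 689.16)
  expect_equal(fit$r_squared, 0.37, tolerance = 0.08)
})

test_that("uncorrelated covariates give near-zero slope and R^2", {
  set.seed(13)
  fit <- covariate_trend(data.frame(x = runif(800), y = rnorm(800)),
                         "x", "y")
  expect_lt(abs(fit$slope), 0.3)
  expect_lt(fit$r_squared, 0.02)
})

sim_mixed <- function(seed, beta = c(0.3, 0.5, -0.2), sigma_b = 0.1,
                      sigma_e = 0.05, n_groups = 6, n_per = 200) {
  set.seed(seed)
  g <- rep(paste0("G", seq_len(n_groups)), each = n_per)
  x1 <- runif(n_groups * n_per)
  x2 <- runif(n_groups * n_per)
  b <- rnorm(n_groups, 0, sigma_b)
  y <- beta[1] + beta[2] * x1 + beta[3] * x2 + b[as.integer(factor(g))] +
    rnorm(n_groups * n_per, 0, sigma_e)
  data.frame(y = y, x1 = x1, x2 = x2, g = g)
}

test_that("profile REML matches lme4 on simulated data", {
  skip_if_not_installed("lme4")
  d <- sim_mixed(21)
  fit <- fit_random_intercept(d, fixed = c("x1", "x2"), group = "g",
                              response = "y")
  ref <- lme4::lmer(y ~ x1 + x2 + (1 | g), data = d, REML = TRUE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma_b, vc$sdcor[1], tolerance = 1e-4)
  expect_equal(fit$sigma_e, vc$sdcor[2], tolerance = 1e-4)
  blup <- lme4::ranef(ref)$g[, 1]
  expect_equal(unname(fit$random_intercepts), blup, tolerance = 1e-4)
})

test_that("REML on a balanced one-way design matches the ANOVA closed form", {
  set.seed(31)
  n_groups <- 8; n_per <- 25
  g <- rep(letters[1:n_groups], each = n_per)
  y <- rnorm(n_groups * n_per, mean = rep(rnorm(n_groups, 0, 0.4),
                                          each = n_per), sd = 0.3)
  d <- data.frame(y = y, g = g)
  fit <- fit_random_intercept(d, fixed = character(0), group = "g",
                              response = "y")
  gm <- tapply(y, g, mean)
  msb <- n_per * sum((gm - mean(y))^2) / (n_groups - 1)
  msw <- sum((y - rep(gm, each = n_per))^2) / (n_groups * (n_per - 1))
  expect_equal(fit$sigma_e^2, msw, tolerance = 1e-6)
  expect_equal(fit$sigma_b^2, max((msb - msw) / n_per, 0), tolerance = 1e-6)
  expect_equal(unname(fit$beta), mean(gm), tolerance = 1e-8)
})

test_that("sigma_b = 0 data collapse to OLS; degenerate cases are handled", {
  d <- sim_mixed(41, sigma_b = 0)
  fit <- fit_random_intercept(d, fixed = c("x1", "x2"), group = "g",
                              response = "y")
  ref <- stats::lm(y ~ x1 + x2, data = d)
  expect_lt(fit$sigma_b, 0.02)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-3)

  single <- d[d$g == "G1", ]
  expect_warning(f1 <- fit_random_intercept(single, fixed = "x1",
                                            group = "g", response = "y"),
                 "single group")
  expect_equal(unname(f1$beta),
               unname(coef(stats::lm(y ~ x1, data = single))),
               tolerance = 1e-8)

  dd <- d; dd$x3 <- dd$x1 * 2
  expect_error(fit_random_intercept(dd, fixed = c("x1", "x3"), group = "g",
                                    response = "y"), "collinear")
})

test_that("group intercepts shrink toward zero as sigma_b/sigma_e -> 0", {
  d <- sim_mixed(51, sigma_b = 0.3, sigma_e = 0.05, n_per = 40)
  strong <- fit_random_intercept(d, fixed = c("x1", "x2"), group = "g",
                                 response = "y")
  d2 <- sim_mixed(51, sigma_b = 0.005, sigma_e = 0.3, n_per = 40)
  weak <- fit_random_intercept(d2, fixed = c("x1", "x2"), group = "g",
                               response = "y")
  expect_gt(mean(abs(strong$random_intercepts)),
            mean(abs(weak$random_intercepts)))
})

test_that("ehi model closure reproduces the scored pipeline identities", {
  world <- small_world(200, seed = 61)
  scored <- score_indicators(world)$records
  scored$t <- 0.4
  mc <- ehi_model_closure("mangrove")
  sub <- scored[scored$ecotone == "mangrove", ]
  ok <- stats::complete.cases(sub[, mc$inputs])
  X <- as.matrix(sub[ok, mc$inputs])
  got <- mc$fn(X)
  want <- compute_ehi(rowMeans(X[, paste0("n_", c("area", "fragment_area",
                                                  "age", "height", "agb",
                                                  "soc"))]),
                      rowMeans(X[, c("p_climate", "p_land", "p_marine",
                                     "p_species")]), 0.4)
  expect_equal(got, want)
})
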