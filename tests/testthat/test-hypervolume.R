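test_that("Silverman bandwidths match the closed form and scale with the data", {
  set.seed(3)
  x <- matrix(rnorm(100), ncol = 1)
  bw <- silverman_bandwidths(x)
  expect_equal(bw, sd(x) * (4 / 3)^(1 / 5) * 100^(-1 / 5))
  # with unit sd and n = 100 the rule gives ~0.4217
  expect_equal(bw / sd(x), 0.4217, tolerance = 1e-3)

  m <- matrix(rnorm(600), ncol = 3)
  expect_equal(silverman_bandwidths(10 * m), 10 * silverman_bandwidths(m))

  expect_error(silverman_bandwidths(matrix(1, 1, 1)), "at least 2")
  degen <- cbind(a = rnorm(20), b = rep(2, 20))
  expect_error(silverman_bandwidths(degen), "b")
})

test_that("hypervolume fitting is seeded-deterministic and translation invariant", {
  set.seed(9)
  x <- matrix(rnorm(300), ncol = 2)
  h1 <- fit_hypervolume(x, seed = 4, n_samples = 4000)
  h2 <- fit_hypervolume(x, seed = 4, n_samples = 4000)
  expect_identical(h1$volume, h2$volume)
  h3 <- fit_hypervolume(x + 100, seed = 4, n_samples = 4000)
  expect_equal(h3$volume, h1$volume, tolerance = 1e-6)
  expect_error(fit_hypervolume(x, mass_quantile = 0), "\\(0, 1\\]")
  expect_error(fit_hypervolume(x[1, , drop = FALSE]), "at least 2")
})

test_that("volume is non-decreasing in the retained mass q", {
  set.seed(10)
  x <- matrix(rnorm(400), ncol = 2)
  vols <- vapply(c(0.5, 0.75, 0.9, 0.99),
                 function(q) fit_hypervolume(x, mass_quantile = q,
                                             seed = 6, n_samples = 4000)$volume,
                 numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("volume scaling: stretching one coordinate scales the volume", {
  set.seed(12)
  x <- matrix(rnorm(500), ncol = 2)
  v1 <- fit_hypervolume(x, seed = 3)$volume
  y <- x; y[, 2] <- 3 * y[, 2]
  v3 <- fit_hypervolume(y, seed = 3)$volume
  expect_equal(v3 / v1, 3, tolerance = 0.05)
})

test_that("1-D volume agrees with the grid-integration oracle and the normal interval", {
  set.seed(21)
  x <- rnorm(600)
  hv <- fit_hypervolume(matrix(x, ncol = 1), mass_quantile = 0.95, seed = 8)
  oracle <- grid_hypervolume_1d(x, q = 0.95)
  expect_equal(hv$volume, oracle$volume, tolerance = 0.05)
  # smoothed 95%-mass interval of a standard normal is a bit over 3.92
  expect_equal(hv$volume, 2 * qnorm(0.975), tolerance = 0.15)
})

test_that("overlap limits: identity, separation, symmetry, monotone decay", {
  set.seed(30)
  x <- matrix(rnorm(400), ncol = 2)
  ha <- fit_hypervolume(x, seed = 5)
  expect_gte(sorensen_overlap(ha, ha)$sorensen, 0.95)

  far <- fit_hypervolume(x + 20, seed = 6)  # 20 pooled SDs away
  expect_lte(sorensen_overlap(ha, far)$sorensen, 0.01)

  hb <- fit_hypervolume(x + 0.8, seed = 7)
  expect_identical(sorensen_overlap(ha, hb)$sorensen,
                   sorensen_overlap(hb, ha)$sorensen)

  seps <- c(0, 1, 2, 4)
  ovs <- vapply(seps, function(s)
    sorensen_overlap(ha, fit_hypervolume(x + s, seed = 9))$sorensen,
    numeric(1))
  expect_true(all(diff(ovs) < 0.02))  # monotone decreasing over MC error

  h1 <- fit_hypervolume(matrix(rnorm(100), ncol = 1), seed = 2)
  expect_error(sorensen_overlap(ha, h1), "mismatch")
})

test_that("1-D overlap agrees with the grid-integration oracle", {
  set.seed(31)
  a <- rnorm(800)
  b <- rnorm(800, mean = 1)
  ha <- fit_hypervolume(matrix(a, ncol = 1), seed = 1)
  hb <- fit_hypervolume(matrix(b, ncol = 1), seed = 2)
  got <- sorensen_overlap(ha, hb)$sorensen
  want <- grid_overlap_1d(a, b, q = 0.95)$sorensen
  expect_equal(got, want, tolerance = 0.05)
})

test_that("log-transform shifts non-positive dimensions and records provenance", {
  m <- cbind(sst = c(10, 20), air = c(-5, 5))
  tr <- climate_log_transform(m)
  expect_equal(unname(tr$shift), c(0, 6))  # min -5 maps to +1
  expect_equal(tr$data[, "air"], log10(c(1, 11)))
  # provenance shift reapplies identically to new data
  tr2 <- climate_log_transform(m, shift = tr$shift)
  expect_identical(tr$data, tr2$data)
  expect_error(climate_log_transform(cbind(x = c(-1, 1)), shift = c(x = 0)),
               "log10")
})

test_that("overlap_matrix groups ecotones and reports sparse groups missing", {
  # all three ecotones share one climate field (same pixels host all
  # three) -> overlaps near 1.  Independent finite samples of the same
  # distribution would sit lower in 5-D (KDE level sets converge slowly).
  set.seed(40)
  n <- 120
  block <- data.frame(
    par = rnorm(n, 40, 3), tidal_amplitude = rnorm(n, 1.5, 0.2),
    sst = rnorm(n, 25, 1), air_temperature = rnorm(n, 24, 1),
    precipitation = rnorm(n, 1800, 100))
  shared <- cbind(ecotone = rep(ecotone_levels(), each = n),
                  continent = "Asia",
                  rbind(block, block, block))
  ov <- overlap_matrix(shared, "worldwide", n_samples = 4000, seed = 3)
  m <- ov$matrices$worldwide
  pairs <- m[upper.tri(m)]
  expect_true(all(pairs >= 0.9))

  # well-separated niches -> overlaps ~ 0
  apart <- shared
  apart$sst <- apart$sst + 60 * (as.integer(factor(apart$ecotone)) - 1)
  ov2 <- overlap_matrix(apart, "worldwide", n_samples = 4000, seed = 3)
  expect_true(all(ov2$matrices$worldwide[upper.tri(m)] <= 0.05))

  # an ecotone absent (or under min_points) on a continent stays NA
  sparse <- shared
  sparse$continent <- rep(c("Asia", "Europe"), length.out = nrow(sparse))
  sparse <- sparse[!(sparse$continent == "Europe" &
                       sparse$ecotone == "mangrove"), ]
  ov3 <- overlap_matrix(sparse, "continent", n_samples = 3000, seed = 3)
  eu <- ov3$matrices$Europe
  expect_true(is.na(eu["mangrove", "seagrass"]))
  expect_false(is.na(eu["salt_marsh", "seagrass"]))
})

test_that("overlap_table flattens to the pair-by-region layout", {
  set.seed(41)
  n <- 60
  d <- data.frame(
    ecotone = rep(c("mangrove", "seagrass"), each = n), continent = "Asia",
    par = rnorm(2 * n, 40, 3), tidal_amplitude = rnorm(2 * n, 1.5, 0.2),
    sst = rnorm(2 * n, 25, 1), air_temperature = rnorm(2 * n, 24, 1),
    precipitation = rnorm(2 * n, 1800, 100))
  ww <- overlap_matrix(d, "worldwide", n_samples = 3000, seed = 1)
  ct <- overlap_matrix(d, "continent", n_samples = 3000, seed = 1)
  tab <- overlap_table(ww, ct)
  expect_equal(tab$pair, "mangrove-seagrass")
  expect_true(is.numeric(tab$worldwide) && is.numeric(tab$Asia))
  # per-pair shared volume carries an MC standard error
  expect_equal(ww$pair_details$pair, "mangrove-seagrass")
  expect_gt(ww$pair_details$shared_se, 0)
  expect_equal(ww$pair_details$sorensen, tab$worldwide)
})
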