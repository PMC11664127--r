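# Independent oracles used to check the package's Monte-Carlo and
# dynamic-programming routes.

# 1-D Gaussian-mixture hypervolume by dense-grid numeric integration:
# threshold found by bisection so the retained probability mass equals q,
# volume = Lebesgue measure of the super-level set.
grid_hypervolume_1d <- function(data, q, n_grid = 8001) {
  bw <- stats::sd(data) * (4 / 3)^(1 / 5) * length(data)^(-1 / 5)
  grid <- seq(min(data) - 6 * bw, max(data) + 6 * bw, length.out = n_grid)
  dx <- grid[2] - grid[1]
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, data, bw)),
                 numeric(1))
  mass_above <- function(c) sum(dens[dens >= c]) * dx
  lo <- 0; hi <- max(dens)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (mass_above(mid) > q) lo <- mid else hi <- mid
  }
  c_hat <- (lo + hi) / 2
  list(volume = sum(dens >= c_hat) * dx, threshold = c_hat,
       grid = grid, dens = dens, dx = dx, bw = bw)
}

# Sorensen overlap of two 1-D mixtures by grid integration of their
# super-level sets.
grid_overlap_1d <- function(data_a, data_b, q, n_grid = 16001) {
  rng <- range(c(data_a, data_b))
  pad <- 6 * max(stats::sd(data_a), stats::sd(data_b))
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = n_grid)
  dx <- grid[2] - grid[1]
  level_set <- function(data) {
    bw <- stats::sd(data) * (4 / 3)^(1 / 5) * length(data)^(-1 / 5)
    dens <- vapply(grid, function(g) mean(stats::dnorm(g, data, bw)),
                   numeric(1))
    lo <- 0; hi <- max(dens)
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (sum(dens[dens >= mid]) * dx > q) lo <- mid else hi <- mid
    }
    dens >= (lo + hi) / 2
  }
  in_a <- level_set(data_a)
  in_b <- level_set(data_b)
  va <- sum(in_a) * dx; vb <- sum(in_b) * dx
  shared <- sum(in_a & in_b) * dx
  list(sorensen = 2 * shared / (va + vb), volume_a = va, volume_b = vb)
}

# Exhaustive-search Jenks oracle for k = 3: minimal within-class SSD over
# all contiguous 2-break partitions of the sorted values.
exhaustive_jenks3_ssd <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) {
    s <- ssd(xs[1:i]) + ssd(xs[(i + 1):j]) + ssd(xs[(j + 1):n])
    if (s < best) best <- s
  }
  best
}

# Small default synthetic world shared by several tests.
small_world <- function(n = 150, seed = 42, ...) {
  generate_world(world_config(n_pixels_per_ecotone = n, seed = seed, ...))
}

# Fast pipeline configuration for smoke/e2e tests.
fast_config <- function(n = 150, seed = 7, ...) {
  run_config(world = world_config(n_pixels_per_ecotone = n, seed = seed),
             sobol_n_base = 256, sobol_n_boot = 25, n_hv_samples = 4000,
             seed = seed, ...)
}
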