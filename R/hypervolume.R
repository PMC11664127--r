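# Kernel-density climatic hypervolumes and their Sorensen overlaps.
#
# The niche of each ecotone is represented as the region of d-dimensional
# climate space where an equal-weight Gaussian mixture (one kernel per
# observation, diagonal Silverman bandwidths) exceeds a density threshold
# chosen to retain a fixed probability mass q.  The measure (volume) of that
# super-level set is estimated by importance sampling from the mixture
# itself:  Vol({f >= c}) = E_f[ 1{f(X) >= c} / f(X) ].  Overlap between two
# hypervolumes is the Sorensen index 2 * shared / (V_A + V_B), with the
# shared volume estimated symmetrically from both sample clouds.

#' Silverman rule-of-thumb bandwidths, per dimension
#'
#' `bw_j = sd_j * (4 / (d + 2))^(1/(d+4)) * n^(-1/(d+4))` for an n x d data
#' matrix (the multivariate normal-reference rule with a diagonal kernel).
#'
#' @param data numeric matrix (n rows, d columns).
#' @return numeric vector of d strictly positive bandwidths.
#' @export
silverman_bandwidths <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data)
  d <- ncol(data)
  if (n < 2) stop("need at least 2 points for bandwidth estimation",
                  call. = FALSE)
  sds <- apply(data, 2, stats::sd)
  zero <- which(sds <= 0 | !is.finite(sds))
  if (length(zero)) {
    labs <- colnames(data)[zero]
    if (is.null(labs)) labs <- as.character(zero)
    stop("zero-variance dimension(s): ", paste(labs, collapse = ", "),
         call. = FALSE)
  }
  sds * (4 / (d + 2))^(1 / (d + 4)) * n^(-1 / (d + 4))
}

#' log10-transform a climate matrix with recorded positivity shifts
#'
#' All hypervolume dimensions are log10-transformed.  Dimensions that can be
#' non-positive on their natural scale (air temperature in Celsius, tidal
#' anomalies) are first shifted so their minimum maps to +1; the shifts are
#' returned so downstream hypervolumes share one reproducible transform.
#'
#' @param data numeric matrix (columns = climate dimensions).
#' @param shift optional named numeric of per-dimension shifts; when NULL,
#'   `shift_j = 1 - min_j` if `min_j <= 0` else 0, computed from `data`.
#' @return list with `data` (log10 scale), `shift` (per dimension).
#' @export
climate_log_transform <- function(data, shift = NULL) {
  data <- as.matrix(data)
  if (is.null(shift)) {
    mins <- apply(data, 2, min, na.rm = TRUE)
    shift <- ifelse(mins <= 0, 1 - mins, 0)
    names(shift) <- colnames(data)
  }
  shifted <- sweep(data, 2, shift, "+")
  if (any(shifted <= 0, na.rm = TRUE))
    stop("non-positive values after shift; log10 undefined", call. = FALSE)
  list(data = log10(shifted), shift = shift)
}

# Gaussian-mixture density of `points` (m x d) under kernels centered at
# `centers` (n x d) with diagonal bandwidths `bw`.  Chunked so the m x n
# distance matrix never exceeds ~32 MB.
mixture_density <- function(points, centers, bw, chunk = 2000L) {
  points <- as.matrix(points)
  centers <- as.matrix(centers)
  n <- nrow(centers)
  d <- ncol(centers)
  log_norm <- -sum(log(bw)) - d / 2 * log(2 * pi) - log(n)
  A <- sweep(centers, 2, bw, "/")
  a2 <- rowSums(A^2)
  out <- numeric(nrow(points))
  for (start in seq(1L, nrow(points), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(points))
    B <- sweep(points[idx, , drop = FALSE], 2, bw, "/")
    d2 <- outer(rowSums(B^2), a2, "+") - 2 * tcrossprod(B, A)
    d2[d2 < 0] <- 0
    out[idx] <- rowSums(exp(-d2 / 2)) * exp(log_norm)
  }
  out
}

#' Fit a kernel-density hypervolume
#'
#' Draws a sample cloud from the equal-weight Gaussian mixture over the data
#' points, sets the density threshold at the (1 - q) quantile of the cloud's
#' own densities (so the retained probability mass is q), and estimates the
#' super-level-set volume by importance sampling.
#'
#' @param data numeric matrix (already on the transformed scale; use
#'   [climate_log_transform()] upstream), n >= 2 rows.
#' @param mass_quantile retained probability mass q in (0, 1\], default 0.95.
#' @param n_samples total Monte Carlo samples; default
#'   `max(10000, ceiling(10000 / n) * n)` (fixed budget).
#' @param seed integer seed; identical seeds give identical fits.
#' @return object of class `bce_hypervolume` with fields dim_labels,
#'   data_points, bandwidths, sample_cloud, sample_density,
#'   density_threshold, volume, volume_se, mass_quantile, seed.
#' @export
fit_hypervolume <- function(data, mass_quantile = 0.95, n_samples = NULL,
                            seed = 1L) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("need at least 2 points", call. = FALSE)
  if (any(!is.finite(data))) stop("data must be finite", call. = FALSE)
  if (!is.numeric(mass_quantile) || length(mass_quantile) != 1L ||
      mass_quantile <= 0 || mass_quantile > 1)
    stop("`mass_quantile` must be in (0, 1]", call. = FALSE)
  n <- nrow(data)
  d <- ncol(data)
  if (is.null(n_samples)) n_samples <- max(10000L, ceiling(10000 / n) * n)
  bw <- silverman_bandwidths(data)
  cloud <- with_seed(seed, {
    pick <- sample.int(n, n_samples, replace = TRUE)
    data[pick, , drop = FALSE] +
      matrix(stats::rnorm(n_samples * d), ncol = d) %*% diag(bw, d)
  })
  dens <- mixture_density(cloud, data, bw)
  # samples are drawn from f itself, so the (1-q) density quantile retains
  # mass q above the threshold
  threshold <- stats::quantile(dens, 1 - mass_quantile, names = FALSE,
                               type = 7)
  w <- ifelse(dens >= threshold, 1 / dens, 0)
  structure(
    list(dim_labels = colnames(data), data_points = data, bandwidths = bw,
         sample_cloud = cloud, sample_density = dens,
         density_threshold = threshold,
         volume = mean(w),
         volume_se = stats::sd(w) / sqrt(n_samples),
         mass_quantile = mass_quantile, n_samples = n_samples,
         seed = as.integer(seed)),
    class = "bce_hypervolume")
}

#' @export
print.bce_hypervolume <- function(x, ...) {
  cat(sprintf("Kernel-density hypervolume: %d points, %d dims, q = %.2f\n",
              nrow(x$data_points), ncol(x$data_points), x$mass_quantile))
  cat(sprintf("  volume = %.4g (MC se %.2g), threshold = %.3g\n",
              x$volume, x$volume_se, x$density_threshold))
  invisible(x)
}

# Directional shared-volume estimate: measure of {f_a >= c_a} intersect
# {f_b >= c_b} using a's importance sample.
shared_volume_directional <- function(hv_from, hv_to) {
  dens_other <- mixture_density(hv_from$sample_cloud, hv_to$data_points,
                                hv_to$bandwidths)
  inside <- hv_from$sample_density >= hv_from$density_threshold &
    dens_other >= hv_to$density_threshold
  w <- ifelse(inside, 1 / hv_from$sample_density, 0)
  c(vol = mean(w), se = stats::sd(w) / sqrt(length(w)))
}

#' Sorensen overlap of two hypervolumes
#'
#' `2 * V_shared / (V_A + V_B)`, with the shared volume estimated as the
#' mean of the two directional importance-sampling estimates (symmetric by
#' construction), clipped to \[0, 1\].
#'
#' @param hv_a,hv_b `bce_hypervolume` objects with identical dim_labels.
#' @return list with `sorensen` (proportion), `shared_volume`, `shared_se`,
#'   and the two input volumes.
#' @export
sorensen_overlap <- function(hv_a, hv_b) {
  if (!inherits(hv_a, "bce_hypervolume") || !inherits(hv_b, "bce_hypervolume"))
    stop("inputs must be bce_hypervolume objects", call. = FALSE)
  if (ncol(hv_a$data_points) != ncol(hv_b$data_points) ||
      !identical(hv_a$dim_labels, hv_b$dim_labels))
    stop("hypervolume dimension mismatch", call. = FALSE)
  ab <- shared_volume_directional(hv_a, hv_b)
  ba <- shared_volume_directional(hv_b, hv_a)
  shared <- (ab[["vol"]] + ba[["vol"]]) / 2
  sor <- 2 * shared / (hv_a$volume + hv_b$volume)
  list(sorensen = min(max(sor, 0), 1),
       shared_volume = shared,
       shared_se = sqrt(ab[["se"]]^2 + ba[["se"]]^2) / 2,
       volume_a = hv_a$volume, volume_b = hv_b$volume)
}

#' Pairwise ecotone overlap matrices, worldwide or per continent
#'
#' Fits one hypervolume per ecotone per region on the five log10-transformed
#' climate covariates (shared shift provenance computed over the whole
#' table) and assembles the pairwise Sorensen overlaps.  Region/ecotone
#' combinations with fewer than `min_points` complete climate rows are
#' reported as missing (NA), not zero.
#'
#' @param records pixel table with climate columns and `ecotone` (and
#'   `continent` when `grouping = "continent"`).
#' @param grouping "worldwide" or "continent".
#' @param mass_quantile,n_samples,seed passed to [fit_hypervolume()].
#' @param min_points minimum complete rows per ecotone per region.
#' @return object of class `bce_overlap_set`: list with `grouping`,
#'   `matrices` (named list of symmetric overlap matrices, diagonal 1),
#'   `volumes`, `shift`, `mass_quantile`, `seed`.
#' @export
overlap_matrix <- function(records, grouping = c("worldwide", "continent"),
                           mass_quantile = 0.95, n_samples = NULL,
                           seed = 1L, min_points = 20L) {
  grouping <- match.arg(grouping)
  cc <- climate_columns()
  ok <- stats::complete.cases(records[, cc])
  recs <- records[ok, , drop = FALSE]
  tr <- climate_log_transform(as.matrix(recs[, cc]))
  groups <- if (grouping == "worldwide") list(worldwide = seq_len(nrow(recs)))
            else split(seq_len(nrow(recs)), recs$continent)
  matrices <- list()
  volumes <- list()
  pair_details <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    ecos <- sort(unique(recs$ecotone[idx]))
    hvs <- list()
    for (eco in ecos) {
      rows <- idx[recs$ecotone[idx] == eco]
      if (length(rows) < min_points) next
      hvs[[eco]] <- fit_hypervolume(tr$data[rows, , drop = FALSE],
                                    mass_quantile = mass_quantile,
                                    n_samples = n_samples,
                                    seed = derive_seed(seed, paste(g, eco)))
    }
    all_ecos <- intersect(ecotone_levels(), unique(records$ecotone))
    m <- matrix(NA_real_, length(all_ecos), length(all_ecos),
                dimnames = list(all_ecos, all_ecos))
    for (e in names(hvs)) m[e, e] <- 1
    if (length(hvs) >= 2) {
      prs <- utils::combn(names(hvs), 2)
      for (k in seq_len(ncol(prs))) {
        a <- prs[1, k]; b <- prs[2, k]
        ov <- sorensen_overlap(hvs[[a]], hvs[[b]])
        m[a, b] <- m[b, a] <- ov$sorensen
        pair_details[[length(pair_details) + 1L]] <- data.frame(
          region = g, pair = paste(a, b, sep = "-"),
          sorensen = ov$sorensen, shared_volume = ov$shared_volume,
          shared_se = ov$shared_se)
      }
    }
    matrices[[g]] <- m
    volumes[[g]] <- vapply(hvs, function(h) h$volume, numeric(1))
  }
  structure(list(grouping = grouping, matrices = matrices, volumes = volumes,
                 pair_details = do.call(rbind, pair_details),
                 shift = tr$shift, mass_quantile = mass_quantile,
                 seed = as.integer(seed), min_points = min_points),
            class = "bce_overlap_set")
}

#' @export
print.bce_overlap_set <- function(x, ...) {
  cat(sprintf("Sorensen overlap matrices (%s, q = %.2f)\n", x$grouping,
              x$mass_quantile))
  for (g in names(x$matrices)) {
    cat(" ", g, ":\n", sep = "")
    print(round(x$matrices[[g]], 3))
  }
  invisible(x)
}

#' Flatten an overlap set to the published table layout
#'
#' Rows are ecotone pairs, columns are regions (Worldwide first, then
#' continents), mirroring the paper-style pairwise-overlap table.
#'
#' @param worldwide,continental `bce_overlap_set` objects.
#' @return data.frame with a `pair` column and one numeric column per region.
#' @export
overlap_table <- function(worldwide, continental = NULL) {
  m0 <- worldwide$matrices[[1]]
  ecos <- rownames(m0)
  if (length(ecos) < 2)
    return(data.frame(pair = character(0)))
  prs <- utils::combn(ecos, 2)
  out <- data.frame(pair = apply(prs, 2, paste, collapse = "-"))
  out$worldwide <- m0[t(prs)]
  if (!is.null(continental)) {
    for (g in names(continental$matrices))
      out[[g]] <- continental$matrices[[g]][t(prs)]
  }
  out
}
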