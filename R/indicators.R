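# Indicator normalization and the Benefit (B) / Pressure (P) aggregation of
# the BPT model.
#
# B is the mean of up to six normalized fitness indicators (area, fragment
# area, age, height, aboveground biomass, soil organic carbon) for mangroves;
# salt marsh and seagrass fitness reduces to normalized area alone.  P is the
# mean of four compound pressure scores (climate, land, marine, species);
# species pressure is excluded for salt marsh.

#' Min-max normalize a vector to \[0, 1\]
#'
#' Optionally winsorizes at the given quantiles before scaling (values beyond
#' the clip quantiles map to 0/1).  Missing entries stay missing; the map is
#' monotone.  A degenerate vector (min == max) maps every present value to
#' 0.5 with a warning.
#'
#' @param values numeric vector, may contain NA.
#' @param clip_quantiles optional length-2 vector of lower/upper quantiles
#'   for winsorization (e.g. `c(0.01, 0.99)`); NULL disables clipping.
#' @return numeric vector in \[0,1\] with NAs preserved.
#' @export
normalize_minmax <- function(values, clip_quantiles = NULL) {
  if (all(is.na(values)))
    stop("cannot normalize an all-missing vector", call. = FALSE)
  x <- values
  if (!is.null(clip_quantiles)) {
    if (length(clip_quantiles) != 2L || clip_quantiles[1] >= clip_quantiles[2])
      stop("`clip_quantiles` must be an increasing pair", call. = FALSE)
    q <- stats::quantile(x, clip_quantiles, na.rm = TRUE, names = FALSE)
    x <- pmin(pmax(x, q[1]), q[2])
  }
  lo <- min(x, na.rm = TRUE)
  hi <- max(x, na.rm = TRUE)
  if (hi == lo) {
    warning("degenerate normalization (min == max): mapping to 0.5",
            call. = FALSE)
    x[!is.na(x)] <- 0.5
    return(x)
  }
  (x - lo) / (hi - lo)
}

assert_normalized <- function(x, name) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad))
    stop(sprintf("`%s` must be normalized to [0, 1]; found value %g", name,
                 x[bad][1]), call. = FALSE)
  invisible(x)
}

#' Benefit score from normalized fitness indicators
#'
#' For mangroves, B is the arithmetic mean of the available normalized
#' indicators, requiring at least `min_present` of the six; below that the
#' record is no-data (NA).  For salt marsh and seagrass, fitness reduces to
#' normalized area alone (other indicators, if present, are ignored).
#'
#' @param fitness data.frame (or single-row list) with normalized columns
#'   area, fragment_area, age, height, agb, soc (any may be NA).
#' @param ecotone one of `ecotone_levels()`.
#' @param min_present minimum indicators required for the mangrove mean.
#' @return numeric vector of B in \[0,1\] (NA where no-data).
#' @export
compute_benefit <- function(fitness, ecotone, min_present = 3L) {
  ecotone <- match_ecotone(ecotone)
  fitness <- as.data.frame(fitness)
  cols <- fitness_columns()
  missing_cols <- setdiff(if (ecotone == "mangrove") cols else "area",
                          names(fitness))
  if (length(missing_cols))
    stop("missing fitness columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (ecotone != "mangrove") {
    assert_normalized(fitness$area, "area")
    return(as.numeric(fitness$area))
  }
  m <- as.matrix(fitness[, cols])
  assert_normalized(as.vector(m), "fitness indicators")
  n_used <- rowSums(!is.na(m))
  b <- rowMeans(m, na.rm = TRUE)
  b[n_used < min_present] <- NA_real_
  b[n_used == 0] <- NA_real_
  as.numeric(b)
}

#' Compound pressure sums from raw sub-layers
#'
#' Builds the four compound pressures: climate (ocean acidification + SST +
#' sea-level rise), land (organic chemical + direct human + nutrient
#' pollution), marine (artisanal and commercial fishing classes + demersal
#' destructive + light + shipping) and species (proportion of threatened
#' species).  Because the raw layers carry heterogeneous units, each
#' sub-layer is min-max normalized across the table before summing by
#' default; the compound sums are returned unnormalized (normalize them with
#' [normalize_minmax()] before [compute_pressure()]).
#'
#' @param records pixel table with the raw sub-layer columns.
#' @param normalize_sublayers normalize each sub-layer before summing
#'   (default TRUE; FALSE sums raw values, for sensitivity to the ordering).
#' @return data.frame with columns p_climate, p_land, p_marine, p_species
#'   (raw compound sums; NA where every sub-layer of a compound is missing).
#' @export
pressure_compounds <- function(records, normalize_sublayers = TRUE) {
  layers <- pressure_sublayers()
  out <- data.frame(row.names = seq_len(nrow(records)))
  for (comp in names(layers)) {
    cols <- intersect(layers[[comp]], names(records))
    if (length(cols) == 0L) {
      out[[comp]] <- NA_real_
      next
    }
    m <- as.matrix(records[, cols, drop = FALSE])
    if (normalize_sublayers)
      m <- apply(m, 2, function(col)
        if (all(is.na(col))) col else normalize_minmax(col))
    m <- matrix(m, nrow = nrow(records))
    s <- rowSums(m, na.rm = TRUE)
    s[rowSums(!is.na(m)) == 0] <- NA_real_
    out[[comp]] <- s
  }
  out
}

#' Total pressure from normalized compound scores
#'
#' P is the mean of the available normalized compounds; species pressure is
#' excluded for salt marsh (too sparse in the source data).  Records with
#' fewer than `min_compounds` available compounds are no-data.
#'
#' @param compounds data.frame with normalized columns p_climate, p_land,
#'   p_marine, p_species (each in \[0,1\] or NA).
#' @param ecotone one of `ecotone_levels()`.
#' @param min_compounds minimum available compounds required (default 2).
#' @return list with `p_total` (numeric vector in \[0,1\], NA = no-data) and
#'   `components` (the per-compound data.frame actually used).
#' @export
compute_pressure <- function(compounds, ecotone, min_compounds = 2L) {
  ecotone <- match_ecotone(ecotone)
  compounds <- as.data.frame(compounds)
  use <- c("p_climate", "p_land", "p_marine",
           if (ecotone != "salt_marsh") "p_species")
  missing_cols <- setdiff(use, names(compounds))
  if (length(missing_cols))
    stop("missing compound columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(compounds[, use, drop = FALSE])
  assert_normalized(as.vector(m), "pressure compounds")
  n_avail <- rowSums(!is.na(m))
  p <- rowMeans(m, na.rm = TRUE)
  p[n_avail < min_compounds] <- NA_real_
  list(p_total = as.numeric(p),
       components = as.data.frame(m))
}

#' Score a pixel table: normalized indicators, Benefit and Pressure
#'
#' Dataset-level wrapper: normalizes the six fitness indicators per ecotone
#' (min-max over that ecotone's non-missing pixels), builds and normalizes
#' the compound pressures per ecotone, and attaches `b`, the four normalized
#' compounds and `p_total`.  Normalization statistics are returned for exact
#' reproducibility.
#'
#' @param records pixel table (one row per pixel x ecotone).
#' @param min_present minimum fitness indicators for the mangrove Benefit.
#' @param min_compounds minimum available pressure compounds.
#' @param clip_quantiles optional winsorization quantiles for indicator
#'   normalization (default NULL = off).
#' @param normalize_sublayers see [pressure_compounds()].
#' @return list with `records` (input plus n_area..n_soc, b, p_climate,
#'   p_land, p_marine, p_species, p_total) and `norm_stats` (per ecotone x
#'   variable min/max used).
#' @export
score_indicators <- function(records, min_present = 3L, min_compounds = 2L,
                             clip_quantiles = NULL,
                             normalize_sublayers = TRUE) {
  out <- records
  for (col in c(paste0("n_", fitness_columns()), "b",
                names(pressure_sublayers()), "p_total"))
    out[[col]] <- NA_real_
  stats_rows <- list()
  for (eco in unique(records$ecotone)) {
    idx <- which(records$ecotone == eco)
    sub <- records[idx, , drop = FALSE]
    # fitness normalization (per ecotone)
    for (col in fitness_columns()) {
      v <- sub[[col]]
      if (all(is.na(v))) next
      out[idx, paste0("n_", col)] <-
        suppressWarnings(normalize_minmax(v, clip_quantiles))
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        ecotone = eco, variable = col,
        min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE))
    }
    nf <- out[idx, paste0("n_", fitness_columns())]
    names(nf) <- fitness_columns()
    out[idx, "b"] <- compute_benefit(nf, eco, min_present = min_present)
    # pressure compounds: sub-layer normalization within ecotone, compound
    # sums re-normalized to [0,1] before entering the pressure mean
    comp <- pressure_compounds(sub, normalize_sublayers = normalize_sublayers)
    for (cn in names(comp)) {
      if (all(is.na(comp[[cn]]))) next
      rng <- range(comp[[cn]], na.rm = TRUE)
      comp[[cn]] <- suppressWarnings(normalize_minmax(comp[[cn]]))
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        ecotone = eco, variable = cn, min = rng[1], max = rng[2])
    }
    pr <- compute_pressure(comp, eco, min_compounds = min_compounds)
    out[idx, names(comp)] <- comp
    if (eco == "salt_marsh") out[idx, "p_species"] <- NA_real_
    out[idx, "p_total"] <- pr$p_total
  }
  list(records = out,
       norm_stats = do.call(rbind, stats_rows))
}
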