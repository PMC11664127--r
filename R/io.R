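# Pixel-table readers/writers and run configuration.

mandatory_columns <- function() c("pixel_id", "latitude", "longitude", "ecotone")

numeric_columns <- function() {
  c("latitude", "longitude", fitness_columns(), unlist(pressure_sublayers()),
    climate_columns())
}

#' Read a pixel table from CSV
#'
#' UTF-8 comma-separated with "." decimal; missing tokens are "", "NA",
#' "NaN".  Mandatory columns: pixel_id, latitude, longitude, ecotone.
#' Unknown columns are preserved as passthrough.  Non-numeric cells in
#' numeric columns are an error naming the row and column.
#'
#' @param path CSV file path.
#' @return data.frame of typed pixel records.
#' @export
read_pixel_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  absent <- setdiff(mandatory_columns(), names(raw))
  if (length(absent))
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  na_tokens <- c("", "NA", "NaN")
  for (col in intersect(numeric_columns(), names(raw))) {
    v <- raw[[col]]
    v[v %in% na_tokens] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   v[bad[1]], col, bad[1]), call. = FALSE)
    raw[[col]] <- num
  }
  if ("no_data" %in% names(raw)) raw$no_data <- raw$no_data %in%
      c("TRUE", "true", "1")
  else raw$no_data <- FALSE
  bad_lat <- which(!is.na(raw$latitude) & abs(raw$latitude) > 90)
  if (length(bad_lat))
    stop("latitude outside [-90, 90] at row ", bad_lat[1], call. = FALSE)
  raw
}

#' Write a pixel table to CSV
#'
#' @param records data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pixel_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write 1x1-degree pixel polygons as GeoJSON
#'
#' Each record becomes the square cell whose center is its
#' (latitude, longitude), with the non-coordinate columns as properties.
#'
#' @param records data.frame with latitude/longitude cell centers.
#' @param path output path.
#' @param properties columns to attach as feature properties.
#' @return the path, invisibly.
#' @export
write_pixel_geojson <- function(records, path,
                                properties = c("pixel_id", "ecotone")) {
  properties <- intersect(properties, names(records))
  feats <- lapply(seq_len(nrow(records)), function(i) {
    lon <- records$longitude[i]; lat <- records$latitude[i]
    ring <- list(c(lon - 0.5, lat - 0.5), c(lon + 0.5, lat - 0.5),
                 c(lon + 0.5, lat + 0.5), c(lon - 0.5, lat + 0.5),
                 c(lon - 0.5, lat - 0.5))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = as.list(records[i, properties, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build a pipeline run configuration
#'
#' Every option has a default; the effective configuration is echoed (with
#' its hash) into the output directory by [run_pipeline()].
#'
#' @param world a [world_config()] (used when `input` is NULL).
#' @param input optional path to an existing pixel CSV (overrides `world`).
#' @param ecotones ecotones to process.
#' @param min_present,min_compounds,clip_quantiles,normalize_sublayers
#'   scoring options (see [score_indicators()]).
#' @param mass_quantile,n_hv_samples,min_points hypervolume options.
#' @param t_rule transformation-risk collapse rule ("max", "mean",
#'   "sum_capped").
#' @param sobol_n_base,sobol_n_boot sensitivity-analysis design sizes.
#' @param seed master seed; stage seeds are derived from it.
#' @return object of class `bce_run_config`.
#' @export
run_config <- function(world = world_config(), input = NULL,
                       ecotones = ecotone_levels(),
                       min_present = 3L, min_compounds = 2L,
                       clip_quantiles = NULL, normalize_sublayers = TRUE,
                       mass_quantile = 0.95, n_hv_samples = NULL,
                       min_points = 20L, t_rule = "max",
                       sobol_n_base = 2048L, sobol_n_boot = 100L,
                       seed = 1L) {
  structure(list(world = world, input = input, ecotones = ecotones,
                 min_present = min_present, min_compounds = min_compounds,
                 clip_quantiles = clip_quantiles,
                 normalize_sublayers = normalize_sublayers,
                 mass_quantile = mass_quantile, n_hv_samples = n_hv_samples,
                 min_points = min_points, t_rule = t_rule,
                 sobol_n_base = as.integer(sobol_n_base),
                 sobol_n_boot = as.integer(sobol_n_boot),
                 seed = as.integer(seed)),
            class = "bce_run_config")
}

config_to_list <- function(config) {
  out <- unclass(config)
  if (inherits(out$world, "bce_world_config")) {
    w <- unclass(out$world)
    w$latitude_bands <- lapply(w$latitude_bands, function(m)
      lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])))
    w$continent_rules <- as.list(w$continent_rules)
    w$climate_gradient <- lapply(w$climate_gradient, as.list)
    w$fitness_gradient <- lapply(w$fitness_gradient, as.list)
    w$pressure_levels <- lapply(w$pressure_levels, as.list)
    w$missing_fraction <- as.list(w$missing_fraction)
    out$world <- w
  }
  out
}

#' Read a run configuration from YAML
#'
#' Scalar options mirror [run_config()] arguments; a `world` block mirrors
#' [world_config()].  Unspecified options keep their defaults.
#'
#' @param path YAML file path.
#' @return `bce_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  wargs <- list()
  if (!is.null(y$world)) {
    w <- y$world
    if (!is.null(w$latitude_bands))
      w$latitude_bands <- lapply(w$latitude_bands, function(b)
        matrix(unlist(b), ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("min", "max"))))
    if (!is.null(w$missing_fraction))
      w$missing_fraction <- unlist(w$missing_fraction)
    for (nm in c("climate_gradient", "fitness_gradient", "pressure_levels"))
      if (!is.null(w[[nm]])) w[[nm]] <- lapply(w[[nm]], unlist)
    wargs <- w
  }
  args <- y[setdiff(names(y), "world")]
  args$world <- do.call(world_config, wargs)
  do.call(run_config, args)
}
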