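# End-to-end BPT pipeline: normalize -> Benefit/Pressure -> hypervolumes ->
# transformation risk -> EHI -> natural-breaks classes -> sensitivity ->
# trends.  Every stage returns new objects (inputs are never mutated) and
# all outputs carry the configuration hash; reruns with the same config are
# byte-identical.

#' Run the full BPT pipeline
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent); NULL skips writing
#'   files and returns the in-memory results only.
#' @param verbose print stage progress.
#' @return (invisibly) list with `records` (scored + classified EHI table),
#'   `overlaps_worldwide`, `overlaps_continent`, `breaks`, `class_summary`,
#'   `sobol` (per ecotone), `trends`, `norm_stats`, `config_hash`, `files`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  cfg_yaml <- yaml::as.yaml(config_to_list(config))
  cfg_hash <- fnv1a_hash(cfg_yaml)

  say("stage: input")
  world <- stage("input", {
    if (!is.null(config$input)) read_pixel_table(config$input)
    else generate_world(config$world)
  })
  world <- world[world$ecotone %in% config$ecotones, , drop = FALSE]

  say("stage: score (normalize + benefit + pressure)")
  scored <- stage("score", score_indicators(
    world, min_present = config$min_present,
    min_compounds = config$min_compounds,
    clip_quantiles = config$clip_quantiles,
    normalize_sublayers = config$normalize_sublayers))
  rec <- scored$records

  say("stage: hypervolumes")
  ov_world <- stage("hypervolume", overlap_matrix(
    rec, "worldwide", mass_quantile = config$mass_quantile,
    n_samples = config$n_hv_samples,
    seed = derive_seed(config$seed, "hv_world"),
    min_points = config$min_points))
  ov_cont <- stage("hypervolume", overlap_matrix(
    rec, "continent", mass_quantile = config$mass_quantile,
    n_samples = config$n_hv_samples,
    seed = derive_seed(config$seed, "hv_continent"),
    min_points = config$min_points))

  say("stage: transformation risk + EHI")
  rec <- stage("ehi", {
    tvals <- rep(NA_real_, nrow(rec))
    tsrc <- rep(NA_character_, nrow(rec))
    combos <- unique(rec[, c("ecotone", "continent")])
    for (i in seq_len(nrow(combos))) {
      tr <- assign_transformation_risk(ov_cont, combos$ecotone[i],
                                       combos$continent[i],
                                       rule = config$t_rule,
                                       worldwide = ov_world)
      sel <- rec$ecotone == combos$ecotone[i] &
        rec$continent == combos$continent[i]
      tvals[sel] <- tr$value
      tsrc[sel] <- tr$source_region
    }
    rec$t <- tvals
    rec$t_source <- tsrc
    rec$ehi <- compute_ehi(rec$b, rec$p_total, rec$t)
    rec
  })

  say("stage: natural breaks + classification")
  cls <- stage("classify", {
    breaks <- list()
    for (eco in unique(rec$ecotone)) {
      vals <- rec$ehi[rec$ecotone == eco]
      if (sum(is.finite(vals)) >= 3 && length(unique(stats::na.omit(vals))) >= 3)
        breaks[[eco]] <- jenks_breaks(vals, k = 3L)
    }
    out <- classify_ehi(rec, breaks)
    out$breaks <- breaks
    out
  })
  rec <- cls$records

  say("stage: sensitivity analysis")
  sobol <- stage("gsa", {
    res <- list()
    for (eco in unique(rec$ecotone)) {
      sub <- rec[rec$ecotone == eco, , drop = FALSE]
      mc <- ehi_model_closure(eco)
      if (!all(vapply(mc$inputs, function(cl) any(!is.na(sub[[cl]])),
                      logical(1)))) next
      res[[eco]] <- sobol_first_order(
        mc$fn, empirical_sampler(sub, mc$inputs),
        n_base = config$sobol_n_base, n_boot = config$sobol_n_boot,
        seed = derive_seed(config$seed, paste0("sobol_", eco)))
    }
    res
  })

  say("stage: trends")
  trends <- stage("trends", {
    out <- list()
    for (eco in unique(rec$ecotone)) {
      fit <- tryCatch(latitudinal_trend(rec, ecotone = eco), error = function(e) NULL)
      if (!is.null(fit)) out[[paste0("latitude_", eco)]] <- fit
    }
    # health-to-stock relation on the raw SOC scale (mangrove analysis)
    mang <- rec[rec$ecotone == "mangrove", , drop = FALSE]
    if (nrow(mang) > 3 && sum(is.finite(mang$ehi) & is.finite(mang$soc)) >= 3)
      out$ehi_soc_mangrove <- covariate_trend(mang, "ehi", "soc")
    out
  })

  result <- list(records = rec, overlaps_worldwide = ov_world,
                 overlaps_continent = ov_cont, breaks = cls$breaks,
                 class_summary = cls$summary, sobol = sobol, trends = trends,
                 norm_stats = scored$norm_stats, config_hash = cfg_hash)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    wr <- function(df, name) {
      path <- file.path(out_dir, name)
      if (nrow(df)) df <- cbind(df, config_hash = cfg_hash)
      else df$config_hash <- character(0)
      utils::write.csv(df, path, row.names = FALSE, na = "NA")
      files <<- c(files, path)
    }
    keep <- c("pixel_id", "latitude", "longitude", "continent", "ecotone",
              paste0("n_", fitness_columns()), "b",
              names(pressure_sublayers()), "p_total", "t", "t_source",
              "ehi", "ehi_class", "no_data")
    wr(rec[, intersect(keep, names(rec))], "ehi_table.csv")
    wr(overlap_table(ov_world), "overlap_worldwide.csv")
    wr(overlap_table(ov_world, ov_cont), "overlap_continent.csv")
    wr(cls$summary, "class_summary.csv")
    sob_df <- do.call(rbind, lapply(names(sobol), function(eco)
      cbind(ecotone = eco, sobol[[eco]]$indices)))
    if (is.null(sob_df)) sob_df <- data.frame(ecotone = character(0))
    wr(sob_df, "sobol.csv")
    tr_df <- do.call(rbind, lapply(names(trends), function(nm) {
      f <- trends[[nm]]
      data.frame(analysis = nm, predictor = f$predictor,
                 response = f$response, slope = f$slope,
                 intercept = f$intercept, r_squared = f$r_squared,
                 p_value = f$p_value, n = f$n)
    }))
    if (is.null(tr_df)) tr_df <- data.frame(analysis = character(0))
    wr(tr_df, "trends.csv")
    prov <- list(config_hash = cfg_hash,
                 seed = config$seed,
                 hypervolume = list(mass_quantile = config$mass_quantile,
                                    shift = as.list(ov_world$shift),
                                    min_points = config$min_points),
                 t_rule = config$t_rule,
                 sobol = list(n_base = config$sobol_n_base,
                              n_boot = config$sobol_n_boot,
                 input_distributions = "independent empirical marginals"),
                 norm_stats = scored$norm_stats,
                 counts = {
                   tab <- table(rec$ecotone, rec$ehi_class)
                   cts <- lapply(rownames(tab), function(r) as.list(tab[r, ]))
                   names(cts) <- rownames(tab)
                   cts
                 })
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    files <- c(files, file.path(out_dir, "provenance.json"))
    writeLines(cfg_yaml, file.path(out_dir, "config.yaml"))
    result$files <- files
  }
  invisible(result)
}
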