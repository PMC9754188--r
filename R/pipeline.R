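# Pipeline orchestration: generate -> clip -> filter -> metrics -> stats,
# with a YAML config, stage logging, and a reproducibility manifest.
#
# Outputs carry no timestamps, and every stochastic stage derives its seed
# from the single config seed, so a rerun with the same config is
# byte-identical.

#' Read and validate a pipeline run configuration
#'
#' YAML with top-level keys: `seed` (mandatory), `output_dir`, optional
#' `landscape` / `visitation` / `anonymization` / `species` blocks overriding
#' the corresponding parameter constructors for synthetic runs, or `inputs`
#' (`tiles_csv`, `layers_dir`) for file-based runs, plus `night_windows`,
#' `trail_buffer`, `n_perm`.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config error: 'seed' is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$output_dir)) stop("config error: 'output_dir' is mandatory")
  cfg$night_windows <- as.integer(cfg$night_windows %||% c(0L, 2L, 4L))
  cfg$trail_buffer <- as.numeric(cfg$trail_buffer %||% 0)
  cfg$n_perm <- as.integer(cfg$n_perm %||% 999L)
  cfg$synthetic <- is.null(cfg$inputs)
  class(cfg) <- "run_config"
  cfg
}

apply_overrides <- function(defaults, overrides) {
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

write_csv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Synthetic mode generates a landscape, ground-truth visitation, anonymized
#' tiles, reservations and tree surveys, then computes per-property activity
#' summaries and land-cover usage, the reservation-validation model, trail
#' regressions, and the composition pCCA. File-based mode starts from an
#' existing tiles CSV and GeoJSON layer directory. All outputs plus a
#' manifest (config hash, package version, per-stage record counts) go to
#' `output_dir`; rerunning with the same config reproduces identical bytes.
#'
#' @param config path to a YAML config or a config list
#'   (see [read_run_config()]).
#' @param quiet suppress stage logging.
#' @param stages how far to run: "all" (default), "generate" (synthetic
#'   inputs only), or "metrics" (inputs + per-property metrics, no models).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE,
                         stages = c("all", "generate", "metrics")) {
  stages <- match.arg(stages)
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_ <- function(...) if (!quiet) message("[parkactivity] ", ...)
  counts <- list()

  # ---- stage 1: inputs ----------------------------------------------------
  if (cfg$synthetic) {
    log_("stage generate: synthetic landscape (seed ", cfg$seed, ")")
    lcfg <- do.call(landscape_config, cfg$landscape %||% list())
    landscape <- generate_landscape(lcfg, seed = cfg$seed)
    vparams <- do.call(visitation_params, cfg$visitation %||% list())
    truth <- simulate_visitation(landscape, vparams,
                                 seed = derive_seed(cfg$seed, "visitation"))
    aargs <- cfg$anonymization %||% list()
    aargs$seed <- aargs$seed %||% derive_seed(cfg$seed, "anonymization")
    anon <- do.call(anonymization_params, aargs)
    tiles <- render_activity_tiles(truth, anon)
    reservations <- generate_reservations(truth,
                                          seed = derive_seed(cfg$seed, "reservations"))
    sargs <- cfg$species %||% list()
    effect <- do.call(species_response, sargs)
    surveys <- generate_tree_surveys(landscape, truth, effect,
                                     seed = derive_seed(cfg$seed, "trees"))
    write_landscape(landscape, file.path(out, "landscape"))
    write_tiles_csv(tiles, file.path(out, "tiles.csv"))
    write_csv_stable(reservations, file.path(out, "reservations.csv"))
    write_csv_stable(surveys, file.path(out, "tree_surveys.csv"))
    counts$truth_records <- nrow(truth$intensity)
    counts$truth_road_cells <- sum(truth$cells$road_flag)
  } else {
    log_("stage load: reading inputs")
    if (is.null(cfg$inputs$tiles_csv) || !file.exists(cfg$inputs$tiles_csv))
      stop("missing input layer: tiles_csv (", cfg$inputs$tiles_csv %||% "unset", ")")
    ldir <- cfg$inputs$layers_dir
    if (is.null(ldir) || !file.exists(file.path(ldir, "properties.geojson")))
      stop("missing input layer: properties.geojson in ", ldir %||% "unset")
    landscape <- read_landscape(ldir, cell_size = cfg$inputs$cell_size %||% 100)
    tiles <- read_tiles_csv(cfg$inputs$tiles_csv)
    resv_path <- cfg$inputs$reservations_csv
    reservations <- if (!is.null(resv_path)) utils::read.csv(resv_path) else NULL
    surv_path <- cfg$inputs$tree_surveys_csv
    surveys <- if (!is.null(surv_path)) utils::read.csv(surv_path) else NULL
  }
  counts$tile_records <- nrow(tiles)
  counts$properties <- length(landscape$green_spaces)
  stats_out <- list()

  finish <- function() {
    cfg_plain <- unclass(cfg)
    cfg_plain$output_dir <- NULL  # hash the science, not the output location
    cfg_json <- jsonlite::toJSON(cfg_plain[order(names(cfg_plain))],
                                 auto_unbox = TRUE, digits = NA)
    tmp <- tempfile()
    writeLines(as.character(cfg_json), tmp)
    manifest <- list(
      package = "parkactivity",
      version = as.character(utils::packageVersion("parkactivity")),
      config_hash = unname(tools::md5sum(tmp)),
      seed = cfg$seed,
      stages = stages,
      counts = counts,
      stats = stats_out)
    unlink(tmp)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_("done: outputs in ", out)
    invisible(manifest)
  }
  if (stages == "generate") return(finish())

  # ---- stage 2: metrics ---------------------------------------------------
  log_("stage metrics: ", counts$properties, " properties, ",
       counts$tile_records, " tile records")
  has_trailed_props <- length(landscape$trails) > 0
  all_cells <- tiles_to_cells(tiles)
  summaries <- list()
  usage <- list()
  for (gs in landscape$green_spaces) {
    p_trails <- Filter(function(t) t$property_id == gs$id, landscape$trails)
    s <- summarize_activity(all_cells, gs, p_trails,
                            night_windows = cfg$night_windows,
                            buffer_m = cfg$trail_buffer)
    summaries[[gs$id]] <- s
    clipped <- clip_cells(all_cells, gs)
    retained <- exclude_cells(clipped,
                              flag_overnight_cells(clipped, cfg$night_windows))
    cover <- Filter(function(u) u$property_id == gs$id, landscape$land_cover)
    if (length(cover) > 0)
      usage[[gs$id]] <- landcover_usage(retained, cover, gs)
  }
  summary_df <- do.call(rbind, summaries)
  rownames(summary_df) <- NULL
  usage_df <- do.call(rbind, usage)
  rownames(usage_df) <- NULL
  write_csv_stable(summary_df, file.path(out, "activity_summary.csv"))
  write_csv_stable(usage_df, file.path(out, "landcover_usage.csv"))
  counts$retained_cells <- sum(summary_df$n_cells_retained[summary_df$day_stratum == "all"])
  counts$excluded_cells <- sum(summary_df$n_cells_excluded[summary_df$day_stratum == "all"])
  log_("stage metrics: retained ", counts$retained_cells,
       " cells, excluded ", counts$excluded_cells, " overnight-flagged cells")

  if (stages == "metrics") return(finish())

  # ---- stage 3: stats -----------------------------------------------------
  if (!is.null(reservations) && nrow(reservations) > 0) {
    log_("stage stats: reservation validation")
    resv <- stats::aggregate(party_size ~ property_id + day_stratum,
                             data = reservations, FUN = sum)
    dens <- summary_df[summary_df$day_stratum %in% c("weekday", "weekend"),
                       c("property_id", "day_stratum", "activity_density")]
    mg <- merge(resv, dens, by = c("property_id", "day_stratum"))
    if (nrow(mg) >= 5) {
      fit <- fit_lm_interaction(mg$activity_density, mg$party_size,
                                factor(mg$day_stratum, c("weekday", "weekend")))
      ct <- data.frame(term = rownames(fit$coefficients), fit$coefficients,
                       row.names = NULL)
      write_csv_stable(ct, file.path(out, "reservation_lm_coefficients.csv"))
      write_csv_stable(fit$anova, file.path(out, "reservation_lm_anova.csv"))
      stats_out$reservation_r_squared <- fit$r_squared
    } else log_("stage stats: too few reservation rows for the validation model")
  }
  if (has_trailed_props) {
    trailed <- summary_df$day_stratum == "all" & summary_df$trail_density > 0
    td <- summary_df[trailed, ]
    if (nrow(td) >= 3) {
      rows <- list()
      add_fit <- function(label, y, x) {
        ok <- is.finite(y) & is.finite(x)
        if (sum(ok) < 3) return(NULL)
        f <- stats::lm(y[ok] ~ x[ok])
        a <- stats::anova(f)
        data.frame(model = label, slope = stats::coef(f)[2],
                   F = a$`F value`[1], p = a$`Pr(>F)`[1],
                   r_squared = summary(f)$r.squared, n = sum(ok),
                   row.names = NULL)
      }
      rows$density <- add_fit("density_vs_trail_density",
                              td$activity_density, td$trail_density)
      rows$coverage <- add_fit("coverage_vs_trail_density",
                               td$activity_coverage_pct, td$trail_density)
      rows$ontrail <- add_fit("on_trail_pct_vs_coverage",
                              td$on_trail_pct, td$activity_coverage_pct)
      trail_df <- do.call(rbind, Filter(Negate(is.null), rows))
      write_csv_stable(trail_df, file.path(out, "trail_models.csv"))
      stats_out$trail_density_slope <- trail_df$slope[trail_df$model ==
                                                        "density_vs_trail_density"]
    }
  } else if (cfg$trail_buffer > 0 || isTRUE(cfg$require_trails)) {
    stop("missing input layer: trails (on-trail metrics requested)")
  }
  if (!is.null(surveys) && nrow(surveys) > 0) {
    log_("stage stats: composition pCCA (", cfg$n_perm, " permutations)")
    parts <- split_survey_table(surveys)
    con <- build_activity_constraints(surveys, summary_df)
    fit <- pcca(parts$Y, con$X, con$Z)
    test <- pcca_permutation(parts$Y, con$X, con$Z, n_perm = cfg$n_perm,
                             seed = derive_seed(cfg$seed, "pcca"))
    yr <- cca_year_check(surveys, n_perm = cfg$n_perm,
                         seed = derive_seed(cfg$seed, "yearcheck"))
    cca_df <- data.frame(
      quantity = c("total_inertia", "conditioned_inertia", "constrained_inertia",
                   "residual_inertia", "pseudo_f", "permutation_p",
                   "frac_constrained_of_total", "frac_constrained_conditional",
                   "r_squared_adj", "year_check_pseudo_f", "year_check_p"),
      value = c(fit$total_inertia, fit$conditioned_inertia,
                fit$constrained_inertia, fit$residual_inertia, fit$pseudo_f,
                test$p_value, fit$frac_constrained_of_total,
                fit$frac_constrained_conditional, fit$r_squared_adj,
                yr$fit$pseudo_f, yr$test$p_value))
    write_csv_stable(cca_df, file.path(out, "cca_summary.csv"))
    write_csv_stable(data.frame(site = rownames(fit$site_scores_lc),
                                fit$site_scores_lc, row.names = NULL),
                     file.path(out, "cca_site_scores.csv"))
    write_csv_stable(data.frame(species = rownames(fit$species_scores),
                                fit$species_scores, row.names = NULL),
                     file.path(out, "cca_species_scores.csv"))
    stats_out$pcca_p <- test$p_value
  }

  finish()
}
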