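# Readers/writers for the tabular and raster interchange formats, and the
# end-to-end pipeline driver.

CLUSTER_COLUMNS <- c("cluster_id", "x_km", "y_km", "year", "season",
                     "n_examined", "n_wasted")

#' Write / read cluster survey records as CSV
#'
#' Canonical tabular interchange: columns \code{cluster_id, x_km, y_km, year,
#' season, n_examined, n_wasted} plus any covariate columns, preceded by a
#' \code{#} metadata comment line. Reading validates the schema: season
#' strings are matched case-insensitively to the four canonical names, and
#' rows with \code{n_wasted > n_examined} (or negative counts) are rejected
#' with their row numbers.
#'
#' @param observations cluster data frame.
#' @param path file path.
#' @param metadata optional named list merged into the metadata line.
#' @return \code{write_clusters_csv}: the path, invisibly;
#'   \code{read_clusters_csv}: a validated data frame.
#' @export
write_clusters_csv <- function(observations, path, metadata = NULL) {
  stopifnot(all(CLUSTER_COLUMNS %in% names(observations)))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(pkg_metadata(), metadata)
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  utils::write.csv(observations, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters_csv
#' @export
read_clusters_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(CLUSTER_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(df$n_wasted > df$n_examined | df$n_wasted < 0 |
                 df$n_examined < 0)
  if (length(bad) > 0) {
    stop("invalid counts (need 0 <= n_wasted <= n_examined) at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  df$season <- tryCatch(canonical_season(df$season), error = function(e) {
    stop("season validation failed: ", conditionMessage(e), call. = FALSE)
  })
  df
}

#' Write zone polygons as GeoJSON
#'
#' @param region a [make_study_region()] object.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_zones_geojson <- function(region, path) {
  stopifnot(inherits(region, "wm_region"))
  features <- lapply(names(region$zones), function(nm) {
    poly <- region$zones[[nm]]
    list(
      type = "Feature",
      properties = list(zone = nm),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(poly)),
                                  function(i) unname(poly[i, ])))
      )
    )
  })
  gj <- list(type = "FeatureCollection",
             metadata = pkg_metadata(),
             features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default end-to-end pipeline configuration
#'
#' Desk-scale synthetic-study settings: a 300 x 300 km three-zone region at
#' 15 km pixels, 250 clusters over two years (eight year-season steps), the
#' five covariate surfaces with the default generator truth, a 60 km mesh
#' edge with a 60 km buffer, model 1, a 10\% de-clustered hold-out, and a
#' 500,000-child under-five population surface.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    region = list(width_km = 300, height_km = 300, resolution_km = 15),
    clusters = list(n = 250, years = c(2007, 2008), n_per_cluster = c(30, 120)),
    covariates = c("rainfall", "evi", "temperature", "dist_water", "urban"),
    selection = list(gamma = 1),
    mesh = list(max_edge_km = 60, buffer_km = 60),
    model = 1,
    optimizer = list(maxit = 120, restarts = 1),
    population = list(total_under5 = 5e5),
    validation = list(fraction = 0.10)
  )
}

log_stage <- function(log_path, stage, ...) {
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage), list(...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE, force = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
}

#' Run the full synthetic analysis pipeline
#'
#' simulate -> select covariates (extended BIC) -> de-clustered hold-out ->
#' Laplace fit on the training data -> gridded prevalence prediction -> WHO
#' risk table -> validation metrics. Deterministic given the config seed;
#' every stage is logged to \code{log.jsonl} and a resumable state marker
#' (\code{state.json}) records completed stages. With \code{model = 2} the
#' seasonal effect sizes are additionally written.
#'
#' @param config configuration list as from [default_config()], or a path to
#'   a YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("wmrun")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- names(default_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.jsonl")
  state_path <- file.path(out_dir, "state.json")
  done <- character(0)
  mark <- function(stage) {
    done <<- c(done, stage)
    jsonlite::write_json(list(completed = done,
                              metadata = pkg_metadata(config$seed, config)),
                         state_path, auto_unbox = TRUE)
  }
  seed <- config$seed %||% 1
  meta <- pkg_metadata(seed, config)

  # -- simulate ---------------------------------------------------------
  region <- make_study_region(config$region$width_km, config$region$height_km,
                              config$region$resolution_km)
  covs <- simulate_covariate_surfaces(region, seed = seed)
  locs <- sample_cluster_locations(region, config$clusters$n, seed = seed + 1)
  years <- config$clusters$years[1]:config$clusters$years[length(config$clusters$years)]
  truth <- true_parameters()
  obs <- simulate_wasting_data(region, locs, covs, truth, years = years,
                               n_per_cluster = config$clusters$n_per_cluster,
                               seed = seed + 2)
  pop <- simulate_population_grid(region, config$population$total_under5,
                                  seed = seed + 3)
  write_clusters_csv(obs, file.path(out_dir, "clusters.csv"),
                     metadata = list(seed = seed))
  write_zones_geojson(region, file.path(out_dir, "zones.geojson"))
  for (nm in names(covs)) {
    write_grid_csv(covs[[nm]], file.path(out_dir, paste0("covariate_", nm, ".csv")))
  }
  write_grid_csv(pop, file.path(out_dir, "population.csv"))
  log_stage(log_path, "simulate", n_clusters = nrow(obs), seed = seed)
  mark("simulate")

  # -- covariate selection ----------------------------------------------
  sel <- select_best_subset(obs, config$covariates,
                            gamma = config$selection$gamma %||% 1)
  jsonlite::write_json(
    list(metadata = meta, gamma = sel$gamma, chosen = sel$chosen,
         table = sel$table),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  log_stage(log_path, "select", chosen = paste(sel$chosen, collapse = "+"))
  mark("select")

  # -- hold-out ----------------------------------------------------------
  split <- spatiotemporal_holdout(obs, config$validation$fraction %||% 0.10,
                                  seed = seed + 4)
  log_stage(log_path, "holdout", n_test = split$meta$n_test)
  mark("holdout")

  # -- fit ---------------------------------------------------------------
  mesh <- build_mesh(region, max_edge_km = config$mesh$max_edge_km,
                     buffer_km = config$mesh$buffer_km)
  mc <- model_config(mesh = mesh, covariates = sel$chosen,
                     model = config$model %||% 1)
  fit <- laplace_fit(split$train, mc,
                     optimizer_config = config$optimizer %||% list(),
                     seed = seed + 5)
  jsonlite::write_json(
    list(metadata = meta, model = mc$model,
         fixed_effects = fit$fixed_effects,
         psi = as.list(fit$psi), log_posterior = fit$log_posterior,
         convergence = fit$convergence),
    file.path(out_dir, "fit_summary.json"), auto_unbox = TRUE, digits = NA)
  log_stage(log_path, "fit", log_posterior = fit$log_posterior)
  mark("fit")

  # -- predict -----------------------------------------------------------
  which_ys <- expand.grid(year = years, season = WM_SEASONS,
                          stringsAsFactors = FALSE)
  prev <- predict_prevalence(fit, region, covs, which_ys, seed = seed + 6)
  for (key in names(prev$surfaces)) {
    write_grid_csv(prev$surfaces[[key]]$mean,
                   file.path(out_dir, paste0("prevalence_", key, ".csv")))
    write_grid_csv(prev$surfaces[[key]]$sd,
                   file.path(out_dir, paste0("prevalence_sd_", key, ".csv")))
  }
  log_stage(log_path, "predict", n_masked = prev$n_masked,
            n_predicted = prev$n_predicted)
  mark("predict")

  # -- risk table --------------------------------------------------------
  risk <- wasted_children_counts(prev, pop, region)
  risk_path <- file.path(out_dir, "risk.csv")
  risk_con <- file(risk_path, "w")
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE)),
             risk_con)
  utils::write.csv(as.data.frame(risk), risk_con, row.names = FALSE)
  close(risk_con)
  writeLines(utils::capture.output(
    print(format_risk_table(risk), row.names = FALSE)),
    file.path(out_dir, "risk_formatted.txt"))
  log_stage(log_path, "classify", total_wasted = sum(risk$wasted))
  mark("classify")

  # -- seasonal effects (model 2 only) ------------------------------------
  seas <- NULL
  if ((config$model %||% 1) == 2) {
    seas <- seasonal_effect_estimates(fit)
    jsonlite::write_json(list(metadata = meta, seasonal_effects = seas),
                         file.path(out_dir, "seasonal_effects.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage(log_path, "seasonal", n = nrow(seas))
    mark("seasonal")
  }

  # -- validation ---------------------------------------------------------
  val <- validate_fit(fit, split$test)
  jsonlite::write_json(
    list(metadata = meta, rmse = val$rmse, me = val$me, mae = val$mae,
         correlation = val$correlation, n_test = val$n,
         split = split$meta),
    file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)
  log_stage(log_path, "validate", rmse = val$rmse)
  mark("validate")

  invisible(list(region = region, observations = obs, selection = sel,
                 split = split, fit = fit, prevalence = prev, risk = risk,
                 seasonal = seas, validation = val, out_dir = out_dir))
}
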