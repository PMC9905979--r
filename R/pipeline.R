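# Orchestration: cohort summary tables, the annotate/fit wrappers, and a
# single reproducible run with a manifest.

#' Cohort summary in the per-species count-table shape
#'
#' Counts of first flights per species and year, split into onshore and
#' offshore routes and detected landings, plus totals, the offshore
#' share, and the number of tagged birds without a recorded flight.
#'
#' @param first_flights First flights with `route` (and `tag_id`).
#' @param landings Landing events (`tag_id`).
#' @param deployments Deployment table (`tag_id`, `species`).
#' @param species_set Allowed species labels.
#' @return List: `table` (one row per species), `totals` (named list with
#'   `flights`, `onshore`, `offshore`, `offshore_pct`, `landings`,
#'   `tagged`, `no_flight`).
#' @export
summarize_cohort <- function(first_flights, landings, deployments,
                             species_set = species_levels()) {
  fl <- data.table::as.data.table(first_flights)
  dep <- data.table::as.data.table(deployments)
  if (!all(dep$species %in% species_set))
    stop("species label outside the configured set: ",
         paste(setdiff(unique(dep$species), species_set), collapse = ", "))
  fl <- dep[, .(tag_id, species)][fl, on = "tag_id"]
  if (!"year" %in% names(fl))
    fl[, year := as.integer(format(begin_ts, "%Y", tz = "UTC"))]
  fl[, landing := tag_id %in% unique(landings$tag_id)]
  years <- sort(unique(fl$year))
  tab <- data.table::rbindlist(lapply(species_set, function(sp) {
    f <- fl[species == sp]
    row <- data.table::data.table(species = sp)
    for (y in years) row[, (as.character(y)) := sum(f$year == y)]
    row[, `:=`(onshore = sum(f$route == "onshore"),
               offshore = sum(f$route == "offshore"),
               landings = sum(f$landing))]
    row
  }), fill = TRUE)
  totals <- list(
    flights = nrow(fl),
    onshore = sum(fl$route == "onshore"),
    offshore = sum(fl$route == "offshore"),
    offshore_pct = round(100 * sum(fl$route == "offshore") / nrow(fl), 1),
    landings = sum(fl$landing),
    tagged = nrow(dep),
    no_flight = nrow(dep) - nrow(fl))
  list(table = tab, totals = totals)
}

#' Annotate processed tracks with weather covariates
#'
#' @param processed Output of [process_tracks()].
#' @param world A `weather_world`.
#' @param deployments Deployment table.
#' @return List `departure_table`, `flight_covariates`.
#' @export
annotate_tracks <- function(processed, world, deployments) {
  list(
    departure_table = build_departure_table(
      processed$stopovers, processed$first_flights, deployments, world),
    flight_covariates = build_flight_covariates(
      processed$first_flights, processed$stopovers, processed$landings,
      deployments, world))
}

#' Fit the three final decision models
#'
#' @param departure_table Output of [build_departure_table()].
#' @param flight_covariates Output of [build_flight_covariates()].
#' @param method,n_draws,seed Passed to the fitters.
#' @return List `departure`, `routing`, `landing` of `migra_fit`s.
#' @export
fit_all_models <- function(departure_table, flight_covariates,
                           method = "laplace", n_draws = 4000, seed = 1L) {
  list(
    departure = fit_departure_model(departure_table, method = method,
                                    n_draws = n_draws, seed = seed),
    routing = fit_logistic_glmm(flight_covariates, routing_spec(),
                                method = method, n_draws = n_draws,
                                seed = seed + 1L),
    landing = fit_logistic_glmm(flight_covariates, landing_spec(),
                                method = method, n_draws = n_draws,
                                seed = seed + 2L))
}

#' Load a run configuration from YAML/JSON
#'
#' Scalar fields override [sim_config()] defaults; `coefs` and `weather`
#' are merged element-wise.
#' @param path YAML or JSON file.
#' @return A `sim_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(sim_config)))]
  if (!is.null(args$n_birds)) args$n_birds <- unlist(args$n_birds)
  if (!is.null(args$bbox)) args$bbox <- unlist(args$bbox)
  if (!is.null(args$coefs)) {
    cf <- default_coefs()
    for (nm in names(args$coefs)) cf[[nm]][names(args$coefs[[nm]])] <-
      unlist(args$coefs[[nm]])
    args$coefs <- cf
  }
  do.call(sim_config, args)
}

#' Run the full pipeline: simulate, process, annotate, fit, report
#'
#' Every stage writes its outputs under `out_dir` before the next starts;
#' a manifest (config hash, seed, per-stage timings, file checksums) is
#' written last.  With `skip_fit = TRUE` the model-fitting stage is
#' omitted.
#'
#' @param config A [sim_config()] (or path to a YAML/JSON run config).
#' @param out_dir Run directory.
#' @param skip_fit Skip the Bayesian fits.
#' @param method,n_draws Fitting options.
#' @param write_weather Also write the long-format weather table.
#' @return The manifest (invisibly), plus all stage outputs in a list.
#' @export
run_all <- function(config, out_dir, skip_fit = FALSE, method = "laplace",
                    n_draws = 4000, write_weather = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  sim <- simulate_world(config)
  write_sim_outputs(sim, out_dir, weather = write_weather)
  timings["simulate"] <- lap(t0)
  message("simulate: ", nrow(sim$detections), " detections, ",
          nrow(sim$histories), " birds")

  t0 <- tic()
  processed <- process_tracks(sim$detections, sim$receivers, sim$deployments)
  write_stage_csv(processed$first_flights, file.path(out_dir, "flights.csv"))
  write_stage_csv(processed$landings, file.path(out_dir, "landings.csv"))
  write_stage_csv(processed$stopovers, file.path(out_dir, "stopovers.csv"))
  timings["process"] <- lap(t0)
  message("process: ", nrow(processed$first_flights), " first flights, ",
          nrow(processed$landings), " landings")

  t0 <- tic()
  ann <- annotate_tracks(processed, sim$world, sim$deployments)
  write_stage_csv(ann$departure_table, file.path(out_dir, "departure_table.csv"))
  write_stage_csv(ann$flight_covariates,
                  file.path(out_dir, "flight_covariates.csv"))
  timings["annotate"] <- lap(t0)

  cohort <- summarize_cohort(processed$first_flights, processed$landings,
                             sim$deployments)
  write_stage_csv(cohort$table, file.path(out_dir, "table1.csv"))

  fits <- NULL
  if (!skip_fit) {
    t0 <- tic()
    fits <- fit_all_models(ann$departure_table, ann$flight_covariates,
                           method = method, n_draws = n_draws,
                           seed = config$seed)
    write_stage_csv(fits$departure$summary, file.path(out_dir, "table2.csv"))
    write_stage_csv(fits$routing$summary, file.path(out_dir, "table3.csv"))
    write_stage_csv(fits$landing$summary, file.path(out_dir, "table4.csv"))
    for (nm in names(fits))
      utils::write.csv(fits[[nm]]$draws,
                       file.path(out_dir, paste0("draws_", nm, ".csv")),
                       row.names = FALSE)
    timings["fit"] <- lap(t0)
  }

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("migradecide")),
    seed = config$seed,
    config_hash = config_hash(config),
    timings_s = as.list(round(timings, 2)),
    outputs = stats::setNames(as.list(unname(tools::md5sum(files))),
                              basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, sim = sim, processed = processed,
                 annotated = ann, cohort = cohort, fits = fits))
}

#' @keywords internal
write_stage_csv <- function(x, path) {
  x <- as.data.frame(x)
  for (cc in names(x))
    if (inherits(x[[cc]], "POSIXct"))
      x[[cc]] <- format(x[[cc]], "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  utils::write.csv(x, path, row.names = FALSE)
}

#' Stable hash of the configuration (functions deparsed)
#' @keywords internal
config_hash <- function(config) {
  x <- config
  x$baseline_rate <- paste(deparse(x$baseline_rate), collapse = "")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x[order(names(x))], force = TRUE,
                              auto_unbox = TRUE, digits = 12), tmp)
  unname(tools::md5sum(tmp))
}
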