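#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()], with sections `synth`
#' (synthetic census and incidence-series parameters and base-year
#' prevalences), `prior`, `mcmc`, `calibration`, `risks`, `strata`,
#' `intervention`, and `output`. The defaults are the US-like study
#' conditions; see the package vignette for the reasoning behind each
#' value.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    synth = list(
      start_year = 2007, end_year = 2050,
      d_first = 0.0090, d_last = 0.0078, migration = 1.0e6,
      incidence_years = 28,
      rho = 0.018, lam0 = -1.54, lam1 = 0.0454,
      phi = 0.6, sigma = 2e-4, se_scale = 0.0042,
      theta1 = 0.0535, theta2 = 0.0765
    ),
    prior = list(q_low = 0.0078, q_high = 0.025, mass = 0.95),
    mcmc = list(chains = 4, warmup = 10000, iter = 10000,
                error_structure = "ar1"),
    calibration = calibration_config(),
    risks = list(low = c(r1 = 1.77, r2 = 2.11),
                 high = c(r1 = 1.00, r2 = 4.08)),
    strata = list(p = NULL, c = NULL, q = NULL), # NULL = from calibration
    intervention = list(nu = NULL, regression_rate = 0),
    output = list(scenarios = c("low", "middle"))
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]; unknown
#' top-level sections are a configuration error.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return nested named list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) {
    stop_diabproj("config_error", "unknown config section(s): %s",
                  paste(bad, collapse = ", "))
  }
  utils::modifyList(cfg, user)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full projection pipeline
#'
#' Generates (or reads) the demographic and incidence inputs, fits the
#' incidence growth model, extracts scenarios, calibrates the state-model
#' constants, runs the three-state grid (low/middle incidence x low/high
#' mortality risk) and the matching five-state intervention runs, and
#' writes every artifact to `out_dir`: `census.csv`, `incidence.csv`,
#' `scenarios.csv`, `diagnostics.json`, `calibration.json`,
#' `trajectory_<model>_<scenario>_<risk>.csv`, `table1.csv`, `table2.csv`,
#' `prevalence.csv`, and `manifest.json`.
#'
#' @param config nested list from [default_config()]/[load_config()].
#' @param out_dir output directory (created if absent).
#' @param seed integer seed driving both the synthetic generators and the
#'   MCMC chains.
#' @param census,incidence optional user-supplied inputs (data.frames with
#'   the `census.csv`/`incidence.csv` schemas); when `NULL` the synthetic
#'   module generates them from `config$synth`.
#' @return (invisibly) a list with the fitted posterior, scenarios,
#'   calibration set, trajectory list, and tables.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = 1L,
                         census = NULL, incidence = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sy <- config$synth

  if (is.null(census)) {
    census <- generate_census(sy$start_year, sy$end_year,
                              profile = census_profile_us(sy$d_first, sy$d_last,
                                                          sy$migration))
  }
  validate_census(census)
  if (is.null(incidence)) {
    icfg <- incidence_config(sy$rho, sy$lam0, sy$lam1, sy$phi, sy$sigma,
                             sy$se_scale)
    incidence <- generate_incidence_series(icfg, sy$incidence_years, seed = seed)
  }
  write.csv(census, file.path(out_dir, "census.csv"), row.names = FALSE)
  write.csv(incidence, file.path(out_dir, "incidence.csv"), row.names = FALSE)

  prior <- build_rho_prior(config$prior$q_low, config$prior$q_high,
                           config$prior$mass)
  ctrl <- mcmc_control(chains = config$mcmc$chains, warmup = config$mcmc$warmup,
                       iter = config$mcmc$iter, seed = seed)
  proj_years <- (sy$start_year + 1):sy$end_year
  fit <- fit_growth_model(incidence, prior, config$mcmc$error_structure,
                          ctrl, project_years = proj_years)
  scen <- extract_scenarios(fit)
  write.csv(scen, file.path(out_dir, "scenarios.csv"), row.names = FALSE)
  write_json_file(list(
    error_structure = fit$error_structure,
    rhat = as.list(fit$diagnostics$rhat),
    ess = as.list(fit$diagnostics$ess),
    accept = fit$diagnostics$accept,
    converged = fit$diagnostics$converged
  ), file.path(out_dir, "diagnostics.json"))

  state0 <- generate_initial_state(census$N[1], sy$theta1, sy$theta2)
  calib <- calibrate(config$calibration, state0)
  write_json_file(c(unclass(calib)[setdiff(names(calib), "duration")],
                    calib$duration),
                  file.path(out_dir, "calibration.json"))

  strata <- list(p = config$strata$p %||% calib$p28,
                 c = config$strata$c %||% calib$c,
                 q = config$strata$q %||% calib$q)
  interv <- list(nu = config$intervention$nu %||% calib$nu,
                 regression_rate = config$intervention$regression_rate %||% 0)
  risks <- list(lowrisk = do.call(mortality_risks, as.list(config$risks$low)),
                highrisk = do.call(mortality_risks, as.list(config$risks$high)))

  trajs <- list()
  for (sc in config$output$scenarios) {
    ser <- scenario_series(scen, sc)
    for (rk in names(risks)) {
      cell <- paste0(sc, "_", rk)
      trajs[[cell]] <- run_three_state(state0, census, ser, calib, risks[[rk]])
      trajs[[paste0(cell, "_interv")]] <-
        run_five_state(state0, census, ser, calib, risks[[rk]],
                       strata = strata, intervention = interv)
      for (tag in c("", "_interv")) {
        mdl <- if (tag == "") "three" else "five"
        write.csv(trajs[[paste0(cell, tag)]],
                  file.path(out_dir, sprintf("trajectory_%s_%s.csv", mdl, cell)),
                  row.names = FALSE)
      }
    }
  }

  tab1 <- format_table(trajs, "table1")
  tab2 <- format_table(trajs, "table2")
  write.csv(tab1, file.path(out_dir, "table1.csv"), row.names = FALSE)
  write.csv(tab2, file.path(out_dir, "table2.csv"), row.names = FALSE)
  prev <- make_prevalence_report(trajs[!grepl("_interv$", names(trajs))])
  write.csv(prev, file.path(out_dir, "prevalence.csv"), row.names = FALSE)

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  files <- list.files(out_dir, pattern = "\\.(csv|json)$", full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  write_json_file(list(
    package_version = as.character(utils::packageVersion("diabproj")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    checksums = as.list(tools::md5sum(files)),
    timestamp = format(Sys.time(), tz = "UTC")
  ), file.path(out_dir, "manifest.json"))
  unlink(cfg_file)

  invisible(list(fit = fit, scenarios = scen, calibration = calib,
                 trajectories = trajs, table1 = tab1, table2 = tab2,
                 prevalence = prev))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
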