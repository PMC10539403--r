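#' Build a pipeline run configuration
#'
#' A run configuration collects every knob of the end-to-end pipeline:
#' the grid, the synthetic land-cover and environment parameters, the
#' abandonment decision rules, the suitability stage, the improvement
#' levers, the scenario list and sweep fractions, and the output
#' directory. It round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param grid list of [grid_spec()] arguments.
#' @param landcover list of [generate_landcover_series()] arguments
#'   (probabilities and noise). The default raises `p_recult` above the
#'   generator's study-scale default because on demo-sized grids the
#'   recultivated class must still contain enough pixels to train the
#'   suitability model.
#' @param environment list of [environment_config()] overrides.
#' @param abandonment list of [abandonment_params()] arguments.
#' @param suitability list with `threshold`, `background_n`, `seed`.
#' @param levers list of [lever_set()] arguments.
#' @param scenarios character vector of representative scenario names.
#' @param fractions sweep fractions in `(0, 1]`.
#' @param sweep_purpose purpose for the prioritization sweep.
#' @param accuracy list with `n_per_stratum`, `seed`.
#' @param horizon clearing amortization horizon (years).
#' @param out_dir output directory for grids, tables and the manifest.
#' @param force when `TRUE`, stages rerun even if their outputs exist.
#' @return object of class `run_config` (a list).
#' @export
run_config <- function(grid = list(n_rows = 96, n_cols = 96, seed = 1),
                       landcover = list(p_recult = 0.15),
                       environment = list(),
                       abandonment = list(),
                       suitability = list(threshold = 0.2,
                                          background_n = 10000, seed = 1),
                       levers = list(),
                       scenarios = c("max_food", "max_climate",
                                     "equal_allocation", "max_combined"),
                       fractions = seq(0.1, 1, by = 0.1),
                       sweep_purpose = "recultivate",
                       accuracy = list(n_per_stratum = 100, seed = 1),
                       horizon = 30,
                       out_dir = tempfile("fallowland_run_"),
                       force = FALSE) {
  structure(as.list(base::environment()), class = "run_config")
}

#' @param config a `run_config`.
#' @param path YAML file path.
#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

# a stage runs only if `force` or any of its outputs is missing
stage_needed <- function(paths, force) force || !all(file.exists(paths))

#' Run the full pipeline
#'
#' Executes simulate, map-abandonment, suitability, potentials,
#' allocate/sweep, and assess-accuracy in order, writing grids (ESRI
#' ASCII), tables (CSV) and a YAML manifest under `config$out_dir`.
#' Stages whose outputs already exist are skipped unless
#' `config$force`; a stage failure aborts with the stage named, keeping
#' the outputs of completed stages on disk. All results are also
#' returned in memory.
#'
#' @param config a [run_config()] or a path to its YAML file.
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) list with `series`, `stack`, `map`, `types`,
#'   `model`, `surfaces`, `maxima`, `scenario_outcomes`, `sweeps`,
#'   `benefit`, `accuracy`, `area`, and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  stage <- function(name, code) {
    s <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
    say("stage %-16s %6.2fs", name, timings[[name]])
    res
  }

  spec <- do.call(grid_spec, config$grid)
  env_cfg <- do.call(environment_config, config$environment)
  params <- do.call(abandonment_params, config$abandonment)

  sim_dir <- file.path(out, "inputs")
  sim <- stage("simulate", {
    sim <- do.call(simulate_study,
                   c(list(spec = spec, env_config = env_cfg),
                     config$landcover))
    if (stage_needed(file.path(sim_dir, c("series.yml", "stack.yml")),
                     config$force)) {
      write_landcover_series(sim$series, sim_dir)
      write_env_stack(sim$stack, sim_dir)
    }
    sim
  })
  validate_stack(sim$stack)

  ab_dir <- file.path(out, "abandonment")
  map <- stage("map-abandonment", {
    filtered <- temporal_filter(sim$series, params$filter_window)
    m <- detect_abandonment(filtered, params)
    if (stage_needed(file.path(ab_dir, "summary.csv"), config$force)) {
      dir.create(ab_dir, showWarnings = FALSE)
      write_grid_asc(as.integer(m$status), spec,
                     file.path(ab_dir, "status.asc"))
      write_grid_asc(m$abandon_year, spec,
                     file.path(ab_dir, "abandon_year.asc"))
      utils::write.csv(abandonment_summary(m),
                       file.path(ab_dir, "summary.csv"), row.names = FALSE)
    }
    m
  })

  su_dir <- file.path(out, "suitability")
  su <- stage("suitability", {
    presence <- detect_recultivation_presence(
      temporal_filter(sim$series, params$filter_window), params)
    model <- fit_recultivation_suitability(
      presence, sim$stack,
      background_n = config$suitability$background_n,
      seed = config$suitability$seed)
    rcv <- predict(model, sim$stack, tau = 0.5)
    types <- classify_suitability(rcv, sim$stack, map,
                                  threshold = config$suitability$threshold)
    if (stage_needed(file.path(su_dir, "coefficients.csv"), config$force)) {
      dir.create(su_dir, showWarnings = FALSE)
      write_grid_asc(rcv, spec, file.path(su_dir, "recultivability.asc"))
      write_grid_asc(as.integer(types$type), spec,
                     file.path(su_dir, "type.asc"))
      utils::write.csv(data.frame(term = names(model$coefficients),
                                  estimate = model$coefficients),
                       file.path(su_dir, "coefficients.csv"),
                       row.names = FALSE)
    }
    list(model = model, types = types)
  })

  po_dir <- file.path(out, "potentials")
  surfaces <- stage("potentials", {
    sf <- potential_surfaces(sim$stack, sim$series, map,
                             horizon = config$horizon)
    sf <- apply_levers(sf, sim$stack, do.call(lever_set, config$levers))
    if (stage_needed(file.path(po_dir, "totals.csv"), config$force)) {
      dir.create(po_dir, showWarnings = FALSE)
      write_grid_asc(sf$productivity, spec,
                     file.path(po_dir, "productivity.asc"))
      write_grid_asc(sf$seq, spec, file.path(po_dir, "seq_rate.asc"))
      write_grid_asc(sf$clear_emit_rate, spec,
                     file.path(po_dir, "clearing_rate.asc"))
      mx0 <- landscape_maxima(su$types, sf, spec)
      utils::write.csv(data.frame(quantity = c("F_max_pcal", "C_max_mtco2"),
                                  value = c(mx0$F_max, mx0$C_max)),
                       file.path(po_dir, "totals.csv"), row.names = FALSE)
    }
    sf
  })
  maxima <- landscape_maxima(su$types, surfaces, spec)

  sc_dir <- file.path(out, "scenarios")
  scen <- stage("allocate", {
    dir.create(sc_dir, showWarnings = FALSE)
    rows <- lapply(config$scenarios, function(nm) {
      alloc <- representative_scenario(nm, su$types, surfaces)
      if (stage_needed(file.path(sc_dir, paste0("allocation_", nm, ".asc")),
                       config$force)) {
        write_grid_asc(as.integer(alloc$purpose), spec,
                       file.path(sc_dir, paste0("allocation_", nm, ".asc")))
      }
      evaluate_allocation(alloc, surfaces, maxima$F_max, maxima$C_max, spec)
    })
    outcomes <- do.call(rbind, rows)
    utils::write.csv(outcomes, file.path(sc_dir, "scenario_outcomes.csv"),
                     row.names = FALSE)
    utils::write.csv(render_scenario_table(outcomes),
                     file.path(sc_dir, "scenario_table.csv"),
                     row.names = FALSE)
    outcomes
  })

  sweeps <- stage("sweep", {
    pri <- fraction_sweep(su$types, surfaces, config$sweep_purpose,
                          config$fractions, "prioritized",
                          seed = spec$seed,
                          F_max = maxima$F_max, C_max = maxima$C_max)
    rnd <- fraction_sweep(su$types, surfaces, config$sweep_purpose,
                          config$fractions, "randomized",
                          seed = spec$seed,
                          F_max = maxima$F_max, C_max = maxima$C_max)
    ben <- prioritization_benefit(pri, rnd)
    utils::write.csv(rbind(pri, rnd), file.path(sc_dir, "sweeps.csv"),
                     row.names = FALSE)
    utils::write.csv(ben, file.path(sc_dir, "prioritization_benefit.csv"),
                     row.names = FALSE)
    list(prioritized = pri, randomized = rnd, benefit = ben)
  })

  ac_dir <- file.path(out, "accuracy")
  acc <- stage("assess-accuracy", {
    dir.create(ac_dir, showWarnings = FALSE)
    mc <- binary_map_class(map)
    n_str <- min(config$accuracy$n_per_stratum, min(table(mc)))
    samp <- stratified_sample(mc, n_str, seed = config$accuracy$seed)
    # reference labels from the generator's noise-free truth
    samp$reference_class <- factor(
      ifelse(sim$series$truth$status[samp$pixel] == "abandoned",
             "abandoned", "not_abandoned"),
      levels = levels(mc))
    w <- strata_weights(mc)
    rep <- confusion_metrics(samp, w)
    area <- error_adjusted_area(samp, w,
                                total_area = n_pixels(spec) *
                                  spec$pixel_area / 1e6)
    utils::write.csv(samp, file.path(ac_dir, "samples.csv"),
                     row.names = FALSE)
    utils::write.csv(area, file.path(ac_dir, "area_estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(
      metric = c("overall_accuracy", "users_accuracy",
                 "producers_accuracy", "f1"),
      value = c(rep$overall_accuracy, rep$users_accuracy,
                rep$producers_accuracy, rep$f1)),
      file.path(ac_dir, "accuracy.csv"), row.names = FALSE)
    list(report = rep, area = area)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("fallowland")),
    seed = spec$seed,
    config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                      c("out_dir", "force"))]),
    timings = timings,
    total_elapsed = round(proc.time()[["elapsed"]] - t0, 3)
  )
  yaml::write_yaml(manifest, file.path(out, "manifest.yml"))
  write_run_config(config, file.path(out, "config.yml"))
  say("pipeline complete in %.1fs -> %s", manifest$total_elapsed, out)

  invisible(list(series = sim$series, stack = sim$stack, map = map,
                 model = su$model, types = su$types, surfaces = surfaces,
                 maxima = maxima, scenario_outcomes = scen,
                 sweeps = sweeps[c("prioritized", "randomized")],
                 benefit = sweeps$benefit,
                 accuracy = acc$report, area = acc$area,
                 manifest = manifest))
}

# every layer the downstream stages need must be present and co-sized
validate_stack <- function(stack) {
  np <- n_pixels(stack$spec)
  layers <- c("harvest_share", "food_loss", "seq_rate", "agb_rate",
              "biomass_stock", "pnv_class", "protected", "covariates")
  for (nm in layers) {
    x <- stack[[nm]]
    if (is.null(x)) {
      stop("missing environment layer: '", nm, "'", call. = FALSE)
    }
    n <- if (is.matrix(x)) nrow(x) else length(x)
    if (n != np) {
      stop("environment layer '", nm, "' has ", n, " pixels; grid has ",
           np, call. = FALSE)
    }
  }
  invisible(stack)
}
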