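#' Assemble a pipeline configuration
#'
#' Bundles the seed, model constants, generator configuration and inversion
#' settings for an end-to-end run; round-trips unchanged through YAML (see
#' [read_pipeline_config()]).
#'
#' @param seed Global seed.
#' @param constants A [sugar_constants()] object.
#' @param generator A [generator_config()] object.
#' @param bandwidth Smoothing bandwidth (fraction of the age span).
#' @param grid_step Rate-grid step (days).
#' @param edge_fraction Interior fraction of the age span on which rates are
#'   reported.
#' @param alpha Significance level for the LSD letters.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, constants = sugar_constants(),
                            generator = generator_config(),
                            bandwidth = 0.6, grid_step = 1,
                            edge_fraction = 0.8, alpha = 0.05) {
  structure(list(seed = seed, constants = constants, generator = generator,
                 bandwidth = bandwidth, grid_step = grid_step,
                 edge_fraction = edge_fraction, alpha = alpha),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()] object.
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  gen <- unclass(config$generator)
  # named numeric vectors must serialise as maps, not bare sequences
  gen$fw_water <- as.list(gen$fw_water)
  gen$dw_water <- as.list(gen$dw_water)
  plain <- list(seed = config$seed,
                constants = unclass(config$constants),
                generator = gen,
                bandwidth = config$bandwidth, grid_step = config$grid_step,
                edge_fraction = config$edge_fraction, alpha = config$alpha)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  gen <- raw$generator
  for (nm in c("fw_water", "dw_water")) gen[[nm]] <- unlist(gen[[nm]])
  for (nm in c("sampling_daa", "temp_range")) gen[[nm]] <- as.numeric(gen[[nm]])
  pipeline_config(seed = raw$seed,
                  constants = do.call(sugar_constants, raw$constants),
                  generator = do.call(generator_config, gen),
                  bandwidth = raw$bandwidth, grid_step = raw$grid_step,
                  edge_fraction = raw$edge_fraction, alpha = raw$alpha)
}

#' Run the full synthetic-experiment pipeline
#'
#' generate -> convert -> invert -> simulate-check -> stats, writing every
#' stage's table to `out_dir`:
#' `observations.csv`, `truth.csv`, `design.csv`, `pools.csv`, `rates.csv`
#' (per treatment), `simulation_check.csv` (forward re-simulation of the
#' control from its inverted rates), `anova_<response>.csv` and
#' `letters_<response>.csv`, plus `run_log.txt` with the seed and package
#' version. Identical configuration and seed give byte-identical numeric
#' outputs.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param responses Responses passed to the ANOVA stage.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         responses = c("fw", "dw", "ssc", "stc")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("Pipeline stage '", name, "' failed: ",
                          conditionMessage(e)))
    })
  }

  synth <- stage("generate", generate_dataset(config$seed, config$generator,
                                              config$constants))
  paths$observations <- write_table(synth$observations,
                                    file.path(out_dir, "observations.csv"))
  paths$truth <- write_table(synth$truth, file.path(out_dir, "truth.csv"))
  paths$design <- write_table(build_design(), file.path(out_dir, "design.csv"))

  pools <- stage("convert", pools_from_observations(
    synth$observations, config$generator$sugar_cf, config$generator$starch_cf,
    config$constants))
  paths$pools <- write_table(carbon_fractions(pools),
                             file.path(out_dir, "pools.csv"))

  rates <- stage("invert", invert_observations(
    synth$observations, env = synth$temperature, const = config$constants,
    sugar_cf = config$generator$sugar_cf, starch_cf = config$generator$starch_cf,
    bandwidth = config$bandwidth, grid_step = config$grid_step,
    edge_fraction = config$edge_fraction))
  paths$rates <- write_table(rates, file.path(out_dir, "rates.csv"))

  sim_check <- stage("simulate-check", {
    ck <- dplyr::filter(pools, .data$treatment == "CK")
    sm <- smooth_pools(ck, vars = c("c_sol", "c_sta", "c_str", "dw"),
                       bandwidth = config$bandwidth,
                       grid_step = config$grid_step)
    r <- estimate_rates(sm, env = synth$temperature, const = config$constants,
                        edge_fraction = 1)
    growth <- tibble::tibble(daa = sm$daa, dw = sm$dw,
                             ddw_dt = pmax(sm$ddw_dt, 0))
    init <- c(c_sol = sm$c_sol[1], c_sta = sm$c_sta[1], c_str = sm$c_str[1])
    simulate_carbon(init, growth, synth$temperature, r, config$constants)
  })
  paths$simulation_check <- file.path(out_dir, "simulation_check.csv")
  write_simulation(sim_check, paths$simulation_check)

  obs <- dplyr::mutate(synth$observations,
                       stage = ifelse(.data$daa <= 57, "II", "III"))
  for (resp in responses) {
    fit <- stage(paste0("stats:", resp),
                 factorial_anova(obs, resp, c("water", "potassium", "stage")))
    paths[[paste0("anova_", resp)]] <-
      write_table(tidy.factorial_anova(fit),
                  file.path(out_dir, paste0("anova_", resp, ".csv")))
    paths[[paste0("letters_", resp)]] <-
      write_table(lsd_groups(fit, "water", config$alpha),
                  file.path(out_dir, paste0("letters_", resp, ".csv")))
  }

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste0("fruitcarbon ", as.character(utils::packageVersion("fruitcarbon"))),
    paste0("R ", R.version.string),
    paste0("seed ", config$seed),
    paste0("bandwidth ", config$bandwidth, " grid_step ", config$grid_step,
           " edge_fraction ", config$edge_fraction)), log_path)
  paths$log <- log_path
  invisible(paths)
}
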