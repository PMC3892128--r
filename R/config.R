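#' Full run configuration
#'
#' One declarative object holding every parameter of a simulate-train-test
#' run. The defaults materialize the reference operating point: 1 kHz
#' sampling, 4 Hz second-order causal low-pass, 200/100 moving-average
#' decimation (10 Hz features), L = 200 hidden nodes, C = 2^7, six
#' postures held 7 s with 5 s recorded and 3 repetitions for training, and
#' the 10-instruction drinking-task sequence repeated 3 times for testing.
#'
#' @param ... named overrides of the defaults, nested as in the returned
#'   list (e.g. `sensor = list(noise_sd = 0)` replaces just that field).
#' @return an object of class `run_config` (a nested named list).
#' @export
#' @examples
#' cfg <- run_config(sensor = list(noise_sd = 0), seeds = list(simulation = 42))
#' cfg$sensor$noise_sd
run_config <- function(...) {
  defaults <- list(
    sensor = list(supply_voltage = 5, base_resistance = 22e3,
                  rest_resistance = 1e7, contact_pressure = 0.05,
                  resistance_scale = 22e3, noise_sd = 0.02,
                  drift_sd = 0.01, sample_rate = 1000),
    filter = list(cutoff = 4, order = 2),
    decimator = list(window = 200, step = 100),
    elm = list(L = 200, C = 2^7),
    training = list(hold_duration = 7, record_duration = 5, repetitions = 3),
    testing = list(instruction_labels = c(1, 2, 3, 4, 5, 6, 5, 4, 3, 1),
                   instruction_duration = 3, class1_duration = 5,
                   repetitions = 3),
    behaviour = list(response_delay_min = 0.5, response_delay_max = 1.5,
                     transition_duration = 0.5, rep_jitter_sd = 0.02),
    templates = list(min_distance = 2),
    stability = list(n_bases = 5),
    seeds = list(simulation = 1, templates = 1, basis = 1)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  stop_if_not(length(bad) == 0, "unknown config section(s): %s",
              paste(bad, collapse = ", "))
  for (sec in names(over)) {
    stop_if_not(is.list(over[[sec]]), "config section '%s' must be a list", sec)
    badf <- setdiff(names(over[[sec]]), names(defaults[[sec]]))
    stop_if_not(length(badf) == 0, "unknown field(s) in '%s': %s",
                sec, paste(badf, collapse = ", "))
    defaults[[sec]] <- modifyList(defaults[[sec]], over[[sec]])
  }
  structure(defaults, class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config` (unknown fields are rejected).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

# Materialize the component spec objects from a run_config
config_sensor <- function(config) do.call(sensor_config, config$sensor)
config_filter <- function(config)
  filter_spec(config$filter$cutoff, config$sensor$sample_rate,
              config$filter$order)
config_decimator <- function(config)
  decimator_spec(config$decimator$window, config$decimator$step)
config_training <- function(config) do.call(training_protocol, config$training)
config_testing <- function(config) do.call(test_protocol, config$testing)

#' Run a complete simulated study
#'
#' Drives the whole pipeline for one simulated participant: draw posture
#' templates, simulate the training phase and assemble the 900-sample
#' training buffer, train the ELM, simulate the drinking-task test session,
#' classify it in streaming order, estimate and compensate the response
#' delay, score, and (optionally) run the random-base stability analysis.
#'
#' @param config a [run_config()].
#' @param stability also run the offline random-base analysis
#'   (default TRUE).
#' @return list with `templates`, `training_set`, `model`, `test_raw`,
#'   `session` (raw real-time record), `delay` ([estimate_delay()]),
#'   `compensated`, `report` ([score_session()]), and `stability`
#'   ([stability_report()] or NULL).
#' @export
#' @examples
#' \donttest{
#' res <- run_study(run_config(seeds = list(simulation = 7)))
#' res$report$overall_accuracy
#' }
run_study <- function(config = run_config(), stability = TRUE) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config_sensor(config)
  fspec <- config_filter(config)
  dspec <- config_decimator(config)
  tprot <- config_training(config)
  teprot <- config_testing(config)
  beh <- config$behaviour

  templates <- default_templates(config$seeds$templates,
                                 min_distance = config$templates$min_distance)
  segments <- simulate_training_segments(templates, cfg, tprot,
                                         seed = config$seeds$simulation,
                                         rep_jitter_sd = beh$rep_jitter_sd)
  tset <- build_training_set(segments, fspec, dspec, tprot)
  model <- train_session(tset, L = config$elm$L, C = config$elm$C,
                         seed = config$seeds$basis)

  scr <- test_script(teprot,
                     response_delay_range = c(beh$response_delay_min,
                                              beh$response_delay_max),
                     transition_duration = beh$transition_duration,
                     rep_jitter_sd = beh$rep_jitter_sd)
  test_raw <- generate_session(scr, templates, cfg,
                               seed = config$seeds$simulation + 1L)
  session <- classify_stream(model, test_raw, fspec, dspec)
  delay <- estimate_delay(session)
  compensated <- compensate_delay(session, delay$mean)
  report <- score_session(compensated)
  stab <- if (isTRUE(stability))
    stability_report(tset, test_raw, report$overall_accuracy, delay$mean,
                     L = config$elm$L, C = config$elm$C,
                     n_bases = config$stability$n_bases,
                     seeds = config$seeds$basis + seq_len(config$stability$n_bases),
                     fspec = fspec, dspec = dspec)
  list(templates = templates, training_set = tset, model = model,
       test_raw = test_raw, session = session, delay = delay,
       compensated = compensated, report = report, stability = stab)
}
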