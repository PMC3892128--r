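#' FSR strap sensor configuration
#'
#' Electrical and noise model of one force-sensing-resistor (FSR) channel
#' read through a voltage divider: `V = Vcc * R_base / (R_base + R_fsr(p))`.
#' At rest the FSR sits above 10 Mohm; under pressure its resistance falls
#' approximately as the inverse of the applied pressure (log-resistance
#' linear in log-pressure), so the divider voltage rises monotonically
#' towards the supply rail.
#'
#' @param supply_voltage supply rail in volts (default 5).
#' @param base_resistance fixed divider resistor in ohm (default 22e3).
#' @param rest_resistance FSR resistance with no contact, ohm (default 1e7).
#' @param contact_pressure pressure below which the sensor stays at
#'   `rest_resistance` (default 0.05 pressure units).
#' @param resistance_scale coefficient of the inverse-pressure law
#'   `R_fsr(p) = resistance_scale / p`, ohm * pressure units (default 22e3,
#'   so unit pressure puts the divider at mid-scale).
#' @param noise_sd additive Gaussian voltage noise, volts (default 0.02).
#' @param drift_sd slow baseline drift magnitude, volts per minute
#'   (default 0.01); realised as an integrated random walk.
#' @param sample_rate sampling rate in Hz (default 1000).
#' @return an object of class `sensor_config`.
#' @export
#' @examples
#' cfg <- sensor_config()
#' pressure_to_voltage(0, cfg)    # rest voltage, ~0.011 V
#' pressure_to_voltage(1, cfg)    # mid-scale, 2.5 V
sensor_config <- function(supply_voltage = 5,
                          base_resistance = 22e3,
                          rest_resistance = 1e7,
                          contact_pressure = 0.05,
                          resistance_scale = 22e3,
                          noise_sd = 0.02,
                          drift_sd = 0.01,
                          sample_rate = 1000) {
  stop_if_not(is_number(supply_voltage) && supply_voltage > 0,
              "supply_voltage must be a positive number")
  stop_if_not(is_number(base_resistance) && base_resistance > 0,
              "base_resistance must be a positive number")
  stop_if_not(is_number(rest_resistance) && rest_resistance >= base_resistance,
              "rest_resistance must be >= base_resistance")
  stop_if_not(is_number(sample_rate) && sample_rate > 0,
              "sample_rate must be positive")
  stop_if_not(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  stop_if_not(is_number(drift_sd) && drift_sd >= 0, "drift_sd must be >= 0")
  stop_if_not(is_number(contact_pressure) && contact_pressure >= 0,
              "contact_pressure must be >= 0")
  stop_if_not(is_number(resistance_scale) && resistance_scale > 0,
              "resistance_scale must be positive")
  structure(list(supply_voltage = supply_voltage,
                 base_resistance = base_resistance,
                 rest_resistance = rest_resistance,
                 contact_pressure = contact_pressure,
                 resistance_scale = resistance_scale,
                 noise_sd = noise_sd,
                 drift_sd = drift_sd,
                 sample_rate = sample_rate),
            class = "sensor_config")
}

#' Convert applied pressure to divider output voltage
#'
#' The FSR resistance is `rest_resistance` below the contact threshold and
#' `min(rest_resistance, resistance_scale / p)` above it; the divider then
#' gives `V = Vcc * R_base / (R_base + R_fsr)`. Non-decreasing in `p` and
#' bounded by the supply voltage.
#'
#' @param p pressure (vectorised), pressure units, must be >= 0.
#' @param cfg a [sensor_config()].
#' @return voltages in volts, same length as `p`.
#' @export
pressure_to_voltage <- function(p, cfg = sensor_config()) {
  stopifnot(inherits(cfg, "sensor_config"))
  stop_if_not(all(is.finite(p)) && all(p >= 0),
              "pressure must be finite and non-negative")
  r <- ifelse(p <= cfg$contact_pressure,
              cfg$rest_resistance,
              pmin(cfg$rest_resistance, cfg$resistance_scale / p))
  cfg$supply_voltage * cfg$base_resistance / (cfg$base_resistance + r)
}

#' Posture pressure template
#'
#' One posture's characteristic pressure pattern over the eight strap
#' channels. Templates are abstract stand-ins for the muscle-bulge pattern a
#' posture produces under the strap; they are not an anatomical model.
#'
#' @param class_label integer class label in 1..6.
#' @param channel_pressures numeric vector of 8 non-negative pressures.
#' @param name optional posture name.
#' @return an object of class `posture_template`.
#' @export
posture_template <- function(class_label, channel_pressures, name = NULL) {
  stop_if_not(is_count(class_label) && class_label >= 1 && class_label <= 6,
              "class_label must be an integer in 1..6")
  stop_if_not(is.numeric(channel_pressures) && length(channel_pressures) == 8L,
              "channel_pressures must have exactly 8 entries")
  stop_if_not(all(is.finite(channel_pressures)) && all(channel_pressures >= 0),
              "channel_pressures must be finite and non-negative")
  structure(list(class_label = as.integer(class_label),
                 channel_pressures = as.numeric(channel_pressures),
                 name = name),
            class = "posture_template")
}

#' Names of the six drinking-task postures
#' @return character vector of length 6, indexed by class label.
#' @export
posture_names <- function() {
  c("Relax", "90 deg Elbow Flexion", "Fingers Extension",
    "Soft Grasp", "120 deg Elbow Flexion", "Wrist Pronation")
}

#' Generate six well-separated posture templates
#'
#' Draws one 8-channel pressure pattern per drinking-task posture. Class 1
#' (relax) uses light baseline strap pressures; the five active postures draw
#' from a wider range. Draws are rejected and retried until every pair of
#' templates is at least `min_distance` apart in Euclidean pressure distance,
#' so the synthetic postures are distinguishable the way real FMG patterns
#' are.
#'
#' @param seed integer seed; the same seed always yields the same templates.
#' @param min_distance minimum pairwise Euclidean distance between templates
#'   in pressure units (default 2).
#' @param relax_range pressure range for the relax posture (default c(0.1, 0.5)).
#' @param active_range pressure range for active postures (default c(0.5, 5)).
#' @return list of 6 [posture_template()] objects, one per class.
#' @export
default_templates <- function(seed, min_distance = 2,
                              relax_range = c(0.1, 0.5),
                              active_range = c(0.5, 5)) {
  stop_if_not(is_number(min_distance) && min_distance >= 0,
              "min_distance must be >= 0")
  nm <- posture_names()
  with_seed(seed, {
    for (attempt in 1:1000) {
      press <- rbind(
        runif(8, relax_range[1], relax_range[2]),
        matrix(runif(5 * 8, active_range[1], active_range[2]), nrow = 5,
               byrow = TRUE)
      )
      if (min(stats::dist(press)) >= min_distance) {
        return(lapply(1:6, function(k)
          posture_template(k, press[k, ], name = nm[k])))
      }
    }
    stop("could not draw templates ", min_distance,
         " apart; lower min_distance or widen the pressure ranges",
         call. = FALSE)
  })
}

#' Minimum pairwise distance between posture templates
#' @param templates list of [posture_template()].
#' @return smallest Euclidean distance between any two channel-pressure vectors.
#' @export
template_separation <- function(templates) {
  press <- do.call(rbind, lapply(templates, `[[`, "channel_pressures"))
  min(stats::dist(press))
}

#' Session script: a timed sequence of commanded postures
#'
#' Describes what the on-screen instructions ask for: an ordered list of
#' (class, duration) steps, plus the human factors the simulator reproduces —
#' the 0.5-1.5 s lag between a new instruction and the actual posture change,
#' the finite time the limb takes to move between postures, and the slight
#' variation of a posture's pattern from one repetition to the next.
#'
#' @param classes integer vector of commanded class labels (1..6).
#' @param durations step durations in seconds (recycled to `length(classes)`).
#' @param response_delay_range numeric c(min, max) seconds; each posture
#'   change lags its command by a uniform draw from this range (default
#'   c(0.5, 1.5)).
#' @param transition_duration seconds taken to move between postures, as a
#'   linear pressure ramp (default 0.5).
#' @param rep_jitter_sd per-step multiplicative template perturbation, as a
#'   fraction (default 0.02).
#' @return an object of class `session_script`.
#' @export
session_script <- function(classes, durations,
                           response_delay_range = c(0.5, 1.5),
                           transition_duration = 0.5,
                           rep_jitter_sd = 0.02) {
  stop_if_not(length(classes) >= 1 && all(classes %in% 1:6),
              "classes must be labels in 1..6")
  durations <- rep_len(as.numeric(durations), length(classes))
  stop_if_not(all(is.finite(durations)) && all(durations > 0),
              "durations must be positive")
  stop_if_not(length(response_delay_range) == 2 &&
                response_delay_range[1] >= 0 &&
                response_delay_range[1] <= response_delay_range[2],
              "response_delay_range must satisfy 0 <= min <= max")
  stop_if_not(is_number(transition_duration) && transition_duration >= 0,
              "transition_duration must be >= 0")
  stop_if_not(is_number(rep_jitter_sd) && rep_jitter_sd >= 0,
              "rep_jitter_sd must be >= 0")
  structure(list(classes = as.integer(classes),
                 durations = durations,
                 response_delay_range = as.numeric(response_delay_range),
                 transition_duration = transition_duration,
                 rep_jitter_sd = rep_jitter_sd),
            class = "session_script")
}

#' Simulate a raw FSR strap recording for a scripted session
#'
#' Produces the 1 kHz eight-channel voltage stream a strap would emit while
#' a wearer follows the script. Three aligned tracks are recorded:
#' `commands` — the instructed class at each sample; `truth` — the class
#' actually being performed, i.e. the commands delayed by a per-step human
#' response delay; and the voltages themselves. After each (delayed) posture
#' change the channel pressures ramp linearly to the next template over
#' `transition_duration`, each step's template is perturbed by multiplicative
#' jitter, and the voltages carry additive Gaussian noise plus an integrated
#' random-walk drift, clamped to `[0, supply_voltage]`.
#'
#' Delays, jitter, noise and drift each draw from an independent sub-stream
#' of `seed`, so e.g. raising `noise_sd` does not change the delays drawn.
#'
#' @param script a [session_script()].
#' @param templates list of [posture_template()] covering every scripted class.
#' @param cfg a [sensor_config()].
#' @param seed integer seed; identical inputs give bit-identical recordings.
#' @return an object of class `raw_recording`: list with `sample_rate`,
#'   `voltages` (n x 8 matrix), `commands`, `truth` (integer vectors),
#'   `delays` (the per-step response delays actually drawn).
#' @export
generate_session <- function(script, templates, cfg = sensor_config(),
                             seed = 1L) {
  stopifnot(inherits(script, "session_script"), inherits(cfg, "sensor_config"))
  tmpl_class <- vapply(templates, `[[`, integer(1), "class_label")
  missing_cls <- setdiff(unique(script$classes), tmpl_class)
  stop_if_not(length(missing_cls) == 0,
              "no template for scripted class(es): %s",
              paste(missing_cls, collapse = ", "))

  fs <- cfg$sample_rate
  nstep <- length(script$classes)
  n_per <- round(script$durations * fs)
  n <- sum(n_per)
  cmd_start <- cumsum(c(0L, n_per[-nstep])) + 1L  # first sample of each step
  commands <- rep(script$classes, n_per)

  seeds <- derive_seeds(seed, 4L)
  delays <- with_seed(seeds[1], runif(nstep, script$response_delay_range[1],
                                      script$response_delay_range[2]))
  delays[1] <- 0  # the session starts already in the first posture
  jit <- with_seed(seeds[2],
                   matrix(rnorm(nstep * 8, 0, script$rep_jitter_sd),
                          nrow = nstep))

  # per-step jittered template pressures (nstep x 8)
  base_p <- do.call(rbind, lapply(script$classes, function(k)
    templates[[match(k, tmpl_class)]]$channel_pressures))
  step_p <- pmax(base_p * (1 + jit), 0)

  # truth track + pressure timeline with linear ramps at each posture change
  change_at <- cmd_start + as.integer(round(delays * fs))  # first new-truth sample
  change_at <- pmin(change_at, n + 1L)
  truth <- integer(n)
  pressures <- matrix(0, n, 8)
  n_ramp <- round(script$transition_duration * fs)
  for (s in seq_len(nstep)) {
    from <- change_at[s]
    to <- if (s < nstep) change_at[s + 1L] - 1L else n
    if (from > to) next
    truth[from:to] <- script$classes[s]
    pressures[from:to, ] <- matrix(step_p[s, ], to - from + 1L, 8,
                                   byrow = TRUE)
    if (s > 1L && n_ramp > 0L) {  # ramp in from the previous posture
      r_to <- min(from + n_ramp - 1L, to)
      if (r_to >= from) {
        w <- (seq_len(r_to - from + 1L)) / n_ramp
        w <- pmin(w, 1)
        prev <- step_p[s - 1L, ]
        pressures[from:r_to, ] <- outer(1 - w, prev) + outer(w, step_p[s, ])
      }
    }
  }
  if (change_at[1] > 1L) {  # should not happen (delay[1] = 0), but be safe
    truth[1:(change_at[1] - 1L)] <- script$classes[1]
    pressures[1:(change_at[1] - 1L), ] <- matrix(step_p[1, ],
                                                 change_at[1] - 1L, 8,
                                                 byrow = TRUE)
  }

  volts <- apply(pressures, 2, pressure_to_voltage, cfg = cfg)
  volts <- matrix(volts, n, 8)
  if (cfg$noise_sd > 0)
    volts <- volts + with_seed(seeds[3], matrix(rnorm(n * 8, 0, cfg$noise_sd),
                                                n, 8))
  if (cfg$drift_sd > 0) {
    step_sd <- cfg$drift_sd / sqrt(60 * fs)  # random walk, sd drift_sd per min
    drift <- with_seed(seeds[4],
                       apply(matrix(rnorm(n * 8, 0, step_sd), n, 8), 2, cumsum))
    volts <- volts + drift
  }
  volts <- pmin(pmax(volts, 0), cfg$supply_voltage)

  structure(list(sample_rate = fs,
                 voltages = volts,
                 commands = as.integer(commands),
                 truth = truth,
                 delays = delays),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples x 8 channels @ %g Hz (%.1f s), classes: %s\n",
              nrow(x$voltages), x$sample_rate,
              nrow(x$voltages) / x$sample_rate,
              paste(sort(unique(x$commands)), collapse = " ")))
  invisible(x)
}

#' Write / read a raw recording as CSV
#'
#' Sessions interchange as plain CSV with columns
#' `time_s, ch1..ch8, command, truth`, one row per 1 kHz sample.
#'
#' @param rec a `raw_recording`.
#' @param path file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `raw_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  n <- nrow(rec$voltages)
  dt <- data.table::data.table(time_s = seq_len(n) / rec$sample_rate)
  for (j in 1:8) dt[[paste0("ch", j)]] <- rec$voltages[, j]
  dt$command <- rec$commands
  dt$truth <- rec$truth
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  dt <- data.table::fread(path)
  need <- c("time_s", paste0("ch", 1:8), "command", "truth")
  miss <- setdiff(need, names(dt))
  stop_if_not(length(miss) == 0, "recording file %s is missing column(s): %s",
              path, paste(miss, collapse = ", "))
  fs <- round(1 / median(diff(dt$time_s)))
  structure(list(sample_rate = fs,
                 voltages = as.matrix(dt[, paste0("ch", 1:8), with = FALSE]),
                 commands = as.integer(dt$command),
                 truth = as.integer(dt$truth),
                 delays = NULL),
            class = "raw_recording")
}
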