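# Shared fixtures: small, fast configurations used across test files.

# A noiseless sensor: deterministic voltages, no drift.
quiet_sensor <- function(...) {
  sensor_config(noise_sd = 0, drift_sd = 0, ...)
}

# Study configuration with all stochastic human/sensor effects off and a
# fixed 1 s response delay: the fully deterministic degenerate run.
clean_config <- function(delay = 1, ...) {
  run_config(sensor = list(noise_sd = 0, drift_sd = 0),
             behaviour = list(response_delay_min = delay,
                              response_delay_max = delay,
                              transition_duration = 0,
                              rep_jitter_sd = 0),
             ...)
}

# Well-separated templates shared by most end-to-end tests.
test_templates <- function(seed = 11) default_templates(seed)

# A small separable 2D-ish training problem for ELM unit tests: six tight
# clusters in [0,1]^8 with n points each.
cluster_data <- function(n = 20, spread = 0.01, seed = 5) {
  set.seed(seed)
  centers <- matrix(runif(6 * 8), 6, 8)
  x <- do.call(rbind, lapply(1:6, function(k)
    matrix(rnorm(n * 8, mean = rep(centers[k, ], each = n), sd = spread),
           n, 8)))
  list(x = x, y = rep(1:6, each = n), centers = centers)
}

# Build a session_record by hand (10 Hz grid).
make_session <- function(command, prediction, truth = command, rate = 10) {
  structure(data.frame(time_s = seq_along(command) / rate,
                       command = command, truth = truth,
                       prediction = prediction),
            class = c("session_record", "data.frame"),
            rate_hz = rate, latency_s = NA_real_)
}
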