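test_that("the default training protocol yields a balanced 900-sample buffer", {
  tpl <- test_templates()
  segs <- simulate_training_segments(tpl, quiet_sensor(), training_protocol(),
                                     seed = 1, rep_jitter_sd = 0)
  tset <- build_training_set(segs)
  expect_equal(nrow(tset$features), 900L)
  expect_equal(tset$n_per_segment, 50L)
  expect_equal(as.vector(table(tset$labels)), rep(150L, 6))
  expect_true(all(is.finite(tset$features)))
  # normalized features span [0, 1] per channel over the training buffer
  expect_equal(unname(apply(tset$features, 2, min)), rep(0, 8))
  expect_equal(unname(apply(tset$features, 2, max)), rep(1, 8))
  # zero noise: the 50 samples within one (class, rep) are identical
  f <- tset$features[tset$labels == 3, ][1:50, ]
  expect_lt(max(abs(sweep(f, 2, f[1, ]))), 1e-6)
})

test_that("incomplete or short training recordings are rejected by name", {
  tpl <- test_templates()
  segs <- simulate_training_segments(tpl, quiet_sensor(), training_protocol(),
                                     seed = 1)
  expect_error(build_training_set(segs[-3]), "missing training segment")
  short <- segs
  short[[2]]$recording$voltages <- short[[2]]$recording$voltages[1:3000, ]
  expect_error(build_training_set(short), "class 2 rep 1.*shorter")
})

test_that("test protocol arithmetic matches its instruction sequence", {
  scr <- test_script(test_protocol())
  expect_length(scr$classes, 30)  # 10 instructions x 3 repetitions
  expect_equal(scr$classes[1:10], c(1L, 2L, 3L, 4L, 5L, 6L, 5L, 4L, 3L, 1L))
  # class-1 (relax) instructions last class1_duration, the rest 3 s
  expect_equal(unique(scr$durations[scr$classes == 1L]), 5)
  expect_equal(unique(scr$durations[scr$classes != 1L]), 3)
  expect_equal(sum(scr$durations), 3 * (8 * 3 + 2 * 5))
})

test_that("streaming classification is causal and respects the rate contract", {
  tpl <- test_templates()
  cfg <- quiet_sensor()
  segs <- simulate_training_segments(tpl, cfg, training_protocol(), seed = 1,
                                     rep_jitter_sd = 0)
  model <- train_session(build_training_set(segs), seed = 4)
  scr <- session_script(c(1, 4, 2), c(4, 3.25, 3),
                        response_delay_range = c(0.6, 0.6),
                        transition_duration = 0.2, rep_jitter_sd = 0)
  raw <- generate_session(scr, tpl, cfg, seed = 5)
  sess <- classify_stream(model, raw)
  n <- nrow(raw$voltages)
  expect_equal(nrow(sess), as.integer(ceiling(n / 100)))  # 10 Hz grid + flush
  expect_equal(attr(sess, "rate_hz"), 10)
  # causality: classifying a prefix of the raw stream gives a prefix of the
  # predictions
  cut <- 6200L
  pre <- raw
  pre$voltages <- raw$voltages[1:cut, ]
  pre$commands <- raw$commands[1:cut]
  pre$truth <- raw$truth[1:cut]
  sp <- classify_stream(model, pre)
  keep <- sp$time_s * 1000 <= (cut %/% 100) * 100
  expect_equal(sp$prediction[keep],
               sess$prediction[seq_len(sum(keep))])
  # constant zero-noise hold is predicted as its class throughout
  hold <- generate_session(session_script(4, 6, response_delay_range = c(0, 0),
                                          transition_duration = 0,
                                          rep_jitter_sd = 0),
                           tpl, cfg, seed = 6)
  expect_true(all(classify_stream(model, hold)$prediction == 4L))
  # mismatched sampling rate is refused
  bad <- raw
  bad$sample_rate <- 500
  expect_error(classify_stream(model, bad), "500")
})

test_that("session records round-trip through CSV", {
  s <- make_session(rep(c(1L, 2L), each = 20), rep(c(1L, 2L), each = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_record(s, path)
  back <- read_session_record(path)
  expect_equal(as.data.frame(back), as.data.frame(s), tolerance = 1e-12)
  expect_equal(attr(back, "rate_hz"), 10)
})

test_that("real-time per-sample processing cost is far under the 200 ms budget", {
  tpl <- test_templates()
  cfg <- quiet_sensor()
  segs <- simulate_training_segments(tpl, cfg, training_protocol(), seed = 1)
  model <- train_session(build_training_set(segs), seed = 2)
  raw <- generate_session(session_script(c(1, 2), c(5, 5)), tpl, cfg, seed = 3)
  sess <- classify_stream(model, raw)
  expect_lt(attr(sess, "latency_s"), 0.2)
})
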