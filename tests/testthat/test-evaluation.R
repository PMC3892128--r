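test_that("response delay is measured from command change to first correct prediction", {
  cmd <- rep(c(1L, 2L, 1L, 2L, 1L, 2L), each = 30)
  # perfect responder: zero delay at every transition
  perfect <- make_session(cmd, cmd)
  expect_equal(estimate_delay(perfect)$delays, rep(0, 3))
  # predictions lag commands by exactly k grid samples
  for (k in c(5L, 10L, 15L)) {
    lag <- make_session(cmd, c(rep(1L, k), cmd[1:(length(cmd) - k)]))
    d <- estimate_delay(lag)
    expect_equal(d$delays, rep(k / 10, 3))
    expect_equal(d$mean, k / 10)
    expect_equal(d$sd, 0)
  }
  expect_error(estimate_delay(make_session(rep(1L, 10), rep(1L, 10))),
               "no 1 -> 2 command transition")
})

test_that("delay compensation shifts the prediction track on the 10 Hz grid", {
  cmd <- rep(c(1L, 2L, 3L, 1L, 2L, 3L), each = 25)
  k <- 7L
  lagged <- make_session(cmd, c(rep(1L, k), cmd[1:(length(cmd) - k)]))
  # delay 0 is the identity
  expect_identical(compensate_delay(lagged, 0), lagged)
  # 0.1 s shifts by exactly one sample
  one <- compensate_delay(lagged, 0.1)
  expect_equal(nrow(one), nrow(lagged) - 1L)
  expect_equal(one$prediction, lagged$prediction[-1])
  # compensating by the construction delay restores 100% on the overlap
  comp <- compensate_delay(lagged, k / 10)
  expect_equal(nrow(comp), nrow(lagged) - k)
  expect_equal(score_session(comp)$overall_accuracy, 100)
  expect_error(compensate_delay(lagged, 1e4), "exceeds")
})

test_that("scoring reports overall, per-class and most-misclassified accuracy", {
  cmd <- rep(1:6, each = 10)
  perfect <- score_session(make_session(cmd, cmd))
  expect_equal(perfect$overall_accuracy, 100)
  expect_equal(unname(perfect$per_class_accuracy), rep(100, 6))
  # degenerate predictor: always class 2
  all2 <- score_session(make_session(cmd, rep(2L, 60)))
  expect_equal(unname(all2$per_class_accuracy),
               c(0, 100, 0, 0, 0, 0))
  expect_equal(sort(all2$most_misclassified_class), c(1L, 3:6))
  # plain counting: 9 of 10 correct is 90%
  p <- c(1L, rep(2L, 9))
  nine <- score_session(make_session(rep(2L, 10), p))
  expect_equal(nine$overall_accuracy, 90)
  # confusion rows sum to per-class command counts
  conf <- score_session(make_session(cmd, rev(cmd)))$confusion
  expect_equal(unname(rowSums(conf)), rep(10, 6))
  expect_error(score_session(make_session(integer(0), integer(0))), "empty")
})

test_that("mean/SD aggregation matches printed-table conventions", {
  # n-1 standard deviation, rounded half away from zero
  expect_equal(aggregate_stats(c(10, 10)), list(mean = 10, sd = 0))
  expect_equal(aggregate_stats(c(1.9, 1.0, 1.1), 2), list(mean = 1.33, sd = 0.49))
  expect_equal(round_half_out(2.5), 3)
  expect_equal(round_half_out(-2.5), -3)
  expect_equal(round_half_out(0.845, 2), 0.85)
  expect_error(aggregate_stats(5), "at least 2")
})

test_that("stability over random bases is degenerate-stable on separable data", {
  tpl <- test_templates()
  cfg <- quiet_sensor()
  segs <- simulate_training_segments(tpl, cfg, training_protocol(), seed = 1,
                                     rep_jitter_sd = 0)
  tset <- build_training_set(segs)
  model <- train_session(tset, seed = 40)
  raw <- generate_session(session_script(c(1, 2, 3), c(4, 3, 3),
                                         response_delay_range = c(1, 1),
                                         transition_duration = 0,
                                         rep_jitter_sd = 0),
                          tpl, cfg, seed = 50)
  sess <- classify_stream(model, raw)
  delay <- estimate_delay(sess)$mean
  acc <- score_session(compensate_delay(sess, delay))$overall_accuracy
  stab <- stability_report(tset, raw, acc, delay, n_bases = 5, seeds = 11:15)
  expect_length(stab$accuracies, 6)
  expect_equal(unname(stab$accuracies), rep(100, 6))
  expect_equal(stab$sd, 0)
  # reproducible for fixed seeds
  stab2 <- stability_report(tset, raw, acc, delay, n_bases = 5, seeds = 11:15)
  expect_identical(stab$accuracies, stab2$accuracies)
})

test_that("errors concentrate near command transitions on realistic sessions", {
  res <- run_study(run_config(seeds = list(simulation = 3, templates = 3,
                                           basis = 3)),
                   stability = FALSE)
  tr <- transition_error_rates(res$compensated, window_s = 0.5)
  expect_gt(tr$transition_error_rate, tr$steady_error_rate)
  # and overall accuracy stays within sane bounds
  expect_gte(res$report$overall_accuracy, 0)
  expect_lte(res$report$overall_accuracy, 100)
})

test_that("noisier sensors never improve the median session accuracy", {
  acc_at <- function(noise, seeds) {
    vapply(seeds, function(s) {
      cfg <- run_config(sensor = list(noise_sd = noise),
                        testing = list(repetitions = 1),
                        seeds = list(simulation = s, templates = 3, basis = 3))
      run_study(cfg, stability = FALSE)$report$overall_accuracy
    }, numeric(1))
  }
  # the preprocessing chain suppresses white noise heavily, so the levels
  # span the regime where residual noise actually perturbs the features
  seeds <- 1:5
  med <- vapply(c(0.02, 2, 5), function(nz) median(acc_at(nz, seeds)),
                numeric(1))
  expect_true(all(diff(med) <= 1e-9))
})
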