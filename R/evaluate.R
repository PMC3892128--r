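#' Estimate the wearer's response delay from a classified session
#'
#' When a new instruction appears the wearer takes roughly 0.5-1.5 s to
#' react, so the prediction track lags the command track. The delay is
#' measured at each `from_class` to `to_class` command transition (by
#' default relax to 90-degree elbow flexion, a transition with consistent
#' response and essentially no misclassification) as the time from the
#' command change to the first prediction equal to `to_class`.
#'
#' @param session a [classify_stream()] `session_record`.
#' @param from_class,to_class the command transition to scan for
#'   (defaults 1 -> 2).
#' @return an object of class `delay_estimate`: list with `delays` (one
#'   per transition/section, seconds), `mean`, `sd` (sample SD, `n - 1`).
#' @export
estimate_delay <- function(session, from_class = 1L, to_class = 2L) {
  stopifnot(inherits(session, "session_record"))
  cmd <- session$command
  n <- length(cmd)
  at <- which(cmd[-1] == to_class & cmd[-n] == from_class) + 1L
  stop_if_not(length(at) >= 1,
              "session has no %d -> %d command transition",
              from_class, to_class)
  delays <- vapply(at, function(j) {
    hit <- which(session$prediction[j:n] == to_class)
    if (length(hit) == 0) return(NA_real_)
    session$time_s[j + hit[1] - 1L] - session$time_s[j]
  }, numeric(1))
  stop_if_not(!anyNA(delays),
              "prediction never reached class %d after some %d -> %d transition",
              to_class, from_class, to_class)
  structure(list(delays = delays,
                 mean = mean(delays),
                 sd = if (length(delays) >= 2) sd(delays) else NA_real_),
            class = "delay_estimate")
}

#' @export
print.delay_estimate <- function(x, ...) {
  cat(sprintf("<delay_estimate> sections: %s s; mean %.2f s, SD %.2f s\n",
              paste(sprintf("%.1f", x$delays), collapse = ", "),
              x$mean, x$sd))
  invisible(x)
}

#' Compensate a session for the wearer's response delay
#'
#' Shifts the prediction track forward in time by `delay` (rounded to the
#' feature grid), so that predictions are scored against the command that
#' was on screen when the wearer initiated the movement. The `round(delay *
#' rate)` overhanging samples are dropped: the first predictions (made
#' before the shifted window) and the last commands (whose delayed
#' responses fall beyond the recording) are excluded from scoring.
#'
#' @param session a `session_record`.
#' @param delay non-negative delay in seconds, typically the `mean` of an
#'   [estimate_delay()].
#' @return a shorter `session_record` with aligned tracks.
#' @export
compensate_delay <- function(session, delay) {
  stopifnot(inherits(session, "session_record"))
  stop_if_not(is_number(delay) && delay >= 0, "delay must be >= 0")
  rate <- attr(session, "rate_hz")
  k <- as.integer(round(delay * rate))
  n <- nrow(session)
  stop_if_not(k < n, "delay (%.2f s) exceeds the session length", delay)
  if (k == 0) return(session)
  out <- data.frame(time_s = session$time_s[seq_len(n - k)],
                    command = session$command[seq_len(n - k)],
                    truth = session$truth[seq_len(n - k)],
                    prediction = session$prediction[seq_len(n - k) + k])
  structure(out, class = class(session),
            rate_hz = rate, latency_s = attr(session, "latency_s"),
            shift_samples = k)
}

#' Score a (delay-compensated) session
#'
#' Overall accuracy is the fraction of feature-grid points whose prediction
#' matches the commanded class, in percent. Per-class accuracy conditions
#' on the command track; the most-misclassified class is the one (or ones,
#' on ties) with the lowest per-class accuracy.
#'
#' @param session a `session_record`, normally after [compensate_delay()].
#' @param class_labels label set for the report (default 1:6).
#' @return an object of class `eval_report`: list with `overall_accuracy`,
#'   `per_class_accuracy` (named, percent; `NA` for classes never
#'   commanded), `most_misclassified_class`, `most_misclassified_accuracy`,
#'   `confusion` (commands in rows, predictions in columns), `n`.
#' @export
score_session <- function(session, class_labels = 1:6) {
  stopifnot(inherits(session, "session_record"))
  n <- nrow(session)
  stop_if_not(n >= 1, "cannot score an empty session")
  cmd <- factor(session$command, levels = class_labels)
  prd <- factor(session$prediction, levels = class_labels)
  confusion <- table(command = cmd, prediction = prd)
  correct <- session$command == session$prediction
  per_class <- vapply(class_labels, function(k) {
    sel <- session$command == k
    if (!any(sel)) return(NA_real_)
    100 * mean(correct[sel])
  }, numeric(1))
  names(per_class) <- as.character(class_labels)
  worst <- which(per_class == min(per_class, na.rm = TRUE))
  structure(list(overall_accuracy = 100 * mean(correct),
                 per_class_accuracy = per_class,
                 most_misclassified_class = class_labels[worst],
                 most_misclassified_accuracy = unname(per_class[worst][1]),
                 confusion = confusion,
                 n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> overall accuracy %.2f%% over %d samples\n",
              x$overall_accuracy, x$n))
  pc <- ifelse(is.na(x$per_class_accuracy), "  -- ",
               sprintf("%5.1f", x$per_class_accuracy))
  cat("  per-class %: ", paste(names(x$per_class_accuracy), pc,
                               sep = "=", collapse = "  "), "\n")
  cat(sprintf("  most misclassified: class %s (%.1f%%)\n",
              paste(x$most_misclassified_class, collapse = " & "),
              x$most_misclassified_accuracy))
  invisible(x)
}

#' Offline stability of the classifier under random hidden bases
#'
#' The hidden layer is random, so a natural question is how much the choice
#' of basis moves the result. The recorded test session is re-classified
#' offline with `n_bases` freshly seeded bases (same training data, same
#' `L` and `C`, same preprocessing and delay compensation as the real-time
#' pass) and the accuracies are aggregated together with the real-time
#' run's.
#'
#' @param tset the [build_training_set()] used for the real-time model.
#' @param raw the recorded raw test session.
#' @param realtime_accuracy overall accuracy (percent) of the real-time run.
#' @param delay the compensation delay (seconds) applied to every run.
#' @param L,C ELM hyperparameters (defaults 200, `2^7`).
#' @param n_bases number of random bases (default 5).
#' @param seeds basis seeds, length `n_bases`; default `1:n_bases`.
#' @param fspec,dspec preprocessing specs.
#' @return an object of class `stability_report`: list with `accuracies`
#'   (real-time first, then one per basis), `mean`, `sd` (sample SD).
#' @export
stability_report <- function(tset, raw, realtime_accuracy, delay,
                             L = 200, C = 2^7, n_bases = 5,
                             seeds = NULL,
                             fspec = filter_spec(),
                             dspec = decimator_spec()) {
  stopifnot(inherits(tset, "training_set"), inherits(raw, "raw_recording"))
  if (is.null(seeds)) seeds <- seq_len(n_bases)
  stop_if_not(length(seeds) == n_bases, "need one seed per basis")
  offline <- vapply(seeds, function(s) {
    model <- train_session(tset, L = L, C = C, seed = s)
    sess <- classify_stream(model, raw, fspec, dspec)
    score_session(compensate_delay(sess, delay))$overall_accuracy
  }, numeric(1))
  acc <- c(realtime = realtime_accuracy,
           setNames(offline, paste0("base", seq_len(n_bases))))
  structure(list(accuracies = acc, mean = mean(acc), sd = sd(acc)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> accuracies: %s %%\n  mean %.1f%%, SD %.1f%%\n",
              paste(sprintf("%.1f", x$accuracies), collapse = ", "),
              x$mean, x$sd))
  invisible(x)
}

#' Mean and sample standard deviation, rounded as printed
#'
#' Aggregates a column of per-participant (or per-section) values the way
#' result tables print them: arithmetic mean and `n - 1` standard
#' deviation, rounded half away from zero to `decimals` places.
#'
#' @param values numeric vector, length >= 2.
#' @param decimals decimal places to round to (default 2).
#' @return list with `mean` and `sd`.
#' @export
#' @examples
#' aggregate_stats(c(95.50, 92.20, 90.20, 87.50, 92.70, 95.90))
aggregate_stats <- function(values, decimals = 2) {
  stop_if_not(is.numeric(values) && length(values) >= 2,
              "need at least 2 values for a sample SD")
  stop_if_not(all(is.finite(values)), "values must be finite")
  list(mean = round_half_out(mean(values), decimals),
       sd = round_half_out(sd(values), decimals))
}

#' Misclassification rate near versus away from command transitions
#'
#' Splits the scored grid points of a compensated session into those within
#' `window_s` seconds of a command change and the rest, and returns the
#' error rate in each stratum. On realistic sessions errors concentrate in
#' the transitional stratum, because the classifier is trained only on
#' steady postures.
#'
#' @param session a compensated `session_record`.
#' @param window_s half-width of the transitional window in seconds
#'   (default 0.5).
#' @return list with `transition_error_rate`, `steady_error_rate` (both in
#'   `[0, 1]`; `NaN` if a stratum is empty), and the stratum sizes.
#' @export
transition_error_rates <- function(session, window_s = 0.5) {
  stopifnot(inherits(session, "session_record"))
  cmd <- session$command
  n <- length(cmd)
  changes <- which(diff(cmd) != 0) + 1L
  near <- rep(FALSE, n)
  rate <- attr(session, "rate_hz")
  w <- as.integer(round(window_s * rate))
  for (j in changes)
    near[max(1L, j - w):min(n, j + w)] <- TRUE
  err <- session$prediction != session$command
  list(transition_error_rate = mean(err[near]),
       steady_error_rate = mean(err[!near]),
       n_transition = sum(near), n_steady = sum(!near))
}
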