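#' Training protocol for the drinking-task postures
#'
#' In the training phase the wearer holds each of the six postures for
#' `hold_duration` seconds while the operator records `record_duration`
#' seconds of steady data from the middle of the hold (transitions between
#' postures are never recorded); the whole sequence is repeated
#' `repetitions` times. With the defaults (5 s recorded, 10 Hz feature
#' rate, 6 postures, 3 repetitions) the training buffer holds exactly
#' 50 x 6 x 3 = 900 feature samples.
#'
#' @param hold_duration seconds each posture is held (default 7).
#' @param record_duration seconds recorded per hold (default 5); must not
#'   exceed `hold_duration`.
#' @param repetitions number of times the 6-posture sequence is repeated
#'   (default 3).
#' @return an object of class `training_protocol`.
#' @export
training_protocol <- function(hold_duration = 7, record_duration = 5,
                              repetitions = 3) {
  stop_if_not(is_number(hold_duration) && hold_duration > 0,
              "hold_duration must be positive")
  stop_if_not(is_number(record_duration) && record_duration > 0 &&
                record_duration <= hold_duration,
              "need 0 < record_duration <= hold_duration")
  stop_if_not(is_count(repetitions), "repetitions must be a positive integer")
  structure(list(classes = 1:6, class_names = posture_names(),
                 hold_duration = hold_duration,
                 record_duration = record_duration,
                 repetitions = as.integer(repetitions)),
            class = "training_protocol")
}

#' Testing protocol: the instructed drinking-task sequence
#'
#' The wearer follows on-screen instructions through the drinking task and
#' back: relax, raise the elbow to 90 degrees, extend the fingers, grasp
#' the cup, flex the elbow to 120 degrees, pronate the wrist to drink, then
#' reverse — supinate, lower the elbow, release, relax. That is 10
#' instructions per repetition, each lasting `instruction_duration` seconds
#' except the relax (class 1) instructions, which last `class1_duration`
#' to let the arm settle fully. The sequence is repeated `repetitions`
#' times in one continuous session.
#'
#' @param instruction_labels ordered class labels of one repetition
#'   (default `c(1, 2, 3, 4, 5, 6, 5, 4, 3, 1)`).
#' @param instruction_duration seconds per instruction (default 3).
#' @param class1_duration seconds for class-1 (relax) instructions
#'   (default 5).
#' @param repetitions number of repetitions (default 3).
#' @return an object of class `test_protocol`.
#' @export
test_protocol <- function(instruction_labels = c(1, 2, 3, 4, 5, 6, 5, 4, 3, 1),
                          instruction_duration = 3,
                          class1_duration = 5,
                          repetitions = 3) {
  stop_if_not(all(instruction_labels %in% 1:6),
              "instruction labels must be classes 1..6")
  stop_if_not(is_number(instruction_duration) && instruction_duration > 0,
              "instruction_duration must be positive")
  stop_if_not(is_number(class1_duration) && class1_duration > 0,
              "class1_duration must be positive")
  stop_if_not(is_count(repetitions), "repetitions must be a positive integer")
  structure(list(instruction_labels = as.integer(instruction_labels),
                 instruction_duration = instruction_duration,
                 class1_duration = class1_duration,
                 repetitions = as.integer(repetitions)),
            class = "test_protocol")
}

#' Expand a test protocol into a full-session script
#'
#' @param protocol a [test_protocol()].
#' @param response_delay_range,transition_duration,rep_jitter_sd passed to
#'   [session_script()].
#' @return a [session_script()] covering all repetitions.
#' @export
test_script <- function(protocol = test_protocol(),
                        response_delay_range = c(0.5, 1.5),
                        transition_duration = 0.5,
                        rep_jitter_sd = 0.02) {
  stopifnot(inherits(protocol, "test_protocol"))
  labels <- rep(protocol$instruction_labels, protocol$repetitions)
  durs <- ifelse(labels == 1L, protocol$class1_duration,
                 protocol$instruction_duration)
  session_script(labels, durs,
                 response_delay_range = response_delay_range,
                 transition_duration = transition_duration,
                 rep_jitter_sd = rep_jitter_sd)
}

#' Simulate the training phase as per-posture, per-repetition segments
#'
#' Each segment is one steady `hold_duration`-second hold of a posture (the
#' operator records only inside the hold, away from any transition), with
#' its own repetition jitter draw so the three repetitions of a posture
#' differ slightly, as real FMG patterns do.
#'
#' @param templates list of 6 [posture_template()].
#' @param cfg a [sensor_config()].
#' @param protocol a [training_protocol()].
#' @param seed master seed; each segment draws from its own sub-stream.
#' @param rep_jitter_sd per-repetition template perturbation (default 0.02).
#' @return list of segments, each a list with `class`, `rep`, `recording`.
#' @export
simulate_training_segments <- function(templates, cfg = sensor_config(),
                                       protocol = training_protocol(),
                                       seed = 1L, rep_jitter_sd = 0.02) {
  stopifnot(inherits(protocol, "training_protocol"))
  nseg <- length(protocol$classes) * protocol$repetitions
  seeds <- derive_seeds(seed, nseg)
  i <- 0L
  out <- vector("list", nseg)
  for (rep in seq_len(protocol$repetitions)) {
    for (cls in protocol$classes) {
      i <- i + 1L
      scr <- session_script(cls, protocol$hold_duration,
                            response_delay_range = c(0, 0),
                            transition_duration = 0,
                            rep_jitter_sd = rep_jitter_sd)
      out[[i]] <- list(class = cls, rep = rep,
                       recording = generate_session(scr, templates, cfg,
                                                    seed = seeds[i]))
    }
  }
  out
}

#' Assemble the training buffer from recorded segments
#'
#' Runs each per-posture, per-repetition segment through the preprocessing
#' chain: the centred `record_duration` seconds of the hold are extracted,
#' low-pass filtered, decimated to the feature rate and truncated to
#' exactly `record_duration * sample_rate / step` samples (50 at the
#' defaults). The segments are concatenated into one buffer (900 samples at
#' the defaults), on which min-max normalization is fitted and applied.
#'
#' @param segments list of `list(class, rep, recording)` as produced by
#'   [simulate_training_segments()] (or assembled from recorded files).
#' @param fspec a [filter_spec()].
#' @param dspec a [decimator_spec()].
#' @param protocol a [training_protocol()].
#' @return an object of class `training_set`: list with `features`
#'   (N x 8, normalized), `labels` (length N), `norm` (the fitted
#'   [fit_normalization()] parameters), `n_per_segment`.
#' @export
build_training_set <- function(segments, fspec = filter_spec(),
                               dspec = decimator_spec(),
                               protocol = training_protocol()) {
  stopifnot(inherits(protocol, "training_protocol"))
  have <- vapply(segments, function(s) paste(s$class, s$rep), character(1))
  want <- as.vector(outer(protocol$classes,
                          seq_len(protocol$repetitions), paste))
  miss <- setdiff(want, have)
  stop_if_not(length(miss) == 0,
              "missing training segment(s) for (class rep): %s",
              paste(miss, collapse = "; "))

  n_keep <- floor(protocol$record_duration * fspec$sample_rate / dspec$step)
  feats <- vector("list", length(segments))
  labels <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    rec <- seg$recording
    stop_if_not(inherits(rec, "raw_recording"),
                "segment %d has no raw_recording", i)
    n <- nrow(rec$voltages)
    n_rec <- round(protocol$record_duration * fspec$sample_rate)
    stop_if_not(n >= n_rec,
                "segment for class %s rep %s is %.2f s, shorter than the %g s record window",
                seg$class, seg$rep, n / fspec$sample_rate,
                protocol$record_duration)
    start <- floor((n - n_rec) / 2) + 1L  # centred within the hold
    v <- rec$voltages[start:(start + n_rec - 1L), , drop = FALSE]
    f <- decimate_mean(lowpass(v, fspec), dspec)$features
    stop_if_not(nrow(f) >= n_keep,
                "segment for class %s rep %s yielded %d feature samples, need %d",
                seg$class, seg$rep, nrow(f), n_keep)
    feats[[i]] <- f[seq_len(n_keep), , drop = FALSE]
    labels[[i]] <- rep(seg$class, n_keep)
  }
  X <- do.call(rbind, feats)
  y <- unlist(labels)
  norm <- fit_normalization(X)
  structure(list(features = apply_normalization(X, norm),
                 labels = y, norm = norm, n_per_segment = n_keep),
            class = "training_set")
}

#' Train an ELM on an assembled training set
#'
#' Generates a fresh random hidden basis from `seed` and solves the output
#' weights in closed form. The normalization fitted on the training buffer
#' travels with the model. The wall time of the linear solve is attached as
#' attribute `train_time_s`; it is a fraction of a second at the default
#' problem size, which is what makes retraining at every strap donning
#' practical.
#'
#' @param tset a [build_training_set()] result.
#' @param L hidden nodes (default 200).
#' @param C regularization parameter (default `2^7`).
#' @param seed basis seed.
#' @param basis optionally, a pre-generated [random_basis()] to reuse
#'   (overrides `L` and `seed`).
#' @return an `elm_model` with `norm` set.
#' @export
train_session <- function(tset, L = 200, C = 2^7, seed = 1L, basis = NULL) {
  stopifnot(inherits(tset, "training_set"))
  if (is.null(basis)) basis <- random_basis(L, ncol(tset$features), seed)
  t0 <- proc.time()[["elapsed"]]
  model <- elm_train(tset$features, tset$labels, basis, C = C,
                     class_labels = 1:6, norm = tset$norm)
  attr(model, "train_time_s") <- proc.time()[["elapsed"]] - t0
  model
}

#' Stream a raw session through the model in real-time order
#'
#' Reproduces the online loop: the raw 1 kHz stream is causally filtered,
#' decimated to 10 Hz, scaled with the normalization parameters stored at
#' training time, and classified sample by sample. Every emitted feature
#' depends only on past raw samples, so classifying a prefix of the stream
#' yields a prefix of the predictions. The command and truth tracks are
#' aligned to the feature grid by taking their value at each decimation
#' window's final raw sample.
#'
#' @param model a trained `elm_model` carrying `norm`.
#' @param raw a `raw_recording`.
#' @param fspec a [filter_spec()]; its sample rate must match the recording.
#' @param dspec a [decimator_spec()].
#' @return an object of class `session_record`: data.frame with columns
#'   `time_s`, `command`, `truth`, `prediction` at the feature rate, with
#'   attributes `rate_hz` and `latency_s` (mean wall time per emitted
#'   prediction, filter + decimate + classify).
#' @export
classify_stream <- function(model, raw, fspec = filter_spec(),
                            dspec = decimator_spec()) {
  stopifnot(inherits(model, "elm_model"), inherits(raw, "raw_recording"))
  stop_if_not(!is.null(model$norm),
              "model carries no normalization parameters; train via train_session()/build_training_set()")
  stop_if_not(raw$sample_rate == fspec$sample_rate,
              "recording is sampled at %g Hz but the pipeline expects %g Hz",
              raw$sample_rate, fspec$sample_rate)
  t0 <- proc.time()[["elapsed"]]
  filt <- lowpass(raw$voltages, fspec)
  dec <- decimate_mean(filt, dspec)
  x <- apply_normalization(dec$features, model$norm)
  pred <- predict(model, x)
  elapsed <- proc.time()[["elapsed"]] - t0
  idx <- dec$index
  rec <- data.frame(time_s = idx / raw$sample_rate,
                    command = raw$commands[idx],
                    truth = raw$truth[idx],
                    prediction = as.integer(pred))
  structure(rec,
            class = c("session_record", "data.frame"),
            rate_hz = raw$sample_rate / dspec$step,
            latency_s = elapsed / max(1L, length(idx)))
}

#' Write / read a session record as CSV
#' @param session a `session_record`.
#' @param path file path.
#' @return `write_session_record` returns `path` invisibly;
#'   `read_session_record` returns a `session_record`.
#' @export
write_session_record <- function(session, path) {
  stopifnot(inherits(session, "session_record"))
  data.table::fwrite(as.data.frame(session), path)
  invisible(path)
}

#' @rdname write_session_record
#' @export
read_session_record <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  need <- c("time_s", "command", "truth", "prediction")
  miss <- setdiff(need, names(dt))
  stop_if_not(length(miss) == 0, "session file %s is missing column(s): %s",
              path, paste(miss, collapse = ", "))
  rate <- 1 / median(diff(dt$time_s))
  structure(dt, class = c("session_record", "data.frame"),
            rate_hz = rate, latency_s = NA_real_)
}
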