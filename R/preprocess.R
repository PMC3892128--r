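#' Low-pass filter specification
#'
#' FMG is slow (muscle bulges change over hundreds of milliseconds), so the
#' raw 1 kHz stream is low-pass filtered at 4 Hz to strip sensor and motion
#' noise. The filter must be causal for streaming use; a Butterworth design
#' gives a maximally flat passband.
#'
#' @param cutoff cutoff frequency in Hz (default 4). Must lie below Nyquist.
#' @param sample_rate sampling rate in Hz (default 1000).
#' @param order filter order (default 2).
#' @param kind filter family; only `"butterworth-causal"` is implemented.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff = 4, sample_rate = 1000, order = 2,
                        kind = "butterworth-causal") {
  stop_if_not(is_number(sample_rate) && sample_rate > 0,
              "sample_rate must be positive")
  stop_if_not(is_number(cutoff) && cutoff > 0 && cutoff < sample_rate / 2,
              "cutoff must lie in (0, sample_rate/2)")
  stop_if_not(is_count(order), "order must be a positive integer")
  kind <- match.arg(kind)
  structure(list(cutoff = cutoff, sample_rate = sample_rate,
                 order = as.integer(order), kind = kind),
            class = "filter_spec")
}

#' Causal low-pass filtering of a multichannel series
#'
#' Applies the Butterworth filter independently per channel, in the forward
#' direction only (no zero-phase `filtfilt`), as a real-time system must.
#' To avoid a start-up transient from zero initial conditions, one second of
#' the first sample is prepended before filtering and dropped afterwards, so
#' a constant input passes through unchanged (DC gain 1).
#'
#' @param x numeric matrix (samples x channels), numeric vector, or a
#'   [generate_session()] `raw_recording` (its voltages are filtered).
#' @param spec a [filter_spec()]; for a `raw_recording` its sample rate must
#'   match the recording's.
#' @return filtered series with the same shape as the input (a
#'   `raw_recording` comes back as one, with filtered voltages).
#' @export
lowpass <- function(x, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(x, "raw_recording")) {
    stop_if_not(x$sample_rate == spec$sample_rate,
                "recording is sampled at %g Hz but the filter expects %g Hz",
                x$sample_rate, spec$sample_rate)
    x$voltages <- lowpass(x$voltages, spec)
    return(x)
  }
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  if (nrow(xm) == 0) return(x)
  bt <- signal::butter(spec$order, spec$cutoff / (spec$sample_rate / 2))
  npad <- ceiling(spec$sample_rate)  # 1 s of settling pad
  out <- apply(xm, 2, function(col) {
    y <- signal::filter(bt, c(rep(col[1], npad), col))
    as.numeric(y)[-seq_len(npad)]
  })
  out <- matrix(out, nrow = nrow(xm))
  if (vec) drop(out) else out
}

#' Moving-average decimator specification
#'
#' The filtered 1 kHz stream is down-sampled by an average filter: every
#' `step` new samples, emit the per-channel mean of the most recent
#' `window` samples. With the defaults (window 200, step 100 at 1 kHz) the
#' feature rate is 10 Hz and 5 s of data yield exactly 50 feature samples.
#'
#' @param window averaging window length in samples (default 200).
#' @param step emission step in samples (default 100).
#' @return an object of class `decimator_spec`.
#' @export
decimator_spec <- function(window = 200, step = 100) {
  stop_if_not(is_count(window) && is_count(step) && window >= step,
              "need window >= step >= 1")
  structure(list(window = as.integer(window), step = as.integer(step)),
            class = "decimator_spec")
}

#' Moving-average decimation of a multichannel series
#'
#' Streaming semantics: an output is emitted at input samples
#' `step, 2*step, ...`, each the per-channel mean of the most recent
#' `min(window, samples seen)` inputs, so early windows are partial rather
#' than discarded. If the stream length is not a multiple of `step` a final
#' output is flushed at the last sample, making the output count
#' `ceiling(n / step)`.
#'
#' @param x numeric matrix (samples x channels) or vector.
#' @param spec a [decimator_spec()].
#' @param flush emit the trailing partial-step output (default TRUE).
#' @return list with `features` (outputs x channels matrix), `index` (the
#'   1-based input sample at which each output was emitted).
#' @export
decimate_mean <- function(x, spec = decimator_spec(), flush = TRUE) {
  stopifnot(inherits(spec, "decimator_spec"))
  xm <- if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
  n <- nrow(xm)
  if (n == 0)
    return(list(features = matrix(numeric(0), 0, ncol(xm)), index = integer(0)))
  idx <- if (n >= spec$step) seq.int(spec$step, n, by = spec$step)
         else integer(0)
  if (flush && (length(idx) == 0 || idx[length(idx)] < n)) idx <- c(idx, n)
  cs <- apply(xm, 2, cumsum)
  cs <- rbind(0, matrix(cs, nrow = n))
  lo <- pmax(idx - spec$window + 1L, 1L)
  feats <- (cs[idx + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (idx - lo + 1L)
  list(features = feats, index = as.integer(idx))
}

#' Fit per-channel min-max normalization on training features
#'
#' The ELM's sigmoid basis works on inputs of comparable scale, so training
#' features are rescaled channel-wise to `[0, 1]` by the training minimum
#' and maximum. The fitted parameters are stored with the model and reused
#' verbatim at test time. A channel whose training values are all equal is
#' flagged degenerate and maps to 0.
#'
#' @param x training feature matrix (samples x 8).
#' @return an object of class `norm_params`: list with `min`, `max`
#'   (length-8), `degenerate` (logical length-8).
#' @export
fit_normalization <- function(x) {
  x <- as.matrix(x)
  stop_if_not(nrow(x) >= 2, "need at least 2 training samples")
  stop_if_not(ncol(x) == 8, "expected 8 feature channels, got %d", ncol(x))
  stop_if_not(all(is.finite(x)), "training features must be finite")
  mn <- apply(x, 2, min)
  mx <- apply(x, 2, max)
  structure(list(min = mn, max = mx, degenerate = mx == mn),
            class = "norm_params")
}

#' Apply stored normalization parameters
#'
#' Per channel, `x' = (x - min) / (max - min)` with the training-phase
#' parameters. Test-time values outside the training range are deliberately
#' not clamped: a feature of 1.3 says the muscle pressed harder than in any
#' training sample, which the classifier may use. Degenerate channels map
#' to 0.
#'
#' @param x feature matrix (samples x 8) or length-8 vector.
#' @param params a fitted [fit_normalization()] object.
#' @return normalized features, same shape as `x`.
#' @export
apply_normalization <- function(x, params) {
  stopifnot(inherits(params, "norm_params"))
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = length(x)) else as.matrix(x)
  stop_if_not(ncol(xm) == 8, "expected 8 feature channels, got %d", ncol(xm))
  rng <- params$max - params$min
  rng[params$degenerate] <- 1  # avoid 0/0; result overwritten below
  out <- sweep(sweep(xm, 2, params$min), 2, rng, "/")
  out[, params$degenerate] <- 0
  if (vec) drop(out) else out
}

#' Invert a normalization (non-degenerate channels)
#' @param x normalized features.
#' @param params a `norm_params`.
#' @return features on the original scale; degenerate channels return the
#'   training constant.
#' @export
invert_normalization <- function(x, params) {
  stopifnot(inherits(params, "norm_params"))
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = length(x)) else as.matrix(x)
  rng <- params$max - params$min
  out <- sweep(sweep(xm, 2, rng, "*"), 2, params$min, "+")
  out[, params$degenerate] <- matrix(params$min[params$degenerate],
                                     nrow(xm), sum(params$degenerate),
                                     byrow = TRUE)
  if (vec) drop(out) else out
}
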