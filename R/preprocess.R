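#' Normalisation configuration
#'
#' Parameters of the envelope + companding stage: a first-order low-pass
#' Butterworth envelope filter and mu-law amplitude companding.
#'
#' @param mu Companding parameter; larger values expand small amplitudes
#'   more strongly. Default 255.
#' @param cutoff_hz Envelope low-pass cutoff in Hz; the supported variants
#'   are 1 (default), 5 and 10.
#' @param filter_order Butterworth order (default 1).
#' @param zero_phase If `TRUE` filter forward-backward (zero phase); the
#'   default is a causal single pass, compatible with real-time use.
#' @param scale Pre-companding scaling: `"per_channel"` divides each channel
#'   by its own max |x|, `"global"` by the session-wide max.
#' @return An object of class `norm_config`.
#' @export
norm_config <- function(mu = 255, cutoff_hz = 1, filter_order = 1L,
                        zero_phase = FALSE, scale = c("per_channel", "global")) {
  if (mu <= 0) stopf("mu must be positive")
  if (!cutoff_hz %in% c(1, 5, 10)) stopf("supported envelope cutoffs are 1, 5 and 10 Hz")
  if (filter_order < 1L) stopf("filter order must be >= 1")
  structure(list(mu = mu, cutoff_hz = cutoff_hz, filter_order = as.integer(filter_order),
                 zero_phase = zero_phase, scale = match.arg(scale)),
            class = "norm_config")
}

#' Window specification
#'
#' @param window_size Window length W in samples.
#' @param skip_step Hop between consecutive window starts, in samples. The
#'   default is 32 for W <= 256 and 64 for W = 512.
#' @param n_ch Horizontal channels kept after decimation (4, 8 or 16).
#' @param n_cv Vertical channels (fixed at 8 for the 16 x 8 layout).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_size, skip_step = if (window_size >= 512) 64L else 32L,
                        n_ch = 16L, n_cv = 8L) {
  if (window_size < 1L) stopf("window size must be >= 1")
  if (skip_step < 1L) stopf("skip step must be >= 1")
  structure(list(window_size = as.integer(window_size), skip_step = as.integer(skip_step),
                 n_ch = as.integer(n_ch), n_cv = as.integer(n_cv)),
            class = "window_spec")
}

#' Full-wave rectification
#'
#' @param x Numeric vector, matrix or `emg_session`.
#' @return Elementwise absolute value, same shape (sessions keep metadata).
#' @export
rectify <- function(x) {
  if (inherits(x, "emg_session")) {
    x$emg <- abs(x$emg)
    x
  } else {
    abs(x)
  }
}

#' Low-pass Butterworth envelope filter
#'
#' Applies a low-pass Butterworth filter independently to each channel.
#' The default is a causal single pass of a first-order filter with unit DC
#' gain; a zero-phase two-pass variant is available through the config.
#'
#' @param x Numeric vector, matrix (samples x channels) or `emg_session`.
#' @param cfg A [norm_config()].
#' @param fs Sampling frequency in Hz (taken from the session if omitted).
#' @return Filtered data of the same shape.
#' @export
envelope_filter <- function(x, cfg = norm_config(), fs = NULL) {
  if (inherits(x, "emg_session")) {
    fs <- x$fs
    x$emg <- envelope_filter(x$emg, cfg, fs)
    return(x)
  }
  if (is.null(fs)) stopf("fs is required when filtering plain data")
  if (cfg$cutoff_hz >= fs / 2) stopf("cutoff %g Hz is at or above Nyquist (%g Hz)", cfg$cutoff_hz, fs / 2)
  bf <- signal::butter(cfg$filter_order, cfg$cutoff_hz / (fs / 2), type = "low")
  apply_one <- function(v) {
    if (cfg$zero_phase) signal::filtfilt(bf, v) else as.numeric(signal::filter(bf, v))
  }
  if (is.matrix(x)) {
    for (ch in seq_len(ncol(x))) x[, ch] <- apply_one(x[, ch])
    x
  } else {
    apply_one(x)
  }
}

#' Mu-law companding normalisation
#'
#' `F(x) = sign(x) * log(1 + mu * |x|) / log(1 + mu)`: an odd, strictly
#' monotone map of `[-1, 1]` onto itself that expands small amplitudes.
#' Inputs must be pre-scaled to `[-1, 1]`.
#'
#' @param x Numeric data in `[-1, 1]`.
#' @param mu Companding parameter, > 0.
#' @return Companded data, same shape.
#' @export
mu_law_normalize <- function(x, mu = 255) {
  if (mu <= 0) stopf("mu must be positive")
  if (any(abs(x) > 1 + 1e-8, na.rm = TRUE))
    stopf("mu-law input must be pre-scaled to [-1, 1] (max |x| = %.3g)", max(abs(x)))
  sign(x) * log1p(mu * pmin(abs(x), 1)) / log1p(mu)
}

#' Remove rest intervals
#'
#' Drops all samples labelled as rest (label 0). Window segmentation later
#' respects (gesture, repetition) run boundaries, so windows never straddle
#' the seams this creates.
#'
#' @param session An `emg_session`.
#' @return The session without rest samples.
#' @export
remove_rest <- function(session) {
  if (!inherits(session, "emg_session")) stopf("session must be an emg_session")
  keep <- session$label != 0L
  if (!any(keep)) {
    warnf("session contains only rest samples; returning an empty session")
  }
  session$emg <- session$emg[keep, , drop = FALSE]
  session$label <- session$label[keep]
  session$repetition <- session$repetition[keep]
  session
}

#' Decimate electrode rows
#'
#' Keeps all, every 2nd, or every 4th row of the stacked electrode grid
#' (rows 0, 2, 4, ... or 0, 4, 8, ... 0-based), reducing the horizontal
#' channel count 16 -> 8 -> 4 while the 8 vertical channels are untouched.
#'
#' @param session An `emg_session`.
#' @param fraction One of 1, 1/2, 1/4.
#' @return The decimated session (grid rows reduced accordingly).
#' @export
select_channels <- function(session, fraction = 1) {
  if (!inherits(session, "emg_session")) stopf("session must be an emg_session")
  step <- if (isTRUE(all.equal(fraction, 1))) 1L
          else if (isTRUE(all.equal(fraction, 1 / 2))) 2L
          else if (isTRUE(all.equal(fraction, 1 / 4))) 4L
          else stopf("supported channel fractions are 1, 1/2 and 1/4")
  if (step == 1L) return(session)
  rows <- session$grid[1]; cols <- session$grid[2]
  if (rows %% step != 0L) stopf("fraction 1/%d does not divide the %d grid rows", step, rows)
  keep_rows <- seq(1L, rows, by = step)
  keep <- as.vector(t(outer(keep_rows - 1L, seq_len(cols), function(r, c) r * cols + c)))
  session$emg <- session$emg[, keep, drop = FALSE]
  session$grid <- c(length(keep_rows), cols)
  session
}

# Contiguous runs of constant (label, repetition) in a rest-free session.
session_segments <- function(session) {
  n <- length(session$label)
  if (n == 0L) return(data.frame(gesture = integer(0), repetition = integer(0),
                                 start = integer(0), end = integer(0)))
  key <- paste(session$label, session$repetition)
  brk <- c(TRUE, key[-1] != key[-n])
  starts <- which(brk)
  ends <- c(starts[-1] - 1L, n)
  data.frame(gesture = session$label[starts], repetition = session$repetition[starts],
             start = starts, end = ends)
}

#' Segment a rest-free session into windows
#'
#' Within every contiguous (gesture, repetition) run of length `Lseg`, emits
#' `floor((Lseg - W) / skip) + 1` windows whose starts are multiples of the
#' skip step (0-based, half-open `[start, start + W)`). Each window carries
#' the run's gesture and repetition ids. Windows are stored flattened with
#' axis order (time, horizontal channel, vertical channel).
#'
#' @param session A rest-free `emg_session` (see [remove_rest()]).
#' @param spec A [window_spec()]; `n_ch`/`n_cv` must match the session grid.
#' @return An object of class `emg_windows` with fields `x` (n x (W * n_ch *
#'   n_cv) matrix), `labels`, `repetitions`, and the spec.
#' @export
segment_windows <- function(session, spec) {
  if (!inherits(session, "emg_session")) stopf("session must be an emg_session")
  if (!inherits(spec, "window_spec")) stopf("spec must be a window_spec")
  if (any(session$label == 0L)) stopf("segment_windows expects a rest-free session; call remove_rest() first")
  rows <- session$grid[1]; cols <- session$grid[2]
  if (spec$n_ch != rows || spec$n_cv != cols)
    stopf("window spec %d x %d does not match the session grid %d x %d",
          spec$n_ch, spec$n_cv, rows, cols)
  W <- spec$window_size; skip <- spec$skip_step
  # reorder session channels (row-major (r, v)) to (ch fast within cv) blocks
  perm <- as.vector(vapply(seq_len(cols), function(v) (seq_len(rows) - 1L) * cols + v,
                           integer(rows)))
  segs <- session_segments(session)
  counts <- pmax(0L, (segs$end - segs$start + 1L - W) %/% skip + 1L)
  counts[(segs$end - segs$start + 1L) < W] <- 0L
  n <- sum(counts)
  if (n == 0L) {
    warnf("window size %d exceeds every segment length; empty dataset", W)
    return(structure(list(x = matrix(0, 0, W * rows * cols), labels = integer(0),
                          repetitions = integer(0), spec = spec),
                     class = "emg_windows"))
  }
  x <- matrix(0, nrow = n, ncol = W * rows * cols)
  labels <- integer(n); repetitions <- integer(n)
  i <- 0L
  for (s in seq_len(nrow(segs))) {
    if (counts[s] == 0L) next
    starts <- segs$start[s] + skip * (seq_len(counts[s]) - 1L)
    for (st in starts) {
      i <- i + 1L
      x[i, ] <- as.vector(session$emg[st:(st + W - 1L), perm])
      labels[i] <- segs$gesture[s]
      repetitions[i] <- segs$repetition[s]
    }
  }
  structure(list(x = x, labels = labels, repetitions = repetitions, spec = spec),
            class = "emg_windows")
}

#' @export
print.emg_windows <- function(x, ...) {
  cat(sprintf("windowed HD-sEMG dataset: %d windows of %d x %d x %d (W x N_ch x N_cv)\n",
              nrow(x$x), x$spec$window_size, x$spec$n_ch, x$spec$n_cv))
  cat(sprintf("  gestures: %d, repetitions: %d\n",
              length(unique(x$labels)), length(unique(x$repetitions))))
  invisible(x)
}

# Reshape one flattened window back to its (W, n_ch, n_cv) array.
window_array <- function(dataset, i) {
  array(dataset$x[i, ], dim = c(dataset$spec$window_size, dataset$spec$n_ch, dataset$spec$n_cv))
}

#' Preprocess a session into a fold-ready windowed dataset
#'
#' The fixed pipeline: rectify -> envelope filter -> scale to `[-1, 1]` ->
#' mu-law companding -> rest removal -> channel decimation -> windowing.
#'
#' @param session An `emg_session`.
#' @param norm A [norm_config()].
#' @param window_size,skip_step Window parameters (see [window_spec()]).
#' @param channel_fraction 1, 1/2 or 1/4 (see [select_channels()]).
#' @param scale_max Optional per-channel scaling maxima (e.g. from a training
#'   portion); defaults to each channel's own max |x| after filtering.
#' @return An `emg_windows` dataset; the scaling maxima used are attached as
#'   attribute `scale_max`.
#' @export
preprocess_session <- function(session, norm = norm_config(), window_size = 64L,
                               skip_step = NULL, channel_fraction = 1,
                               scale_max = NULL) {
  s <- rectify(session)
  s <- envelope_filter(s, norm)
  if (is.null(scale_max)) {
    scale_max <- if (norm$scale == "per_channel") apply(abs(s$emg), 2L, max)
                 else rep(max(abs(s$emg)), ncol(s$emg))
  }
  scale_max[scale_max == 0] <- 1
  s$emg <- sweep(s$emg, 2L, scale_max, `/`)
  s$emg[s$emg > 1] <- 1
  s$emg[s$emg < -1] <- -1
  s$emg <- mu_law_normalize(s$emg, norm$mu)
  s <- remove_rest(s)
  s <- select_channels(s, channel_fraction)
  spec <- window_spec(window_size,
                      skip_step %||% (if (window_size >= 512) 64L else 32L),
                      n_ch = s$grid[1], n_cv = s$grid[2])
  out <- segment_windows(s, spec)
  attr(out, "scale_max") <- scale_max
  out
}

#' Equivalent moving-average window of a low-pass cutoff
#'
#' A moving-average filter has cutoff `f = 0.443 / T_w`; solving for the
#' window length at cutoff `f` gives `T_w = 0.443 / f`.
#'
#' @param cutoff_hz Low-pass cutoff frequency in Hz.
#' @return Equivalent moving-average window length in milliseconds.
#' @export
moving_average_window_ms <- function(cutoff_hz) {
  if (any(cutoff_hz <= 0)) stopf("cutoff must be positive")
  1000 * 0.443 / cutoff_hz
}

#' Raw (unfiltered) windowed dataset
#'
#' Windows the raw signal with the same rest removal, channel decimation
#' and segmentation as [preprocess_session()] but without rectification,
#' envelope filtering or companding. Window boundaries therefore align
#' one-to-one with the preprocessed dataset of the same spec; used by the
#' decomposition path, which needs the unenveloped waveforms.
#'
#' @inheritParams preprocess_session
#' @return An `emg_windows` dataset of raw signal windows.
#' @export
raw_window_dataset <- function(session, window_size = 512L, skip_step = NULL,
                               channel_fraction = 1) {
  s <- remove_rest(session)
  s <- select_channels(s, channel_fraction)
  spec <- window_spec(window_size,
                      skip_step %||% (if (window_size >= 512) 64L else 32L),
                      n_ch = s$grid[1], n_cv = s$grid[2])
  segment_windows(s, spec)
}
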