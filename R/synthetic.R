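#' Biphasic motor-unit action-potential template
#'
#' Default temporal MUAP shape: the first derivative of a Gaussian, a biphasic
#' waveform that fits inside the 20-sample spike-triggered-averaging window.
#'
#' @param length Template support in samples (must be <= 20).
#' @param sigma Width of the underlying Gaussian, in samples.
#' @param amplitude Peak absolute amplitude of the template.
#' @return Numeric vector of `length` samples with peak |value| = `amplitude`.
#' @export
mu_template <- function(length = 15L, sigma = 2, amplitude = 1) {
  if (length > 20L) stopf("template length %d exceeds the 20-sample STA window", length)
  t <- seq_len(length) - (length + 1) / 2
  w <- -t * exp(-t^2 / (2 * sigma^2))
  w / max(abs(w)) * amplitude
}

#' Motor-unit specification
#'
#' Describes one simulated motor unit: where on the electrode grid its
#' territory sits, how widely its action potential spreads spatially, its
#' temporal MUAP template, and its firing statistics.
#'
#' @param center Grid coordinate `c(row, col)` of the territory centre
#'   (fractional values allowed).
#' @param spread Standard deviation (in electrode pitches) of the Gaussian
#'   spatial profile; must be positive.
#' @param template Temporal MUAP template, at most 20 samples.
#' @param mean_rate Mean firing rate in firings per second; must be positive.
#' @param isi_cov Coefficient of variation of the inter-spike interval.
#' @return An object of class `mu_spec`.
#' @export
motor_unit_spec <- function(center, spread = 1.5, template = mu_template(),
                            mean_rate = 20, isi_cov = 0.15) {
  if (length(center) != 2L) stopf("center must be c(row, col)")
  if (spread <= 0) stopf("spatial spread must be positive")
  if (mean_rate <= 0) stopf("mean firing rate must be positive")
  if (length(template) > 20L) stopf("temporal template longer than the 20-sample STA window")
  if (isi_cov < 0) stopf("isi_cov must be non-negative")
  structure(list(center = as.numeric(center), spread = spread,
                 template = as.numeric(template), mean_rate = mean_rate,
                 isi_cov = isi_cov),
            class = "mu_spec")
}

#' Synthetic HD-sEMG session specification
#'
#' Defines a full recording session layout: gestures times repetitions with
#' rest intervals in between, a pool of motor units, and a gesture-by-unit
#' activation matrix of firing-rate multipliers.
#'
#' @param motor_units List of [motor_unit_spec()] objects.
#' @param activation Gesture-by-unit matrix with entries in `[0, 1]`; row `g`
#'   scales each unit's mean rate during gesture `g`. Every gesture must
#'   activate at least one unit.
#' @param n_repetitions Repetitions per gesture (the dataset layout uses 5).
#' @param repetition_duration Active duration of one repetition, seconds.
#' @param rest_duration Rest between active segments, seconds (default 5).
#' @param noise_std Standard deviation of additive Gaussian sensor noise (V).
#' @param grid Electrode grid as `c(rows, cols)`; default the stacked 16 x 8.
#' @param fs Sampling frequency in Hz (default 2048).
#' @param seed Integer seed making the session reproducible.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(motor_units, activation,
                         n_repetitions = 5L, repetition_duration = 4,
                         rest_duration = 5, noise_std = 0.05,
                         grid = c(16L, 8L), fs = 2048, seed = 1L) {
  if (length(motor_units) == 0L) stopf("at least one motor unit is required")
  if (!all(vapply(motor_units, inherits, logical(1), "mu_spec")))
    stopf("motor_units must be a list of motor_unit_spec objects")
  activation <- as.matrix(activation)
  if (ncol(activation) != length(motor_units))
    stopf("activation must have one column per motor unit")
  if (any(activation < 0 | activation > 1)) stopf("activation entries must lie in [0, 1]")
  if (any(rowSums(activation > 0) == 0L)) stopf("every gesture must activate at least one motor unit")
  if (repetition_duration <= 0 || rest_duration < 0) stopf("durations must be positive")
  if (fs <= 0) stopf("sampling frequency must be positive")
  structure(list(motor_units = motor_units, activation = activation,
                 n_gestures = nrow(activation), n_repetitions = as.integer(n_repetitions),
                 repetition_duration = repetition_duration, rest_duration = rest_duration,
                 noise_std = noise_std, grid = as.integer(grid), fs = fs,
                 seed = as.integer(seed)),
            class = "session_spec")
}

# Gaussian spatial profile of a motor unit over the electrode grid.
# Channels are enumerated row-major: channel = (row - 1) * cols + col.
mu_spatial_weights <- function(mu, grid) {
  rows <- grid[1]; cols <- grid[2]
  rr <- rep(seq_len(rows), each = cols)
  cc <- rep(seq_len(cols), times = rows)
  d2 <- (rr - mu$center[1])^2 + (cc - mu$center[2])^2
  exp(-d2 / (2 * mu$spread^2))
}

# Draw one renewal spike train on [from, to] (sample indices) at `rate` Hz.
# Gaussian inter-spike intervals truncated at 1 sample.
draw_spike_train <- function(from, to, rate, isi_cov, fs) {
  if (rate <= 0 || to < from) return(integer(0))
  mean_isi <- fs / rate
  t <- from + stats::runif(1, 0, mean_isi)
  out <- numeric(0)
  while (t <= to) {
    out <- c(out, t)
    isi <- max(1, stats::rnorm(1, mean_isi, isi_cov * mean_isi))
    t <- t + isi
  }
  as.integer(round(out))
}

#' Generate a synthetic HD-sEMG session
#'
#' Builds a labelled multichannel recording as a convolutive mixture: each
#' motor unit's temporal template, scaled per channel by a Gaussian spatial
#' profile around its territory centre, is placed at the firing instants of a
#' renewal spike train, and Gaussian sensor noise is added. Rest intervals
#' separate active segments and contain noise only.
#'
#' @param spec A [session_spec()].
#' @return A list with components `session` (an `emg_session`: matrix `emg` of
#'   size T x channels, per-sample `label` and `repetition`, `fs`, `grid`) and
#'   `truth` (ground truth: `spike_trains[[gesture]][[repetition]][[unit]]`
#'   absolute firing indices, `templates` channel-by-time per unit, per-sample
#'   labels, and the segment table).
#' @export
generate_session <- function(spec) {
  if (!inherits(spec, "session_spec")) stopf("spec must be a session_spec")
  set.seed(spec$seed)
  fs <- spec$fs
  rows <- spec$grid[1]; cols <- spec$grid[2]
  n_chan <- rows * cols
  G <- spec$n_gestures; R <- spec$n_repetitions
  rep_len <- round(spec$repetition_duration * fs)
  rest_len <- round(spec$rest_duration * fs)
  n_seg <- G * R
  total <- n_seg * (rest_len + rep_len) + rest_len

  label <- integer(total)
  repetition <- integer(total)
  segments <- data.frame(gesture = integer(n_seg), repetition = integer(n_seg),
                         start = integer(n_seg), end = integer(n_seg))
  pos <- 0L
  k <- 0L
  for (g in seq_len(G)) {
    for (r in seq_len(R)) {
      k <- k + 1L
      pos <- pos + rest_len
      segments$gesture[k] <- g
      segments$repetition[k] <- r
      segments$start[k] <- pos + 1L
      segments$end[k] <- pos + rep_len
      label[(pos + 1L):(pos + rep_len)] <- g
      repetition[(pos + 1L):(pos + rep_len)] <- r
      pos <- pos + rep_len
    }
  }

  M <- length(spec$motor_units)
  emg <- matrix(0, nrow = total, ncol = n_chan)
  spike_trains <- lapply(seq_len(G), function(g)
    lapply(seq_len(R), function(r) vector("list", M)))
  templates <- vector("list", M)

  for (m in seq_len(M)) {
    mu <- spec$motor_units[[m]]
    w <- mu_spatial_weights(mu, spec$grid)
    tpl <- mu$template
    L <- length(tpl)
    offs <- seq_len(L) - 1L - (L %/% 2L)  # template centred on the spike
    templates[[m]] <- outer(w, tpl)       # channels x time
    drive <- numeric(total)
    for (k in seq_len(n_seg)) {
      g <- segments$gesture[k]; r <- segments$repetition[k]
      rate <- mu$mean_rate * spec$activation[g, m]
      if (rate <= 0) { spike_trains[[g]][[r]][[m]] <- integer(0); next }
      # keep the whole template inside the active segment
      lo <- segments$start[k] - min(offs)
      hi <- segments$end[k] - max(offs)
      sp <- draw_spike_train(lo, hi, rate, mu$isi_cov, fs)
      sp <- sp[sp >= lo & sp <= hi]
      spike_trains[[g]][[r]][[m]] <- sp
      if (length(sp) > 0L) {
        idx <- as.vector(outer(offs, sp, `+`))
        acc <- rowsum(rep(tpl, times = length(sp)), idx)
        drive[as.integer(rownames(acc))] <- drive[as.integer(rownames(acc))] + acc[, 1]
      }
    }
    nz <- which(drive != 0)
    if (length(nz) > 0L) emg[nz, ] <- emg[nz, ] + drive[nz] %o% w
  }

  if (spec$noise_std > 0) {
    for (ch in seq_len(n_chan)) emg[, ch] <- emg[, ch] + stats::rnorm(total, 0, spec$noise_std)
  }

  session <- new_session(emg, fs = fs, label = label, repetition = repetition,
                         grid = spec$grid, subject_id = "synthetic")
  truth <- list(spike_trains = spike_trains, templates = templates,
                label = label, repetition = repetition, segments = segments)
  list(session = session, truth = truth)
}

#' Construct a separable synthetic benchmark specification
#'
#' Builds a [session_spec()] whose gestures are distinguishable to a degree
#' controlled by `difficulty`: at 0 each gesture drives its own disjoint
#' subset of motor units; at 1 all gestures share the same activation row.
#' Intermediate values linearly blend the disjoint rows toward their mean.
#'
#' @param n_gestures Number of gestures (>= 2).
#' @param difficulty Real in `[0, 1]`; pairwise overlap of activation rows.
#' @param seed Integer seed (drives unit placement and the session itself).
#' @param units_per_gesture Motor units assigned to each gesture's subset.
#' @param n_repetitions,repetition_duration,rest_duration,noise_std,grid,fs
#'   Passed to [session_spec()].
#' @return A `session_spec`.
#' @export
make_separable_benchmark <- function(n_gestures, difficulty = 0, seed = 1L,
                                     units_per_gesture = 3L,
                                     n_repetitions = 5L, repetition_duration = 4,
                                     rest_duration = 5, noise_std = 0.05,
                                     grid = c(16L, 8L), fs = 2048) {
  if (n_gestures < 2L) stopf("a benchmark needs at least 2 gestures")
  if (difficulty < 0 || difficulty > 1) stopf("difficulty must lie in [0, 1]")
  set.seed(seed)
  M <- n_gestures * units_per_gesture
  rows <- grid[1]; cols <- grid[2]
  centers <- cbind(stats::runif(M, 1.5, rows - 0.5), stats::runif(M, 1.5, cols - 0.5))
  units <- lapply(seq_len(M), function(m)
    motor_unit_spec(center = centers[m, ],
                    spread = stats::runif(1, 1.2, 2.0),
                    template = mu_template(sigma = stats::runif(1, 1.5, 2.5)),
                    mean_rate = stats::runif(1, 15, 25),
                    isi_cov = 0.15))
  act <- matrix(0, n_gestures, M)
  for (g in seq_len(n_gestures)) {
    act[g, ((g - 1L) * units_per_gesture + 1L):(g * units_per_gesture)] <- 1
  }
  shared <- matrix(colMeans(act), n_gestures, M, byrow = TRUE)
  act <- (1 - difficulty) * act + difficulty * shared
  act <- act / max(act)
  session_spec(motor_units = units, activation = act,
               n_repetitions = n_repetitions,
               repetition_duration = repetition_duration,
               rest_duration = rest_duration, noise_std = noise_std,
               grid = grid, fs = fs, seed = seed)
}

#' Construct a benchmark separable only through motor-unit waveforms
#'
#' Builds a [session_spec()] in which every gesture drives the same motor
#' units at identical firing rates, but each gesture's units carry a
#' differently shaped temporal template whose mean absolute amplitude is
#' matched across gestures. The per-channel signal envelope is therefore
#' (in expectation) identical for all gestures, while the peak-to-peak MUAP
#' amplitude differs: envelope-based (macro) classification is near chance
#' and decomposition-based (micro) classification is informative.
#'
#' @param n_gestures Number of gestures (>= 2).
#' @param seed Integer seed.
#' @param n_units Motor units shared by all gestures.
#' @param n_repetitions,repetition_duration,rest_duration,noise_std,grid,fs
#'   Passed to [session_spec()].
#' @return A `session_spec` whose unit list holds `n_gestures * n_units`
#'   entries (one waveform variant per gesture) with a block-diagonal
#'   activation over waveform variants at shared territories.
#' @export
make_mu_pattern_benchmark <- function(n_gestures = 3L, seed = 1L, n_units = 4L,
                                      n_repetitions = 5L, repetition_duration = 3,
                                      rest_duration = 1, noise_std = 0.01,
                                      grid = c(8L, 8L), fs = 2048) {
  if (n_gestures < 2L) stopf("a benchmark needs at least 2 gestures")
  set.seed(seed)
  rows <- grid[1]; cols <- grid[2]
  centers <- cbind(stats::runif(n_units, 1.5, rows - 0.5),
                   stats::runif(n_units, 1.5, cols - 0.5))
  rates <- stats::runif(n_units, 15, 25)
  spreads <- stats::runif(n_units, 1.0, 1.5)
  sigmas <- seq(1.2, 3.0, length.out = n_gestures)   # waveform width per gesture
  target_mean_abs <- 0.35
  units <- list()
  for (g in seq_len(n_gestures)) {
    tpl <- mu_template(sigma = sigmas[g], amplitude = 1)
    tpl <- tpl * (target_mean_abs / mean(abs(tpl)))  # match mean |template|
    for (m in seq_len(n_units)) {
      units[[(g - 1L) * n_units + m]] <-
        motor_unit_spec(center = centers[m, ], spread = spreads[m],
                        template = tpl, mean_rate = rates[m], isi_cov = 0.15)
    }
  }
  act <- matrix(0, n_gestures, n_gestures * n_units)
  for (g in seq_len(n_gestures)) {
    act[g, ((g - 1L) * n_units + 1L):(g * n_units)] <- 1
  }
  session_spec(motor_units = units, activation = act,
               n_repetitions = n_repetitions,
               repetition_duration = repetition_duration,
               rest_duration = rest_duration, noise_std = noise_std,
               grid = grid, fs = fs, seed = seed)
}
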