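#' Decomposition configuration
#'
#' Parameters of the blind-source-separation stage that extracts motor-unit
#' spike trains from a windowed HD-sEMG signal.
#'
#' @param max_sources Maximum number of new-source extraction attempts (and
#'   hence of accepted sources) per window; default 7.
#' @param silhouette_threshold Acceptance threshold on the silhouette of the
#'   spike/baseline peak-amplitude split, on the raw `[-1, 1]` scale;
#'   default 0.92.
#' @param extension_factor Number of delayed copies appended per channel
#'   (R); default 10.
#' @param sta_window Spike-triggered-averaging window in samples; default 20.
#' @param sil_scale `"raw"` keeps the silhouette in `[-1, 1]`; `"unit"`
#'   maps it to `[0, 1]` via `(s + 1) / 2`.
#' @param n_ica_iter Skewness fixed-point iterations per source before the
#'   spike-triggered refinement.
#' @param refine_iter Maximum spike-triggered refinement iterations.
#' @param whiten_tol Signal-subspace truncation: eigenvalues below
#'   `whiten_tol` times the median eigenvalue are dropped during whitening
#'   (suppresses noise amplification along near-null directions).
#' @param seed Integer seed (initialisation and 2-means tie-breaks).
#' @return An object of class `decomp_config`.
#' @export
decomp_config <- function(max_sources = 7L, silhouette_threshold = 0.92,
                          extension_factor = 10L, sta_window = 20L,
                          sil_scale = c("raw", "unit"), n_ica_iter = 3L,
                          refine_iter = 20L, whiten_tol = 10,
                          seed = 1L) {
  if (max_sources < 1L) stopf("max_sources must be >= 1")
  if (silhouette_threshold <= 0 || silhouette_threshold >= 1)
    stopf("silhouette threshold must lie in (0, 1)")
  structure(list(max_sources = as.integer(max_sources),
                 silhouette_threshold = silhouette_threshold,
                 extension_factor = as.integer(extension_factor),
                 sta_window = as.integer(sta_window),
                 sil_scale = match.arg(sil_scale),
                 n_ica_iter = as.integer(n_ica_iter),
                 refine_iter = as.integer(refine_iter),
                 whiten_tol = whiten_tol, seed = as.integer(seed)),
            class = "decomp_config")
}

#' Extend and whiten a multichannel observation window
#'
#' Flattens the channels, appends `R` delayed copies of each (delays 1..R,
#' zero-padded at the start), removes the row means, and whitens with the
#' eigendecomposition of the covariance so the output has (numerically)
#' identity covariance. Near-zero eigenvalues are ridge-regularised.
#'
#' @param window `W x n_ch x n_cv` array, flattened window vector, or a
#'   `W x channels` matrix.
#' @param R Extension factor (number of delayed copies per channel).
#' @param dims Optional `c(W, n_ch, n_cv)` when `window` is a plain vector.
#' @param truncate Optional signal-subspace truncation: keep only
#'   eigendirections whose eigenvalue exceeds `truncate` times the median
#'   eigenvalue. `NULL` (default) whitens the full space with a ridge, so
#'   the output covariance is the identity.
#' @return List with `Z` (whitened extended observations, rows = kept
#'   components, columns = time), `whitening` (the transform), `means`,
#'   and `X` (the extended, demeaned, unwhitened matrix).
#' @export
extend_and_whiten <- function(window, R = 10L, dims = NULL, truncate = NULL) {
  xm <- window_to_matrix(window, dims)      # W x channels
  W <- nrow(xm); K <- ncol(xm)
  if (W <= R) stopf("window length %d must exceed the extension factor %d", W, R)
  X <- matrix(0, nrow = K * (R + 1L), ncol = W)
  for (j in 0:R) {
    rows <- j * K + seq_len(K)
    if (j == 0L) X[rows, ] <- t(xm)
    else X[rows, (j + 1L):W] <- t(xm[1:(W - j), , drop = FALSE])
  }
  mns <- rowMeans(X)
  X <- X - mns
  Cv <- (X %*% t(X)) / (W - 1L)
  eg <- eigen(Cv, symmetric = TRUE)
  lam <- eg$values
  if (is.null(truncate)) {
    ridge <- 1e-12 * max(lam)
    small <- lam < 1e-8 * max(lam)
    if (any(small)) warnf("covariance is rank deficient; %d eigenvalues regularised", sum(small))
    Wm <- diag(1 / sqrt(pmax(lam, 0) + ridge)) %*% t(eg$vectors)
  } else {
    # floor guards the noiseless case, where the median eigenvalue is ~0
    keep <- lam > max(truncate * stats::median(pmax(lam, 0)), 1e-10 * max(lam))
    Wm <- diag(1 / sqrt(lam[keep]), sum(keep)) %*% t(eg$vectors[, keep, drop = FALSE])
  }
  list(Z = Wm %*% X, whitening = Wm, means = mns, X = X)
}

window_to_matrix <- function(window, dims = NULL) {
  if (is.matrix(window)) return(window)
  if (is.array(window) && length(dim(window)) == 3L) {
    d <- dim(window)
    return(matrix(window, nrow = d[1], ncol = d[2] * d[3]))
  }
  if (!is.null(dims)) return(matrix(as.vector(window), nrow = dims[1]))
  stopf("window must be a matrix, a 3-D array, or a vector with dims supplied")
}

#' Silhouette of a two-cluster split
#'
#' Standard average silhouette of 1-D points under a binary assignment:
#' for each point, `(b - a) / max(a, b)` with `a` the mean distance to its
#' own cluster and `b` to the other; singleton clusters score 0 for that
#' point. Returns 0 if either cluster is empty.
#'
#' @param values Numeric vector (peak amplitudes).
#' @param assignment Logical or 0/1 vector: TRUE for the high (spike)
#'   cluster.
#' @param scale `"raw"` for `[-1, 1]`, `"unit"` for `(s + 1) / 2`.
#' @return Mean silhouette.
#' @export
silhouette_score <- function(values, assignment, scale = c("raw", "unit")) {
  scale <- match.arg(scale)
  assignment <- as.logical(assignment)
  n1 <- sum(assignment); n0 <- sum(!assignment)
  if (n1 == 0L || n0 == 0L) return(0)
  D <- abs(outer(values, values, `-`))
  s <- numeric(length(values))
  for (i in seq_along(values)) {
    own <- assignment == assignment[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(D[i, own]) else 0
    b <- mean(D[i, !(assignment == assignment[i])])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  out <- mean(s)
  if (scale == "unit") (out + 1) / 2 else out
}

# Local maxima of a non-negative sequence (strictly above the left
# neighbour, at least the right one).
find_peaks <- function(p) {
  n <- length(p)
  if (n < 3L) return(integer(0))
  which(p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n]) + 1L
}

# Split peak amplitudes into high/low clusters with 2-means; returns the
# logical high-cluster assignment.
split_peaks <- function(amps) {
  if (length(unique(amps)) < 2L) return(rep(FALSE, length(amps)))
  km <- suppressWarnings(stats::kmeans(amps, centers = range(amps), iter.max = 50L))
  amps >= min(amps[km$cluster == which.max(km$centers)])
}

#' Extract motor-unit spike trains from a whitened observation
#'
#' Deflationary source extraction on the whitened extended observations: up
#' to `max_sources` attempts, each initialised from the highest-activity
#' instant not yet used, sharpened by a few skewness fixed-point updates,
#' then refined by spike-triggered re-estimation (the separation vector is
#' repeatedly replaced by the mean whitened observation over the currently
#' detected spikes until the spike set stabilises). Spikes are detected by
#' peak picking on the squared positive source with a 2-means amplitude
#' split; a source is accepted only when the silhouette of that split
#' reaches the threshold. Duplicate sources (spike overlap > 50% with an
#' earlier accepted train after delay alignment) are discarded.
#'
#' @param white Output of [extend_and_whiten()] (or a whitened matrix).
#' @param config A [decomp_config()].
#' @return An object of class `mu_decomposition`: `spike_trains` (list of
#'   increasing sample-index vectors), `silhouettes`, `separation_vectors`,
#'   and `n_attempted`.
#' @export
extract_musts <- function(white, config = decomp_config()) {
  Z <- if (is.list(white)) white$Z else white
  n <- nrow(Z); Tn <- ncol(Z)
  empty <- structure(list(spike_trains = list(), silhouettes = numeric(0),
                          separation_vectors = matrix(0, n, 0), n_attempted = 0L),
                     class = "mu_decomposition")
  if (n == 0L) return(empty)   # no signal subspace survived whitening
  set.seed(config$seed)
  accepted_w <- matrix(0, n, 0)
  all_w <- matrix(0, n, 0)
  trains <- list(); sils <- numeric(0)
  energy <- colSums(Z * Z)
  blocked <- rep(FALSE, Tn)   # instants excluded from initialisation

  # deflate against every attempted source so repeated attempts explore
  # new directions
  deflate <- function(w) {
    if (ncol(all_w) > 0L) w <- as.vector(w - all_w %*% crossprod(all_w, w))
    nw <- sqrt(sum(w * w))
    if (nw < 1e-12) return(NULL)
    w / nw
  }
  block <- function(at, radius) {
    lo <- pmax(1L, at - radius); hi <- pmin(Tn, at + radius)
    for (i in seq_along(at)) blocked[lo[i]:hi[i]] <<- TRUE
  }
  # peak picking + 2-means split of one source estimate
  source_spikes <- function(w) {
    s <- crossprod(Z, w)[, 1]
    if (mean(s^3) < 0) { s <- -s; w <- -w }  # spikes point upward
    p <- s^2 * (s > 0)
    pk <- find_peaks(p)
    if (length(pk) < 4L) return(NULL)
    hi <- split_peaks(p[pk])
    if (sum(hi) < 2L || all(hi)) return(NULL)
    list(w = w, spikes = sort(pk[hi]), amps = p[pk], hi = hi)
  }

  n_attempted <- 0L
  for (it in seq_len(config$max_sources)) {
    # initialise from the highest-activity instant not yet tried or
    # explained by an accepted source
    cand <- which(!blocked)
    if (length(cand) == 0L) break
    t0 <- cand[which.max(energy[cand])]
    block(t0, 5L)
    n_attempted <- n_attempted + 1L
    w <- deflate(Z[, t0])
    if (is.null(w)) next
    # a few skewness fixed-point updates sharpen the source estimate
    for (k in seq_len(config$n_ica_iter)) {
      s <- crossprod(Z, w)[, 1]
      w_new <- deflate((Z %*% (s * s))[, 1] / Tn)
      if (is.null(w_new)) break
      w <- w_new
    }
    # seed spike set: strongest source peaks, excluding the self-peak of
    # the initialisation instant (w correlates perfectly with Z[, t0])
    s <- crossprod(Z, w)[, 1]
    if (mean(s^3) < 0) s <- -s
    p <- s^2 * (s > 0)
    pk <- find_peaks(p)
    pk <- pk[abs(pk - t0) > 2L]
    if (length(pk) < 4L) { all_w <- cbind(all_w, w); next }
    spikes <- sort(pk[order(p[pk], decreasing = TRUE)][1:min(10L, length(pk))])
    # spike-triggered refinement until the detected set stabilises
    det <- NULL
    for (k in seq_len(config$refine_iter)) {
      w_new <- deflate(rowMeans(Z[, spikes, drop = FALSE]))
      if (is.null(w_new)) break
      det_new <- source_spikes(w_new)
      if (is.null(det_new)) break
      stable <- length(det_new$spikes) == length(spikes) &&
        all(det_new$spikes == spikes)
      det <- det_new
      spikes <- det_new$spikes
      if (stable) break
    }
    if (is.null(det)) { all_w <- cbind(all_w, w); next }
    all_w <- cbind(all_w, det$w)           # deflate against every attempt
    if (length(det$spikes) < 3L) next
    sil <- silhouette_score(det$amps, det$hi, scale = config$sil_scale)
    if (sil < config$silhouette_threshold) next
    if (is_duplicate_train(det$spikes, trains)) next
    trains[[length(trains) + 1L]] <- det$spikes
    sils <- c(sils, sil)
    accepted_w <- cbind(accepted_w, det$w)
    block(det$spikes, 2L)   # future inits target unexplained activity
  }
  structure(list(spike_trains = trains, silhouettes = sils,
                 separation_vectors = accepted_w, n_attempted = n_attempted),
            class = "mu_decomposition")
}

# TRUE when, after optimal alignment (extension makes delayed replicas of
# the same unit equally valid sources), > 50% of the spikes coincide with an
# earlier accepted train at +/-1 sample.
is_duplicate_train <- function(spikes, trains, max_shift = 20L) {
  for (tr in trains) {
    if (spike_train_f1(spikes, tr, tol = 1L, max_shift = max_shift)$f1 > 0.5) return(TRUE)
  }
  FALSE
}

#' @export
print.mu_decomposition <- function(x, ...) {
  cat(sprintf("motor-unit decomposition: %d accepted source(s) of %d attempted\n",
              length(x$spike_trains), x$n_attempted))
  if (length(x$spike_trains) > 0L) {
    cat(sprintf("  spikes per source: %s; silhouettes: %s\n",
                paste(lengths(x$spike_trains), collapse = ", "),
                paste(sprintf("%.3f", x$silhouettes), collapse = ", ")))
  }
  invisible(x)
}

#' Spike-triggered averaging
#'
#' Estimates the per-channel MUAP template of one motor unit by averaging
#' `sta_window`-sample segments of the raw signal centred on each firing
#' (offsets `-sta_window/2 .. sta_window/2 - 1`). Segments clipped by the
#' window boundary are dropped; channels with no usable spike get a zero
#' template and a flag.
#'
#' @param window Raw (unenveloped) `W x n_ch x n_cv` array, matrix, or
#'   vector with `dims`.
#' @param spikes Firing sample indices within the window.
#' @param sta_window Averaging window length in samples (default 20).
#' @param dims Optional dimensions for a flattened `window`.
#' @return `channels x sta_window` matrix of templates; attributes
#'   `"n_used"` (spikes averaged) and `"dims"`.
#' @export
spike_triggered_average <- function(window, spikes, sta_window = 20L, dims = NULL) {
  if (length(spikes) == 0L) stopf("spike-triggered averaging needs at least one spike")
  xm <- window_to_matrix(window, dims)
  W <- nrow(xm)
  offs <- seq_len(sta_window) - 1L - (sta_window %/% 2L)
  spikes <- unique(as.integer(spikes))
  ok <- spikes + min(offs) >= 1L & spikes + max(offs) <= W
  used <- spikes[ok]
  tpl <- matrix(0, nrow = ncol(xm), ncol = sta_window)
  if (length(used) > 0L) {
    for (t in used) tpl <- tpl + t(xm[t + offs, , drop = FALSE])
    tpl <- tpl / length(used)
  } else {
    warnf("no spike leaves the STA window inside the signal; zero template")
  }
  attr(tpl, "n_used") <- length(used)
  attr(tpl, "dims") <- if (is.array(window) && length(dim(window)) == 3L) dim(window)[2:3] else dims[2:3]
  tpl
}

#' Peak-to-peak MUAP image
#'
#' Per channel, the max minus min of the STA template: a non-negative
#' `n_ch x n_cv` map of how strongly the unit projects to each electrode.
#'
#' @param templates `channels x sta_window` template matrix from
#'   [spike_triggered_average()].
#' @param dims Grid dimensions `c(n_ch, n_cv)`; taken from the template
#'   attribute when present.
#' @return `n_ch x n_cv` matrix of peak-to-peak amplitudes.
#' @export
peak_to_peak_image <- function(templates, dims = attr(templates, "dims")) {
  p2p <- apply(templates, 1L, function(v) max(v) - min(v))
  if (is.null(dims)) stopf("grid dimensions are required to shape the image")
  matrix(p2p, nrow = dims[1], ncol = dims[2])
}

#' Decompose one raw window into motor units and MUAP images
#'
#' Convenience wrapper: extension/whitening, source extraction, STA on the
#' raw window, and peak-to-peak imaging for every accepted unit.
#'
#' @param window Raw `W x n_ch x n_cv` array (or matrix/vector with `dims`).
#' @param config A [decomp_config()].
#' @param dims Optional dimensions for flattened input.
#' @return The `mu_decomposition` with an extra `images` field (list of
#'   `n_ch x n_cv` matrices) and `templates`.
#' @export
decompose_window <- function(window, config = decomp_config(), dims = NULL) {
  if (is.array(window) && length(dim(window)) == 3L) dims <- dim(window)
  if (is.null(dims) && is.matrix(window)) dims <- c(nrow(window), ncol(window), 1L)
  white <- extend_and_whiten(window, R = config$extension_factor, dims = dims,
                             truncate = config$whiten_tol)
  dec <- extract_musts(white, config)
  dec$templates <- lapply(dec$spike_trains, function(sp)
    spike_triggered_average(window, sp, config$sta_window, dims = dims))
  dec$images <- lapply(dec$templates, function(tpl)
    peak_to_peak_image(tpl, dims = dims[2:3]))
  dec
}

#' Spike-train agreement (F1 after global-shift alignment)
#'
#' Extended/whitened source separation recovers spike trains only up to a
#' small constant delay, so the estimate is first aligned to the reference
#' by the integer shift that maximises matches; the F1 score then counts a
#' hit when an estimated spike lands within `tol` samples of an unmatched
#' reference spike.
#'
#' @param est,truth Spike sample-index vectors.
#' @param tol Matching tolerance in samples (default 1).
#' @param max_shift Alignment search range in samples.
#' @return List with `f1`, `shift`, `n_matched`.
#' @export
spike_train_f1 <- function(est, truth, tol = 1L, max_shift = 20L) {
  if (length(est) == 0L || length(truth) == 0L)
    return(list(f1 = 0, shift = 0L, n_matched = 0L))
  best <- list(f1 = 0, shift = 0L, n_matched = 0L)
  for (sh in -max_shift:max_shift) {
    e <- sort(est + sh)
    m <- 0L; i <- 1L; j <- 1L
    while (i <= length(e) && j <= length(truth)) {
      d <- e[i] - truth[j]
      if (abs(d) <= tol) { m <- m + 1L; i <- i + 1L; j <- j + 1L }
      else if (d < 0) i <- i + 1L
      else j <- j + 1L
    }
    f1 <- 2 * m / (length(est) + length(truth))
    if (f1 > best$f1) best <- list(f1 = f1, shift = sh, n_matched = m)
  }
  best
}

#' Decompose every window of a raw dataset
#'
#' Runs [decompose_window()] on each window of a raw windowed dataset and
#' collects the per-window peak-to-peak MUAP images for the micro path.
#'
#' @param dataset An `emg_windows` dataset of raw windows (see
#'   [raw_window_dataset()]).
#' @param config A [decomp_config()].
#' @return List with `images` (per-window lists of `n_ch x n_cv` matrices,
#'   possibly empty) and `n_sources` (accepted source count per window).
#' @export
decompose_dataset <- function(dataset, config = decomp_config()) {
  n <- nrow(dataset$x)
  dims <- c(dataset$spec$window_size, dataset$spec$n_ch, dataset$spec$n_cv)
  images <- vector("list", n)
  n_sources <- integer(n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    dec <- decompose_window(dataset$x[i, ], cfg_i, dims = dims)
    images[[i]] <- dec$images
    n_sources[i] <- length(dec$spike_trains)
  }
  list(images = images, n_sources = n_sources)
}
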