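#' TD-PSD configuration
#'
#' @param lambda Dimensionless exponent applied to the spectral-moment
#'   roots (default 0.1, per the feature family's source literature).
#' @param derivative_mode `"as_printed"` follows the published root
#'   definitions literally (under which the third and fourth roots coincide
#'   and the m3 - m2 feature is identically zero); `"ordered"` maps the five
#'   roots to difference orders 0..4, removing the degeneracy.
#' @return An object of class `tdpsd_config`.
#' @export
tdpsd_config <- function(lambda = 0.1, derivative_mode = c("as_printed", "ordered")) {
  if (lambda <= 0) stopf("lambda must be positive")
  structure(list(lambda = lambda, derivative_mode = match.arg(derivative_mode)),
            class = "tdpsd_config")
}

#' Time-domain power-spectral-density moment features
#'
#' Estimates spectral moments m0..m4 from time-domain root statistics of a
#' channel: via Parseval's theorem the signal power equals the integrated
#' spectrum, and powers of successive discrete derivatives estimate higher
#' spectral moments. Each root `r` is mapped to `m = r^lambda / lambda` and
#' the feature set is `{m0, m1 - m0, m2, m3 - m2, m4 - m3}`.
#'
#' In `as_printed` mode the third root repeats the second-derivative RMS,
#' making `m3 - m2` identically zero; `ordered` mode uses difference orders
#' 0 through 4.
#'
#' @param x Numeric channel signal (length >= 4).
#' @param config A [tdpsd_config()].
#' @return Named numeric vector of the 5 features.
#' @export
tdpsd_features <- function(x, config = tdpsd_config()) {
  N <- length(x)
  if (N < 4L) stopf("TD-PSD needs at least 4 samples (third difference)")
  lam <- config$lambda
  rms_over_N <- function(v) sqrt(sum(v * v) / N)   # divisor N as printed
  d1 <- diff(x); d2 <- diff(d1); d3 <- diff(d2); d4 <- diff(d3)
  if (config$derivative_mode == "as_printed") {
    roots <- c(rms_over_N(x), rms_over_N(d1), rms_over_N(d2),
               rms_over_N(d2), rms_over_N(d3))
  } else {
    roots <- c(rms_over_N(x), rms_over_N(d1), rms_over_N(d2),
               rms_over_N(d3), rms_over_N(d4))
  }
  m <- ifelse(roots > 0, roots^lam / lam, 0)
  c(m0 = m[1], dm1 = m[2] - m[1], m2 = m[3], dm3 = m[4] - m[3], dm4 = m[5] - m[4])
}

#' Classical time-domain features
#'
#' Root mean square, zero crossings (strict sign changes), slope sign
#' changes (strict), and waveform length (total variation).
#'
#' @param x Numeric channel signal (length >= 3).
#' @return Named numeric vector `c(rms, zc, ssc, wl)`.
#' @export
classical_features <- function(x) {
  N <- length(x)
  if (N < 3L) stopf("classical features need at least 3 samples")
  sgn <- sign(x)
  zc <- sum(sgn[-N] * sgn[-1] < 0)
  dx <- diff(x)
  sd_ <- sign(dx)
  ssc <- sum(sd_[-length(sd_)] * sd_[-1] < 0)
  c(rms = sqrt(mean(x * x)), zc = zc, ssc = ssc, wl = sum(abs(dx)))
}

# Feature matrix for a windowed dataset: features per channel, concatenated
# over the n_ch x n_cv channels.
window_features <- function(dataset, feature_set = c("tdpsd", "classical"),
                            config = tdpsd_config()) {
  feature_set <- match.arg(feature_set)
  W <- dataset$spec$window_size
  K <- dataset$spec$n_ch * dataset$spec$n_cv
  nf <- if (feature_set == "tdpsd") 5L else 4L
  out <- matrix(0, nrow(dataset$x), nf * K)
  for (i in seq_len(nrow(dataset$x))) {
    xm <- matrix(dataset$x[i, ], nrow = W)
    f <- apply(xm, 2L, function(ch)
      if (feature_set == "tdpsd") tdpsd_features(ch, config) else classical_features(ch))
    out[i, ] <- as.vector(f)
  }
  out
}

# Regularised LDA fallback for singular within-class covariances.
fit_lda_safe <- function(X, y) {
  tryCatch(MASS::lda(X, grouping = factor(y)),
           error = function(e) {
             warnf("within-class covariance singular; ridge-regularised LDA fallback")
             Xj <- X + matrix(stats::rnorm(length(X), 0, 1e-6 * max(1, stats::sd(X))),
                              nrow(X))
             MASS::lda(Xj, grouping = factor(y))
           })
}

#' Fit and evaluate a feature-based baseline classifier
#'
#' Extracts TD-PSD (`*-V1`) or classical (`*-V2`) features per window,
#' standardises them with training-fold statistics, fits an SVM (RBF) or
#' LDA per fold, and evaluates with the same repetition-wise folds as the
#' deep models.
#'
#' @param dataset An `emg_windows` dataset.
#' @param kind `"svm"` or `"lda"`.
#' @param feature_set `"tdpsd"` or `"classical"`.
#' @param folds A fold object from [repetition_folds()]; defaults to the
#'   dataset's repetitions (pass the shared object to guarantee identical
#'   splits across models).
#' @param tdpsd A [tdpsd_config()].
#' @return An `emgvit_report` with attribute `"folds"`.
#' @export
fit_baseline <- function(dataset, kind = c("svm", "lda"),
                         feature_set = c("tdpsd", "classical"),
                         folds = repetition_folds(dataset$repetitions),
                         tdpsd = tdpsd_config()) {
  kind <- match.arg(kind); feature_set <- match.arg(feature_set)
  F <- window_features(dataset, feature_set, tdpsd)
  if (any(!is.finite(F))) stopf("non-finite feature values")
  y <- as.integer(dataset$labels)
  C <- max(y)
  counts <- matrix(0, C, C)
  fold_acc <- numeric(length(folds))
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    mu <- colMeans(F[f$train, , drop = FALSE])
    sdv <- apply(F[f$train, , drop = FALSE], 2L, stats::sd)
    keep <- sdv > 1e-12 & is.finite(sdv)   # constant features carry no signal
    Tr <- sweep(sweep(F[f$train, keep, drop = FALSE], 2L, mu[keep]), 2L, sdv[keep], `/`)
    Te <- sweep(sweep(F[f$test, keep, drop = FALSE], 2L, mu[keep]), 2L, sdv[keep], `/`)
    ytr <- y[f$train]
    pred <- if (kind == "svm") {
      fit <- e1071::svm(Tr, factor(ytr, levels = seq_len(C)), kernel = "radial")
      as.integer(as.character(predict(fit, Te)))
    } else {
      fit <- fit_lda_safe(Tr, ytr)
      as.integer(as.character(predict(fit, Te)$class))
    }
    truth <- y[f$test]
    fold_acc[k] <- mean(pred == truth)
    counts <- counts + confusion_counts(truth, pred, C)
  }
  rep_ <- eval_report(fold_acc, counts, C)
  attr(rep_, "folds") <- folds
  rep_
}

# ---- 3D CNN baseline --------------------------------------------------------

#' 3D CNN baseline configuration
#'
#' Two 3D convolution layers (16 then 32 filters of size 5 x 3 x 3, stride
#' 1, valid padding), each followed by GELU, dropout and a time-only
#' (2, 1, 1) max pooling, then fully connected layers of 256 and 128 units
#' and a linear head.
#'
#' @param window,n_ch,n_cv Input shape.
#' @param n_classes Number of classes.
#' @param filters Filter counts of the two conv layers.
#' @param kernel Kernel size `c(kt, kr, kc)`.
#' @param fc Fully connected layer widths.
#' @param dropout Dropout probability (training only).
#' @return An object of class `cnn3d_config`.
#' @export
cnn3d_config <- function(window = 64L, n_ch = 8L, n_cv = 8L, n_classes = 66L,
                         filters = c(16L, 32L), kernel = c(5L, 3L, 3L),
                         fc = c(256L, 128L), dropout = 0.2) {
  dims1 <- c(window, n_ch, n_cv) - kernel + 1L
  if (any(dims1 < 1L)) stopf("input too small for the first conv layer")
  dims1p <- c(dims1[1] %/% 2L, dims1[2], dims1[3])
  dims2 <- dims1p - kernel + 1L
  if (any(dims2 < 1L)) stopf("input too small for the second conv layer")
  dims2p <- c(dims2[1] %/% 2L, dims2[2], dims2[3])
  structure(list(window = window, n_ch = n_ch, n_cv = n_cv,
                 n_classes = as.integer(n_classes), filters = as.integer(filters),
                 kernel = as.integer(kernel), fc = as.integer(fc),
                 dropout = dropout, dims1 = dims1, dims1p = dims1p,
                 dims2 = dims2, dims2p = dims2p,
                 flat = prod(dims2p) * filters[2]),
            class = "cnn3d_config")
}

#' Parameter count of the 3D CNN baseline
#'
#' @param config A [cnn3d_config()].
#' @return Integer count (convolutions, FC layers and head, with biases).
#' @export
cnn3d_count_parameters <- function(config) {
  k <- prod(config$kernel)
  conv1 <- k * 1L * config$filters[1] + config$filters[1]
  conv2 <- k * config$filters[1] * config$filters[2] + config$filters[2]
  fc1 <- config$flat * config$fc[1] + config$fc[1]
  fc2 <- config$fc[1] * config$fc[2] + config$fc[2]
  head <- config$fc[2] * config$n_classes + config$n_classes
  conv1 + conv2 + fc1 + fc2 + head
}

# im2col index matrix for a valid 3-D convolution on input dims (t, r, c)
# with Cin channels: rows = output positions, cols = kernel taps x Cin.
conv3d_indices <- function(in_dims, Cin, kernel) {
  kt <- kernel[1]; kr <- kernel[2]; kc <- kernel[3]
  ot <- in_dims[1] - kt + 1L; or_ <- in_dims[2] - kr + 1L; oc <- in_dims[3] - kc + 1L
  base <- function(t, r, c, ch) t + (r - 1L) * in_dims[1] +
    (c - 1L) * in_dims[1] * in_dims[2] + (ch - 1L) * prod(in_dims)
  pos <- expand.grid(t = seq_len(ot), r = seq_len(or_), c = seq_len(oc))
  tap <- expand.grid(dt = 0:(kt - 1L), dr = 0:(kr - 1L), dc = 0:(kc - 1L),
                     ch = seq_len(Cin))
  idx <- matrix(0L, nrow(pos), nrow(tap))
  for (j in seq_len(nrow(tap))) {
    idx[, j] <- base(pos$t + tap$dt[j], pos$r + tap$dr[j], pos$c + tap$dc[j], tap$ch[j])
  }
  idx
}

#' Initialise the 3D CNN baseline
#'
#' @param config A [cnn3d_config()].
#' @param seed Integer seed.
#' @return Parameter list (class `cnn3d_params`) with cached index maps.
#' @export
cnn3d_init <- function(config, seed = 1L) {
  set.seed(seed)
  k <- prod(config$kernel)
  tn <- function(nr, nc) matrix(rtruncnorm02(nr * nc), nr, nc)
  p <- list(W1 = tn(k, config$filters[1]), b1 = rep(0, config$filters[1]),
            W2 = tn(k * config$filters[1], config$filters[2]),
            b2 = rep(0, config$filters[2]),
            Wf1 = tn(config$flat, config$fc[1]), bf1 = rep(0, config$fc[1]),
            Wf2 = tn(config$fc[1], config$fc[2]), bf2 = rep(0, config$fc[2]),
            Wh = tn(config$fc[2], config$n_classes), bh = rep(0, config$n_classes))
  attr(p, "idx1") <- conv3d_indices(c(config$window, config$n_ch, config$n_cv),
                                    1L, config$kernel)
  attr(p, "idx2") <- conv3d_indices(config$dims1p, config$filters[1], config$kernel)
  class(p) <- "cnn3d_params"
  p
}

# Forward pass of the 3D CNN for a batch of flattened windows; dropout is
# applied only when `train = TRUE` (with the current RNG stream).
cnn3d_forward <- function(params, X, config, train = FALSE) {
  idx1 <- attr(params, "idx1"); idx2 <- attr(params, "idx2")
  B <- nrow(X)
  logits <- matrix(0, B, config$n_classes)
  drop_keep <- 1 - config$dropout
  for (b in seq_len(B)) {
    x <- X[b, ]
    c1 <- matrix(x[idx1], nrow(idx1)) %*% params$W1 +
      row_broadcast(params$b1, nrow(idx1))
    a1 <- gelu(c1)
    if (train && config$dropout > 0)
      a1 <- a1 * (matrix(stats::runif(length(a1)), nrow(a1)) < drop_keep) / drop_keep
    p1 <- maxpool_time(a1, config$dims1)
    c2 <- matrix(as.vector(p1)[idx2], nrow(idx2)) %*% params$W2 +
      row_broadcast(params$b2, nrow(idx2))
    a2 <- gelu(c2)
    if (train && config$dropout > 0)
      a2 <- a2 * (matrix(stats::runif(length(a2)), nrow(a2)) < drop_keep) / drop_keep
    p2 <- maxpool_time(a2, config$dims2)
    f <- as.vector(p2)
    h1 <- gelu(drop(f %*% params$Wf1) + params$bf1)
    h2 <- gelu(drop(h1 %*% params$Wf2) + params$bf2)
    logits[b, ] <- drop(h2 %*% params$Wh) + params$bh
  }
  logits
}

# Max pooling over non-overlapping time pairs; A has rows ordered
# (t fastest, r, c) and one column per filter.
maxpool_time <- function(A, dims) {
  t_in <- dims[1]; rc <- dims[2] * dims[3]
  t_out <- t_in %/% 2L
  arr <- array(A, dim = c(t_in, rc, ncol(A)))
  arr <- pmax(arr[seq(1L, 2L * t_out, by = 2L), , , drop = FALSE],
              arr[seq(2L, 2L * t_out, by = 2L), , , drop = FALSE])
  matrix(arr, nrow = t_out * rc, ncol = ncol(A))
}

#' 3D CNN forward pass (inference)
#'
#' Deterministic (dropout disabled) class logits for a batch of windows.
#'
#' @param params A `cnn3d_params` list.
#' @param x Matrix of flattened windows (or one window array/vector).
#' @param config The matching [cnn3d_config()].
#' @return Logit matrix, one row per window.
#' @export
cnn3d_logits <- function(params, x, config) {
  X <- if (is.matrix(x) && ncol(x) == config$window * config$n_ch * config$n_cv) x
       else matrix(as.vector(x), nrow = 1L)
  cnn3d_forward(params, X, config, train = FALSE)
}

# Forward + backward for one sample (dropout masks drawn by the caller's RNG
# stream when training). Returns the logits and parameter gradients.
cnn3d_sample_grad <- function(params, x, y, config, train = TRUE) {
  idx1 <- attr(params, "idx1"); idx2 <- attr(params, "idx2")
  keep <- 1 - config$dropout
  xc1 <- matrix(x[idx1], nrow(idx1))
  c1 <- xc1 %*% params$W1 + row_broadcast(params$b1, nrow(idx1))
  a1 <- gelu(c1)
  m1 <- if (train && config$dropout > 0)
    (matrix(stats::runif(length(a1)), nrow(a1)) < keep) / keep else 1
  a1d <- a1 * m1
  pool1 <- maxpool_time_ix(a1d, config$dims1)
  xc2 <- matrix(as.vector(pool1$out)[idx2], nrow(idx2))
  c2 <- xc2 %*% params$W2 + row_broadcast(params$b2, nrow(idx2))
  a2 <- gelu(c2)
  m2 <- if (train && config$dropout > 0)
    (matrix(stats::runif(length(a2)), nrow(a2)) < keep) / keep else 1
  a2d <- a2 * m2
  pool2 <- maxpool_time_ix(a2d, config$dims2)
  f <- as.vector(pool2$out)
  z1 <- drop(f %*% params$Wf1) + params$bf1; h1 <- gelu(z1)
  z2 <- drop(h1 %*% params$Wf2) + params$bf2; h2 <- gelu(z2)
  logits <- drop(h2 %*% params$Wh) + params$bh

  # softmax cross-entropy backward
  p <- exp(logits - max(logits)); p <- p / sum(p)
  dlog <- p; dlog[y] <- dlog[y] - 1
  g <- list()
  g$Wh <- h2 %o% dlog; g$bh <- dlog
  dh2 <- drop(params$Wh %*% dlog) * gelu_grad(z2)
  g$Wf2 <- h1 %o% dh2; g$bf2 <- dh2
  dh1 <- drop(params$Wf2 %*% dh2) * gelu_grad(z1)
  g$Wf1 <- f %o% dh1; g$bf1 <- dh1
  df <- drop(params$Wf1 %*% dh1)
  da2 <- unpool_time_ix(matrix(df, ncol = ncol(a2)), pool2, config$dims2) * m2
  dc2 <- da2 * gelu_grad(c2)
  g$W2 <- t(xc2) %*% dc2; g$b2 <- colSums(dc2)
  dxc2 <- dc2 %*% t(params$W2)
  dp1 <- numeric(length(pool1$out))
  for (j in seq_len(ncol(idx2))) {
    acc <- rowsum(dxc2[, j], idx2[, j])
    dp1[as.integer(rownames(acc))] <- dp1[as.integer(rownames(acc))] + acc[, 1]
  }
  da1 <- unpool_time_ix(matrix(dp1, ncol = ncol(a1)), pool1, config$dims1) * m1
  dc1 <- da1 * gelu_grad(c1)
  g$W1 <- t(xc1) %*% dc1; g$b1 <- colSums(dc1)
  list(loss = -log(max(p[y], 1e-12)), grads = g)
}

# Max pooling over time pairs, remembering which element of each pair won.
maxpool_time_ix <- function(A, dims) {
  t_in <- dims[1]; rc <- dims[2] * dims[3]; t_out <- t_in %/% 2L
  arr <- array(A, dim = c(t_in, rc, ncol(A)))
  o1 <- arr[seq(1L, 2L * t_out, by = 2L), , , drop = FALSE]
  o2 <- arr[seq(2L, 2L * t_out, by = 2L), , , drop = FALSE]
  first <- o1 >= o2
  list(out = matrix(pmax(o1, o2), nrow = t_out * rc, ncol = ncol(A)),
       first = first, t_out = t_out)
}

unpool_time_ix <- function(dOut, pool, dims) {
  t_in <- dims[1]; rc <- dims[2] * dims[3]; t_out <- pool$t_out
  darr <- array(dOut, dim = c(t_out, rc, ncol(dOut)))
  full <- array(0, dim = c(t_in, rc, ncol(dOut)))
  full[seq(1L, 2L * t_out, by = 2L), , ] <- darr * pool$first
  full[seq(2L, 2L * t_out, by = 2L), , ] <- darr * !pool$first
  matrix(full, nrow = t_in * rc, ncol = ncol(dOut))
}

#' Train the 3D CNN baseline
#'
#' Adam on softmax cross-entropy with the same schedule interface as the
#' transformer models. Intended for small-scale comparisons; the per-sample
#' convolution backward makes this the slowest baseline.
#'
#' @param dataset An `emg_windows` dataset (or list with `x`, `labels`).
#' @param config A [cnn3d_config()].
#' @param control A [train_control()].
#' @return List of class `cnn3d_fit` with `params`, `config`, `loss_trace`.
#' @export
cnn3d_fit <- function(dataset, config, control = train_control()) {
  X <- dataset$x; y <- as.integer(dataset$labels)
  set.seed(control$seed)
  params <- cnn3d_init(config, seed = control$seed)
  tr <- unclass(params)[c("W1", "b1", "W2", "b2", "Wf1", "bf1", "Wf2", "bf2", "Wh", "bh")]
  state <- adam_init(tr)
  losses <- numeric(control$epochs)
  n <- nrow(X)
  for (epoch in seq_len(control$epochs)) {
    lr <- lr_at_epoch(control, epoch)
    ord <- sample.int(n)
    ep <- 0; nb <- 0L
    for (start in seq(1L, n, by = control$batch_size)) {
      take <- ord[start:min(start + control$batch_size - 1L, n)]
      grads <- NULL; loss <- 0
      for (b in take) {
        sg <- cnn3d_sample_grad(params, X[b, ], y[b], config, train = TRUE)
        grads <- if (is.null(grads)) sg$grads
                 else tree_map(`+`, grads, sg$grads)
        loss <- loss + sg$loss
      }
      grads <- tree_map(function(g) g / length(take), grads[names(tr)])
      if (control$weight_decay > 0)
        grads <- tree_map(function(g, p) g + control$weight_decay * p, grads, tr)
      st <- adam_step(tr, grads, state, lr, control)
      tr <- st$params; state <- st$state
      for (nm in names(tr)) params[[nm]] <- tr[[nm]]
      ep <- ep + loss / length(take); nb <- nb + 1L
    }
    losses[epoch] <- ep / nb
  }
  structure(list(params = params, config = config, loss_trace = losses),
            class = "cnn3d_fit")
}
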