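#' Training control parameters
#'
#' Adam hyperparameters and schedule for subject-wise training: 20 epochs,
#' batch 128, learning rate 1e-4, weight decay 1e-3, cross-entropy loss,
#' with learning-rate annealing after the first 10 epochs.
#'
#' @param epochs Training epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty added to the gradient of every parameter.
#' @param beta1,beta2 Adam moment decay rates.
#' @param anneal_after Epoch after which the learning rate is annealed
#'   (must be <= `epochs`).
#' @param schedule Annealing shape: `"linear"` decays linearly toward 0,
#'   `"cosine"` follows a half cosine.
#' @param seed Integer seed for initialisation and batch shuffling.
#' @param verbose Print per-epoch loss.
#' @return An object of class `train_control`.
#' @export
train_control <- function(epochs = 20L, batch_size = 128L, lr = 1e-4,
                          weight_decay = 1e-3, beta1 = 0.9, beta2 = 0.999,
                          anneal_after = 10L, schedule = c("linear", "cosine"),
                          seed = 1L, verbose = FALSE) {
  if (epochs < 1L) stopf("epochs must be >= 1")
  if (anneal_after > epochs) stopf("anneal_after must be <= epochs")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 anneal_after = as.integer(anneal_after),
                 schedule = match.arg(schedule), seed = as.integer(seed),
                 verbose = verbose),
            class = "train_control")
}

lr_at_epoch <- function(ctrl, epoch) {
  if (epoch <= ctrl$anneal_after) return(ctrl$lr)
  span <- ctrl$epochs - ctrl$anneal_after + 1
  if (ctrl$schedule == "linear") {
    ctrl$lr * (ctrl$epochs - epoch + 1) / span
  } else {
    ctrl$lr * 0.5 * (1 + cos(pi * (epoch - ctrl$anneal_after) / span))
  }
}

# Cross-entropy loss and gradient for a batch; y is a 1-based class vector.
ce_loss_grad <- function(logits, y) {
  B <- nrow(logits)
  P <- softmax_rows(logits)
  picked <- P[cbind(seq_len(B), y)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dP <- P
  dP[cbind(seq_len(B), y)] <- dP[cbind(seq_len(B), y)] - 1
  list(loss = loss, dlogits = dP / B)
}

adam_init <- function(params) {
  zeros <- tree_map(function(x) { y <- x; y[] <- 0; y }, params)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, ctrl) {
  state$t <- state$t + 1L
  b1 <- ctrl$beta1; b2 <- ctrl$beta2
  state$m <- tree_map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) b2 * v + (1 - b2) * g * g, state$v, grads)
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  params <- tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + 1e-8),
                     params, state$m, state$v)
  list(params = params, state = state)
}

# Core SGD loop shared by the macro, micro and baseline deep models.
train_vit <- function(X, y, config, ctrl) {
  n <- nrow(X)
  if (n == 0L) stopf("training set is empty")
  if (any(y < 1L | y > config$n_classes))
    stopf("labels must lie in 1..%d", config$n_classes)
  set.seed(ctrl$seed)
  params <- init_params(config, seed = ctrl$seed)
  attr(params, "patch_idx") <- patch_indices(config)
  tr <- unclass(params)[c("E", "x0", "Epos", "layers", "Wh", "bh")]
  state <- adam_init(tr)
  losses <- numeric(ctrl$epochs)
  # rearrange the training windows into patch form once; batches then only
  # gather rows
  Xp <- patchify(X, config, attr(params, "patch_idx"))
  N <- config$n_patches
  patch_offsets <- (seq_len(N) - 1L) * n
  for (epoch in seq_len(ctrl$epochs)) {
    lr <- lr_at_epoch(ctrl, epoch)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = ctrl$batch_size)) {
      take <- ord[start:min(start + ctrl$batch_size - 1L, n)]
      rows <- as.vector(outer(take, patch_offsets, `+`))
      fw <- vit_forward(params, Xp[rows, , drop = FALSE], config,
                        keep_cache = TRUE, prepatched = TRUE)
      lg <- ce_loss_grad(fw$logits, y[take])
      grads <- vit_backward(params, fw, lg$dlogits, config)
      if (ctrl$weight_decay > 0) {
        grads <- tree_map(function(g, p) g + ctrl$weight_decay * p, grads, tr)
      }
      st <- adam_step(tr, grads, state, lr, ctrl)
      tr <- st$params; state <- st$state
      for (nm in names(tr)) params[[nm]] <- tr[[nm]]
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    losses[epoch] <- ep_loss / nb
    if (ctrl$verbose) message(sprintf("epoch %d: loss %.4f (lr %.2e)", epoch, losses[epoch], lr))
  }
  list(params = params, loss_trace = losses)
}

#' Fit the transformer gesture classifier
#'
#' Trains the class-token vision transformer on a windowed HD-sEMG dataset
#' with Adam and cross-entropy loss. This is the package's central fitting
#' function; the returned object supports `print`, `summary`, `coef`,
#' `predict` and `plot`.
#'
#' @param dataset An `emg_windows` dataset (see [preprocess_session()]), or
#'   a list with fields `x` (windows x features matrix) and `labels`.
#' @param config A [vit_config()]; defaults to the V1 variant matched to the
#'   dataset's shape and class count.
#' @param control A [train_control()].
#' @return An object of class `emgvit` with the trained parameters, the
#'   configuration and the per-epoch training-loss trace.
#' @export
emgvit <- function(dataset, config = NULL, control = train_control()) {
  X <- dataset$x
  y <- as.integer(dataset$labels)
  if (is.null(config)) {
    spec <- dataset$spec
    if (is.null(spec)) stopf("config is required when dataset carries no window spec")
    config <- standard_config("V1", window = spec$window_size,
                              channels = spec$n_ch * spec$n_cv,
                              n_classes = max(y))
  }
  fit <- train_vit(X, y, config, control)
  structure(list(config = config, params = fit$params, control = control,
                 loss_trace = fit$loss_trace, n_obs = nrow(X),
                 classes = seq_len(config$n_classes), call = match.call()),
            class = "emgvit")
}

#' Predict from a fitted transformer
#'
#' @param object An `emgvit` fit.
#' @param newdata An `emg_windows` dataset or a matrix of flattened windows.
#' @param type `"class"` (argmax, ties to the lowest index), `"prob"`
#'   (softmax), `"logit"`, or `"token"` (the final class-token embedding,
#'   used by the fusion model).
#' @param batch_size Windows per forward batch.
#' @param ... Unused.
#' @return Vector of classes, or a matrix with one row per window.
#' @export
predict.emgvit <- function(object, newdata, type = c("class", "prob", "logit", "token"),
                           batch_size = 256L, ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else newdata$x
  n <- nrow(X)
  d_out <- if (type == "token") object$config$d else object$config$n_classes
  out <- matrix(0, n, d_out)
  for (start in seq(1L, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    fw <- vit_forward(object$params, X[take, , drop = FALSE], object$config)
    out[take, ] <- if (type == "token") fw$tokens else fw$logits
  }
  switch(type,
         class = max.col(out, ties.method = "first"),
         prob = softmax_rows(out),
         logit = out,
         token = out)
}

#' @export
print.emgvit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("emgvit %s: d=%d, L=%d, h=%d, mlp=%d, patch (%d,%d), %d classes\n",
              cfg$variant, cfg$d, cfg$L, cfg$h, cfg$mlp_hidden,
              cfg$patch[1], cfg$patch[2], cfg$n_classes))
  cat(sprintf("  input %d x %d x %d -> %d patches (+1 class token), %s parameters\n",
              cfg$window, cfg$n_ch, cfg$n_cv, cfg$n_patches,
              format(count_parameters(cfg), big.mark = ",")))
  cat(sprintf("  trained on %d windows, final loss %.4f\n",
              x$n_obs, tail(x$loss_trace, 1)))
  invisible(x)
}

#' Parameter-count breakdown of a fitted or configured model
#'
#' @param object An `emgvit` fit.
#' @param ... Unused.
#' @return A data frame with one row per parameter group (invisibly printed).
#' @export
summary.emgvit <- function(object, ...) {
  cfg <- object$config
  d <- cfg$d; m <- cfg$mlp_hidden; N <- cfg$n_patches; C <- cfg$n_classes
  breakdown <- data.frame(
    group = c("patch projection", "class token", "positional embedding",
              "encoder layers", "head"),
    parameters = c(cfg$patch_dim * d, d, (N + 1) * d,
                   cfg$L * (4 * d + 4 * (d * d + d) + (d * m + m) + (m * d + d)),
                   d * C + C))
  out <- list(config = cfg, breakdown = breakdown,
              total = count_parameters(cfg),
              introspective = tree_size(unclass(object$params)[
                c("E", "x0", "Epos", "layers", "Wh", "bh")]))
  class(out) <- "summary.emgvit"
  out
}

#' @export
print.summary.emgvit <- function(x, ...) {
  print(x$breakdown, row.names = FALSE)
  cat(sprintf("total: %s trainable parameters\n", format(x$total, big.mark = ",")))
  invisible(x)
}

#' @export
coef.emgvit <- function(object, ...) object$params

#' @export
plot.emgvit <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "b",
                 xlab = "epoch", ylab = "training loss",
                 main = "emgvit training loss", ...)
  invisible(x)
}
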