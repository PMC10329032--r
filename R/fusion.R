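#' Train the micro-path classifier on peak-to-peak MUAP images
#'
#' Trains a V3 transformer on per-unit peak-to-peak images. Every accepted
#' motor unit of a window contributes one independent training sample
#' carrying the window's gesture label.
#'
#' @param images List (one element per window) of lists of `n_ch x n_cv`
#'   peak-to-peak matrices (possibly empty for windows with no accepted
#'   unit).
#' @param labels Gesture label per window.
#' @param config A [vit_config()], normally `standard_config("V3", ...)`.
#' @param control A [train_control()]; the micro path defaults are Adam
#'   with learning rate 3e-4, weight decay 1e-3, batch 64, 50 epochs.
#' @return An `emgvit` fit on the image samples.
#' @export
train_micro <- function(images, labels, config,
                        control = train_control(epochs = 50L, batch_size = 64L,
                                                lr = 3e-4, weight_decay = 1e-3,
                                                anneal_after = 50L)) {
  flat <- list(); y <- integer(0)
  for (i in seq_along(images)) {
    for (img in images[[i]]) {
      flat[[length(flat) + 1L]] <- as.vector(img)
      y <- c(y, labels[i])
    }
  }
  if (length(flat) == 0L) stopf("no MUAP images to train on")
  X <- do.call(rbind, flat)
  if (ncol(X) != config$window * config$n_ch * config$n_cv)
    stopf("image size %d does not match the V3 input (%d values)",
          ncol(X), config$window * config$n_ch * config$n_cv)
  emgvit(list(x = X, labels = y), config = config, control = control)
}

#' Aggregate a window's MUAP images into one micro class token
#'
#' Runs the micro model on each of the window's accepted-unit images and
#' aggregates the class tokens (mean by default). A window with no accepted
#' unit yields a zero token flagged via attribute `"no_mu"`.
#'
#' @param images List of `n_ch x n_cv` images for one window (may be empty).
#' @param micro_fit An `emgvit` micro-path fit.
#' @param aggregation `"mean"` or `"max"` over the per-unit tokens.
#' @return Length-`d` token vector.
#' @export
window_micro_token <- function(images, micro_fit, aggregation = c("mean", "max")) {
  aggregation <- match.arg(aggregation)
  d <- micro_fit$config$d
  if (length(images) == 0L) {
    out <- numeric(d)
    attr(out, "no_mu") <- TRUE
    return(out)
  }
  X <- do.call(rbind, lapply(images, as.vector))
  tok <- predict(micro_fit, X, type = "token")
  out <- if (aggregation == "mean") colMeans(tok) else apply(tok, 2L, max)
  attr(out, "no_mu") <- FALSE
  out
}

# Two-layer fusion head: linear expansion + GELU + linear classifier,
# trained with Adam; only these weights receive gradients.
fusion_head_init <- function(d_in, d_hidden, C, seed) {
  set.seed(seed)
  list(W1 = matrix(rtruncnorm02(d_in * d_hidden), d_in, d_hidden),
       b1 = rep(0, d_hidden),
       W2 = matrix(rtruncnorm02(d_hidden * C), d_hidden, C),
       b2 = rep(0, C))
}

fusion_head_forward <- function(head, X) {
  A1 <- X %*% head$W1 + row_broadcast(head$b1, nrow(X))
  H1 <- gelu(A1)
  list(logits = H1 %*% head$W2 + row_broadcast(head$b2, nrow(X)), A1 = A1, H1 = H1)
}

#' Fit the macro-micro fusion classifier
#'
#' Freezes the trained macro (raw-window) and micro (MUAP-image) backbones,
#' strips their heads, concatenates their class tokens per window, expands
#' the concatenation through a hidden fully connected layer (default 1024
#' units, GELU), and trains a linear classifier on top. Only the fusion-head
#' weights are updated.
#'
#' @param macro_fit Trained `emgvit` on raw windows.
#' @param micro_fit Trained `emgvit` on MUAP images.
#' @param dataset The `emg_windows` dataset feeding the macro path.
#' @param images Per-window lists of peak-to-peak images (micro inputs).
#' @param feature_dim Hidden width of the fusion head (default 1024).
#' @param aggregation Per-window multi-unit token aggregation.
#' @param control A [train_control()] for the head (defaults: Adam, lr 3e-4,
#'   weight decay 1e-3, batch 64, 50 epochs).
#' @return Object of class `emgvit_fusion` with the frozen backbones, the
#'   trained head and the training-loss trace.
#' @export
fuse_and_classify <- function(macro_fit, micro_fit, dataset, images,
                              feature_dim = 1024L,
                              aggregation = c("mean", "max"),
                              control = train_control(epochs = 50L, batch_size = 64L,
                                                      lr = 3e-4, weight_decay = 1e-3,
                                                      anneal_after = 50L)) {
  aggregation <- match.arg(aggregation)
  if (length(images) != nrow(dataset$x))
    stopf("need one image list per window (%d lists for %d windows)",
          length(images), nrow(dataset$x))
  feats <- fusion_features(macro_fit, micro_fit, dataset, images, aggregation)
  y <- as.integer(dataset$labels)
  C <- macro_fit$config$n_classes
  head <- fusion_head_init(ncol(feats), feature_dim, C, control$seed)
  state <- adam_init(head)
  n <- nrow(feats)
  set.seed(control$seed)
  losses <- numeric(control$epochs)
  for (epoch in seq_len(control$epochs)) {
    lr <- lr_at_epoch(control, epoch)
    ord <- sample.int(n)
    ep <- 0; nb <- 0L
    for (start in seq(1L, n, by = control$batch_size)) {
      take <- ord[start:min(start + control$batch_size - 1L, n)]
      X <- feats[take, , drop = FALSE]
      fw <- fusion_head_forward(head, X)
      lg <- ce_loss_grad(fw$logits, y[take])
      dH1 <- lg$dlogits %*% t(head$W2)
      dA1 <- dH1 * gelu_grad(fw$A1)
      grads <- list(W1 = t(X) %*% dA1, b1 = colSums(dA1),
                    W2 = t(fw$H1) %*% lg$dlogits, b2 = colSums(lg$dlogits))
      if (control$weight_decay > 0)
        grads <- tree_map(function(g, p) g + control$weight_decay * p, grads, head)
      st <- adam_step(head, grads, state, lr, control)
      head <- st$params; state <- st$state
      ep <- ep + lg$loss; nb <- nb + 1L
    }
    losses[epoch] <- ep / nb
  }
  structure(list(macro = macro_fit, micro = micro_fit, head = head,
                 aggregation = aggregation, feature_dim = feature_dim,
                 loss_trace = losses, control = control),
            class = "emgvit_fusion")
}

# Concatenated (macro token, micro token) feature matrix for a dataset.
fusion_features <- function(macro_fit, micro_fit, dataset, images, aggregation) {
  macro_tok <- predict(macro_fit, dataset, type = "token")
  micro_tok <- t(vapply(images, window_micro_token, numeric(micro_fit$config$d),
                        micro_fit = micro_fit, aggregation = aggregation))
  cbind(macro_tok, micro_tok)
}

#' Predict from a fusion model
#'
#' @param object An `emgvit_fusion` fit.
#' @param dataset An `emg_windows` dataset (macro input).
#' @param images Per-window image lists (micro input).
#' @param type `"class"`, `"prob"` or `"logit"`.
#' @param ... Unused.
#' @return Predicted classes or a score matrix.
#' @export
predict.emgvit_fusion <- function(object, dataset, images,
                                  type = c("class", "prob", "logit"), ...) {
  type <- match.arg(type)
  feats <- fusion_features(object$macro, object$micro, dataset, images,
                           object$aggregation)
  logits <- fusion_head_forward(object$head, feats)$logits
  switch(type,
         class = max.col(logits, ties.method = "first"),
         prob = softmax_rows(logits),
         logit = logits)
}

#' @export
print.emgvit_fusion <- function(x, ...) {
  cat(sprintf("macro-micro fusion: %d + %d token dims -> %d hidden -> %d classes\n",
              x$macro$config$d, x$micro$config$d, x$feature_dim,
              x$macro$config$n_classes))
  cat(sprintf("  backbones frozen; head trained %d epochs, final loss %.4f\n",
              x$control$epochs, tail(x$loss_trace, 1)))
  invisible(x)
}
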