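#' Transformer model configuration
#'
#' Describes the class-token vision transformer: embedding dimension `d`,
#' `L` pre-norm encoder layers with `h`-head self-attention, an MLP block
#' with `mlp_hidden` units, a patch size `(H, V)` tiling the (time,
#' horizontal-channel) axes of the `W x n_ch x n_cv` input, and a linear
#' class-token head over `n_classes`.
#'
#' @param d Embedding dimension (must be divisible by `h`).
#' @param L Number of encoder layers.
#' @param h Number of attention heads.
#' @param mlp_hidden Hidden units of the encoder MLP block.
#' @param patch Patch size `c(H, V)`; `H` must divide `window` and `V` must
#'   divide `n_ch`.
#' @param n_classes Number of gesture classes.
#' @param window,n_ch,n_cv Input shape (time samples, horizontal channels,
#'   vertical channels).
#' @param variant Label: one of `"V1"`, `"V2"`, `"V3"`, `"instantaneous"`,
#'   `"custom"`.
#' @param scale Attention scaling: `"per_head"` uses `1/sqrt(d/h)` inside
#'   each head (the standard multi-head form); `"full_d"` uses `1/sqrt(d)`.
#' @return An object of class `vit_config` with derived fields `n_patches`
#'   (the effective sequence length before the class token) and `patch_dim`.
#' @export
vit_config <- function(d = 64L, L = 1L, h = 8L, mlp_hidden = 64L,
                       patch = c(8L, 8L), n_classes = 66L,
                       window = 64L, n_ch = 8L, n_cv = 8L,
                       variant = "custom", scale = c("per_head", "full_d")) {
  scale <- match.arg(scale)
  d <- as.integer(d); L <- as.integer(L); h <- as.integer(h)
  if (d %% h != 0L) stopf("embedding dimension %d is not divisible by %d heads", d, h)
  H <- as.integer(patch[1]); V <- as.integer(patch[2])
  if (window %% H != 0L) stopf("patch height %d does not divide window %d", H, window)
  if (n_ch %% V != 0L) stopf("patch width %d does not divide n_ch %d", V, n_ch)
  N <- (window %/% H) * (n_ch %/% V)
  if (N < 1L) stopf("configuration yields no patches")
  structure(list(d = d, L = L, h = h, mlp_hidden = as.integer(mlp_hidden),
                 patch = c(H, V), n_classes = as.integer(n_classes),
                 window = as.integer(window), n_ch = as.integer(n_ch),
                 n_cv = as.integer(n_cv), variant = variant, scale = scale,
                 n_patches = as.integer(N), patch_dim = as.integer(H * V * n_cv)),
            class = "vit_config")
}

#' Standard model configurations
#'
#' The named variants: `V1` (d = 64, 1 layer, 8 heads, MLP 64), `V2`
#' (d = 128, MLP 256), `V3` (the micro path: a single-frame peak-to-peak
#' MUAP image split into 2 patches), and `instantaneous` (a single time
#' frame as one whole-frame token).
#'
#' @param name One of `"V1"`, `"V2"`, `"V3"`, `"instantaneous"`.
#' @param window Window size in samples (ignored for V3/instantaneous).
#' @param channels Total electrode count: 32, 64 or 128.
#' @param n_classes Number of gesture classes.
#' @return A [vit_config()].
#' @export
standard_config <- function(name = c("V1", "V2", "V3", "instantaneous"),
                            window = 64L, channels = 128L, n_classes = 66L) {
  name <- match.arg(name)
  patch_for <- function(channels) switch(as.character(channels),
    "32" = c(8L, 4L), "64" = c(8L, 8L), "128" = c(8L, 16L),
    stopf("supported channel counts are 32, 64 and 128"))
  n_ch_for <- function(channels) channels %/% 8L
  switch(name,
    V1 = vit_config(d = 64L, L = 1L, h = 8L, mlp_hidden = 64L,
                    patch = patch_for(channels), n_classes = n_classes,
                    window = window, n_ch = n_ch_for(channels), n_cv = 8L,
                    variant = "V1"),
    V2 = vit_config(d = 128L, L = 1L, h = 8L, mlp_hidden = 256L,
                    patch = patch_for(channels), n_classes = n_classes,
                    window = window, n_ch = n_ch_for(channels), n_cv = 8L,
                    variant = "V2"),
    V3 = {
      # input is one peak-to-peak MUAP image laid out as rows x columns;
      # two patches regardless of the electrode count
      if (channels == 128L) {
        vit_config(d = 64L, L = 1L, h = 8L, mlp_hidden = 64L,
                   patch = c(8L, 8L), n_classes = n_classes,
                   window = 8L, n_ch = 16L, n_cv = 1L, variant = "V3")
      } else if (channels == 64L) {
        vit_config(d = 64L, L = 1L, h = 8L, mlp_hidden = 64L,
                   patch = c(8L, 4L), n_classes = n_classes,
                   window = 8L, n_ch = 8L, n_cv = 1L, variant = "V3")
      } else stopf("V3 supports 64 or 128 electrodes")
    },
    instantaneous = vit_config(d = 64L, L = 1L, h = 8L, mlp_hidden = 64L,
                               patch = c(1L, 8L), n_classes = n_classes,
                               window = 1L, n_ch = 8L, n_cv = 8L,
                               variant = "instantaneous"))
}

#' Closed-form trainable-parameter count
#'
#' Patch projection (no bias) + class token + positional embedding +
#' per-layer (2 norms, 4 d x d projections with biases, 2 MLP linears) +
#' linear head. Matches an introspective count of the parameter tensors.
#'
#' @param config A [vit_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  d <- config$d; m <- config$mlp_hidden; N <- config$n_patches
  C <- config$n_classes; L <- config$L
  config$patch_dim * d +          # patch projection, no bias
    d +                           # class token
    (N + 1L) * d +                # positional embedding
    L * (4L * d +                 # two layer norms (scale + shift)
         4L * (d * d + d) +       # Wq, Wk, Wv, Wo with biases
         (d * m + m) +            # MLP in
         (m * d + d)) +           # MLP out
    (d * C + C)                   # head
}

# Linear indices (into the flattened W x n_ch x n_cv window) of each patch,
# as a patch_dim x N matrix. Patches tile (time, horizontal channel) with the
# time tile varying fastest; within a patch the flattening order is (time,
# horizontal channel, vertical channel).
patch_indices <- function(config) {
  W <- config$window; n_ch <- config$n_ch; n_cv <- config$n_cv
  H <- config$patch[1]; V <- config$patch[2]
  nt <- W %/% H; nc <- n_ch %/% V
  idx <- matrix(0L, nrow = config$patch_dim, ncol = config$n_patches)
  p <- 0L
  for (ct in seq_len(nc)) {
    for (tt in seq_len(nt)) {
      p <- p + 1L
      t_rng <- ((tt - 1L) * H + 1L):(tt * H)
      r_rng <- ((ct - 1L) * V + 1L):(ct * V)
      lin <- outer(t_rng, (r_rng - 1L) * W, `+`)            # H x V, time fastest
      lin <- outer(as.vector(lin), ((seq_len(n_cv)) - 1L) * W * n_ch, `+`)
      idx[, p] <- as.vector(lin)
    }
  }
  # columns are enumerated with the time tile fastest, channel tile slower
  idx
}

#' Split a window into flattened patches
#'
#' Tiles the `W x n_ch x n_cv` window into `N` non-overlapping
#' `H x V x n_cv` patches and flattens each in (time, horizontal channel,
#' vertical channel) order.
#'
#' @param window A `W x n_ch x n_cv` array or its flattened vector.
#' @param config A [vit_config()].
#' @return `N x (H * V * n_cv)` matrix, one patch per row.
#' @export
make_patches <- function(window, config) {
  v <- as.vector(window)
  if (length(v) != config$window * config$n_ch * config$n_cv)
    stopf("window has %d values; config expects %d", length(v),
          config$window * config$n_ch * config$n_cv)
  idx <- patch_indices(config)
  t(matrix(v[idx], nrow = nrow(idx)))
}

#' Reassemble a window from its patches
#'
#' Exact inverse of [make_patches()].
#'
#' @param patches `N x patch_dim` matrix.
#' @param config A [vit_config()].
#' @return `W x n_ch x n_cv` array.
#' @export
unmake_patches <- function(patches, config) {
  idx <- patch_indices(config)
  v <- numeric(config$window * config$n_ch * config$n_cv)
  v[as.vector(idx)] <- as.vector(t(patches))
  array(v, dim = c(config$window, config$n_ch, config$n_cv))
}

#' Initialise model parameters
#'
#' Truncated-normal (sd 0.02, clipped at two standard deviations) for the
#' projections and embeddings, zeros for biases, ones/zeros for layer-norm
#' scale/shift.
#'
#' @param config A [vit_config()].
#' @param seed Integer seed.
#' @return A nested parameter list (class `vit_params`).
#' @export
init_params <- function(config, seed = 1L) {
  set.seed(seed)
  d <- config$d; m <- config$mlp_hidden
  tn <- function(nr, nc) matrix(rtruncnorm02(nr * nc), nr, nc)
  layers <- lapply(seq_len(config$L), function(l) list(
    g1 = rep(1, d), s1 = rep(0, d),
    Wq = tn(d, d), bq = rep(0, d),
    Wk = tn(d, d), bk = rep(0, d),
    Wv = tn(d, d), bv = rep(0, d),
    Wo = tn(d, d), bo = rep(0, d),
    g2 = rep(1, d), s2 = rep(0, d),
    W1 = tn(d, m), b1 = rep(0, m),
    W2 = tn(m, d), b2 = rep(0, d)))
  p <- list(E = tn(config$patch_dim, d),
            x0 = rtruncnorm02(d),
            Epos = tn(config$n_patches + 1L, d),
            layers = layers,
            Wh = tn(d, config$n_classes),
            bh = rep(0, config$n_classes))
  class(p) <- "vit_params"
  p
}

# ---- forward pass -----------------------------------------------------------

# Layer norm over the feature axis of an n x d matrix.
layernorm_forward <- function(x, g, s, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv_std <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv_std
  list(y = xhat * row_broadcast(g, nrow(x)) + row_broadcast(s, nrow(x)),
       xhat = xhat, inv_std = inv_std)
}

layernorm_backward <- function(dy, cache, g) {
  n <- nrow(dy); d <- ncol(dy)
  dg <- colSums(dy * cache$xhat)
  ds <- colSums(dy)
  dxhat <- dy * row_broadcast(g, n)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$inv_std * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx, dg = dg, ds = ds)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T * scale) V` with rows of the softmax forming probability
#' vectors. Exposed directly for testing; the encoder uses the batched
#' multi-head form internally.
#'
#' @param Q,K,V Token matrices with equal row counts (K and V share rows).
#' @param scale_dim Dimension whose inverse square root scales the scores
#'   (defaults to `ncol(Q)`).
#' @return List with `output` (tokens x ncol(V)) and `weights` (the softmax
#'   attention matrix).
#' @export
scaled_dot_product_attention <- function(Q, K, V, scale_dim = ncol(Q)) {
  S <- (Q %*% t(K)) / sqrt(scale_dim)
  A <- softmax_rows(S)
  list(output = A %*% V, weights = A)
}

# Multi-head attention over a token-major batched activation matrix
# ((B*T) x d, token block t occupying rows (t-1)*B + 1:B). The per-sample,
# per-head loops run in compiled code (src/attention.cpp).
mha_forward <- function(Q, K, V, B, T, nh, scl) {
  .mha_fwd_cpp(Q, K, V, B, T, nh, scl)
}

mha_backward <- function(dO, A, Q, K, V, B, T, nh, scl) {
  .mha_bwd_cpp(dO, A, Q, K, V, B, T, nh, scl)
}

# Rearrange a batch of flattened windows (B x D) into the patch design
# matrix ((B*N) x patch_dim) whose token block p occupies rows
# (p-1)*B + 1:B. Done once per training set to keep the per-batch work to a
# row gather.
patchify <- function(X, config, idx = patch_indices(config)) {
  B <- nrow(X)
  Mw <- X[, as.vector(idx), drop = FALSE]       # B x (patch_dim * N)
  dim(Mw) <- c(B, nrow(idx), config$n_patches)
  Mw <- aperm(Mw, c(1L, 3L, 2L))                # B x N x patch_dim
  dim(Mw) <- c(B * config$n_patches, nrow(idx))
  Mw
}

# Full forward pass over a batch of flattened windows (B x D matrix), or —
# with `prepatched = TRUE` — over a (B*N) x patch_dim design matrix from
# patchify(). Returns logits, class tokens, and optionally the backprop cache.
vit_forward <- function(params, X, config, keep_cache = FALSE, prepatched = FALSE) {
  N <- config$n_patches; T <- N + 1L; d <- config$d
  scl <- if (config$scale == "per_head") 1 / sqrt(d / config$h) else 1 / sqrt(d)
  if (prepatched) {
    Mw <- X
    B <- nrow(X) %/% N
  } else {
    B <- nrow(X)
    idx <- attr(params, "patch_idx")
    if (is.null(idx)) idx <- patch_indices(config)
    Mw <- patchify(X, config, idx)
  }
  Zp <- Mw %*% params$E                         # (B*N) x d, token-major blocks
  Z <- rbind(row_broadcast(params$x0, B), Zp) +
    params$Epos[rep(seq_len(T), each = B), , drop = FALSE]

  cache <- if (keep_cache) list(Mw = Mw, layers = vector("list", config$L)) else NULL
  for (l in seq_len(config$L)) {
    lp <- params$layers[[l]]
    ln1 <- layernorm_forward(Z, lp$g1, lp$s1)
    Q <- ln1$y %*% lp$Wq + row_broadcast(lp$bq, B * T)
    K <- ln1$y %*% lp$Wk + row_broadcast(lp$bk, B * T)
    V <- ln1$y %*% lp$Wv + row_broadcast(lp$bv, B * T)
    att <- mha_forward(Q, K, V, B, T, config$h, scl)
    msa <- att$O %*% lp$Wo + row_broadcast(lp$bo, B * T)
    Zp1 <- Z + msa
    ln2 <- layernorm_forward(Zp1, lp$g2, lp$s2)
    A1 <- ln2$y %*% lp$W1 + row_broadcast(lp$b1, B * T)
    P1 <- stats::pnorm(A1)                      # cached for the GELU backward
    H1 <- A1 * P1
    Z2 <- Zp1 + H1 %*% lp$W2 + row_broadcast(lp$b2, B * T)
    if (keep_cache) {
      cache$layers[[l]] <- list(Zin = Z, ln1 = ln1, Q = Q, K = K, V = V,
                                A = att$A, O = att$O, Zp1 = Zp1, ln2 = ln2,
                                A1 = A1, P1 = P1, H1 = H1)
    }
    Z <- Z2
  }
  tokens <- Z[seq_len(B), , drop = FALSE]       # class-token rows
  logits <- tokens %*% params$Wh + row_broadcast(params$bh, B)
  list(logits = logits, tokens = tokens, Z = if (keep_cache) Z else NULL,
       cache = cache, B = B, T = T, scl = scl)
}

# Backward pass; dlogits is B x C. Returns gradients in the parameter tree
# structure.
vit_backward <- function(params, fw, dlogits, config) {
  B <- fw$B; T <- fw$T; d <- config$d
  grads <- tree_map(function(x) { y <- x; y[] <- 0; y },
                    unclass(params)[c("E", "x0", "Epos", "layers", "Wh", "bh")])
  tokens <- fw$tokens
  grads$Wh <- crossprod(tokens, dlogits)
  grads$bh <- colSums(dlogits)
  dZ <- matrix(0, B * T, d)
  dZ[seq_len(B), ] <- tcrossprod(dlogits, params$Wh)

  for (l in rev(seq_len(config$L))) {
    lp <- params$layers[[l]]; cc <- fw$cache$layers[[l]]
    # MLP block
    dH2 <- dZ
    grads$layers[[l]]$W2 <- crossprod(cc$H1, dH2)
    grads$layers[[l]]$b2 <- colSums(dH2)
    # GELU'(x) = Phi(x) + x phi(x), with Phi cached from the forward pass
    gg <- cc$P1 + cc$A1 * (0.3989422804014327 * exp(-0.5 * cc$A1 * cc$A1))
    dA1 <- tcrossprod(dH2, lp$W2) * gg
    grads$layers[[l]]$W1 <- crossprod(cc$ln2$y, dA1)
    grads$layers[[l]]$b1 <- colSums(dA1)
    ln2b <- layernorm_backward(tcrossprod(dA1, lp$W1), cc$ln2, lp$g2)
    grads$layers[[l]]$g2 <- ln2b$dg
    grads$layers[[l]]$s2 <- ln2b$ds
    dZp1 <- dZ + ln2b$dx
    # MSA block
    dMSA <- dZp1
    grads$layers[[l]]$Wo <- crossprod(cc$O, dMSA)
    grads$layers[[l]]$bo <- colSums(dMSA)
    dO <- tcrossprod(dMSA, lp$Wo)
    ab <- mha_backward(dO, cc$A, cc$Q, cc$K, cc$V, B, T, config$h, fw$scl)
    grads$layers[[l]]$Wq <- crossprod(cc$ln1$y, ab$dQ)
    grads$layers[[l]]$bq <- colSums(ab$dQ)
    grads$layers[[l]]$Wk <- crossprod(cc$ln1$y, ab$dK)
    grads$layers[[l]]$bk <- colSums(ab$dK)
    grads$layers[[l]]$Wv <- crossprod(cc$ln1$y, ab$dV)
    grads$layers[[l]]$bv <- colSums(ab$dV)
    dln1 <- tcrossprod(ab$dQ, lp$Wq) + tcrossprod(ab$dK, lp$Wk) +
      tcrossprod(ab$dV, lp$Wv)
    ln1b <- layernorm_backward(dln1, cc$ln1, lp$g1)
    grads$layers[[l]]$g1 <- ln1b$dg
    grads$layers[[l]]$s1 <- ln1b$ds
    dZ <- dZp1 + ln1b$dx
  }

  # embedding backward
  grads$Epos <- rowsum(dZ, rep(seq_len(T), each = B))
  dimnames(grads$Epos) <- NULL
  grads$x0 <- colSums(dZ[seq_len(B), , drop = FALSE])
  dZp <- dZ[(B + 1L):(B * T), , drop = FALSE]
  grads$E <- crossprod(fw$cache$Mw, dZp)
  grads
}

#' Forward pass: logits for a batch of windows
#'
#' Applies the transformer to one or more flattened windows and returns the
#' class logits (the linear head reads the class-token row only).
#'
#' @param params A `vit_params` parameter list.
#' @param x A single `W x n_ch x n_cv` window (array or vector) or a matrix
#'   of flattened windows (one per row).
#' @param config The matching [vit_config()].
#' @return Matrix of logits, one row per window.
#' @export
vit_logits <- function(params, x, config) {
  X <- if (is.matrix(x) && ncol(x) == config$window * config$n_ch * config$n_cv) x
       else matrix(as.vector(x), nrow = 1L)
  vit_forward(params, X, config)$logits
}
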