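test_that("parameter counts reproduce the published architecture sizes exactly", {
  expect_identical(count_parameters(standard_config("V1", 64, 32)), 46530L)
  expect_identical(count_parameters(standard_config("V1", 128, 32)), 47042L)
  expect_identical(count_parameters(standard_config("V1", 256, 32)), 48066L)
  expect_identical(count_parameters(standard_config("V1", 64, 64)), 62914L)
  expect_identical(count_parameters(standard_config("V1", 64, 128)), 95682L)
  expect_identical(count_parameters(standard_config("V1", 512, 128)), 99266L)
  expect_identical(count_parameters(standard_config("V2", 64, 128)), 273346L)
  expect_identical(count_parameters(standard_config("V2", 512, 128)), 280514L)
})

test_that("closed-form count equals the introspective trainable-tensor count", {
  for (cfg in list(standard_config("V1", 64, 32), standard_config("V2", 128, 128),
                   standard_config("V3", channels = 128),
                   standard_config("instantaneous", channels = 64),
                   tiny_config(L = 3L))) {
    p <- init_params(cfg, seed = 1)
    introspective <- emgvit:::tree_size(unclass(p)[c("E", "x0", "Epos", "layers",
                                                     "Wh", "bh")])
    expect_identical(as.integer(introspective), as.integer(count_parameters(cfg)))
  }
})

test_that("patching tiles the window exactly and invertibly", {
  cfg <- standard_config("V1", 512, 128)
  expect_equal(cfg$n_patches, 64L)
  w <- array(rnorm(512 * 16 * 8), c(512, 16, 8))
  pt <- make_patches(w, cfg)
  expect_equal(dim(pt), c(64L, 8L * 16L * 8L))
  expect_identical(unmake_patches(pt, cfg), w)
  # random shapes: N equals a brute-force count of disjoint tiles
  set.seed(7)
  for (i in 1:8) {
    H <- sample(c(2, 4, 8), 1); V <- sample(c(1, 2), 1)
    W <- H * sample(1:6, 1); n_ch <- V * sample(1:4, 1)
    cfg2 <- vit_config(d = 8, h = 2, mlp_hidden = 4, patch = c(H, V),
                       n_classes = 2, window = W, n_ch = n_ch, n_cv = 2)
    brute <- length(seq(1, W, by = H)) * length(seq(1, n_ch, by = V))
    expect_equal(cfg2$n_patches, brute)
    w2 <- array(rnorm(W * n_ch * 2), c(W, n_ch, 2))
    expect_identical(unmake_patches(make_patches(w2, cfg2), cfg2), w2)
  }
  expect_error(vit_config(patch = c(3, 8), window = 64, n_ch = 8), "divide")
})

test_that("patch counts for 128 channels follow W * n_ch / (H * V)", {
  expect_equal(standard_config("V1", 64, 128)$n_patches, 8L)
  expect_equal(standard_config("V1", 128, 128)$n_patches, 16L)
  expect_equal(standard_config("V1", 256, 128)$n_patches, 32L)
  expect_equal(standard_config("V1", 512, 128)$n_patches, 64L)
})

test_that("standard configurations match their published hyperparameters", {
  v1 <- standard_config("V1", 64, 32)
  expect_equal(c(v1$d, v1$L, v1$h, v1$mlp_hidden), c(64, 1, 8, 64))
  expect_equal(v1$patch, c(8L, 4L))
  v2 <- standard_config("V2", 64, 128)
  expect_equal(c(v2$d, v2$mlp_hidden), c(128, 256))
  expect_equal(v2$patch, c(8L, 16L))
  v3 <- standard_config("V3", channels = 128)
  expect_equal(v3$n_patches, 2L)       # two patches, sequence length 3
  inst <- standard_config("instantaneous", channels = 64)
  expect_equal(inst$n_patches, 1L)     # class token + one whole-frame patch
  expect_equal(inst$window, 1L)
  expect_error(standard_config("V1", 64, 48), "channel counts")
})

test_that("scaled dot-product attention matches a hand-rolled oracle", {
  Q <- matrix(c(1, 0.5, -0.3, 0.2), 2, 2, byrow = TRUE)
  K <- matrix(c(0.4, -1, 0.7, 0.1), 2, 2, byrow = TRUE)
  V <- matrix(c(2, 1, -1, 3), 2, 2, byrow = TRUE)
  out <- scaled_dot_product_attention(Q, K, V)
  expect_equal(out$output,
               matrix(c(0.0623168584492897, 2.29178876103381,
                        0.4311055951468357, 2.04592960323544), 2, 2, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(rowSums(out$weights), c(1, 1), tolerance = 1e-12)
  # single token: softmax of a scalar is 1
  single <- scaled_dot_product_attention(matrix(1, 1, 2), matrix(2, 1, 2),
                                         matrix(c(5, -3), 1, 2))
  expect_equal(single$output, matrix(c(5, -3), 1, 2))
  # identical keys: uniform weights, output = mean of values
  Kc <- matrix(1, 3, 2)
  Vv <- matrix(rnorm(6), 3, 2)
  unif <- scaled_dot_product_attention(matrix(rnorm(6), 3, 2), Kc, Vv)
  expect_equal(unif$output, matrix(colMeans(Vv), 3, 2, byrow = TRUE))
})

test_that("batched multi-head attention agrees with per-sample single-head math", {
  set.seed(21)
  for (T in c(5L, 20L)) {           # short and long sequence paths
    B <- 7L; d <- 8L; nh <- 2L; dh <- d / nh; scl <- 1 / sqrt(dh)
    Q <- matrix(rnorm(B * T * d), B * T)
    K <- matrix(rnorm(B * T * d), B * T)
    V <- matrix(rnorm(B * T * d), B * T)
    out <- emgvit:::mha_forward(Q, K, V, B, T, nh, scl)
    for (b in c(1L, B)) {
      rows <- b + B * (0:(T - 1))
      for (h in seq_len(nh)) {
        hc <- ((h - 1) * dh + 1):(h * dh)
        oracle <- scaled_dot_product_attention(Q[rows, hc], K[rows, hc],
                                               V[rows, hc], scale_dim = dh)
        expect_equal(out$O[rows, hc], oracle$output, tolerance = 1e-12)
        expect_equal(rowSums(oracle$weights), rep(1, T), tolerance = 1e-6)
      }
    }
  }
})

test_that("h = 1 multi-head attention equals plain single-head attention", {
  set.seed(3)
  B <- 4L; T <- 6L; d <- 8L
  Q <- matrix(rnorm(B * T * d), B * T)
  K <- matrix(rnorm(B * T * d), B * T)
  V <- matrix(rnorm(B * T * d), B * T)
  out <- emgvit:::mha_forward(Q, K, V, B, T, 1L, 1 / sqrt(d))
  rows <- 2 + B * (0:(T - 1))
  oracle <- scaled_dot_product_attention(Q[rows, ], K[rows, ], V[rows, ])
  expect_equal(out$O[rows, ], oracle$output, tolerance = 1e-12)
})

test_that("embedding is affine in the patches with the class token prepended", {
  cfg <- tiny_config()
  p <- init_params(cfg, seed = 5)
  D <- cfg$window * cfg$n_ch * cfg$n_cv
  z <- matrix(0, 1, D)
  p0 <- p; p0$Epos[] <- 0
  fw0 <- emgvit:::vit_forward(p0, z, cfg, keep_cache = TRUE)
  # zero patches, zero positions: patch tokens are zero, class row is x0
  expect_equal(fw0$cache$layers[[1]]$Zin[1, ], p0$x0)
  expect_equal(fw0$cache$layers[[1]]$Zin[-1, ], matrix(0, cfg$n_patches, cfg$d))
  # linearity of the embedding map
  x <- matrix(rnorm(D), 1)
  z0 <- function(params, xx) emgvit:::vit_forward(params, xx, cfg,
                                                  keep_cache = TRUE)$cache$layers[[1]]$Zin
  a <- 2.5
  lhs <- z0(p, a * x) - z0(p, 0 * x)
  rhs <- a * (z0(p, x) - z0(p, 0 * x))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("an all-zero encoder layer is the identity (pure residual)", {
  cfg <- tiny_config()
  p <- init_params(cfg, seed = 2)
  lp <- p$layers[[1]]
  for (nm in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo", "W1", "b1",
               "W2", "b2")) lp[[nm]][] <- 0
  p$layers[[1]] <- lp
  x <- matrix(rnorm(2 * cfg$window * cfg$n_ch * cfg$n_cv), 2)
  fw <- emgvit:::vit_forward(p, x, cfg, keep_cache = TRUE)
  expect_equal(fw$Z, fw$cache$layers[[1]]$Zin, tolerance = 1e-12)
})

test_that("the head reads only the class token and breaks ties to the lowest index", {
  cfg <- tiny_config()
  p <- init_params(cfg, seed = 9)
  x <- matrix(rnorm(3 * cfg$window * cfg$n_ch * cfg$n_cv), 3)
  base <- vit_logits(p, x, cfg)
  # identical windows give identical logits; forward is deterministic
  xx <- rbind(x[1, ], x[1, ])
  same <- vit_logits(p, xx, cfg)
  expect_equal(same[1, ], same[2, ], tolerance = 1e-12)
  expect_equal(vit_logits(p, x, cfg), base, tolerance = 1e-15)
  expect_equal(max.col(matrix(c(1, 1, 0), 1), ties.method = "first"), 1L)
})

test_that("backpropagation matches numerical gradients on both attention paths", {
  for (cfg in list(tiny_config(L = 2L),
                   vit_config(d = 8, L = 1, h = 2, mlp_hidden = 6, patch = c(1, 2),
                              n_classes = 3, window = 10, n_ch = 4, n_cv = 1))) {
    set.seed(42)
    p <- init_params(cfg, seed = 7)
    attr(p, "patch_idx") <- emgvit:::patch_indices(cfg)
    D <- cfg$window * cfg$n_ch * cfg$n_cv
    X <- matrix(rnorm(3 * D), 3)
    y <- sample(seq_len(cfg$n_classes), 3, replace = TRUE)
    tr <- unclass(p)[c("E", "x0", "Epos", "layers", "Wh", "bh")]
    lossfun <- function(trx) {
      q <- p
      for (nm in names(trx)) q[[nm]] <- trx[[nm]]
      emgvit:::ce_loss_grad(emgvit:::vit_forward(q, X, cfg)$logits, y)$loss
    }
    fw <- emgvit:::vit_forward(p, X, cfg, keep_cache = TRUE)
    gr <- emgvit:::vit_backward(p, fw, emgvit:::ce_loss_grad(fw$logits, y)$dlogits, cfg)
    gv <- emgvit:::tree_flatten(gr)
    fv <- emgvit:::tree_flatten(tr)
    check <- sample(length(fv), 60)    # spot-check a random subset
    eps <- 1e-6
    for (i in check) {
      a <- fv; a[i] <- a[i] + eps
      b <- fv; b[i] <- b[i] - eps
      num <- (lossfun(emgvit:::tree_unflatten(tr, a)) -
                lossfun(emgvit:::tree_unflatten(tr, b))) / (2 * eps)
      expect_lt(abs(num - gv[i]), 1e-6)
    }
  }
})

test_that("permuting patches changes logits only through positional embeddings", {
  cfg <- tiny_config()
  p <- init_params(cfg, seed = 31)
  D <- cfg$window * cfg$n_ch * cfg$n_cv
  x <- matrix(rnorm(D), 1)
  # build a window whose patch order is swapped
  pt <- make_patches(x, cfg)
  perm <- rev(seq_len(cfg$n_patches))
  x_perm <- matrix(as.vector(unmake_patches(pt[perm, ], cfg)), 1)
  with_pos <- vit_logits(p, x, cfg) - vit_logits(p, x_perm, cfg)
  expect_gt(max(abs(with_pos)), 1e-8)
  p0 <- p; p0$Epos[] <- 0
  without_pos <- vit_logits(p0, x, cfg) - vit_logits(p0, x_perm, cfg)
  expect_lt(max(abs(without_pos)), 1e-10)
})

test_that("the fitted model object supports the standard S3 surface", {
  set.seed(1)
  cfg <- tiny_config(n_classes = 2L)
  D <- cfg$window * cfg$n_ch * cfg$n_cv
  n <- 60
  y <- rep(1:2, length.out = n)
  X <- matrix(rnorm(n * D, mean = rep(c(-1, 1), length.out = n)), n)
  fit <- emgvit(list(x = X, labels = y), cfg,
                train_control(epochs = 5, batch_size = 16, lr = 1e-2,
                              anneal_after = 5, seed = 1))
  expect_s3_class(fit, "emgvit")
  expect_output(print(fit), "emgvit")
  sm <- summary(fit)
  expect_equal(sm$total, sm$introspective)
  expect_named(coef(fit), c("E", "x0", "Epos", "layers", "Wh", "bh"))
  expect_length(predict(fit, X), n)
  expect_equal(dim(predict(fit, X, type = "prob")), c(n, 2L))
  expect_equal(dim(predict(fit, X, type = "token")), c(n, cfg$d))
  expect_true(all(abs(rowSums(predict(fit, X, type = "prob")) - 1) < 1e-9))
  # loss decreased and the separable problem is learned
  expect_lt(tail(fit$loss_trace, 1), fit$loss_trace[1])
  expect_gt(mean(predict(fit, X) == y), 0.95)
})
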