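test_that("metrics match hand-computed values from their definitions", {
  # identity counts: everything perfect
  m <- compute_metrics(diag(c(5, 3, 2)))
  expect_equal(m$accuracy, 1)
  expect_equal(m$precision, rep(1, 3))
  expect_equal(m$recall, rep(1, 3))
  expect_equal(m$f1, rep(1, 3))
  expect_equal(m$mcc, 1)
  # symmetric binary confusion: no association
  m0 <- compute_metrics(matrix(c(10, 10, 10, 10), 2))
  expect_equal(m0$mcc, 0)
  # 3 x 3 fixture against brute-force per-class computation
  cm <- matrix(c(8, 2, 1,
                 1, 6, 0,
                 2, 1, 9), 3, 3, byrow = TRUE)
  m3 <- compute_metrics(cm)
  for (k in 1:3) {
    tp <- cm[k, k]; fp <- sum(cm[-k, k]); fn <- sum(cm[k, -k])
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    expect_equal(m3$precision[k], prec)
    expect_equal(m3$recall[k], rec)
    expect_equal(m3$f1[k], 2 * prec * rec / (prec + rec))
  }
  s <- sum(cm); c_ <- sum(diag(cm))
  pk <- colSums(cm); tk <- rowSums(cm)
  expect_equal(m3$mcc, (c_ * s - sum(pk * tk)) /
                 sqrt((s^2 - sum(pk^2)) * (s^2 - sum(tk^2))))
  expect_equal(rowSums(m3$confusion), rep(1, 3))
  expect_equal(m3$accuracy, c_ / s)
  expect_error(compute_metrics(matrix(0, 2, 2)), "all zero")
  # zero-denominator classes are flagged and scored 0
  mz <- compute_metrics(matrix(c(4, 0, 3, 0), 2))
  expect_true(mz$undefined[2])
  expect_equal(mz$precision[2], 0)
})

test_that("repetition folds partition the windows with no leakage", {
  reps <- rep(1:5, times = c(10, 12, 9, 11, 8))
  folds <- repetition_folds(reps)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_setequal(c(f$train, f$test), seq_along(reps))
    expect_true(all(reps[f$test] == f$test_repetition))
  }
  expect_setequal(vapply(folds, `[[`, numeric(1), "test_repetition"), 1:5)
  expect_error(repetition_folds(rep(1L, 10)), ">= 2")
})

test_that("a constant-class predictor scores that class's share per fold", {
  set.seed(2)
  reps <- rep(1:3, each = 30)
  labs <- sample(1:4, 90, replace = TRUE)
  folds <- repetition_folds(reps)
  for (f in folds) {
    truth <- labs[f$test]
    pred <- rep(2L, length(truth))
    expect_equal(mean(pred == truth), mean(truth == 2L))
  }
})

test_that("cross-validation trains one fold per repetition without leakage", {
  spec <- make_separable_benchmark(2L, difficulty = 0, seed = 14,
                                   repetition_duration = 1,
                                   rest_duration = 0.2, grid = c(8L, 8L),
                                   n_repetitions = 3L)
  gen <- generate_session(spec)
  ds <- preprocess_session(gen$session, window_size = 64, skip_step = 64)
  cfg <- standard_config("V1", 64, 64, n_classes = 2)
  rep_ <- crossval_by_repetition(ds, cfg,
                                 train_control(epochs = 3, anneal_after = 3, seed = 1))
  expect_length(rep_$fold_accuracies, 3L)
  folds <- attr(rep_, "folds")
  for (f in folds) expect_length(intersect(f$train, f$test), 0L)
  expect_equal(rep_$mean_accuracy, mean(rep_$fold_accuracies))
  expect_equal(sum(rep_$counts), nrow(ds$x))   # every window tested exactly once
})

test_that("shuffled-split evaluation is seeded and splits by the stated fraction", {
  spec <- make_separable_benchmark(2L, difficulty = 0, seed = 15,
                                   repetition_duration = 1,
                                   rest_duration = 0.2, grid = c(8L, 8L),
                                   n_repetitions = 2L)
  gen <- generate_session(spec)
  ds <- preprocess_session(gen$session, window_size = 64, skip_step = 64)
  cfg <- standard_config("V1", 64, 64, n_classes = 2)
  ctrl <- train_control(epochs = 2, anneal_after = 2, seed = 1)
  r1 <- shuffled_split_eval(ds, cfg, ctrl, train_fraction = 0.8, seed = 5)
  r2 <- shuffled_split_eval(ds, cfg, ctrl, train_fraction = 0.8, seed = 5)
  expect_identical(attr(r1, "split"), attr(r2, "split"))
  expect_equal(r1$fold_accuracies, r2$fold_accuracies)
  expect_length(attr(r1, "split")$train, round(0.8 * nrow(ds$x)))
  expect_error(shuffled_split_eval(ds, cfg, ctrl, train_fraction = 1), "train_fraction")
})

test_that("identical training seeds give identical fits", {
  set.seed(99)
  cfg <- tiny_config(n_classes = 2L)
  D <- cfg$window * cfg$n_ch * cfg$n_cv
  X <- matrix(rnorm(40 * D), 40)
  y <- rep(1:2, 20)
  ctrl <- train_control(epochs = 3, batch_size = 8, anneal_after = 3, seed = 4)
  f1 <- emgvit(list(x = X, labels = y), cfg, ctrl)
  f2 <- emgvit(list(x = X, labels = y), cfg, ctrl)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$params$Wh, f2$params$Wh)
  expect_error(emgvit(list(x = X, labels = rep(5L, 40)), cfg, ctrl), "labels")
})

test_that("learning-rate annealing is constant then decays monotonically", {
  ctrl <- train_control(epochs = 20, anneal_after = 10, lr = 1e-4)
  lrs <- vapply(1:20, function(e) emgvit:::lr_at_epoch(ctrl, e), numeric(1))
  expect_true(all(lrs[1:10] == 1e-4))
  expect_lt(lrs[11], lrs[10])
  expect_true(all(diff(lrs[11:20]) < 0))
  expect_gt(min(lrs), 0)
  cosine <- train_control(epochs = 20, anneal_after = 10, lr = 1e-4,
                          schedule = "cosine")
  lrc <- vapply(11:20, function(e) emgvit:::lr_at_epoch(cosine, e), numeric(1))
  expect_true(all(diff(lrc) < 0))
})

test_that("Wilcoxon comparisons annotate p-values with the conventional bins", {
  expect_equal(p_annotation(0.5), "ns")
  expect_equal(p_annotation(0.03), "*")
  expect_equal(p_annotation(0.005), "**")
  expect_equal(p_annotation(5e-4), "***")
  expect_equal(p_annotation(5e-5), "****")
  a <- c(80, 82, 85, 88, 90, 91)
  b <- c(70, 71, 74, 77, 80, 81)
  res <- wilcoxon_compare(a, b)
  expect_equal(res$p_value,
               suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))$p.value)
  expect_false(res$degenerate)
  expect_warning(deg <- wilcoxon_compare(a, a), "degenerate")
  expect_equal(deg$annotation, "ns")
  expect_error(wilcoxon_compare(a, a[-1]), "equal length")
  expect_error(wilcoxon_compare(1:3, 2:4), "at least 5")
})

test_that("positional similarity is a symmetric cosine matrix over patch rows", {
  cfg <- tiny_config()
  p <- init_params(cfg, seed = 17)
  S <- positional_similarity(p)
  N <- cfg$n_patches
  expect_equal(dim(S), c(N, N))
  expect_equal(diag(S), rep(1, N))
  expect_lt(max(abs(S - t(S))), 1e-12)
  # orthogonal rows give zero off-diagonals
  p2 <- p
  p2$Epos <- rbind(0, diag(1, N, cfg$d))
  S2 <- positional_similarity(p2)
  expect_equal(S2, diag(1, N), ignore_attr = TRUE)
  # zero-norm rows are flagged and scored 0
  p3 <- p
  p3$Epos[2, ] <- 0
  S3 <- positional_similarity(p3)
  expect_equal(attr(S3, "zero_rows"), 1L)
  expect_true(all(S3[1, ] == 0))
})

test_that("accuracy equals trace over total of the count matrix", {
  set.seed(8)
  truth <- sample(1:3, 50, replace = TRUE)
  pred <- sample(1:3, 50, replace = TRUE)
  counts <- emgvit:::confusion_counts(truth, pred, 3)
  expect_equal(compute_metrics(counts)$accuracy, mean(truth == pred))
})
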