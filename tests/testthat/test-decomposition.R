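test_that("extension and whitening honour their structural contract", {
  set.seed(13)
  x <- matrix(rnorm(400 * 6), 400, 6)
  out <- extend_and_whiten(x, R = 3)
  expect_equal(nrow(out$Z), 6L * 4L)          # channels x (R + 1)
  # unit covariance within tolerance
  Cv <- tcrossprod(out$Z) / (ncol(out$Z) - 1)
  expect_lt(max(abs(Cv - diag(nrow(Cv)))), 1e-6)
  # R = 0 on white noise: output covariance close to identity
  out0 <- extend_and_whiten(x, R = 0)
  Cv0 <- tcrossprod(out0$Z) / (ncol(out0$Z) - 1)
  expect_lt(max(abs(Cv0 - diag(6))), 1e-6)
  expect_error(extend_and_whiten(x[1:3, ], R = 10), "exceed")
  # rank-deficient input triggers the regularisation warning
  xr <- cbind(x[, 1], x[, 1], x[, 2])
  expect_warning(extend_and_whiten(xr, R = 0), "rank deficient")
})

test_that("silhouette scoring matches a brute-force per-point computation", {
  vals <- c(0.1, 0.12, 0.09, 0.11, 0.10, 0.9, 0.95, 0.88, 0.92, 0.91)
  assign <- vals > 0.5
  brute <- local({
    s <- numeric(length(vals))
    for (i in seq_along(vals)) {
      own <- which(assign == assign[i] & seq_along(vals) != i)
      oth <- which(assign != assign[i])
      a <- mean(abs(vals[i] - vals[own]))
      b <- mean(abs(vals[i] - vals[oth]))
      s[i] <- (b - a) / max(a, b)
    }
    mean(s)
  })
  expect_equal(silhouette_score(vals, assign), brute)
  # well-separated clusters approach 1; identical values give 0
  expect_gt(silhouette_score(vals, assign), 0.9)
  expect_equal(silhouette_score(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0)
  expect_equal(silhouette_score(vals, rep(TRUE, 10)), 0)   # empty cluster
  expect_equal(silhouette_score(vals, assign, scale = "unit"),
               (silhouette_score(vals, assign) + 1) / 2)
})

test_that("spike-triggered averaging recovers the injected template", {
  burst <- single_burst_session(distinct_units()[1], noise_std = 0, seed = 31)
  spikes <- burst$truth[[1]]
  tpl <- spike_triggered_average(burst$raw, spikes[1], sta_window = 20,
                                 dims = c(nrow(burst$raw), 8L, 8L))
  # a single noiseless spike reproduces the true template exactly
  true_tpl <- burst$gen$truth$templates[[1]]
  offs <- seq_len(15) - 1L - 7L
  sta_offs <- seq_len(20) - 1L - 10L
  aligned <- matrix(0, 64, 20)
  aligned[, match(offs, sta_offs)] <- true_tpl
  expect_equal(tpl[, ], aligned, ignore_attr = TRUE, tolerance = 1e-12)
  # duplicated spike indices equal the single-spike result
  tpl2 <- spike_triggered_average(burst$raw, rep(spikes[1], 3), 20,
                                  dims = c(nrow(burst$raw), 8L, 8L))
  expect_equal(tpl2[, ], tpl[, ], ignore_attr = TRUE)
  expect_error(spike_triggered_average(burst$raw, integer(0)), "at least one")
})

test_that("STA error shrinks as the number of averaged spikes grows", {
  unit <- distinct_units()[1]
  rmse <- vapply(c(2, 10, 40), function(k) {
    errs <- vapply(1:4, function(rep_seed) {
      burst <- single_burst_session(unit, noise_std = 0.15, seed = 40 + rep_seed,
                                    duration = 3)
      spikes <- burst$truth[[1]][seq_len(k)]
      tpl <- spike_triggered_average(burst$raw, spikes, 20,
                                     dims = c(nrow(burst$raw), 8L, 8L))
      true_tpl <- burst$gen$truth$templates[[1]]
      offs <- seq_len(15) - 1L - 7L
      sta_offs <- seq_len(20) - 1L - 10L
      aligned <- matrix(0, 64, 20)
      aligned[, match(offs, sta_offs)] <- true_tpl
      sqrt(mean((tpl - aligned)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("peak-to-peak images are the per-channel template range", {
  tpl <- matrix(0, 4, 20)
  tpl[2, ] <- c(rep(0, 5), 0.3, rep(0, 8), -0.2, rep(0, 5))
  img <- peak_to_peak_image(tpl, dims = c(2, 2))
  expect_equal(img[2, 1], 0.5)
  expect_equal(img[1, 1], 0)
  expect_true(all(img >= 0))
  # invariant to per-channel constant offsets
  img2 <- peak_to_peak_image(tpl + 3, dims = c(2, 2))
  expect_equal(img2, img)
  expect_equal(peak_to_peak_image(matrix(0, 4, 20), dims = c(2, 2)),
               matrix(0, 2, 2))
})

test_that("a noiseless 3-unit mixture is fully decomposed with aligned trains", {
  burst <- single_burst_session(distinct_units(), noise_std = 0, seed = 21)
  dec <- decompose_window(burst$raw, decomp_config(seed = 1),
                          dims = c(nrow(burst$raw), 8L, 8L))
  expect_gte(length(dec$spike_trains), 3L)
  per_mu <- vapply(burst$truth, function(tt)
    max(vapply(dec$spike_trains, function(sp) spike_train_f1(sp, tt)$f1,
               numeric(1))), numeric(1))
  expect_true(all(per_mu >= 0.95))
  expect_true(all(dec$silhouettes >= 0.92))
  expect_lte(length(dec$spike_trains), 7L)
  # every accepted train is strictly increasing
  for (sp in dec$spike_trains) expect_true(all(diff(sp) > 0))
})

test_that("pure noise yields no accepted sources at the default threshold", {
  set.seed(77)
  noise <- matrix(rnorm(4096 * 64, 0, 0.05), 4096)
  dec <- decompose_window(noise, decomp_config(seed = 2), dims = c(4096, 8L, 8L))
  expect_length(dec$spike_trains, 0L)
})

test_that("raising the silhouette threshold never accepts more sources", {
  burst <- single_burst_session(distinct_units(), noise_std = 0.05, seed = 23)
  white <- extend_and_whiten(burst$raw, R = 10, truncate = 10)
  counts <- vapply(c(0.5, 0.8, 0.92, 0.99), function(thr)
    length(extract_musts(white, decomp_config(silhouette_threshold = thr,
                                              seed = 1))$spike_trains),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("max_sources bounds the accepted sources", {
  burst <- single_burst_session(distinct_units(), noise_std = 0.01, seed = 25)
  dec <- decompose_window(burst$raw, decomp_config(max_sources = 2, seed = 1),
                          dims = c(nrow(burst$raw), 8L, 8L))
  expect_lte(length(dec$spike_trains), 2L)
  expect_lte(dec$n_attempted, 2L)
})

test_that("spike-train F1 alignment finds the true shift", {
  truth <- c(100L, 200L, 300L, 400L)
  est <- truth + 5L
  res <- spike_train_f1(est, truth, tol = 1, max_shift = 10)
  expect_equal(res$f1, 1)
  expect_lte(abs(res$shift + 5L), 1L)   # any shift within tolerance of -5
  expect_equal(spike_train_f1(integer(0), truth)$f1, 0)
  miss <- spike_train_f1(truth[1:2], truth)$f1
  expect_equal(miss, 2 * 2 / (2 + 4))
})
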