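#' Classification metrics from a confusion count matrix
#'
#' Per-class precision, recall and F1, the generalised (multiclass) Matthews
#' correlation coefficient, overall accuracy, and the row-normalised
#' confusion matrix. Zero-denominator classes score 0 and are flagged.
#'
#' @param counts C x C confusion matrix of counts; rows are true classes,
#'   columns predicted.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `mcc`,
#'   `confusion` (row-normalised), `counts`, and `undefined` (logical vector
#'   flagging classes whose precision or recall had a zero denominator).
#' @export
compute_metrics <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("confusion counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stopf("confusion matrix is all zero")
  C <- nrow(counts)
  tp <- diag(counts)
  pred_k <- colSums(counts)
  true_k <- rowSums(counts)
  precision <- ifelse(pred_k > 0, tp / pred_k, 0)
  recall <- ifelse(true_k > 0, tp / true_k, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  undefined <- pred_k == 0 | true_k == 0
  # generalised MCC from the count matrix
  c_ <- sum(tp); s <- total
  denom <- sqrt(s^2 - sum(pred_k^2)) * sqrt(s^2 - sum(true_k^2))
  mcc <- if (denom > 0) (c_ * s - sum(pred_k * true_k)) / denom else 0
  conf <- counts
  nz <- true_k > 0
  conf[nz, ] <- conf[nz, , drop = FALSE] / true_k[nz]
  list(accuracy = c_ / s, precision = precision, recall = recall, f1 = f1,
       mcc = mcc, confusion = conf, counts = counts, undefined = undefined)
}

confusion_counts <- function(truth, pred, n_classes) {
  tab <- table(factor(truth, levels = seq_len(n_classes)),
               factor(pred, levels = seq_len(n_classes)))
  matrix(as.numeric(tab), n_classes, n_classes)
}

#' Repetition-wise cross-validation folds
#'
#' One fold per distinct repetition id: the fold's test set is every window
#' of that repetition, the train set all remaining windows. Shared between
#' the deep models and the feature baselines so both see identical splits.
#'
#' @param repetitions Integer vector of per-window repetition ids.
#' @return List of folds, each with `test_repetition`, `train`, `test`
#'   (window indices).
#' @export
repetition_folds <- function(repetitions) {
  reps <- sort(unique(repetitions))
  if (length(reps) < 2L) stopf("repetition-wise cross-validation needs >= 2 repetitions")
  lapply(reps, function(r) {
    test <- which(repetitions == r)
    list(test_repetition = r, train = which(repetitions != r), test = test)
  })
}

eval_report <- function(fold_acc, counts, n_classes) {
  m <- compute_metrics(counts)
  structure(list(fold_accuracies = 100 * fold_acc,
                 mean_accuracy = 100 * mean(fold_acc),
                 sd_accuracy = 100 * stats::sd(fold_acc),
                 confusion = m$confusion, counts = counts,
                 precision = m$precision, recall = m$recall, f1 = m$f1,
                 mcc = m$mcc),
            class = "emgvit_report")
}

#' @export
print.emgvit_report <- function(x, ...) {
  cat(sprintf("fold accuracies (%%): %s\n",
              paste(sprintf("%.2f", x$fold_accuracies), collapse = ", ")))
  cat(sprintf("mean %.2f%% (sd %.2f), MCC %.3f\n",
              x$mean_accuracy, if (is.na(x$sd_accuracy)) 0 else x$sd_accuracy, x$mcc))
  invisible(x)
}

#' Repetition-wise cross-validated evaluation
#'
#' Trains one model per fold (each repetition held out once; its windows
#' never enter training), collects per-fold accuracy, and pools the
#' confusion counts across folds before row-normalising.
#'
#' @param dataset An `emg_windows` dataset with >= 2 repetition ids.
#' @param config A [vit_config()].
#' @param control A [train_control()]; fold `k` trains with seed
#'   `control$seed + k - 1` so folds are independent but reproducible.
#' @return An `emgvit_report`; the per-fold fits are attached as attribute
#'   `"fits"` and the fold object as `"folds"`.
#' @export
crossval_by_repetition <- function(dataset, config, control = train_control()) {
  folds <- repetition_folds(dataset$repetitions)
  C <- config$n_classes
  counts <- matrix(0, C, C)
  fold_acc <- numeric(length(folds))
  fits <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    ctrl <- control; ctrl$seed <- control$seed + k - 1L
    fit <- emgvit(list(x = dataset$x[f$train, , drop = FALSE],
                       labels = dataset$labels[f$train]),
                  config = config, control = ctrl)
    pred <- predict(fit, dataset$x[f$test, , drop = FALSE])
    truth <- dataset$labels[f$test]
    fold_acc[k] <- mean(pred == truth)
    counts <- counts + confusion_counts(truth, pred, C)
    fits[[k]] <- fit
  }
  rep_ <- eval_report(fold_acc, counts, C)
  attr(rep_, "fits") <- fits
  attr(rep_, "folds") <- folds
  rep_
}

#' Shuffled-split evaluation
#'
#' Pools windows across repetitions, shuffles them with the given seed, and
#' splits by `train_fraction`. Because windows from the same repetition can
#' land on both sides of the split, this protocol is optimistic relative to
#' repetition-wise cross-validation.
#'
#' @param dataset An `emg_windows` dataset.
#' @param config A [vit_config()].
#' @param control A [train_control()].
#' @param train_fraction Fraction of windows assigned to training (0, 1).
#' @param seed Shuffle seed.
#' @return An `emgvit_report` (single split, so the fold vector has length 1).
#' @export
shuffled_split_eval <- function(dataset, config, control = train_control(),
                                train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) stopf("train_fraction must lie in (0, 1)")
  n <- nrow(dataset$x)
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- round(train_fraction * n)
  tr <- ord[seq_len(n_train)]; te <- ord[(n_train + 1L):n]
  fit <- emgvit(list(x = dataset$x[tr, , drop = FALSE], labels = dataset$labels[tr]),
                config = config, control = control)
  pred <- predict(fit, dataset$x[te, , drop = FALSE])
  truth <- dataset$labels[te]
  counts <- confusion_counts(truth, pred, config$n_classes)
  rep_ <- eval_report(mean(pred == truth), counts, config$n_classes)
  attr(rep_, "fit") <- fit
  attr(rep_, "split") <- list(train = tr, test = te)
  rep_
}

#' Paired Wilcoxon signed-rank comparison of two accuracy vectors
#'
#' Two-sided signed-rank test on paired per-subject (or per-fold) accuracies
#' with the conventional significance annotation bins:
#' `ns` for p > 0.05, `*` for p in (0.01, 0.05], `**` for (0.001, 0.01],
#' `***` for (1e-4, 1e-3], `****` for p <= 1e-4.
#'
#' @param acc_a,acc_b Equal-length paired accuracy vectors (length >= 5).
#' @return List with `p_value`, `annotation`, and `degenerate` (TRUE when
#'   every pair is tied, reported as `ns` with a warning).
#' @export
wilcoxon_compare <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stopf("paired samples must have equal length")
  if (length(acc_a) < 5L) stopf("need at least 5 pairs")
  if (all(acc_a == acc_b)) {
    warnf("all paired differences are zero; comparison is degenerate")
    return(list(p_value = 1, annotation = "ns", degenerate = TRUE))
  }
  p <- suppressWarnings(stats::wilcox.test(acc_a, acc_b, paired = TRUE,
                                           alternative = "two.sided"))$p.value
  list(p_value = p, annotation = p_annotation(p), degenerate = FALSE)
}

#' Significance annotation for a p-value
#'
#' @param p A p-value.
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
p_annotation <- function(p) {
  if (p <= 1e-4) "****"
  else if (p <= 1e-3) "***"
  else if (p <= 1e-2) "**"
  else if (p <= 5e-2) "*"
  else "ns"
}

#' Cosine-similarity matrix of the positional embedding
#'
#' Pairwise cosine similarity between the learned positional-embedding rows
#' of the patch positions (the class-token row is excluded). Zero-norm rows
#' yield 0 entries and are flagged.
#'
#' @param params A `vit_params` list (or an `emgvit` fit).
#' @return N x N symmetric matrix with unit diagonal (where defined);
#'   attribute `"zero_rows"` flags zero-norm positions.
#' @export
positional_similarity <- function(params) {
  if (inherits(params, "emgvit")) params <- params$params
  E <- params$Epos[-1L, , drop = FALSE]
  nrm <- sqrt(rowSums(E * E))
  zero <- nrm == 0
  nrm[zero] <- 1
  En <- E / nrm
  S <- En %*% t(En)
  S[zero, ] <- 0; S[, zero] <- 0
  dg <- diag(S); dg[!zero] <- 1; diag(S) <- dg
  attr(S, "zero_rows") <- which(zero)
  S
}
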