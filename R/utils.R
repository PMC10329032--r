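# Internal helpers shared across modules.

# Gaussian error linear unit and its derivative (exact, via the normal CDF).
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Row-wise softmax of a matrix, numerically stabilised.
softmax_rows <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# Truncated-normal draws (resample outside +/- 2 sd), used for initialisation.
rtruncnorm02 <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  bad <- which(abs(x) > 2 * sd)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[abs(x[bad]) > 2 * sd]
  }
  x
}

# Broadcast a length-d vector across the rows of an n x d matrix.
row_broadcast <- function(v, n) matrix(v, nrow = n, ncol = length(v), byrow = TRUE)

# Recursively apply a function over parallel (nested) lists of arrays,
# preserving structure. Used by the Adam optimiser and gradient checks.
tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1L]]
  if (is.list(t1)) {
    out <- vector("list", length(t1))
    names(out) <- names(t1)
    for (i in seq_along(t1)) {
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

# Flatten a nested parameter list into one numeric vector (and back).
tree_flatten <- function(tree) {
  if (is.list(tree)) unlist(lapply(tree, tree_flatten), use.names = FALSE) else as.numeric(tree)
}

tree_unflatten <- function(tree, values) {
  pos <- 0L
  fill <- function(t) {
    if (is.list(t)) {
      lapply(t, fill)
    } else {
      k <- length(t)
      out <- t
      out[] <- values[(pos + 1L):(pos + k)]
      pos <<- pos + k
      out
    }
  }
  fill(tree)
}

# Number of scalars in a nested parameter list.
tree_size <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_size, numeric(1))) else length(tree)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
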