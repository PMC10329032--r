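#' Recording session container
#'
#' A labelled multichannel HD-sEMG recording. Channels are stored column-wise
#' in row-major grid order (channel = (row - 1) * cols + col).
#'
#' @param emg Numeric matrix, samples x channels.
#' @param fs Sampling frequency in Hz.
#' @param label Integer per-sample gesture id (0 = rest).
#' @param repetition Integer per-sample repetition id (0 = rest).
#' @param grid Electrode grid `c(rows, cols)`; `rows * cols` must equal the
#'   number of channels.
#' @param subject_id Free-form subject identifier.
#' @return An object of class `emg_session`.
#' @export
new_session <- function(emg, fs, label, repetition, grid, subject_id = "") {
  emg <- as.matrix(emg)
  if (nrow(emg) == 0L) stopf("session must contain at least one sample")
  if (fs <= 0) stopf("sampling frequency must be positive")
  if (length(label) != nrow(emg)) stopf("label stream length (%d) does not match emg (%d samples)",
                                        length(label), nrow(emg))
  if (length(repetition) != nrow(emg)) stopf("repetition stream length (%d) does not match emg (%d samples)",
                                             length(repetition), nrow(emg))
  grid <- as.integer(grid)
  if (prod(grid) != ncol(emg)) stopf("grid %d x %d does not match %d channels",
                                     grid[1], grid[2], ncol(emg))
  structure(list(emg = emg, fs = fs, label = as.integer(label),
                 repetition = as.integer(repetition), grid = grid,
                 subject_id = subject_id),
            class = "emg_session")
}

#' @export
print.emg_session <- function(x, ...) {
  cat(sprintf("HD-sEMG session: %d samples (%.1f s at %g Hz), %d x %d grid\n",
              nrow(x$emg), nrow(x$emg) / x$fs, x$fs, x$grid[1], x$grid[2]))
  g <- sort(unique(x$label[x$label > 0]))
  cat(sprintf("  gestures: %d, repetitions: %d, rest fraction: %.2f\n",
              length(g), length(unique(x$repetition[x$repetition > 0])),
              mean(x$label == 0)))
  invisible(x)
}

#' Write a session to disk
#'
#' Serialises an `emg_session` as a single JSON document (datasets `emg`,
#' `label`, `repetition`; attributes `fs`, `grid`, `subject_id`). Intended
#' for interchange of desk-scale sessions; the format round-trips exactly
#' through [read_session()].
#'
#' @param session An `emg_session`.
#' @param path Output file path.
#' @param digits Numeric precision written; `NA` keeps full precision.
#' @export
write_session <- function(session, path, digits = NA) {
  if (!inherits(session, "emg_session")) stopf("session must be an emg_session")
  payload <- list(format = "emgvit-session-1",
                  fs = session$fs, grid = session$grid,
                  subject_id = session$subject_id,
                  label = session$label, repetition = session$repetition,
                  emg = unclass(session$emg), emg_dim = dim(session$emg))
  jsonlite::write_json(payload, path, digits = digits, auto_unbox = TRUE)
  invisible(path)
}

#' Read a session from disk
#'
#' @param path File written by [write_session()].
#' @return An `emg_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stopf("no such session file: %s", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("fs", "emg", "label", "repetition", "grid")) {
    if (is.null(p[[field]])) stopf("session file is missing the '%s' dataset/attribute", field)
  }
  if (p$fs <= 0) stopf("session file has non-positive fs")
  emg <- p$emg
  if (is.list(emg)) emg <- do.call(rbind, emg)
  emg <- matrix(as.numeric(emg), nrow = p$emg_dim[1], ncol = p$emg_dim[2])
  new_session(emg, fs = p$fs, label = p$label, repetition = p$repetition,
              grid = p$grid, subject_id = p$subject_id %||% "")
}

#' Write decomposition ground truth to a JSON sidecar
#'
#' @param truth The `truth` component of [generate_session()].
#' @param path Output file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(spike_trains = truth$spike_trains,
                            templates = lapply(truth$templates, unclass),
                            segments = truth$segments),
                       path, digits = NA)
  invisible(path)
}
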