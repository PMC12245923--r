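#' Epoch-structured multi-channel EEG
#'
#' The central container of the package: a 3-d voltage array of shape
#' (channels x samples x trials) in microvolts, with a sampling rate, the
#' time offset of the first sample relative to stimulus onset, per-trial
#' labels and per-channel metadata.  The time axis of an epoch set is
#' `t0_offset + k / fs` for `k = 0 .. n_samples - 1`.
#'
#' @param data numeric array (n_channels x n_samples x n_trials), microvolts.
#' @param fs sampling rate in Hz.
#' @param t0_offset time of the first sample relative to stimulus onset, s.
#' @param labels data.frame with one row per trial and columns `subject`,
#'   `condition` (one of `"overt"`, `"imagined"`) and `word`.
#' @param channels channel metadata as returned by [channel_info()]; by
#'   default unnamed channels `ch1..chN` are generated.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, t0_offset, labels,
                      channels = channel_info(paste0("ch", seq_len(dim(data)[1])))) {
  if (length(dim(data)) != 3L) stop("data must be a 3-d array")
  if (!all(is.finite(data))) stop("epoch data must be finite")
  if (!is.data.frame(labels) ||
      !all(c("subject", "condition", "word") %in% names(labels)))
    stop("labels must be a data.frame with subject, condition, word")
  if (nrow(labels) != dim(data)[3L])
    stop(sprintf("label count (%d) does not match trial count (%d)",
                 nrow(labels), dim(data)[3L]))
  if (nrow(channels) != dim(data)[1L])
    stop("channel metadata does not match channel count")
  bad <- !(labels$condition %in% study_conditions())
  if (any(bad))
    stop("unknown condition in labels: ",
         paste(unique(labels$condition[bad]), collapse = ", "))
  structure(list(data = data, fs = fs, t0_offset = t0_offset,
                 labels = labels, channels = channels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d channels x %d samples x %d trials @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %.4g .. %.4g s relative to stimulus onset\n",
              x$t0_offset, x$t0_offset + (d[2] - 1) / x$fs))
  tab <- table(x$labels$condition, x$labels$word)
  print(tab)
  if (any(x$channels$is_bad))
    cat("  bad channels:",
        paste(x$channels$name[x$channels$is_bad], collapse = ", "), "\n")
  invisible(x)
}

#' Time axis of an epoch set
#' @param es an `epoch_set`.
#' @return Numeric vector of sample times in seconds relative to onset.
#' @export
epoch_times <- function(es) {
  es$t0_offset + (seq_len(dim(es$data)[2]) - 1) / es$fs
}

#' Number of trials / samples / channels
#' @param es an `epoch_set`.
#' @return Integer count.
#' @export
n_trials <- function(es) dim(es$data)[3L]

#' @rdname n_trials
#' @export
n_samples <- function(es) dim(es$data)[2L]

#' @rdname n_trials
#' @export
n_channels <- function(es) dim(es$data)[1L]

#' Subset trials of an epoch set
#'
#' Label alignment is preserved: row `i` of the labels always describes
#' slice `i` of the data array.
#'
#' @param es an `epoch_set`.
#' @param idx integer or logical trial index.
#' @return An `epoch_set` with the selected trials.
#' @export
subset_trials <- function(es, idx) {
  if (is.logical(idx)) idx <- which(idx)
  if (length(idx) == 0L) stop("trial subset is empty")
  es$data <- es$data[, , idx, drop = FALSE]
  es$labels <- es$labels[idx, , drop = FALSE]
  rownames(es$labels) <- NULL
  es
}

#' Crop an epoch set to a closed time window
#'
#' Both endpoint samples are included, so the 0..0.5 s classification
#' window at 256 Hz contains 129 samples.
#'
#' @param es an `epoch_set`.
#' @param window numeric length-2, `c(from, to)` seconds relative to onset.
#' @return A cropped `epoch_set`.
#' @export
crop_window <- function(es, window) {
  t <- epoch_times(es)
  idx <- window_indices(t, window)
  if (length(idx) == 0L)
    stop(sprintf("window [%g, %g] lies outside the epoch (%g..%g s)",
                 window[1], window[2], t[1], t[length(t)]))
  es$data <- es$data[, idx, , drop = FALSE]
  es$t0_offset <- t[idx[1]]
  es
}

#' Concatenate epoch sets trial-wise
#'
#' @param ... `epoch_set` objects with identical channels, fs and window.
#' @return A combined `epoch_set`.
#' @export
bind_trials <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "epoch_set")) sets <- sets[[1]]
  ref <- sets[[1]]
  for (es in sets[-1]) {
    if (!identical(es$channels$name, ref$channels$name))
      stop("channel mismatch between epoch sets")
    if (es$fs != ref$fs || abs(es$t0_offset - ref$t0_offset) > 1e-9 ||
        n_samples(es) != n_samples(ref))
      stop("time axis mismatch between epoch sets")
  }
  data <- array(0, c(n_channels(ref), n_samples(ref),
                     sum(vapply(sets, n_trials, 1L))))
  at <- 0L
  for (es in sets) {
    data[, , at + seq_len(n_trials(es))] <- es$data
    at <- at + n_trials(es)
  }
  labels <- do.call(rbind, lapply(sets, `[[`, "labels"))
  rownames(labels) <- NULL
  epoch_set(data, ref$fs, ref$t0_offset, labels, ref$channels)
}

#' Labelled classifier predictions
#'
#' Pairs true and predicted class labels over an ordered class set, the
#' common currency of the performance-metric functions.
#'
#' @param y_true,y_pred vectors of class labels of equal length.
#' @param class_set ordered vector of the possible labels.
#' @return An object of class `labeled_predictions`.
#' @export
labeled_predictions <- function(y_true, y_pred,
                                class_set = sort(unique(c(y_true, y_pred)))) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (!all(y_true %in% class_set) || !all(y_pred %in% class_set))
    stop("labels outside the declared class set")
  structure(list(y_true = as.character(y_true), y_pred = as.character(y_pred),
                 class_set = as.character(class_set)),
            class = "labeled_predictions")
}
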