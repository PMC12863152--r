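#' Multichannel EEG recording container
#'
#' Bundles a channels-by-samples potential matrix (microvolts) with its
#' sampling rate, channel names and epoch structure.  Epochs are half-open
#' 0-based sample intervals `[start, end)`; all processing (filtering, peak
#' detection, segmentation) treats epochs independently and never crosses
#' their boundaries.
#'
#' @param data Numeric matrix, channels x samples, no missing values.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param epochs Two-column integer matrix (`start`, `end`), 0-based,
#'   half-open, sorted, non-overlapping.  Default: one epoch spanning the
#'   whole recording.
#' @return An object of class `ms_recording`.
#' @export
recording <- function(data, fs, channel_names = rownames(data), epochs = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data))
    stop("recording data must be a numeric matrix without missing values")
  if (nrow(data) < 2) stop("a recording needs at least 2 channels")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length must equal the number of channels")
  n <- ncol(data)
  if (is.null(epochs)) epochs <- cbind(start = 0L, end = n)
  epochs <- matrix(as.integer(epochs), ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
  validate_epochs(epochs, n)
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 epochs = epochs),
            class = "ms_recording")
}

validate_epochs <- function(epochs, n_samples) {
  if (any(epochs[, "end"] <= epochs[, "start"]))
    stop("epochs must be non-empty half-open intervals [start, end)")
  if (any(epochs[, "start"] < 0) || any(epochs[, "end"] > n_samples))
    stop("epochs must lie within [0, n_samples)")
  if (nrow(epochs) > 1) {
    o <- order(epochs[, "start"])
    if (any(o != seq_len(nrow(epochs)))) stop("epochs must be sorted by start")
    if (any(epochs[-nrow(epochs), "end"] > epochs[-1, "start"]))
      stop("epochs must not overlap")
  }
  invisible(epochs)
}

#' @export
print.ms_recording <- function(x, ...) {
  cat(sprintf("<ms_recording> %d channels x %d samples @ %g Hz (%.1f s), %d epoch(s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$epochs)))
  invisible(x)
}

#' Re-reference a recording (or map matrix) to the common average
#'
#' Subtracts, at every sample, the spatial mean across channels, so each
#' column of the data sums to zero.  This is a projection: applying it twice
#' equals applying it once.
#'
#' @param x An `ms_recording`, or a channels-by-n numeric matrix of maps.
#' @return Object of the same type, average-referenced.
#' @examples
#' average_reference(matrix(c(3, 1), 2, 1))  # -> 1, -1
#' @export
average_reference <- function(x) UseMethod("average_reference")

#' @export
average_reference.ms_recording <- function(x) {
  x$data <- avg_ref_matrix(x$data)
  x
}

#' @export
average_reference.matrix <- function(x) avg_ref_matrix(x)

#' @export
average_reference.numeric <- function(x) x - mean(x)

avg_ref_matrix <- function(m) {
  sweep(m, 2, colMeans(m), "-")
}

epoch_indices <- function(epochs) {
  # list of 1-based sample index vectors, one per epoch
  lapply(seq_len(nrow(epochs)), function(i)
    seq.int(epochs[i, "start"] + 1L, epochs[i, "end"]))
}
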