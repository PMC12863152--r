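#' Zero-phase band-pass filter
#'
#' Filters every channel of every epoch with a Butterworth band-pass
#' (designed by `signal::butter`) applied forward and backward with odd
#' reflection padding, giving zero phase distortion; the two passes double
#' the effective order.  Epochs are filtered independently; an epoch too
#' short for the filter's edge padding is left unfiltered and counted in a
#' warning.
#'
#' @param rec An [recording()].
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @param order Butterworth order (applied twice by filtfilt). Default 4.
#' @return The filtered `ms_recording`.
#' @export
bandpass <- function(rec, lo = 2, hi = 20, order = 4) {
  stopifnot(inherits(rec, "ms_recording"))
  fs <- rec$fs
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    stop("band edges must satisfy 0 < lo < hi < fs/2")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  pad <- 3L * (2L * order + 1L)   # reflection padding per edge
  skipped <- 0L
  for (idx in epoch_indices(rec$epochs)) {
    if (length(idx) <= pad) { skipped <- skipped + 1L; next }
    rec$data[, idx] <- filtfilt_mat(bf$b, bf$a,
                                    rec$data[, idx, drop = FALSE], pad)
  }
  if (skipped > 0)
    warning(sprintf("%d epoch(s) shorter than the filter span were left unfiltered",
                    skipped))
  rec
}

#' Global field power
#'
#' The GFP at each sample is the spatial standard deviation of the
#' average-referenced map: `sqrt(mean((v - mean(v))^2))` across channels
#' (population form, divisor C).  It indexes the instantaneous strength of
#' the scalp field; microstate analysis samples topographies at its peaks.
#'
#' @param rec An [recording()] (will be average-referenced internally;
#'   the operation is idempotent), or a channels-by-samples matrix.
#' @return An object of class `ms_gfp`: list with `values` (per-sample GFP),
#'   `peak_indices` (initially `NULL`; see [find_gfp_peaks()]), `fs`, `epochs`.
#' @examples
#' gfp(matrix(c(1, -1), 2, 1))$values  # 1
#' @export
gfp <- function(rec) {
  if (inherits(rec, "ms_recording")) {
    m <- avg_ref_matrix(rec$data)
    fs <- rec$fs; epochs <- rec$epochs
  } else {
    m <- avg_ref_matrix(as.matrix(rec))
    fs <- NA_real_; epochs <- cbind(start = 0L, end = ncol(m))
  }
  v <- sqrt(colMeans(m^2))
  structure(list(values = v, peak_indices = NULL, fs = fs, epochs = epochs),
            class = "ms_gfp")
}

#' Locate GFP peaks
#'
#' Marks strict local maxima of the GFP series within each epoch:
#' `values[i-1] < values[i] > values[i+1]`.  A plateau (equal consecutive
#' values) counts once, at its first sample.  Epoch boundary samples are never
#' peaks.  Optional minimum peak distance and prominence constraints are
#' available but off by default.
#'
#' @param g An `ms_gfp` from [gfp()].
#' @param min_distance Minimum spacing between retained peaks, in samples
#'   (0 = none).  When two peaks are closer, the larger wins.
#' @param min_prominence Minimum GFP value for a retained peak (0 = none).
#' @return `g` with `peak_indices` filled in (0-based sample indices, sorted).
#' @examples
#' g <- gfp(matrix(rnorm(20), 2))
#' find_gfp_peaks(g)$peak_indices
#' @export
find_gfp_peaks <- function(g, min_distance = 0L, min_prominence = 0) {
  stopifnot(inherits(g, "ms_gfp"))
  v <- g$values
  peaks <- integer(0)
  for (idx in epoch_indices(g$epochs)) {
    if (length(idx) < 3) next
    p <- local_maxima(v[idx])
    if (length(p)) peaks <- c(peaks, idx[p] - 1L)  # back to 0-based
  }
  if (min_prominence > 0) peaks <- peaks[v[peaks + 1L] >= min_prominence]
  if (min_distance > 0 && length(peaks) > 1) {
    keep <- order(v[peaks + 1L], decreasing = TRUE)
    sel <- logical(length(peaks))
    taken <- integer(0)
    for (j in keep) {
      if (!length(taken) || all(abs(peaks[j] - taken) >= min_distance)) {
        sel[j] <- TRUE; taken <- c(taken, peaks[j])
      }
    }
    peaks <- peaks[sel]
  }
  g$peak_indices <- sort(peaks)
  g
}

# strict local maxima of a vector with plateau handling (first sample of a
# plateau that is a maximum); endpoints excluded. Returns 1-based positions.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  # collapse plateaus: runs of equal values
  r <- rle(v)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  inner <- 2:(k - 1)
  is_max <- r$values[inner] > r$values[inner - 1] &
    r$values[inner] > r$values[inner + 1]
  starts[inner][is_max]
}
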