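#' Assign GFP-peak topographies to their best-fitting templates
#'
#' Each peak map takes the label of the template with maximal
#' polarity-invariant spatial correlation; ties go to the lowest class index.
#' Flat (zero-variance) maps are left unassigned with a warning.
#'
#' @param peak_maps Channels-by-n matrix of maps at GFP peaks.
#' @param templates A sorted [template_set()].
#' @param polarity_invariant Ignore polarity (default `TRUE`).
#' @return Integer vector of 1-based template indices (`NA` = unassigned),
#'   with attribute `"r"` holding the winning absolute correlations.
#' @export
assign_peaks <- function(peak_maps, templates, polarity_invariant = TRUE) {
  V <- as.matrix(peak_maps)
  n <- ncol(V)
  Vc <- avg_ref_matrix(V)
  nrm <- sqrt(colSums(Vc^2))
  flat <- nrm < 1e-12
  if (any(flat))
    warning(sprintf("%d flat peak map(s) left unassigned", sum(flat)))
  R <- corr_matrix(V[, !flat, drop = FALSE], templates$maps)
  if (polarity_invariant) R <- abs(R)
  lab <- rep(NA_integer_, n)
  rwin <- rep(NA_real_, n)
  if (any(!flat)) {
    lab[!flat] <- max.col(R, ties.method = "first")
    rwin[!flat] <- R[cbind(seq_len(nrow(R)), lab[!flat])]
  }
  attr(lab, "r") <- rwin
  lab
}

#' Expand peak labels to a continuous per-sample label stream
#'
#' Within each epoch every sample takes the label of its nearest GFP peak in
#' time (the standard operationalisation of interpolating the peak assignment
#' to inter-peak periods; labels are categorical, so "interpolation" is
#' nearest-peak expansion).  A sample exactly midway between two peaks takes
#' the earlier peak's label.  Samples before the first / after the last peak
#' of an epoch take that peak's label; epochs with no peaks stay unassigned.
#'
#' @param peak_labels Integer labels per peak (NA allowed = unassigned peak).
#' @param peak_indices 0-based sample indices of the peaks, sorted.
#' @param epochs Epoch matrix (`start`,`end`), 0-based half-open.
#' @param n_samples Total number of samples.
#' @param fs Sampling rate (stored on the result).
#' @param K Number of classes (default `max(peak_labels)`).
#' @return An `ms_segmentation`: list with `labels` (per-sample, NA =
#'   unassigned), `fs`, `epochs`, `K`, and `segments` (run list: class,
#'   start, length, truncated_left, truncated_right, epoch).
#' @export
interpolate_labels <- function(peak_labels, peak_indices, epochs, n_samples,
                               fs = NA_real_, K = NULL) {
  stopifnot(length(peak_labels) == length(peak_indices))
  if (is.unsorted(peak_indices)) stop("peak_indices must be sorted")
  if (is.null(K)) K <- if (all(is.na(peak_labels))) 0L else max(peak_labels, na.rm = TRUE)
  labels <- rep(NA_integer_, n_samples)
  for (e in seq_len(nrow(epochs))) {
    s0 <- epochs[e, "start"]; s1 <- epochs[e, "end"]
    sel <- peak_indices >= s0 & peak_indices < s1
    pk <- peak_indices[sel]; pl <- peak_labels[sel]
    if (!length(pk)) next
    samp <- s0:(s1 - 1L)
    if (length(pk) == 1L) {
      labels[samp + 1L] <- pl
    } else {
      # boundaries: sample <= floor midpoint belongs to the earlier peak
      mids <- floor((head(pk, -1) + tail(pk, -1)) / 2)
      idx <- findInterval(samp, mids + 1L) + 1L  # which peak serves the sample
      labels[samp + 1L] <- pl[idx]
    }
  }
  segmentation(labels, fs = fs, epochs = epochs, K = K)
}

#' Build a segmentation from a per-sample label vector
#'
#' Derives the run-length segment list within each epoch; consecutive
#' segments always differ in class, and runs touching an epoch boundary are
#' flagged as truncated.
#'
#' @param labels Per-sample integer labels (NA = unassigned).
#' @param fs Sampling rate in Hz.
#' @param epochs Epoch matrix; default one epoch over all samples.
#' @param K Number of classes.
#' @return An object of class `ms_segmentation`.
#' @export
segmentation <- function(labels, fs, epochs = NULL, K = max(labels, na.rm = TRUE)) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (is.null(epochs)) epochs <- cbind(start = 0L, end = n)
  validate_epochs(epochs, n)
  segs <- vector("list", nrow(epochs))
  for (e in seq_len(nrow(epochs))) {
    idx <- (epochs[e, "start"] + 1L):epochs[e, "end"]
    lv <- labels[idx]
    r <- rle(lv)
    m <- length(r$lengths)
    starts <- epochs[e, "start"] + cumsum(c(0L, r$lengths))[seq_len(m)]
    segs[[e]] <- data.frame(
      class = r$values, start = starts, length = r$lengths,
      truncated_left = c(TRUE, rep(FALSE, m - 1L)),
      truncated_right = c(rep(FALSE, m - 1L), TRUE),
      epoch = e)
  }
  segs <- do.call(rbind, segs)
  segs <- segs[!is.na(segs$class), , drop = FALSE]
  rownames(segs) <- NULL
  structure(list(labels = labels, fs = fs, epochs = epochs, K = K,
                 segments = segs),
            class = "ms_segmentation")
}

#' @export
print.ms_segmentation <- function(x, ...) {
  cat(sprintf("<ms_segmentation> %d samples @ %g Hz, %d epochs, %d segments, K=%d\n",
              length(x$labels), x$fs, nrow(x$epochs), nrow(x$segments), x$K))
  invisible(x)
}

#' Backfit sorted templates to a recording
#'
#' Convenience wrapper: computes GFP and its peaks, assigns each peak map to
#' its best-fitting template, and expands the assignment to a continuous
#' per-sample microstate stream.
#'
#' @param rec An [recording()] (band-passed and average-referenced by the
#'   caller, or raw -- average referencing is applied internally).
#' @param templates A sorted [template_set()].
#' @param polarity_invariant Ignore polarity (default `TRUE`).
#' @param min_distance,min_prominence Peak constraints, see [find_gfp_peaks()].
#' @return An `ms_segmentation`.
#' @export
backfit <- function(rec, templates, polarity_invariant = TRUE,
                    min_distance = 0L, min_prominence = 0) {
  rec <- average_reference(rec)
  g <- find_gfp_peaks(gfp(rec), min_distance, min_prominence)
  pk <- g$peak_indices
  lab <- assign_peaks(rec$data[, pk + 1L, drop = FALSE], templates,
                      polarity_invariant)
  interpolate_labels(lab, pk, rec$epochs, ncol(rec$data), fs = rec$fs,
                     K = ncol(templates$maps))
}
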