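#' Microstate temporal parameters
#'
#' Computes the four classic microstate parameter families from a
#' segmentation: mean duration (ms), occurrence rate (1/s), time coverage
#' (fraction of labeled time), and the first-order segment transition matrix.
#'
#' Segments that touch an epoch boundary are of unknown true length; by
#' default (`truncated = "exclude"`) they are excluded from the duration mean
#' but still counted for occurrence and coverage.  With
#' `truncated = "include"` all runs count everywhere and the identity
#' `coverage = occurrence * duration / 1000` holds exactly.
#'
#' @param seg An `ms_segmentation`.
#' @param truncated `"exclude"` (default) or `"include"` boundary-truncated
#'   runs in the duration average.
#' @param transition `"conditional"` (rows sum to 1; default) or `"joint"`
#'   (entries sum to 1 over all ordered pairs).
#' @return An `ms_params` list: `by_class` data frame (class, n_segments,
#'   duration_ms, occurrence_per_s, coverage), `transition` K x K matrix,
#'   `n_segments`, `total_labeled_s`.
#' @export
ms_parameters <- function(seg, truncated = c("exclude", "include"),
                          transition = c("conditional", "joint")) {
  truncated <- match.arg(truncated)
  transition <- match.arg(transition)
  K <- seg$K
  total_s <- sum(!is.na(seg$labels)) / seg$fs
  by_class <- data.frame(
    class = seq_len(K),
    n_segments = vapply(seq_len(K), function(k)
      sum(seg$segments$class == k), numeric(1)),
    duration_ms = vapply(seq_len(K), function(k)
      ms_duration(seg, k, truncated), numeric(1)),
    occurrence_per_s = vapply(seq_len(K), function(k)
      ms_occurrence(seg, k), numeric(1)),
    coverage = vapply(seq_len(K), function(k)
      ms_coverage(seg, k), numeric(1)))
  structure(list(by_class = by_class,
                 transition = transition_matrix(seg, mode = transition),
                 n_segments = nrow(seg$segments),
                 total_labeled_s = total_s),
            class = "ms_params")
}

#' @export
print.ms_params <- function(x, ...) {
  cat(sprintf("<ms_params> %d segments over %.1f s labeled time\n",
              x$n_segments, x$total_labeled_s))
  print(x$by_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mean microstate duration (ms)
#'
#' Mean run length of a class's segments in milliseconds.  Boundary-truncated
#' runs are excluded by default (their true length is unknown; including them
#' biases the mean downward).
#'
#' @inheritParams ms_parameters
#' @param class 1-based class index.
#' @return Mean duration in ms; `NA` if the class has no counted segment.
#' @export
ms_duration <- function(seg, class, truncated = c("exclude", "include")) {
  truncated <- match.arg(truncated)
  s <- seg$segments[seg$segments$class == class, , drop = FALSE]
  if (truncated == "exclude")
    s <- s[!(s$truncated_left | s$truncated_right), , drop = FALSE]
  if (!nrow(s)) return(NA_real_)
  mean(s$length) / seg$fs * 1000
}

#' Microstate occurrence rate (1/s)
#'
#' Number of segments of the class per second of labeled time.
#' @inheritParams ms_duration
#' @export
ms_occurrence <- function(seg, class) {
  total_s <- sum(!is.na(seg$labels)) / seg$fs
  if (total_s <= 0) stop("no labeled time")
  sum(seg$segments$class == class) / total_s
}

#' Microstate time coverage (fraction)
#'
#' Fraction of all labeled samples spent in the class.
#' @inheritParams ms_duration
#' @export
ms_coverage <- function(seg, class) {
  lab <- seg$labels[!is.na(seg$labels)]
  if (!length(lab)) stop("no labeled time")
  mean(lab == class)
}

#' Segment-level transition matrix
#'
#' Counts ordered within-epoch segment pairs `i -> j` (`i != j`; transitions
#' never cross epoch boundaries).  `"conditional"` normalises each row by its
#' outgoing count (rows with no outgoing transition stay all-zero and are
#' flagged in attribute `"inactive"`); `"joint"` divides all entries by the
#' total transition count.
#'
#' @inheritParams ms_parameters
#' @param mode `"conditional"` (default) or `"joint"`.
#' @return K x K matrix; diagonal is structurally zero.
#' @export
transition_matrix <- function(seg, mode = c("conditional", "joint")) {
  mode <- match.arg(mode)
  K <- seg$K
  cnt <- matrix(0, K, K)
  s <- seg$segments
  if (nrow(s) > 1) {
    same <- s$epoch[-nrow(s)] == s$epoch[-1]  # segments are epoch-ordered
    from <- s$class[-nrow(s)][same]
    to <- s$class[-1][same]
    if (length(from))
      cnt <- matrix(as.numeric(table(factor(from, 1:K), factor(to, 1:K))), K, K)
  }
  if (mode == "joint") {
    tot <- sum(cnt)
    P <- if (tot > 0) cnt / tot else cnt
    attr(P, "inactive") <- which(rowSums(cnt) == 0)
    return(P)
  }
  out <- rowSums(cnt)
  P <- cnt
  act <- out > 0
  P[act, ] <- cnt[act, , drop = FALSE] / out[act]
  attr(P, "inactive") <- which(!act)
  P
}

# fast path used by simulations: parameters straight from a segment label
# sequence (single epoch, known segment lengths in samples)
params_from_segments <- function(cls, len, fs, K) {
  total <- sum(len)
  dur <- vapply(seq_len(K), function(k) {
    l <- len[cls == k]
    if (!length(l)) return(NA_real_)
    mean(l) / fs * 1000
  }, numeric(1))
  occ <- vapply(seq_len(K), function(k) sum(cls == k), numeric(1)) / (total / fs)
  cov <- vapply(seq_len(K), function(k) sum(len[cls == k]), numeric(1)) / total
  cnt <- matrix(0, K, K)
  if (length(cls) > 1) {
    from <- cls[-length(cls)]; to <- cls[-1]
    tab <- table(factor(from, 1:K), factor(to, 1:K))
    cnt <- matrix(as.numeric(tab), K, K)
  }
  out <- rowSums(cnt)
  P <- cnt
  act <- out > 0
  P[act, ] <- cnt[act, , drop = FALSE] / out[act]
  list(duration_ms = dur, occurrence_per_s = occ, coverage = cov,
       transition = P, counts = cnt)
}
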