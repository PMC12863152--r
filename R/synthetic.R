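#' Ground truth for synthetic microstate EEG
#'
#' Defines a generative model of resting-state-like EEG whose topography at
#' every instant is one of K fixed template maps, modulated by a rectified
#' sinusoidal amplitude envelope, plus spatially white Gaussian noise.  Labels
#' follow a semi-Markov process: segment classes follow a zero-diagonal
#' row-stochastic transition matrix; segment lengths are drawn from a
#' geometric (default) or gamma dwell law with per-class mean `mean_dwell`.
#'
#' Defaults mirror a typical resting-state recording regime: 1,000 Hz
#' sampling, 10 Hz alpha-band carrier, 2-s epochs, 80 ms mean dwell per class,
#' uniform off-diagonal transitions.
#'
#' @param templates An [template_set()]; default the canonical A-D atlas on
#'   the 60-channel montage.
#' @param transition K x K row-stochastic matrix with zero diagonal; default
#'   uniform over the other classes.
#' @param mean_dwell Per-class mean segment duration in ms (recycled to K).
#' @param carrier_freq Envelope carrier in Hz, in (1, 40).
#' @param snr Ratio of time-averaged template signal power to additive noise
#'   power per channel; `Inf` = noiseless.
#' @param fs Sampling rate in Hz.
#' @param epoch_s Epoch length in seconds.
#' @param peak_gfp Target GFP (microvolts) at envelope maxima.
#' @param dwell_law `"geometric"` (default) or `"gamma"`.
#' @param gamma_shape Shape for the gamma dwell law.
#' @param align_to_carrier If `TRUE` (default), segment switches fall on
#'   carrier zero crossings: dwells are drawn as whole numbers of half
#'   carrier periods (geometric or rounded-gamma counts) with the requested
#'   per-class mean preserved.  This reproduces the classic resting-EEG
#'   phenomenology -- topographies stay stable around GFP peaks and change
#'   during troughs -- and makes every segment contain at least one GFP
#'   peak.  `FALSE` draws exact sample-resolution dwells instead.
#' @return Object of class `ms_ground_truth`.
#' @export
ms_ground_truth <- function(templates = canonical_atlas(),
                            transition = NULL,
                            mean_dwell = 80,
                            carrier_freq = 10,
                            snr = 1,
                            fs = 1000,
                            epoch_s = 2,
                            peak_gfp = 5,
                            dwell_law = c("geometric", "gamma"),
                            gamma_shape = 2,
                            align_to_carrier = TRUE) {
  dwell_law <- match.arg(dwell_law)
  K <- ncol(templates$maps)
  if (is.null(transition)) {
    transition <- matrix(1 / (K - 1), K, K)
    diag(transition) <- 0
  }
  check_transition(transition, K)
  mean_dwell <- rep_len(mean_dwell, K)
  if (any(mean_dwell <= 0)) stop("mean_dwell must be positive")
  if (carrier_freq <= 1 || carrier_freq >= 40)
    stop("carrier_freq must lie in (1, 40) Hz")
  if (align_to_carrier && any(mean_dwell < 1000 / (2 * carrier_freq)))
    stop("with align_to_carrier, mean_dwell must be at least half a carrier period")
  R <- corr_matrix(templates$maps, templates$maps)
  if (max(abs(R[upper.tri(R)])) >= 0.95)
    stop("templates must be distinguishable (pairwise |r| < 0.95)")
  structure(list(templates = templates, transition = transition,
                 mean_dwell = mean_dwell, carrier_freq = carrier_freq,
                 snr = snr, fs = fs, epoch_s = epoch_s, peak_gfp = peak_gfp,
                 dwell_law = dwell_law, gamma_shape = gamma_shape,
                 align_to_carrier = align_to_carrier, K = K),
            class = "ms_ground_truth")
}

check_transition <- function(P, K) {
  if (!is.matrix(P) || nrow(P) != K || ncol(P) != K)
    stop("transition must be a K x K matrix")
  if (any(diag(P) != 0)) stop("transition diagonal must be exactly zero")
  if (any(P < 0)) stop("transition entries must be nonnegative")
  bad <- which(abs(rowSums(P) - 1) > 1e-12)
  if (length(bad))
    stop(sprintf("transition row(s) %s do not sum to 1",
                 paste(bad, collapse = ", ")))
  invisible(P)
}

#' @export
print.ms_ground_truth <- function(x, ...) {
  cat(sprintf("<ms_ground_truth> K=%d, fs=%g Hz, carrier=%g Hz, snr=%s, dwell=%s ms (%s)\n",
              x$K, x$fs, x$carrier_freq, format(x$snr),
              paste(round(x$mean_dwell), collapse = "/"), x$dwell_law))
  invisible(x)
}

#' Sample a ground-truth microstate label stream
#'
#' Draws a semi-Markov label sequence: segment classes from the ground
#' truth's transition matrix (consecutive segments never share a class, since
#' the diagonal is zero), segment lengths from the dwell law, then expands to
#' a per-sample stream cut into epochs.
#'
#' @param gt An [ms_ground_truth()].
#' @param duration_s Stream length in seconds; must cover at least 10 maximal
#'   mean dwells.
#' @param seed Optional integer seed (explicit; no hidden state).
#' @param single_epoch If `TRUE`, one epoch spans the stream (transitions are
#'   then never lost at epoch boundaries); default uses `gt$epoch_s` epochs.
#' @return An `ms_segmentation` with attribute `"true_segments"` holding the
#'   generating segment classes and lengths.
#' @export
sample_label_stream <- function(gt, duration_s, seed = NULL,
                                single_epoch = FALSE) {
  fs <- gt$fs
  n <- round(duration_s * fs)
  if (n < 10 * max(gt$mean_dwell) * fs / 1000)
    stop("stream must cover at least 10 maximal mean dwells")
  if (!is.null(seed)) set.seed(seed)
  mean_samp <- gt$mean_dwell * fs / 1000
  # draw generously, trim to n samples
  est <- ceiling(1.3 * n / min(mean_samp)) + 50
  cls <- markov_labels(gt$transition, est, -1L)
  len <- draw_dwell(gt, cls, mean_samp)
  cum <- cumsum(len)
  last <- which(cum >= n)[1]
  if (is.na(last)) {  # top up (rare)
    while (is.na(last)) {
      more <- markov_labels(gt$transition, est, cls[length(cls)] - 1L)[-1]
      lmore <- draw_dwell(gt, more, mean_samp)
      cls <- c(cls, more); len <- c(len, lmore)
      cum <- cumsum(len); last <- which(cum >= n)[1]
    }
  }
  cls <- cls[seq_len(last)]; len <- len[seq_len(last)]
  len[last] <- len[last] - (cum[last] - n)
  if (len[last] == 0L) { cls <- cls[-last]; len <- len[-last] }
  labels <- rep(cls, len)
  epochs <- if (single_epoch) cbind(start = 0L, end = n) else
    make_epochs(n, gt$epoch_s * fs)
  seg <- segmentation(labels, fs = fs, epochs = epochs, K = gt$K)
  attr(seg, "true_segments") <- data.frame(class = cls, length = len)
  seg
}

draw_dwell <- function(gt, cls, mean_samp) {
  m <- mean_samp[cls]
  if (gt$align_to_carrier) {
    # dwells in whole half carrier periods; switches land on zero crossings
    h <- gt$fs / (2 * gt$carrier_freq)        # half period, samples
    mean_count <- m / h                        # >= 1 by construction
    counts <- if (gt$dwell_law == "geometric") {
      rgeom(length(cls), prob = pmin(1, 1 / mean_count)) + 1L
    } else {
      pmax(1L, as.integer(round(rgamma(length(cls), shape = gt$gamma_shape,
                                       scale = mean_count / gt$gamma_shape))))
    }
    # cumulative rounding keeps boundaries on the zero-crossing grid for any
    # fs/carrier ratio
    b <- round(cumsum(counts) * h)
    return(as.integer(diff(c(0, b))))
  }
  if (gt$dwell_law == "geometric") {
    # support >= 1 sample, mean m
    rgeom(length(cls), prob = 1 / pmax(m, 1)) + 1L
  } else {
    pmax(1L, as.integer(round(rgamma(length(cls), shape = gt$gamma_shape,
                                     scale = m / gt$gamma_shape))))
  }
}

make_epochs <- function(n, epoch_len) {
  starts <- seq(0L, n - 1L, by = as.integer(epoch_len))
  cbind(start = starts, end = pmin(starts + as.integer(epoch_len), n))
}

#' Render synthetic EEG from a label stream
#'
#' Each sample equals the active class's template map scaled by a sinusoidal
#' carrier `sin(2 pi f t)` and a gain chosen so envelope maxima reach
#' `gt$peak_gfp` microvolts of GFP, plus spatially white Gaussian noise
#' scaled so the ratio of time-averaged signal power to noise power per
#' channel equals `gt$snr`.  The output is average-referenced per sample.
#'
#' The carrier is signed: the topography reverses polarity every half
#' period, as oscillatory scalp fields do -- this is precisely why the
#' downstream analysis is polarity-invariant.  The GFP traces the rectified
#' envelope `|sin|`, peaking twice per carrier period, and (with the ground
#' truth's default carrier alignment) microstate switches fall on envelope
#' troughs, so topographies are stable around GFP peaks and change during
#' troughs.  The in-band carrier passes a 2-20 Hz zero-phase band-pass
#' essentially untouched.
#'
#' @param labels An `ms_segmentation` from [sample_label_stream()] (all
#'   samples must be assigned).
#' @param gt The generating [ms_ground_truth()].
#' @param seed Optional integer seed for the noise.
#' @return An [recording()] carrying the label stream's epochs.
#' @export
render_eeg <- function(labels, gt, seed = NULL) {
  if (gt$fs < 2 * gt$carrier_freq)
    stop("sampling rate below twice the carrier frequency (aliasing)")
  lab <- labels$labels
  if (anyNA(lab)) stop("label stream must be fully assigned")
  if (!is.null(seed)) set.seed(seed)
  n <- length(lab)
  C <- nrow(gt$templates$maps)
  tt <- (seq_len(n) - 1) / gt$fs
  carrier <- sin(2 * pi * gt$carrier_freq * tt)
  gain <- gt$peak_gfp * sqrt(C)  # unit-norm map has spatial SD 1/sqrt(C)
  X <- gt$templates$maps[, lab, drop = FALSE] *
    rep(gain * carrier, each = C)
  if (is.finite(gt$snr)) {
    # mean signal power per channel: gain^2 * E[env^2] / C;  E[|sin|^2] = 1/2
    sigma <- sqrt(gain^2 * 0.5 / (C * gt$snr))
    X <- X + matrix(rnorm(C * n, sd = sigma), C, n)
  }
  rec <- recording(X, fs = gt$fs,
                   channel_names = gt$templates$channel_names,
                   epochs = labels$epochs)
  average_reference(rec)
}

#' @rdname sample_label_stream
#' @param object An `ms_ground_truth`.
#' @param nsim Number of recordings to simulate.
#' @param duration_s Length of each recording, seconds.
#' @param ... Unused.
#' @return For `simulate()`: a list of `ms_recording`s, each with attribute
#'   `"truth"` (its generating segmentation).
#' @export
simulate.ms_ground_truth <- function(object, nsim = 1, seed = NULL,
                                     duration_s = 60, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    seg <- sample_label_stream(object, duration_s)
    rec <- render_eeg(seg, object)
    attr(rec, "truth") <- seg
    rec
  })
}

#' Group specification for cohort simulation
#'
#' Describes one group of a two-group design: its size and the multiplicative
#' offsets ("deltas") applied to the ground truth's per-class mean dwell and
#' transition entries (rows renormalised afterwards).  Subject-level
#' log-normal jitter is applied on top.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param dwell_delta Per-class multiplicative factor on `mean_dwell`
#'   (recycled to K).
#' @param transition_delta K x K multiplicative factor on transition entries
#'   (diagonal ignored); default all 1.
#' @param age_range Range of ages to sample uniformly (years).
#' @param p_female Probability a subject is female.
#' @param jitter_sd SD of subject-level log-normal jitter on dwell and
#'   transition parameters.
#' @return Object of class `ms_group_spec`.
#' @export
group_spec <- function(n_subjects, dwell_delta = 1, transition_delta = NULL,
                       age_range = c(17, 23), p_female = 0.64,
                       jitter_sd = 0.1) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  structure(list(n_subjects = n_subjects, dwell_delta = dwell_delta,
                 transition_delta = transition_delta, age_range = age_range,
                 p_female = p_female, jitter_sd = jitter_sd),
            class = "ms_group_spec")
}

#' Direction-of-effect preset for SES group contrasts
#'
#' Encodes, as generator deltas for the low-status group, the qualitative
#' pattern reported for low- versus high-SES resting EEG: longer dwell and
#' more frequent visits of class A (boosted A-B and A-D transition entries),
#' with correspondingly reduced engagement of class C (damped B-C and C-D
#' entries).  Magnitudes are configurable; the literature reports directions,
#' not sizes.
#'
#' @param strength Fractional effect size (default 0.3 = 30\%).
#' @param K Number of classes (A..D layout assumed for K = 4).
#' @return List with `dwell_delta` and `transition_delta` suitable for
#'   [group_spec()].
#' @export
ses_effect_preset <- function(strength = 0.3, K = 4) {
  stopifnot(K == 4)
  dwell <- c(1 + strength, 1, 1, 1)
  tr <- matrix(1, K, K)
  up <- rbind(c(1, 2), c(2, 1), c(1, 4), c(4, 1))   # A<->B, A<->D
  dn <- rbind(c(2, 3), c(3, 2), c(3, 4), c(4, 3))   # B<->C, C<->D
  tr[up] <- 1 + strength
  tr[dn] <- 1 / (1 + strength)
  list(dwell_delta = dwell, transition_delta = tr)
}

apply_deltas <- function(gt, dwell_delta = 1, transition_delta = NULL,
                         jitter_sd = 0) {
  K <- gt$K
  dw <- gt$mean_dwell * rep_len(dwell_delta, K)
  P <- gt$transition
  if (!is.null(transition_delta)) P <- P * transition_delta
  if (jitter_sd > 0) {
    dw <- dw * exp(rnorm(K, sd = jitter_sd))
    P <- P * matrix(exp(rnorm(K * K, sd = jitter_sd)), K, K)
  }
  diag(P) <- 0
  P <- P / rowSums(P)
  gt$mean_dwell <- dw
  gt$transition <- P
  gt
}

#' Simulate a two-group cohort with demographics
#'
#' Generates per-subject recordings (or, cheaply, label streams only) for a
#' low- and a high-status group sharing one template set, with group deltas
#' and subject-level jitter on dwell/transition parameters, and a demographic
#' table (parental education 1-5, parental occupation 1-10, age, gender)
#' whose latent status separates the two groups.
#'
#' @param spec_low,spec_high [group_spec()]s for the two groups; deltas in
#'   `spec_low`/`spec_high` act on the shared ground truth.
#' @param gt The shared [ms_ground_truth()].
#' @param duration_s Recording length per subject, seconds.
#' @param seed Integer seed governing everything.
#' @param render `"eeg"` renders full recordings; `"labels"` returns the
#'   ground-truth segmentations only (fast path for statistical simulation).
#' @return List with `subjects` (list of per-subject lists: `id`, `group`,
#'   `recording` or `truth`, `gt` with that subject's realised parameters)
#'   and `demographics` (data frame: subject_id, group, age, gender,
#'   parent_edu_1, parent_edu_2, parent_occ_1, parent_occ_2).
#' @export
simulate_cohort <- function(spec_low, spec_high, gt, duration_s = 240,
                            seed = NULL, render = c("eeg", "labels")) {
  render <- match.arg(render)
  if (!is.null(seed)) set.seed(seed)
  specs <- list(low = spec_low, high = spec_high)
  subjects <- list()
  demo <- list()
  sid <- 0L
  for (gname in names(specs)) {
    sp <- specs[[gname]]
    for (i in seq_len(sp$n_subjects)) {
      sid <- sid + 1L
      gt_i <- apply_deltas(gt, sp$dwell_delta, sp$transition_delta,
                           jitter_sd = sp$jitter_sd)
      truth <- sample_label_stream(gt_i, duration_s)
      rec <- if (render == "eeg") render_eeg(truth, gt_i) else NULL
      subjects[[sid]] <- list(id = sprintf("S%03d", sid), group = gname,
                              recording = rec, truth = truth, gt = gt_i)
      # latent status drives parental education/occupation
      z <- if (gname == "high") rnorm(1, 1.2, 0.6) else rnorm(1, -1.2, 0.6)
      demo[[sid]] <- data.frame(
        subject_id = sprintf("S%03d", sid), group = gname,
        age = round(runif(1, sp$age_range[1], sp$age_range[2])),
        gender = ifelse(runif(1) < sp$p_female, "F", "M"),
        parent_edu_1 = clamp_int(3 + z + rnorm(1, 0, 0.7), 1, 5),
        parent_edu_2 = clamp_int(3 + z + rnorm(1, 0, 0.7), 1, 5),
        parent_occ_1 = clamp_int(5.5 + 2 * z + rnorm(1, 0, 1.2), 1, 10),
        parent_occ_2 = clamp_int(5.5 + 2 * z + rnorm(1, 0, 1.2), 1, 10))
    }
  }
  list(subjects = subjects, demographics = do.call(rbind, demo))
}

clamp_int <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))

#' Simulate a plain SES sample
#'
#' Draws `n` participants' parental education (1-5) and occupation (1-10)
#' scores from a correlated latent-status model, plus age and gender, for use
#' with [ses_score()] and [extreme_group_split()].
#'
#' @param n Number of participants.
#' @param seed Optional integer seed.
#' @return Demographic data frame (no `group` column).
#' @export
simulate_ses_sample <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- rnorm(n)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = round(runif(n, 17, 23)),
    gender = ifelse(runif(n) < 0.64, "F", "M"),
    parent_edu_1 = clamp_int(3 + z + rnorm(n, 0, 0.7), 1, 5),
    parent_edu_2 = clamp_int(3 + z + rnorm(n, 0, 0.7), 1, 5),
    parent_occ_1 = clamp_int(5.5 + 2 * z + rnorm(n, 0, 1.2), 1, 10),
    parent_occ_2 = clamp_int(5.5 + 2 * z + rnorm(n, 0, 1.2), 1, 10))
}
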