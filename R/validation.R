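#' Ground-truth recovery and calibration studies
#'
#' These functions run the package's standard self-validation experiments:
#' recovery of generator parameters through the full EEG pipeline, and
#' calibration / power of the statistics layer on label-stream cohorts.
#' They are what `scripts/acceptance.R` and the acceptance test suite
#' execute.
#'
#' @name validation
NULL

#' Transition-matrix recovery from a long label stream
#'
#' Samples a single-epoch semi-Markov label stream with approximately
#' `n_segments` segments from a default ground truth, re-estimates the
#' segment-level transition matrix and per-class mean dwell, and returns the
#' errors against the generator.
#'
#' @param n_segments Target number of segments (default 50,000).
#' @param gt Ground truth (default [ms_ground_truth()] with a non-uniform
#'   transition matrix so every entry is informative).
#' @param seed Integer seed.
#' @return List: `max_abs_error` (entrywise, estimated vs generator
#'   transition matrix), `dwell_rel_error` (per class), `n_segments`.
#' @export
transition_recovery_study <- function(n_segments = 50000, gt = NULL,
                                      seed = 1) {
  if (is.null(gt)) {
    P <- rbind(c(0, 0.5, 0.3, 0.2),
               c(0.4, 0, 0.4, 0.2),
               c(0.25, 0.25, 0, 0.5),
               c(0.1, 0.3, 0.6, 0))
    gt <- ms_ground_truth(transition = P)
  }
  # 5% margin so the realised segment count reaches the target
  duration_s <- 1.05 * n_segments * mean(gt$mean_dwell) / 1000
  seg <- sample_label_stream(gt, duration_s, seed = seed,
                             single_epoch = TRUE)
  P_hat <- transition_matrix(seg)
  ts <- attr(seg, "true_segments")
  dwell_hat <- vapply(seq_len(gt$K), function(k)
    mean(ts$length[ts$class == k]) / gt$fs * 1000, numeric(1))
  list(max_abs_error = max(abs(P_hat - gt$transition)),
       dwell_rel_error = (dwell_hat - gt$mean_dwell) / gt$mean_dwell,
       n_segments = nrow(ts))
}

#' Duration recovery through the full EEG pipeline
#'
#' Simulates a two-group cohort of synthetic recordings (no group contrast,
#' no subject jitter, so the generator's `mean_dwell` is the common truth),
#' runs the complete two-level pipeline (filter, reference, GFP peaks,
#' individual AAHC, group templates, canonical sorting, backfit,
#' parameters), and compares the cohort-mean recovered duration of every
#' class with the generating mean dwell.
#'
#' Recordings are rendered one at a time through a generator closure, so
#' memory stays flat in the cohort size.
#'
#' @param snr Signal-to-noise ratio of the rendered EEG (`Inf` = noiseless).
#' @param n_per_group Subjects per group (default 29).
#' @param duration_s Recording length per subject (default 240 s).
#' @param seed Integer seed; subject `i` uses `seed + i`.
#' @param gt Ground truth (default canonical templates, 80 ms dwell).
#' @return List: `duration_rel_error` (per class, cohort mean vs truth),
#'   `max_abs_rel_error`, `gev_by_group` (mean and sd of per-subject backfit
#'   GEV, percent), `cohort` (the fitted `ms_cohort`).
#' @export
duration_recovery_study <- function(snr = Inf, n_per_group = 29,
                                    duration_s = 240, seed = 1, gt = NULL) {
  if (is.null(gt)) gt <- ms_ground_truth(snr = snr) else gt$snr <- snr
  n <- 2 * n_per_group
  make_subject <- function(i) {
    seg <- sample_label_stream(gt, duration_s, seed = seed + i)
    render_eeg(seg, gt)
  }
  cohort <- microstate_cohort(make_subject, n_subjects = n,
                              groups = rep(c("low", "high"),
                                           each = n_per_group),
                              K = gt$K, band = c(2, 20),
                              atlas = gt$templates)
  agg <- tapply(cohort$params$duration_ms, cohort$params$class_label, mean)
  agg <- agg[gt$templates$labels]
  rel <- (agg - gt$mean_dwell) / gt$mean_dwell
  gev_by_group <- do.call(rbind, lapply(split(cohort$gev, cohort$groups),
                                        function(v)
                                          c(mean = 100 * mean(v),
                                            sd = 100 * sd(v))))
  list(duration_rel_error = rel, max_abs_rel_error = max(abs(rel)),
       gev_by_group = gev_by_group, cohort = cohort)
}

# per-subject parameters from a generated segment list (single epoch,
# all-runs mode): fast path used by the label-stream cohort studies
subject_params_from_truth <- function(cls, len, fs, K) {
  p <- params_from_segments(cls, len, fs, K)
  data.frame(class = seq_len(K), duration_ms = p$duration_ms,
             occurrence_per_s = p$occurrence_per_s, coverage = p$coverage)
}

# simulate one label-stream cohort and return the per-subject parameter
# table, transitions array, and demographics
label_cohort <- function(n_per_group, duration_s, gt, deltas_low = NULL,
                         jitter_sd = 0.1) {
  K <- gt$K
  n <- 2 * n_per_group
  groups <- rep(c("low", "high"), each = n_per_group)
  trans <- array(NA_real_, c(K, K, n))
  params <- vector("list", n)
  demo <- simulate_ses_sample(n)
  demo$group <- groups
  mean_samp <- gt$mean_dwell * gt$fs / 1000
  n_seg <- ceiling(duration_s * 1000 / mean(gt$mean_dwell))
  for (i in seq_len(n)) {
    gt_i <- if (groups[i] == "low" && !is.null(deltas_low))
      apply_deltas(gt, deltas_low$dwell_delta, deltas_low$transition_delta,
                   jitter_sd = jitter_sd)
    else
      apply_deltas(gt, jitter_sd = jitter_sd)
    cls <- markov_labels(gt_i$transition, n_seg, -1L)
    len <- draw_dwell(gt_i, cls, gt_i$mean_dwell * gt_i$fs / 1000)
    p <- params_from_segments(cls, len, gt_i$fs, K)
    trans[, , i] <- p$transition
    params[[i]] <- data.frame(subject = demo$subject_id[i], group = groups[i],
                              class = seq_len(K),
                              duration_ms = p$duration_ms,
                              occurrence_per_s = p$occurrence_per_s,
                              coverage = p$coverage)
  }
  list(params = do.call(rbind, params), transitions = trans, demo = demo)
}

#' Type-I calibration of the statistics layer under null cohorts
#'
#' Repeatedly simulates two-group label-stream cohorts with no group
#' contrast (subject-level jitter only), computes microstate parameters per
#' subject, and applies the package's tests: Pearson correlation between the
#' (independent) SES composite and class-A duration, the mixed ANCOVA
#' group-by-class interaction on duration, and the pooled t-test on the
#' A-to-B transition probability.  Under the null each should reject at the
#' nominal rate.
#'
#' @param n_replicates Number of simulated cohorts (default 1,000).
#' @param n_per_group Subjects per group (default 29).
#' @param duration_s Label-stream length per subject (default 60 s).
#' @param alpha Nominal level (default 0.05).
#' @param seed Integer seed.
#' @return List of rejection rates: `correlation`, `ancova_interaction`,
#'   `ttest_transition`, plus `n_replicates`.
#' @export
calibration_study <- function(n_replicates = 1000, n_per_group = 29,
                              duration_s = 60, alpha = 0.05, seed = 1) {
  set.seed(seed)
  gt <- ms_ground_truth(snr = 1)
  rej <- matrix(FALSE, n_replicates, 3,
                dimnames = list(NULL, c("cor", "ancova", "ttest")))
  for (r in seq_len(n_replicates)) {
    co <- label_cohort(n_per_group, duration_s, gt)
    demo <- ses_score(co$demo)
    durA <- co$params$duration_ms[co$params$class == 1]
    rej[r, "cor"] <- ms_correlate(demo$ses_z, durA)$p < alpha
    pt <- data.frame(subject = co$params$subject, group = co$params$group,
                     class = co$params$class, value = co$params$duration_ms,
                     age = demo$age[match(co$params$subject,
                                          demo$subject_id)],
                     gender = demo$gender[match(co$params$subject,
                                                demo$subject_id)])
    av <- mixed_ancova(pt)
    rej[r, "ancova"] <- av$p[av$effect == "group:class"] < alpha
    tt <- transition_ttests(co$transitions, co$demo$group)
    rej[r, "ttest"] <- tt$p[tt$from == 1 & tt$to == 2] < alpha
  }
  list(correlation = mean(rej[, "cor"]),
       ancova_interaction = mean(rej[, "ancova"]),
       ttest_transition = mean(rej[, "ttest"]),
       n_replicates = n_replicates)
}

#' Power to reproduce the low-status class-A pattern
#'
#' Simulates two-group label-stream cohorts where the low group carries the
#' [ses_effect_preset()] contrast (30\% longer class-A dwell plus boosted
#' A-B / A-D transition entries).  A replicate counts as reproducing the
#' pattern when the covariate-adjusted class-A duration contrast is
#' significant at `alpha` with the low group higher, and the low group's
#' mean class-A occurrence and coverage are also higher.
#'
#' @inheritParams calibration_study
#' @param strength Effect strength passed to [ses_effect_preset()].
#' @return List: `power_pattern` (fraction of replicates reproducing the
#'   full pattern), `power_duration` (significant duration contrast alone),
#'   `n_replicates`.
#' @export
power_study <- function(n_replicates = 200, n_per_group = 29,
                        duration_s = 60, strength = 0.3, alpha = 0.05,
                        seed = 1) {
  set.seed(seed)
  gt <- ms_ground_truth(snr = 1)
  pre <- ses_effect_preset(strength)
  hit_dur <- hit_all <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    co <- label_cohort(n_per_group, duration_s, gt, deltas_low = pre)
    demo <- co$demo
    pt <- data.frame(subject = co$params$subject, group = co$params$group,
                     class = co$params$class, value = co$params$duration_ms,
                     age = demo$age[match(co$params$subject,
                                          demo$subject_id)],
                     gender = demo$gender[match(co$params$subject,
                                                demo$subject_id)])
    ph <- posthoc_bonferroni(pt)
    rowA <- ph[ph$class == "1", ]
    # group factor levels are high < low, so a positive "low" effect means
    # the estimate for the low level exceeds high; check via group means
    mlow <- function(col) {
      x <- co$params[co$params$class == 1, ]
      mean(x[[col]][x$group == "low"]) - mean(x[[col]][x$group == "high"])
    }
    hit_dur[r] <- rowA$p_adj < alpha && mlow("duration_ms") > 0
    hit_all[r] <- hit_dur[r] && mlow("occurrence_per_s") > 0 &&
      mlow("coverage") > 0
  }
  list(power_pattern = mean(hit_all), power_duration = mean(hit_dur),
       n_replicates = n_replicates)
}
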