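#' Two-level microstate pipeline over a cohort
#'
#' Runs the standard group analysis: each subject's recording is filtered,
#' re-referenced, and clustered individually with AAHC at fixed `K`; the
#' individual template maps are pooled (per group when group labels are
#' given, matching the convention of clustering each status group
#' separately) and re-clustered into group templates; group templates are
#' sorted against the canonical atlas; each subject's maps are sorted
#' against their own group's sorted templates; finally each subject's GFP
#' peaks are backfitted with their sorted individual maps and expanded into
#' a continuous microstate stream from which duration, occurrence, coverage,
#' and the transition matrix are computed.
#'
#' Recordings may be given as in-memory objects, file paths (read with
#' [read_recording()]), or a generator `function(i)` returning the i-th
#' recording -- the pipeline holds only one recording in memory at a time.
#'
#' @param recordings List of [recording()]s / file paths, or `function(i)`.
#' @param n_subjects Required when `recordings` is a function.
#' @param groups Optional group factor (one entry per subject).
#' @param K Number of classes (default 4).
#' @param band Band-pass edges in Hz (`NULL` = none).
#' @param atlas Reference [template_set()] anchoring the A-D labels, or
#'   `NULL` to anchor on a pooled whole-cohort AAHC reference (labels then
#'   have no canonical meaning but are consistent across groups).
#' @param polarity_invariant Ignore polarity throughout (default `TRUE`).
#' @param subject_ids Optional subject identifiers.
#' @param verbose Log per-subject peak counts and GEV (default `FALSE`).
#' @return Object of class `ms_cohort`: `group_templates` (named list per
#'   group), `subject_templates`, `gev` (per-subject backfit GEV),
#'   `params` (long data frame: subject, group, class, class_label,
#'   duration_ms, occurrence_per_s, coverage), `transitions`
#'   (K x K x subjects array), `segment_counts`, `K`, `groups`.
#' @export
microstate_cohort <- function(recordings, n_subjects = NULL, groups = NULL,
                              K = 4, band = c(2, 20),
                              atlas = canonical_atlas(),
                              polarity_invariant = TRUE,
                              subject_ids = NULL, verbose = FALSE) {
  get_rec <- make_rec_source(recordings)
  if (is.null(n_subjects)) {
    if (is.function(recordings))
      stop("n_subjects is required when recordings is a generator function")
    n_subjects <- length(recordings)
  }
  if (n_subjects < 1) stop("empty subject list")
  if (is.null(groups)) groups <- rep("all", n_subjects)
  groups <- factor(groups)
  if (length(groups) != n_subjects) stop("groups must match n_subjects")
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n_subjects))

  # pass 1: individual fits (keep peak maps only, not raw data)
  indiv <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    rec <- get_rec(i)
    fit <- microstate(rec, K = K, band = band, sort_against = NULL,
                      polarity_invariant = polarity_invariant)
    indiv[[i]] <- fit
    if (verbose)
      message(sprintf("subject %s: %d peaks, unsorted GEV %.3f",
                      subject_ids[i], length(fit$peaks), fit$gev_total))
  }

  # pass 2: group templates per group, sorted against the atlas
  if (is.null(atlas)) {
    atlas <- group_templates(lapply(indiv, function(f) f$templates), K = K)
    atlas$labels <- LETTERS[seq_len(K)]
    colnames(atlas$maps) <- atlas$labels
  }
  grp_templates <- list()
  for (g in levels(groups)) {
    sel <- which(groups == g)
    gt <- group_templates(lapply(indiv[sel], function(f) f$templates), K = K)
    grp_templates[[g]] <- sort_templates(gt, atlas)
  }

  # pass 3: sort individual maps against own group's templates, backfit
  params <- list()
  trans <- array(NA_real_, c(K, K, n_subjects))
  gev_subj <- numeric(n_subjects)
  seg_counts <- integer(n_subjects)
  subj_templates <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    f <- indiv[[i]]
    st <- sort_templates(f$templates, grp_templates[[as.character(groups[i])]])
    subj_templates[[i]] <- st
    lab <- assign_peaks(f$peak_maps, st, polarity_invariant)
    g2 <- gev(f$peak_maps, f$peak_gfp, st, lab, polarity_invariant)
    gev_subj[i] <- g2$gev_total
    seg <- interpolate_labels(lab, f$peaks, f$epochs, f$n_samples,
                              fs = f$fs, K = K)
    p <- ms_parameters(seg)
    seg_counts[i] <- p$n_segments
    trans[, , i] <- p$transition
    params[[i]] <- data.frame(subject = subject_ids[i],
                              group = as.character(groups[i]),
                              class = p$by_class$class,
                              class_label = st$labels[p$by_class$class],
                              duration_ms = p$by_class$duration_ms,
                              occurrence_per_s = p$by_class$occurrence_per_s,
                              coverage = p$by_class$coverage)
    indiv[[i]]$peak_maps <- NULL  # free memory
  }
  structure(list(group_templates = grp_templates,
                 subject_templates = subj_templates,
                 gev = gev_subj, params = do.call(rbind, params),
                 transitions = trans, segment_counts = seg_counts,
                 K = K, groups = groups, subject_ids = subject_ids,
                 atlas_labels = atlas$labels),
            class = "ms_cohort")
}

make_rec_source <- function(recordings) {
  if (is.function(recordings)) return(recordings)
  function(i) {
    r <- recordings[[i]]
    if (is.character(r)) r <- read_recording(r)
    if (!inherits(r, "ms_recording")) stop("not a recording: subject ", i)
    r
  }
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat(sprintf("<ms_cohort> %d subjects, K=%d, groups: %s\n",
              length(x$gev), x$K,
              paste(levels(x$groups), collapse = "/")))
  cat(sprintf("mean backfit GEV: %.1f%%\n", 100 * mean(x$gev)))
  invisible(x)
}

#' @export
summary.ms_cohort <- function(object, ...) {
  g <- tapply(object$gev, object$groups, function(v)
    c(mean = mean(v), sd = sd(v)))
  cat(sprintf("<ms_cohort> %d subjects, K=%d\n", length(object$gev), object$K))
  for (nm in names(g))
    cat(sprintf("  %s: GEV %.2f%% (SD %.2f%%)\n",
                nm, 100 * g[[nm]]["mean"], 100 * g[[nm]]["sd"]))
  agg <- aggregate(cbind(duration_ms, occurrence_per_s, coverage) ~
                     class_label + group, data = object$params, FUN = mean)
  print(agg, row.names = FALSE, digits = 4)
  invisible(object)
}

#' Group statistics on a fitted cohort
#'
#' Applies the statistics layer to a cohort's parameter tables: mixed
#' ANCOVAs (group x class with age + gender covariates) per parameter,
#' Bonferroni-corrected per-class post hoc contrasts, independent t-tests on
#' all ordered transition probabilities, and (when SES composites are
#' supplied) Pearson correlations between SES and every per-class parameter.
#'
#' @param cohort An `ms_cohort`.
#' @param demographics Data frame with `subject_id`, `age`, `gender`, and
#'   optionally `ses_z` (see [ses_score()]).
#' @param params Which parameter families to test.
#' @return List of class `ms_group_stats`: `ancova` (per parameter),
#'   `posthoc` (per parameter), `transitions`, `correlations` (or `NULL`).
#' @export
ms_group_stats <- function(cohort, demographics,
                           params = c("duration_ms", "occurrence_per_s",
                                      "coverage")) {
  stopifnot(inherits(cohort, "ms_cohort"))
  d <- demographics[match(cohort$subject_ids, demographics$subject_id), ]
  if (anyNA(d$subject_id)) stop("demographics missing subjects")
  keep <- cohort$groups %in% names(which(table(cohort$groups) >= 2))
  ancova <- list(); posthoc <- list(); correlations <- NULL
  two_groups <- nlevels(droplevels(cohort$groups[keep])) == 2
  for (pm in params) {
    pt <- data.frame(subject = cohort$params$subject,
                     group = cohort$params$group,
                     class = cohort$params$class_label,
                     value = cohort$params[[pm]],
                     age = d$age[match(cohort$params$subject, d$subject_id)],
                     gender = d$gender[match(cohort$params$subject,
                                             d$subject_id)])
    if (two_groups) {
      ancova[[pm]] <- mixed_ancova(pt)
      posthoc[[pm]] <- posthoc_bonferroni(pt)
    }
    if (!is.null(d$ses_z)) {
      for (cl in levels(factor(pt$class))) {
        v <- pt$value[pt$class == cl][match(d$subject_id,
                                            pt$subject[pt$class == cl])]
        cc <- ms_correlate(d$ses_z, v)
        cc <- cbind(parameter = pm, class = cl, cc)
        correlations <- rbind(correlations, cc)
      }
    }
  }
  tt <- if (two_groups)
    transition_ttests(cohort$transitions[, , keep, drop = FALSE],
                      droplevels(cohort$groups[keep])) else NULL
  structure(list(ancova = ancova, posthoc = posthoc, transitions = tt,
                 correlations = correlations),
            class = "ms_group_stats")
}

#' @export
print.ms_group_stats <- function(x, ...) {
  for (pm in names(x$ancova)) {
    cat(sprintf("\n== %s: mixed ANCOVA ==\n", pm))
    print(x$ancova[[pm]], row.names = FALSE, digits = 4)
  }
  if (!is.null(x$transitions)) {
    cat("\n== transition t-tests (unadjusted) ==\n")
    print(x$transitions[x$transitions$p < 0.05 & !x$transitions$degenerate, ],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}
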