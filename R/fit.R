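#' Fit a microstate model to one recording
#'
#' The package's central fitting function.  Band-pass filters the recording
#' (zero-phase Butterworth), re-references it to the common average, computes
#' the global field power and extracts its peaks, and clusters the peak
#' topographies with polarity-invariant AAHC at fixed `K`.  If a reference
#' template set is supplied the fitted maps are sorted (and sign-aligned)
#' against it and the whole recording is backfitted into a continuous
#' microstate stream with temporal parameters.
#'
#' @param rec An [recording()].
#' @param K Number of microstate classes; the canonical choice is 4.
#' @param band Band-pass edges in Hz, or `NULL` to skip filtering.
#' @param sort_against Optional [template_set()] (e.g. [canonical_atlas()] or
#'   group templates) to sort the fitted maps and backfit.  `NULL` leaves the
#'   maps unsorted and skips segmentation.
#' @param polarity_invariant Ignore map polarity throughout (default `TRUE`).
#' @param min_distance,min_prominence GFP-peak constraints
#'   (see [find_gfp_peaks()]).
#' @return An object of class `ms_fit`: `templates`, `gev_total`,
#'   `gev_per_class`, `peaks` (indices), `peak_gfp`, `peak_assignment`,
#'   `segmentation` + `params` (when sorted), `K`, `fs`, `call`.
#' @seealso [microstate_cohort()] for the two-level group pipeline.
#' @examples
#' gt <- ms_ground_truth(snr = 4)
#' rec <- simulate(gt, seed = 1, duration_s = 4)[[1]]
#' fit <- microstate(rec, K = 4, sort_against = canonical_atlas())
#' fit
#' @export
microstate <- function(rec, K = 4, band = c(2, 20), sort_against = NULL,
                       polarity_invariant = TRUE,
                       min_distance = 0L, min_prominence = 0) {
  stopifnot(inherits(rec, "ms_recording"))
  if (!is.null(band)) rec <- bandpass(rec, band[1], band[2])
  rec <- average_reference(rec)
  g <- find_gfp_peaks(gfp(rec), min_distance, min_prominence)
  pk <- g$peak_indices
  if (length(pk) < K)
    stop(sprintf("only %d GFP peaks found; need at least K=%d", length(pk), K))
  peak_maps <- rec$data[, pk + 1L, drop = FALSE]
  peak_gfp <- g$values[pk + 1L]
  fit <- aahc(peak_maps, weights = peak_gfp, K = K)
  templates <- fit$templates
  segmentation <- NULL
  params <- NULL
  peak_assignment <- fit$assignment
  gev_total <- fit$gev_total
  gev_per_class <- fit$gev_per_class
  if (!is.null(sort_against)) {
    templates <- sort_templates(templates, sort_against)
    peak_assignment <- assign_peaks(peak_maps, templates, polarity_invariant)
    g2 <- gev(peak_maps, peak_gfp, templates, peak_assignment,
              polarity_invariant)
    gev_total <- g2$gev_total
    gev_per_class <- g2$gev_per_class
    segmentation <- interpolate_labels(peak_assignment, pk, rec$epochs,
                                       ncol(rec$data), fs = rec$fs, K = K)
    params <- ms_parameters(segmentation)
  }
  structure(list(templates = templates, gev_total = gev_total,
                 gev_per_class = gev_per_class, peaks = pk,
                 peak_gfp = peak_gfp, peak_maps = peak_maps,
                 peak_assignment = peak_assignment,
                 segmentation = segmentation, params = params,
                 K = K, fs = rec$fs, n_samples = ncol(rec$data),
                 epochs = rec$epochs,
                 polarity_invariant = polarity_invariant,
                 call = match.call()),
            class = "ms_fit")
}

#' @export
print.ms_fit <- function(x, ...) {
  cat(sprintf("Microstate fit: K=%d classes, %d GFP peaks, GEV = %.1f%%\n",
              x$K, length(x$peaks), 100 * x$gev_total))
  cat("Templates:", paste(x$templates$labels, collapse = " "),
      sprintf("(%s)\n", x$templates$level))
  invisible(x)
}

#' @export
summary.ms_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ms_fit")
}

#' @export
print.summary.ms_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("GEV per class: %s\n",
              paste(sprintf("%s=%.1f%%", names(f$gev_per_class),
                            100 * f$gev_per_class), collapse = ", ")))
  if (!is.null(f$params)) {
    cat("\nTemporal parameters:\n")
    bc <- f$params$by_class
    bc$class <- f$templates$labels[bc$class]
    print(bc, row.names = FALSE, digits = 4)
    cat("\nTransition probabilities (row = from):\n")
    P <- matrix(f$params$transition, f$K, f$K,
                dimnames = list(f$templates$labels, f$templates$labels))
    print(round(P, 3))
  }
  invisible(x)
}

#' @export
coef.ms_fit <- function(object, ...) object$templates$maps

#' Backfit a fitted microstate model to (new) data
#'
#' @param object An `ms_fit` with sorted templates.
#' @param newdata An [recording()]; its GFP peaks are assigned to the fitted
#'   templates and expanded to a per-sample stream.
#' @param ... Unused.
#' @return An `ms_segmentation`.
#' @export
predict.ms_fit <- function(object, newdata, ...) {
  backfit(newdata, object$templates,
          polarity_invariant = object$polarity_invariant)
}

#' @export
residuals.ms_fit <- function(object, ...) {
  # per-peak unexplained topographic variance: 1 - r^2 against the assigned
  # template (GFP-independent misfit measure)
  R <- corr_matrix(object$peak_maps, object$templates$maps)
  ok <- !is.na(object$peak_assignment)
  r <- rep(NA_real_, length(object$peak_assignment))
  r[ok] <- R[cbind(which(ok), object$peak_assignment[ok])]
  1 - r^2
}

#' Plot fitted template maps
#'
#' Draws each template as a colour-coded sensor map on the montage's 2-D
#' projection (base graphics; red positive, blue negative).
#'
#' @param x An `ms_fit` or `ms_templates`.
#' @param montage Montage data frame matching the channel count.
#' @param ... Passed to [graphics::symbols()].
#' @export
plot.ms_fit <- function(x, montage = standard_montage(), ...) {
  plot(x$templates, montage = montage, ...)
}

#' @export
plot.ms_templates <- function(x, montage = standard_montage(), ...) {
  maps <- x$maps
  K <- ncol(maps)
  if (nrow(montage) != nrow(maps))
    stop("montage does not match the template channel count")
  pal <- colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  old <- par(mfrow = c(1, K), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(par(old))
  for (k in seq_len(K)) {
    v <- maps[, k]
    col <- pal[round(50 * v / max(abs(v))) + 51]
    plot(montage$x, montage$y, asp = 1, axes = FALSE, xlab = "", ylab = "",
         pch = 21, bg = col, cex = 2, ...)
    title(x$labels[k])
  }
  invisible(x)
}
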