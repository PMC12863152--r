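#' Template set container
#'
#' An ordered, labelled set of K microstate template maps.  Each map is
#' average-referenced (spatial mean 0) and unit-L2-normalised; polarity is
#' arbitrary unless the set has been sorted against a reference.
#'
#' @param maps Channels-by-K numeric matrix of topographies (columns are
#'   maps); normalised internally.
#' @param labels Character vector of K unique class names.  Default
#'   `"1".."K"` for unsorted sets.
#' @param channel_names Optional channel names.
#' @param level Provenance: `"individual"`, `"group"` or `"canonical"`.
#' @return Object of class `ms_templates` with elements `maps`, `labels`,
#'   `channel_names`, `level`.
#' @export
template_set <- function(maps, labels = NULL, channel_names = rownames(maps),
                         level = "individual") {
  maps <- as.matrix(maps)
  K <- ncol(maps)
  if (K < 2) stop("a template set needs K >= 2 maps")
  maps <- avg_ref_matrix(maps)
  nrm <- sqrt(colSums(maps^2))
  if (any(nrm < 1e-12)) stop("flat (zero-variance) template map")
  maps <- sweep(maps, 2, nrm, "/")
  if (is.null(labels)) labels <- as.character(seq_len(K))
  if (anyDuplicated(labels)) stop("template labels must be unique")
  colnames(maps) <- labels
  if (!is.null(channel_names)) rownames(maps) <- channel_names
  structure(list(maps = maps, labels = labels,
                 channel_names = channel_names, level = level),
            class = "ms_templates")
}

#' @export
print.ms_templates <- function(x, ...) {
  cat(sprintf("<ms_templates> K=%d [%s], %d channels, level=%s\n",
              ncol(x$maps), paste(x$labels, collapse = ","),
              nrow(x$maps), x$level))
  invisible(x)
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation of two scalp maps across channels.  With
#' `polarity_invariant = TRUE` (the microstate convention) the absolute value
#' is returned, treating a map and its sign-inverse as identical.
#'
#' @param a,b Numeric vectors of equal length (one value per channel).
#' @param polarity_invariant Ignore map polarity? Default `TRUE`.
#' @return Scalar in `[0, 1]` (invariant) or `[-1, 1]`.
#' @examples
#' spatial_correlation(c(1, -1, 0), -c(1, -1, 0))  # 1
#' @export
spatial_correlation <- function(a, b, polarity_invariant = TRUE) {
  if (length(a) != length(b)) stop("maps must share the channel count")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12)
    stop("spatial correlation undefined for a flat (zero-variance) map")
  r <- sum(a * b) / (na * nb)
  if (polarity_invariant) abs(r) else r
}

# correlation of every column of V (centered) against every column of C:
# returns n x k matrix of signed Pearson r
corr_matrix <- function(V, C) {
  Vc <- avg_ref_matrix(V); Cc <- avg_ref_matrix(C)
  Vn <- sweep(Vc, 2, pmax(sqrt(colSums(Vc^2)), 1e-300), "/")
  Cn <- sweep(Cc, 2, pmax(sqrt(colSums(Cc^2)), 1e-300), "/")
  crossprod(Vn, Cn)
}

#' Atomize-agglomerate hierarchical clustering of topographies
#'
#' Polarity-invariant AAHC: every map starts as its own cluster; the cluster
#' contributing least to the global explained variance (GEV) is repeatedly
#' dissolved ("atomized") and each of its maps is reassigned independently to
#' the surviving cluster whose centroid it matches best by absolute spatial
#' correlation.  Centroids are the first principal direction of the member
#' maps (GFP-weighted scatter), which is the polarity-invariant analogue of
#' the mean.  The procedure stops at `K` clusters and is deterministic given
#' the input order; ties (equal GEV contributions or equal correlations) go
#' to the lowest cluster index.
#'
#' @param peak_maps Channels-by-n matrix of (average-referenced) topographies,
#'   typically the maps at GFP peaks.
#' @param weights Per-map weights, typically the GFP at each peak.  Default:
#'   the spatial SD of each supplied map.
#' @param K Number of clusters to keep.
#' @return An `ms_fitlist`-free list of class `ms_clusterfit`: `templates`
#'   (an [template_set()]), `assignment` (per-map 1-based class index),
#'   `gev_total`, `gev_per_class`.
#' @export
aahc <- function(peak_maps, weights = NULL, K = 4) {
  V <- as.matrix(peak_maps)
  n <- ncol(V)
  if (n < K) stop(sprintf("AAHC needs at least K=%d maps, got %d", K, n))
  V <- avg_ref_matrix(V)
  nrm <- sqrt(colSums(V^2))
  if (any(nrm < 1e-12)) stop("flat map(s) supplied to aahc")
  if (is.null(weights)) weights <- nrm / sqrt(nrow(V))
  if (length(weights) != n) stop("weights must have one entry per map")
  Vn <- sweep(V, 2, nrm, "/")
  res <- aahc_core(Vn, as.numeric(weights)^2, as.integer(K))
  assignment <- res$assignment + 1L
  templates <- template_set(res$centroids, level = "individual",
                            channel_names = rownames(peak_maps))
  g <- gev(V, weights, templates, assignment)
  structure(list(templates = templates, assignment = assignment,
                 gev_total = g$gev_total, gev_per_class = g$gev_per_class),
            class = "ms_clusterfit")
}

#' @export
print.ms_clusterfit <- function(x, ...) {
  cat(sprintf("<ms_clusterfit> K=%d over %d maps, GEV=%.4f\n",
              ncol(x$templates$maps), length(x$assignment), x$gev_total))
  invisible(x)
}

#' Global explained variance of a labelled set of maps
#'
#' GEV is the GFP-weighted fraction of topographic variance explained by
#' representing each map by its assigned template:
#' `sum_t (w_t * r_t)^2 / sum_t w_t^2`, where `w_t` is the GFP of map `t` and
#' `r_t` its (polarity-invariant) spatial correlation with the assigned
#' template.  Per-class components partition the numerator by assigned class.
#'
#' @param peak_maps Channels-by-n matrix of maps.
#' @param weights Per-map GFP weights.
#' @param templates An [template_set()].
#' @param assignment Per-map 1-based template index.
#' @param polarity_invariant Ignore polarity (default `TRUE`).
#' @return List with `gev_total` and `gev_per_class` (named by template
#'   labels; sums to `gev_total`).
#' @export
gev <- function(peak_maps, weights, templates, assignment,
                polarity_invariant = TRUE) {
  V <- as.matrix(peak_maps)
  n <- ncol(V)
  stopifnot(length(assignment) == n, length(weights) == n)
  R <- corr_matrix(V, templates$maps)
  r <- R[cbind(seq_len(n), assignment)]
  if (polarity_invariant) r <- abs(r)
  w2 <- as.numeric(weights)^2
  denom <- sum(w2)
  contrib <- w2 * r^2
  per_class <- vapply(seq_len(ncol(templates$maps)),
                      function(k) sum(contrib[assignment == k]), numeric(1))
  names(per_class) <- templates$labels
  list(gev_total = sum(contrib) / denom, gev_per_class = per_class / denom)
}

#' Group-level template maps from individual fits
#'
#' Pools the individual template maps of all subjects and re-clusters them
#' with [aahc()] (uniform weights) at the same `K`, the standard two-level
#' procedure for deriving group mean maps under polarity invariance.  A
#' simple label-wise averaging mode (first principal direction per label
#' across subjects) is available for pre-sorted fits.
#'
#' @param individual_fits List of `ms_clusterfit` (or `ms_templates`) objects
#'   sharing a montage and `K`.
#' @param K Number of group clusters (default: the individuals' `K`).
#' @param method `"aahc"` (default) or `"average"` (requires identically
#'   labelled, sorted inputs).
#' @return An [template_set()] with `level = "group"`.
#' @export
group_templates <- function(individual_fits, K = NULL, method = c("aahc", "average")) {
  method <- match.arg(method)
  tls <- lapply(individual_fits, function(f)
    if (inherits(f, "ms_clusterfit")) f$templates else f)
  C <- nrow(tls[[1]]$maps)
  for (i in seq_along(tls)) {
    if (nrow(tls[[i]]$maps) != C)
      stop(sprintf("montage mismatch for subject %d", i))
  }
  if (is.null(K)) K <- ncol(tls[[1]]$maps)
  pooled <- do.call(cbind, lapply(tls, function(t) t$maps))
  if (method == "aahc") {
    fit <- aahc(pooled, weights = rep(1, ncol(pooled)), K = K)
    ts <- fit$templates
  } else {
    labs <- tls[[1]]$labels
    maps <- sapply(labs, function(lb) {
      M <- sapply(tls, function(t) t$maps[, lb])
      principal_direction(M)
    })
    ts <- template_set(maps, labels = labs,
                       channel_names = tls[[1]]$channel_names)
  }
  ts$level <- "group"
  ts
}

# first principal direction (sign-aligned mean) of a set of column maps
principal_direction <- function(M) {
  S <- tcrossprod(avg_ref_matrix(M))
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1]
  # deterministic sign convention: largest-magnitude channel positive
  s <- sign(v[which.max(abs(v))])
  if (s == 0) s <- 1
  v * s
}
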