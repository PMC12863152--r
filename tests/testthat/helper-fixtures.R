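# Shared fixtures: small montages, orthogonal template sets, toy recordings.
# Everything is generated in code; heavy cohort simulations live only in
# test-acceptance.R.

# k orthogonal, average-referenced, unit-norm maps on c channels (c > k)
orthogonal_maps <- function(c = 8, k = 4) {
  stopifnot(c > k)
  # Helmert-style contrasts are zero-mean and mutually orthogonal
  H <- stats::contr.helmert(c)[, seq_len(k), drop = FALSE]
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

# small ground truth on a tiny montage for fast simulations
tiny_gt <- function(snr = Inf, fs = 500, K = 4, C = 12, mean_dwell = 80,
                    transition = NULL, ...) {
  maps <- orthogonal_maps(C, K)
  ts <- template_set(maps, labels = LETTERS[seq_len(K)])
  ms_ground_truth(templates = ts, transition = transition,
                  mean_dwell = mean_dwell, snr = snr, fs = fs, ...)
}

# exhaustive AAHC oracle: best achievable GEV over every assignment of n
# maps into exactly K non-empty clusters, centroid = top eigenvector of the
# weighted scatter (same objective AAHC optimises greedily)
best_gev_exhaustive <- function(V, weights, K) {
  V <- sweep(V, 2, colMeans(V), "-")
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  n <- ncol(V)
  w2 <- weights^2
  denom <- sum(w2)
  grid <- do.call(expand.grid, rep(list(seq_len(K)), n))
  best <- 0
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (length(unique(a)) < K) next
    tot <- 0
    for (k in seq_len(K)) {
      idx <- which(a == k)
      S <- matrix(0, nrow(V), nrow(V))
      for (i in idx) S <- S + w2[i] * tcrossprod(V[, i])
      tot <- tot + max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    }
    best <- max(best, tot / denom)
  }
  best
}

# empirical conditional transition matrix from a segment class sequence
params_from_segments_test <- function(cls, K) {
  from <- cls[-length(cls)]; to <- cls[-1]
  cnt <- matrix(as.numeric(table(factor(from, 1:K), factor(to, 1:K))), K, K)
  cnt / rowSums(cnt)
}

# column-wise Pearson correlations between two map matrices (test-side)
corr_matrix_test <- function(A, B) {
  stats::cor(A, B)
}

# brute-force optimal assignment oracle over all K! permutations
best_perm_bruteforce <- function(S) {
  K <- nrow(S)
  perms <- all_perms(K)
  scores <- vapply(seq_len(nrow(perms)), function(i)
    sum(S[cbind(perms[i, ], seq_len(K))]), numeric(1))
  list(perm = perms[which.max(scores), ], score = max(scores))
}

all_perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- all_perms(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}
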