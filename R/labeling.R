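#' Sort template maps into canonical order
#'
#' Finds the one-to-one assignment of unsorted maps to reference labels that
#' maximises the total polarity-invariant spatial correlation (exact
#' assignment, solved by dynamic programming over label subsets), then
#' reorders, relabels, and sign-aligns each map so it correlates positively
#' with its reference.  Used at the group level against the canonical A-D
#' atlas and at the individual level against the group templates.
#'
#' @param unsorted An [template_set()] to sort.
#' @param reference An [template_set()] (canonical atlas or group templates)
#'   with the same `K` and montage.
#' @return The sorted `ms_templates`, carrying the reference's labels and an
#'   attribute `"match_r"` with the per-map absolute correlations.
#' @examples
#' atlas <- canonical_atlas()
#' shuf <- template_set(atlas$maps[, c(3, 1, 4, 2)] %*% diag(c(1, -1, 1, -1)))
#' sort_templates(shuf, atlas)$labels  # "A" "B" "C" "D"
#' @export
sort_templates <- function(unsorted, reference) {
  if (ncol(unsorted$maps) != ncol(reference$maps))
    stop("K mismatch between template sets")
  if (nrow(unsorted$maps) != nrow(reference$maps))
    stop("montage mismatch between template sets")
  K <- ncol(unsorted$maps)
  R <- corr_matrix(unsorted$maps, reference$maps)  # K x K signed r
  perm <- solve_assignment(abs(R))  # perm[j] = which unsorted map gets label j
  maps <- unsorted$maps[, perm, drop = FALSE]
  rsel <- R[cbind(perm, seq_len(K))]
  flip <- ifelse(rsel < 0, -1, 1)
  maps <- sweep(maps, 2, flip, "*")
  out <- template_set(maps, labels = reference$labels,
                      channel_names = unsorted$channel_names,
                      level = unsorted$level)
  attr(out, "match_r") <- abs(rsel)
  out
}

#' Exact linear assignment by subset dynamic programming
#'
#' Maximises `sum_j S[perm[j], j]` over permutations `perm`.  Exact for any
#' square score matrix; O(K 2^K), intended for the small K of microstate
#' sorting.
#'
#' @param S Square score matrix (rows: items, columns: slots).
#' @return Integer vector `perm` with `perm[j]` the row assigned to column `j`.
#' @keywords internal
solve_assignment <- function(S) {
  K <- nrow(S)
  if (K != ncol(S)) stop("score matrix must be square")
  if (K > 20) stop("assignment solver intended for small K")
  nmask <- bitwShiftL(1L, K)
  best <- rep(-Inf, nmask)       # best[mask]: max score using rows in mask
  choice <- vector("list", nmask)  # row chosen for the last filled column
  best[1] <- 0
  for (mask in seq_len(nmask - 1)) {
    j <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(K - 1))) != 0)  # popcount = column j
    for (i in seq_len(K)) {
      bit <- bitwShiftL(1L, i - 1L)
      if (bitwAnd(mask, bit) == 0) next
      prev <- bitwXor(mask, bit)
      cand <- best[prev + 1] + S[i, j]
      if (cand > best[mask + 1]) {
        best[mask + 1] <- cand
        choice[[mask + 1]] <- i
      }
    }
  }
  perm <- integer(K)
  mask <- nmask - 1L
  for (j in K:1) {
    i <- choice[[mask + 1]]
    perm[j] <- i
    mask <- bitwXor(mask, bitwShiftL(1L, i - 1L))
  }
  perm
}
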