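#' Exhaustive best order (brute-force oracle)
#'
#' Enumerates every distinct marker order — all k!/2 canonical permutations,
#' exploiting the reversal symmetry of SARF — and returns the global SARF
#' minimizer. Intended as a ground-truth oracle for small marker sets when
#' validating heuristic orderers; refuses to run beyond `max_k` markers.
#'
#' @param D a [distance_matrix()].
#' @param max_k combinatorial guard (default 9; 9!/2 = 181440 orders).
#' @return a list with `order` (canonical permutation, ties broken
#'   lexicographically), `sarf`, and `n_evaluated`.
#' @examples
#' D <- true_distance_matrix(demo_genome(), group = 4)
#' exhaustive_best_order(D)$sarf  # 100 cM
#' @export
exhaustive_best_order <- function(D, max_k = 9L) {
  stopifnot(inherits(D, "dist_matrix"))
  k <- nrow(D$d)
  if (k < 2L) stop("need at least 2 markers")
  if (k > max_k)
    stop("refusing exhaustive search for k = ", k, " > max_k = ", max_k)
  perms <- all_permutations(k)
  canon <- perms[perms[, 1L] < perms[, k], , drop = FALSE]
  d <- D$d
  vals <- numeric(nrow(canon))
  for (j in seq_len(k - 1L))
    vals <- vals + d[canon[, j] + (canon[, j + 1L] - 1L) * k]
  # lexicographic tie-break: all_permutations emits rows in lexicographic
  # order, so the first minimizer is the lexicographically smallest
  best <- which.min(vals)
  list(order = as.integer(canon[best, ]), sarf = vals[best],
       n_evaluated = nrow(canon))
}

# all k! permutations of 1..k, one per row, in lexicographic order
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  row <- 1L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    block <- cbind(first, matrix(rest[sub], nrow(sub), k - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}
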