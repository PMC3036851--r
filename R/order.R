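#' Canonicalize a marker order
#'
#' A marker order and its reversal describe the same linkage map, so orders
#' are canonicalized to the representative whose first marker index is
#' smaller than its last. Idempotent.
#'
#' @param order integer permutation of `1..k`.
#' @return the canonical permutation (the input or its reversal).
#' @examples
#' canonicalize_order(c(4, 2, 1, 3))  # -> 3 1 2 4
#' @export
canonicalize_order <- function(order) {
  order <- check_order(order)
  k <- length(order)
  if (k >= 2L && order[1L] > order[k]) rev(order) else order
}

check_order <- function(order, k = NULL) {
  order <- as.integer(order)
  n <- length(order)
  if (!is.null(k) && n != k)
    stop("order has length ", n, " but the distance matrix has ", k, " markers")
  if (n < 1L || anyNA(order) || !setequal(order, seq_len(n)))
    stop("'order' must be a permutation of 1..k")
  order
}

#' Sum of adjacent recombination fractions (SARF) of a marker order
#'
#' The ordering criterion: the total distance walked along the markers in the
#' given order, \eqn{f(x) = \sum_{i=1}^{k-1} D[\sigma_i, \sigma_{i+1}]}.
#' Invariant under order reversal. Units follow `D$units` (cM by default).
#'
#' @param order integer permutation of `1..k`.
#' @param D a [distance_matrix()].
#' @return the total adjacent distance (scalar).
#' @export
sarf <- function(order, D) {
  stopifnot(inherits(D, "dist_matrix"))
  k <- nrow(D$d)
  if (k < 2L) stop("need at least 2 markers")
  order <- check_order(order, k)
  sum(D$d[cbind(order[-k], order[-1L])])
}

#' Ordering objectives: SARF, PARF, SALOD
#'
#' Evaluates a marker order under one of the three classic two-point ordering
#' criteria: SARF (sum of adjacent distances, minimized), PARF (product of
#' adjacent recombination fractions, minimized; needs `D$r`) or SALOD (sum of
#' adjacent LOD scores, maximized; needs `D$lod`).
#'
#' @inheritParams sarf
#' @param kind `"sarf"`, `"parf"` or `"salod"`.
#' @return the criterion value (scalar).
#' @export
objective <- function(order, D, kind = c("sarf", "parf", "salod")) {
  kind <- match.arg(kind)
  stopifnot(inherits(D, "dist_matrix"))
  k <- nrow(D$d)
  if (k < 2L) stop("need at least 2 markers")
  order <- check_order(order, k)
  adj <- cbind(order[-k], order[-1L])
  switch(kind,
    sarf = sum(D$d[adj]),
    parf = {
      if (is.null(D$r)) stop("PARF requires the companion 'r' matrix")
      prod(D$r[adj])
    },
    salod = {
      if (is.null(D$lod)) stop("SALOD requires the companion 'lod' matrix")
      sum(D$lod[adj])
    }
  )
}
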