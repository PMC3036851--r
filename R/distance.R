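#' Pairwise marker distance matrix
#'
#' Container for the pairwise inputs to marker ordering: a symmetric map
#' distance matrix `d` (cM) with zero diagonal, plus optional companion
#' matrices of recombination-fraction estimates `r` (in `[0, 0.5]`, required
#' by rapid chain delineation and the PARF criterion) and LOD scores `lod`
#' (required by SALOD).
#'
#' @param d symmetric numeric matrix of map distances (cM), zero diagonal,
#'   all entries finite.
#' @param r optional symmetric matrix of recombination fractions.
#' @param lod optional symmetric matrix of LOD scores.
#' @param markers marker names; defaults to `colnames(d)` or `m1..mk`.
#' @param units units of `d`, `"cM"` (default) or `"r"`.
#' @return an object of class `dist_matrix`.
#' @export
distance_matrix <- function(d, r = NULL, lod = NULL, markers = NULL,
                            units = c("cM", "r")) {
  units <- match.arg(units)
  d <- as.matrix(d)
  k <- nrow(d)
  check_square_sym <- function(m, what, tol = 1e-8) {
    if (!is.matrix(m) || nrow(m) != k || ncol(m) != k)
      stop("'", what, "' must be a ", k, "x", k, " matrix")
    if (any(!is.finite(m)))
      stop("'", what, "' contains non-finite entries")
    if (max(abs(m - t(m))) > tol)
      stop("'", what, "' is not symmetric")
    if (any(abs(diag(m)) > tol))
      stop("'", what, "' must have a zero diagonal")
    (m + t(m)) / 2
  }
  if (k < 2L) stop("need at least 2 markers")
  d <- check_square_sym(d, "d")
  if (!is.null(r)) {
    r <- check_square_sym(as.matrix(r), "r")
    if (any(r < 0 | r > 0.5 + 1e-12))
      stop("'r' entries must lie in [0, 0.5]")
  }
  if (!is.null(lod)) lod <- check_square_sym(as.matrix(lod), "lod")
  if (is.null(markers)) markers <- colnames(d)
  if (is.null(markers)) markers <- paste0("m", seq_len(k))
  if (length(markers) != k) stop("'markers' must have length ", k)
  dimnames(d) <- list(markers, markers)
  if (!is.null(r)) dimnames(r) <- dimnames(d)
  if (!is.null(lod)) dimnames(lod) <- dimnames(d)
  structure(list(d = d, r = r, lod = lod, markers = markers, units = units),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix: %d markers, units %s%s%s\n",
              length(x$markers), x$units,
              if (!is.null(x$r)) ", with r" else "",
              if (!is.null(x$lod)) ", with LOD" else ""))
  invisible(x)
}

#' True-map distance matrix of a linkage group
#'
#' Builds the noise-free distance matrix implied by the true marker positions
#' of one linkage group: `d[i,j] = |pos_i - pos_j|` (truncated at `cap`),
#' with the companion `r` matrix obtained through the chosen map function.
#' Useful as a ground-truth input for orderer sanity checks.
#'
#' @param genome a [genome_spec()].
#' @param group group index.
#' @inheritParams r_to_cm
#' @return a [distance_matrix()].
#' @examples
#' D <- true_distance_matrix(demo_genome(), group = 4)
#' sarf(seq_len(6), D)  # 100 cM: the true order walks the group end to end
#' @export
true_distance_matrix <- function(genome, group = 1L,
                                 map = c("haldane", "kosambi"), cap = 100) {
  map <- match.arg(map)
  stopifnot(inherits(genome, "genome_spec"))
  g <- genome[[group]]
  d <- pmin(abs(outer(g$pos, g$pos, "-")), cap)
  r <- cm_to_r(d, map)
  distance_matrix(d, r = r, markers = g$markers)
}
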