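#' Joint genotype probabilities for an F2 co-dominant marker pair
#'
#' The 3x3 table of expected joint genotype frequencies for two co-dominant
#' markers in an F2 intercross at recombination fraction `r` (coupling
#' phase). Rows index the first marker's genotype (0, 1, 2), columns the
#' second's:
#' corner cells (parental/double-recombinant homozygotes) have mass
#' \eqn{(1-r)^2/4} and \eqn{r^2/4}, single-heterozygote cells
#' \eqn{r(1-r)/2}, and the phase-ambiguous double heterozygote
#' \eqn{((1-r)^2 + r^2)/2}. The table sums to one for any `r`.
#'
#' @param r recombination fraction in `[0, 0.5]`.
#' @return a 3x3 probability matrix with dimnames `0:2`.
#' @export
f2_joint_probs <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0 || r > 0.5)
    stop("'r' must be a single value in [0, 0.5]")
  p <- (1 - r)^2 / 4
  q <- r^2 / 4
  s <- r * (1 - r) / 2
  m <- matrix(c(p, s, q,
                s, ((1 - r)^2 + r^2) / 2, s,
                q, s, p), nrow = 3L, byrow = TRUE)
  dimnames(m) <- list(g1 = 0:2, g2 = 0:2)
  m
}

#' Cross-tabulate joint genotypes of a marker pair
#'
#' Counts the 3x3 table of jointly observed genotype codes for two markers,
#' dropping individuals missing at either marker (pairwise-complete).
#'
#' @param g1,g2 integer genotype vectors (codes 0/1/2, `NA` missing).
#' @return a 3x3 integer matrix of counts.
#' @export
pair_counts <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("genotype vectors differ in length")
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  if (any(!(g1 %in% 0:2)) || any(!(g2 %in% 0:2)))
    stop("genotype codes must be 0, 1 or 2")
  m <- matrix(tabulate(3L * g1 + g2 + 1L, nbins = 9L), nrow = 3L, byrow = TRUE)
  dimnames(m) <- list(g1 = 0:2, g2 = 0:2)
  m
}

f2_pair_loglik <- function(r, counts) {
  p <- f2_joint_probs(r)
  used <- counts > 0
  sum(counts[used] * log(p[used]))
}

#' EM estimate of the recombination fraction for an F2 marker pair
#'
#' Maximum-likelihood estimation of the two-point recombination fraction from
#' a 3x3 joint genotype table. All cells except the double heterozygote carry
#' a known number of recombinant gametes (0, 1 or 2 of the individual's two);
#' the double heterozygote is phase-ambiguous (0 or 2 recombinants), and EM
#' imputes its expected recombinant count \eqn{2r^2/(r^2 + (1-r)^2)}. The
#' M step is then the recombinant-gamete proportion:
#' \deqn{r' = \frac{R_1 + 2R_2 + N_{11} \cdot 2r^2/(r^2+(1-r)^2)}{2N}}
#' with \eqn{R_1} the single-recombinant cell total and \eqn{R_2} the
#' double-recombinant homozygote total. Iteration starts at r = 0.25 and the
#' estimate is kept inside `[1e-9, 0.5]` to avoid the absorbing boundary
#' at zero while the double-heterozygote cell is occupied.
#'
#' @param counts 3x3 joint genotype count table (see [pair_counts()]).
#' @param tol convergence tolerance on `|r' - r|`.
#' @param max_iter iteration cap.
#' @return a list of class `rf_est`: `rhat`, `lod` (base-10 LOD versus
#'   r = 0.5), `n_used`, `converged`, `iterations` and `loglik_trace`
#'   (log-likelihood after each EM step; non-decreasing).
#' @export
est_rf_em <- function(counts, tol = 1e-8, max_iter = 1000L) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("'counts' must be a 3x3 table of non-negative integer counts")
  if (tol <= 0) stop("'tol' must be positive")
  n <- sum(counts)
  if (n < 1L) stop("no informative pairs: the joint count table is empty")
  r1 <- counts[1, 2] + counts[2, 1] + counts[2, 3] + counts[3, 2]
  r2 <- counts[1, 3] + counts[3, 1]
  n11 <- counts[2, 2]
  r <- 0.25
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- 2 * r^2 / (r^2 + (1 - r)^2)
    r_new <- (r1 + 2 * r2 + n11 * w) / (2 * n)
    r_new <- min(max(r_new, 1e-9), 0.5)
    trace[it] <- f2_pair_loglik(r_new, counts)
    if (abs(r_new - r) < tol) {
      r <- r_new
      converged <- TRUE
      break
    }
    r <- r_new
  }
  rhat <- min(max(r, 0), 0.5)
  lod <- if (rhat >= 0.5) 0 else
    (f2_pair_loglik(rhat, counts) - f2_pair_loglik(0.5, counts)) / log(10)
  structure(list(rhat = rhat, lod = max(lod, 0), n_used = n,
                 converged = converged, iterations = it,
                 loglik_trace = trace),
            class = "rf_est")
}

#' @export
print.rf_est <- function(x, ...) {
  cat(sprintf("Two-point estimate: r = %.4f, LOD = %.2f (n = %d, %s in %d EM iterations)\n",
              x$rhat, x$lod, x$n_used,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Pairwise recombination matrix of a linkage group
#'
#' Runs [est_rf_em()] on every marker pair of one linkage group (or an
#' explicit marker selection), pairwise-complete over missing data, and
#' assembles the [distance_matrix()] used by the orderers: `r` holds the EM
#' estimates, `lod` the LOD scores, and `d` the map distances obtained from
#' `r` through the chosen map function with the unlinked cap.
#'
#' @param gm genotype matrix as from [simulate_f2()] or [read_genotypes()].
#' @param group linkage group to analyse: a single group index (matched
#'   against the matrix's `group` attribute), a vector of marker names or
#'   column indices, or `NULL` (default) for all markers.
#' @inheritParams r_to_cm
#' @param tol,max_iter passed to [est_rf_em()].
#' @return a [distance_matrix()] with companion `r` and `lod`.
#' @export
recomb_matrix <- function(gm, group = NULL, map = c("haldane", "kosambi"),
                          cap = 100, tol = 1e-8, max_iter = 1000L) {
  map <- match.arg(map)
  grp_attr <- attr(gm, "group")
  cols <- if (is.null(group)) {
    seq_len(ncol(gm))
  } else if (length(group) == 1L && is.numeric(group) && !is.null(grp_attr)) {
    which(grp_attr == group)
  } else if (is.character(group)) {
    match(group, colnames(gm))
  } else {
    as.integer(group)
  }
  if (anyNA(cols) || length(cols) < 2L)
    stop("group selection must name at least 2 markers present in 'gm'")
  g <- unclass(gm)[, cols, drop = FALSE]
  k <- ncol(g)
  markers <- colnames(g)
  if (is.null(markers)) markers <- paste0("m", cols)
  r <- matrix(0, k, k)
  lod <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      cnt <- pair_counts(g[, i], g[, j])
      if (sum(cnt) == 0L)
        stop("no complete observations for pair (", markers[i], ", ",
             markers[j], ")")
      est <- est_rf_em(cnt, tol = tol, max_iter = max_iter)
      r[i, j] <- r[j, i] <- est$rhat
      lod[i, j] <- lod[j, i] <- est$lod
    }
  }
  d <- r_to_cm(r, map, cap)
  d <- matrix(d, k, k)
  diag(d) <- 0
  distance_matrix(d, r = r, lod = lod, markers = markers)
}
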