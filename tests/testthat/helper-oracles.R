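# Independent test oracles. These deliberately avoid the package's own code
# paths (no canonical-form dedup, no delta updates) so that agreement is a
# genuine cross-check.

# random symmetric distance matrix with zero diagonal
rand_dist <- function(k, lo = 1, hi = 50, with_r = FALSE) {
  m <- matrix(runif(k * k, lo, hi), k)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  r <- NULL
  if (with_r) {
    r <- matrix(runif(k * k, 0, 0.5), k)
    r <- (r + t(r)) / 2
    diag(r) <- 0
  }
  distance_matrix(m, r = r)
}

# SARF by direct summation, no fancy indexing
sarf_naive <- function(order, d) {
  s <- 0
  for (i in seq_len(length(order) - 1L)) s <- s + d[order[i], order[i + 1L]]
  s
}

# exhaustive minimum over ALL k! permutations (no reversal dedup), built on
# recursive enumeration rather than the package's lexicographic generator
full_bruteforce_best <- function(d) {
  k <- nrow(d)
  best <- list(sarf = Inf, order = NULL)
  recurse <- function(prefix, remaining) {
    if (length(remaining) == 0L) {
      s <- sarf_naive(prefix, d)
      if (s < best$sarf - 1e-12) best <<- list(sarf = s, order = prefix)
      return(invisible())
    }
    for (x in remaining) recurse(c(prefix, x), setdiff(remaining, x))
  }
  recurse(integer(0), seq_len(k))
  best
}

# recombination-fraction matrix -> capped Haldane cM matrix, shape preserved
r_to_cm_mat <- function(r) {
  d <- matrix(r_to_cm(r), nrow(r))
  diag(d) <- 0
  d
}

# grid-search maximizer of the F2 two-point multinomial log-likelihood
grid_rf <- function(counts, npts = 5001L) {
  rs <- seq(0, 0.5, length.out = npts)
  ll <- vapply(rs, function(r) {
    p <- f2_joint_probs(r)
    used <- counts > 0
    sum(counts[used] * log(p[used]))
  }, 1)
  rs[which.max(ll)]
}

# random 3x3 count table with at least one observation
rand_counts <- function(n = 100L) {
  r <- runif(1, 0.02, 0.48)
  tab <- matrix(as.vector(stats::rmultinom(1, n, as.vector(f2_joint_probs(r)))),
                3L, 3L)
  tab
}

# small genome for fast end-to-end runs
tiny_genome <- function() {
  genome_spec(list(
    list(name = "A", markers = paste0("a", 1:6), pos = seq(0, 100, by = 20)),
    list(name = "B", markers = paste0("b", 1:4), pos = c(0, 10, 25, 45))))
}
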