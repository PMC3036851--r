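#' Simulate gametes for one linkage group
#'
#' Generates haploid gametes along a chromosome with no crossover
#' interference: the first allele is Bernoulli(1/2) and the allele switches
#' across each adjacent interval of length d cM independently with
#' probability equal to the Haldane recombination fraction
#' \eqn{r = (1 - e^{-2d/100})/2}. The crossover process is therefore Markov
#' along the chromosome, the assumption under which Haldane distances are
#' exact.
#'
#' @param pos strictly increasing marker positions (cM).
#' @param n number of gametes.
#' @return an `n` x `length(pos)` 0/1 matrix of alleles.
#' @export
sim_gametes <- function(pos, n) {
  k <- length(pos)
  if (k < 1L) stop("need at least one marker position")
  if (k > 1L && any(diff(pos) <= 0))
    stop("positions must be strictly increasing")
  if (n == 0L) return(matrix(integer(0), nrow = 0L, ncol = k))
  first <- rbinom(n, 1L, 0.5)
  if (k == 1L) return(matrix(first, ncol = 1L))
  r <- cm_to_r(diff(pos), "haldane")
  switches <- matrix(rbinom(n * (k - 1L), 1L, rep(r, each = n)), nrow = n)
  # allele_j = first XOR (cumulative number of switches up to j) mod 2
  cum <- switches
  for (j in seq_len(k - 1L)[-1L]) cum[, j] <- cum[, j] + cum[, j - 1L]
  (cbind(first, first + cum) %% 2L)[, , drop = FALSE]
}

#' Simulate an F2 co-dominant population
#'
#' Each F2 individual is the union of two independent gametes per linkage
#' group (see [sim_gametes()]); genotype codes are 0 (homozygote aa),
#' 1 (heterozygote) and 2 (homozygote AA), so marker genotypes segregate
#' 1:2:1. Linkage groups are simulated independently (unlinked), each from
#' its own RNG stream derived from `seed`, so any group is individually
#' reproducible.
#'
#' @param genome a [genome_spec()].
#' @param n population size (individuals); `n = 0` gives an empty matrix
#'   with named columns.
#' @param seed optional integer seed; fixed seed gives identical output.
#' @return an integer matrix of class `f2_geno`, `n` rows x one column per
#'   marker, with `colnames` the marker names and attribute `group` giving
#'   each marker's linkage-group index.
#' @examples
#' gm <- simulate_f2(demo_genome(), n = 5, seed = 1)
#' dim(gm)  # 5 x 89
#' @export
simulate_f2 <- function(genome, n, seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("'n' must be a non-negative integer")
  if (!is.null(seed)) set.seed(seed)
  group_seeds <- sample.int(.Machine$integer.max - 1L, length(genome))
  cols <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    set.seed(group_seeds[i])
    g <- genome[[i]]
    codes <- sim_gametes(g$pos, n) + sim_gametes(g$pos, n)
    colnames(codes) <- g$markers
    cols[[i]] <- codes
  }
  gm <- do.call(cbind, cols)
  if (n == 0L) {
    gm <- matrix(integer(0), nrow = 0L,
                 ncol = sum(vapply(genome, function(g) length(g$markers), 1L)))
    colnames(gm) <- unlist(lapply(genome, `[[`, "markers"))
  }
  storage.mode(gm) <- "integer"
  structure(gm, group = rep(seq_along(genome),
                            vapply(genome, function(g) length(g$markers), 1L)),
            class = c("f2_geno", class(gm)))
}

#' Knock out genotype calls at random
#'
#' Sets each genotype call to missing (`NA`) independently with probability
#' `rate`; a robustness utility for studying orderer behavior under
#' incomplete data. `rate = 0` returns the input unchanged.
#'
#' @param gm a genotype matrix as from [simulate_f2()].
#' @param rate missing probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @return the genotype matrix with missing entries.
#' @export
inject_missing <- function(gm, rate, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1)
    stop("'rate' must lie in [0, 1)")
  if (rate == 0) return(gm)
  if (!is.null(seed)) set.seed(seed)
  drop <- runif(length(gm)) < rate
  gm[drop] <- NA_integer_
  gm
}

#' @export
print.f2_geno <- function(x, ...) {
  cat(sprintf("F2 genotype matrix: %d individuals x %d markers (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}
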