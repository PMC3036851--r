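#' Head-to-head comparison of the orderers on simulated data
#'
#' Reproduces the benchmark protocol: simulate one F2 co-dominant population
#' over `genome`, estimate the pairwise recombination matrix of each linkage
#' group, order each group once by rapid chain delineation and `reps` times
#' by independently seeded simulated annealing, and tabulate per group the
#' per-repetition SARF values and the percentage of repetitions in which
#' annealing attained a SARF less than or equal to RCD's (ties count as
#' wins: when both methods recover the same order they are commensurate).
#'
#' All annealing repetitions run on the same simulated population — the
#' comparison varies only the orderer's random seed, so differences reflect
#' the orderers, not sampling noise.
#'
#' @param genome a [genome_spec()] (default [demo_genome()]).
#' @param n population size (individuals).
#' @param reps number of annealing repetitions per group.
#' @param config an [sa_config()]; its `seed` is ignored (per-repetition
#'   seeds are derived from `seed`).
#' @param seed master seed driving the simulation and every repetition.
#' @param map,cap passed to [recomb_matrix()].
#' @param keep_trajectory record the first repetition's trajectory per group.
#' @return an object of class `sarf_comparison`: a list with `n`, `reps`,
#'   `seed` and per-group entries holding `group`, `k`, `rcd_order`,
#'   `rcd_sarf`, `sa_sarfs` (length `reps`), `sa_best_order`, `sa_best_sarf`,
#'   `pct_win`, `sa_time_s`, and optionally `trajectory`.
#' @examples
#' \donttest{
#' cmp <- run_comparison(n = 50, reps = 5, seed = 1)
#' summary_table(cmp)
#' }
#' @export
run_comparison <- function(genome = demo_genome(), n, reps = 100L,
                           config = sa_config(), seed = 1L,
                           map = c("haldane", "kosambi"), cap = 100,
                           keep_trajectory = TRUE) {
  map <- match.arg(map)
  reps <- as.integer(reps)
  if (reps < 1L) stop("'reps' must be at least 1")
  n_groups <- length(genome)
  set.seed(seed)
  sim_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  sa_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_groups * reps),
                     nrow = n_groups)
  gm <- simulate_f2(genome, n, seed = sim_seed)
  groups <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    D <- recomb_matrix(gm, group = g, map = map, cap = cap)
    rcd_fit <- rcd(D)
    sa_sarfs <- numeric(reps)
    best_sarf <- Inf
    best_order <- NULL
    traj <- NULL
    t0 <- proc.time()[["elapsed"]]
    for (rep in seq_len(reps)) {
      cfg <- config
      cfg$seed <- sa_seeds[g, rep]
      fit <- anneal(D, cfg,
                    trajectory_thin = if (keep_trajectory && rep == 1L) NULL else 0L)
      sa_sarfs[rep] <- fit$sarf
      if (fit$sarf < best_sarf) {
        best_sarf <- fit$sarf
        best_order <- fit$order
      }
      if (keep_trajectory && rep == 1L) traj <- fit$trajectory
    }
    sa_time <- proc.time()[["elapsed"]] - t0
    groups[[g]] <- list(
      group = genome[[g]]$name, k = length(genome[[g]]$markers),
      rcd_order = rcd_fit$order, rcd_sarf = rcd_fit$sarf,
      sa_sarfs = sa_sarfs, sa_best_order = best_order,
      sa_best_sarf = best_sarf,
      pct_win = 100 * mean(sa_sarfs <= rcd_fit$sarf + 1e-9),
      sa_time_s = sa_time, trajectory = traj)
  }
  structure(list(n = n, reps = reps, seed = seed, map = map,
                 genome = genome, groups = groups),
            class = "sarf_comparison")
}

#' Tabulate a comparison result
#'
#' One row per linkage group: marker count, RCD SARF, best and mean
#' annealing SARF over the repetitions, the win percentage (annealing SARF
#' less than or equal to RCD's, ties counting), and annealing wall time.
#'
#' @param result a [run_comparison()] result.
#' @return a data.frame.
#' @export
summary_table <- function(result) {
  stopifnot(inherits(result, "sarf_comparison"))
  gs <- result$groups
  if (length(gs) == 0L) {
    return(data.frame(population_size = integer(0), group = character(0),
                      n_markers = integer(0), rcd_sarf = numeric(0),
                      sa_best_sarf = numeric(0), sa_mean_sarf = numeric(0),
                      pct_win = numeric(0), sa_time_s = numeric(0)))
  }
  data.frame(
    population_size = result$n,
    group = vapply(gs, `[[`, "", "group"),
    n_markers = vapply(gs, `[[`, 1L, "k"),
    rcd_sarf = vapply(gs, `[[`, 1, "rcd_sarf"),
    sa_best_sarf = vapply(gs, `[[`, 1, "sa_best_sarf"),
    sa_mean_sarf = vapply(gs, function(g) mean(g$sa_sarfs), 1),
    pct_win = vapply(gs, `[[`, 1, "pct_win"),
    sa_time_s = vapply(gs, `[[`, 1, "sa_time_s"))
}

#' @export
print.sarf_comparison <- function(x, ...) {
  cat(sprintf("Orderer comparison: n = %d individuals, %d SA repetitions per group\n",
              x$n, x$reps))
  print(summary_table(x), digits = 4)
  invisible(x)
}

#' Write or read a comparison summary as TSV
#'
#' The tabulated comparison round-trips losslessly through TSV.
#'
#' @param result a [run_comparison()] result (or a data.frame from
#'   [summary_table()]).
#' @param path file path.
#' @return `read_summary_tsv()` returns the data.frame.
#' @export
write_summary_tsv <- function(result, path) {
  tab <- if (inherits(result, "sarf_comparison")) summary_table(result)
         else result
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary_tsv
#' @export
read_summary_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
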