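#' Annealing configuration
#'
#' Controls for the simulated-annealing orderer. Defaults follow the
#' benchmark protocol: initial control parameter (temperature) `A = 2`,
#' chain length `L` equal to the number of markers, and a number of cooling
#' steps `m` sized so that a run performs about `eval_budget` objective
#' evaluations (1e5 by default, the scale at which the 51-marker group is
#' searched adequately).
#'
#' @param A initial control parameter (temperature); must be positive. The
#'   default is 2. On the cM scale, where candidate moves can change SARF by
#'   tens of cM, this admits small uphill steps early on while the search is
#'   dominated by stochastic descent with tie acceptance.
#' @param m number of cooling steps; `NULL` (default) resolves at run time
#'   to `ceiling(eval_budget / L)`.
#' @param L chain length per temperature (constant over the run); `NULL`
#'   resolves to the number of markers `k`.
#' @param schedule cooling schedule: `"linear"` (default,
#'   `c_n = A (1 - n/(m+1))`), `"geometric"` (`c_n = A alpha^n`) or
#'   `"log"` (`c_n = A / log(n + e)`); all strictly positive and
#'   non-increasing in `n`.
#' @param alpha geometric decay factor.
#' @param neighborhood candidate-move kind: `"reverse"` (reverse a uniformly
#'   chosen contiguous block of length >= 2, the TSP 2-opt analog and the
#'   default) or `"swap"` (exchange two uniformly chosen positions).
#' @param patience stop after this many consecutive temperatures without an
#'   improvement of the best SARF; `NULL` disables early stopping.
#' @param seed optional integer seed; fixed seed makes [anneal()] fully
#'   reproducible.
#' @param eval_budget target number of objective evaluations used to resolve
#'   `m` when `m` is `NULL`.
#' @return a list of class `sa_config`.
#' @export
sa_config <- function(A = 2, m = NULL, L = NULL,
                      schedule = c("linear", "geometric", "log"),
                      alpha = 0.95, neighborhood = c("reverse", "swap"),
                      patience = NULL, seed = NULL, eval_budget = 1e5) {
  schedule <- match.arg(schedule)
  neighborhood <- match.arg(neighborhood)
  if (!is.numeric(A) || length(A) != 1L || A <= 0) stop("'A' must be positive")
  if (!is.null(m) && (m < 1L)) stop("'m' must be at least 1")
  if (!is.null(L) && (L < 1L)) stop("'L' must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  structure(list(A = A, m = if (is.null(m)) NULL else as.integer(m),
                 L = if (is.null(L)) NULL else as.integer(L),
                 schedule = schedule, alpha = alpha,
                 neighborhood = neighborhood,
                 patience = if (is.null(patience)) NULL else as.integer(patience),
                 seed = seed, eval_budget = eval_budget),
            class = "sa_config")
}

#' Cooling schedule value
#'
#' The control parameter (temperature) at cooling step `n`, for
#' `0 <= n <= m`. `c_0 = A` for every schedule; all schedules are strictly
#' positive and non-increasing in `n`.
#'
#' @param n cooling step (0-based).
#' @param config an [sa_config()]; its `m` must be set (or pass `m`).
#' @param m number of cooling steps, overriding `config$m`.
#' @return the temperature `c_n`.
#' @export
cooling <- function(n, config = sa_config(), m = config$m) {
  if (is.null(m)) stop("'m' must be known to evaluate the schedule")
  if (any(n < 0) || any(n > m)) stop("'n' must lie in [0, m]")
  A <- config$A
  switch(config$schedule,
    linear = A * (1 - n / (m + 1)),
    geometric = A * config$alpha^n,
    log = A / log(n + exp(1))
  )
}

#' Metropolis acceptance probability
#'
#' Probability of accepting a candidate order with criterion value `f_y`
#' when the current order has value `f_x`, at temperature `c`: 1 whenever
#' `f_y <= f_x` (non-worsening moves, including ties, are always taken),
#' otherwise `exp(-(f_y - f_x)/c)`.
#'
#' @param f_x,f_y criterion values of the current and candidate orders.
#' @param c temperature; must be positive.
#' @return acceptance probability in `[0, 1]`.
#' @export
accept_prob <- function(f_x, f_y, c) {
  if (any(c <= 0)) stop("temperature 'c' must be positive")
  ifelse(f_y <= f_x, 1, exp(-(f_y - f_x) / c))
}

#' Draw a candidate order from the neighborhood
#'
#' Applies one uniformly chosen elementary move to a marker order: `"swap"`
#' exchanges the markers at two distinct uniformly chosen positions;
#' `"reverse"` reverses a uniformly chosen contiguous block of length at
#' least 2. The candidate always differs from the input as a permutation.
#'
#' @param order integer permutation of `1..k`, `k >= 2`.
#' @param kind move kind.
#' @return the candidate permutation.
#' @export
neighbor_order <- function(order, kind = c("swap", "reverse")) {
  kind <- match.arg(kind)
  order <- check_order(order)
  k <- length(order)
  if (k < 2L) stop("need at least 2 markers")
  ij <- sort(sample.int(k, 2L))
  if (kind == "swap") {
    order[ij] <- order[rev(ij)]
  } else {
    order[ij[1L]:ij[2L]] <- order[ij[2L]:ij[1L]]
  }
  order
}

#' Order markers by simulated annealing
#'
#' Metropolis-type stochastic search for the marker order minimizing SARF.
#' Starting from a uniformly random order, each of `m + 1` cooling steps runs
#' `L` iterations: a candidate is drawn from the neighborhood and accepted
#' whenever it does not worsen the criterion, or with probability
#' `exp(-delta/c_n)` when it does. The best order ever visited is tracked and
#' returned (canonicalized); its SARF is recomputed from scratch at the end.
#'
#' @param D a [distance_matrix()].
#' @param config an [sa_config()].
#' @param trajectory_thin record every `trajectory_thin`-th iteration in the
#'   trajectory (plus the final one); `0` disables trajectory recording.
#'   `NULL` (default) aims for about 2000 trajectory rows.
#' @return an object of class `anneal` with components `order` (canonical
#'   best permutation), `sarf` (its SARF, recomputed), `accepted` (number of
#'   accepted moves), `evaluations`, `trajectory` (data.frame: `iteration`,
#'   `temperature`, `current_sarf`, `best_sarf`; best-so-far column is
#'   non-increasing), `config`, and the marker names.
#' @examples
#' D <- true_distance_matrix(demo_genome(), group = 4)
#' fit <- anneal(D, sa_config(seed = 1))
#' fit$order  # 1..6: the true order is recovered
#' @export
anneal <- function(D, config = sa_config(), trajectory_thin = NULL) {
  stopifnot(inherits(D, "dist_matrix"), inherits(config, "sa_config"))
  k <- nrow(D$d)
  if (k < 2L) stop("need at least 2 markers")
  if (any(!is.finite(D$d))) stop("distance matrix has non-finite entries")
  L <- if (is.null(config$L)) k else config$L
  m <- if (is.null(config$m)) max(1L, as.integer(ceiling(config$eval_budget / L)))
       else config$m
  patience <- if (is.null(config$patience)) m + 1L else config$patience
  total <- (m + 1L) * L
  thin <- if (is.null(trajectory_thin)) max(1L, as.integer(total / 2000L))
          else as.integer(trajectory_thin)
  if (!is.null(config$seed)) set.seed(config$seed)
  perm0 <- sample.int(k)
  res <- sa_core(D$d, perm0 - 1L, config$A, m, L,
                 match(config$schedule, c("linear", "geometric", "log")) - 1L,
                 config$alpha,
                 match(config$neighborhood, c("swap", "reverse")) - 1L,
                 patience, thin)
  best <- canonicalize_order(res$best_perm + 1L)
  traj <- data.frame(iteration = res$traj_iter,
                     temperature = res$traj_temp,
                     current_sarf = res$traj_cur,
                     best_sarf = res$traj_best)
  structure(list(order = best, sarf = sarf(best, D),
                 accepted = res$accepted, evaluations = res$evaluations,
                 trajectory = traj, config = config,
                 markers = D$markers, m = m, L = L),
            class = "anneal")
}

#' @export
print.anneal <- function(x, ...) {
  cat(sprintf("Simulated annealing: %d markers, SARF = %.4f (%d evaluations, %d accepted)\n",
              length(x$order), x$sarf, x$evaluations, x$accepted))
  cat("Order:", paste(x$markers[x$order], collapse = " "), "\n")
  invisible(x)
}

#' Plot the annealing trajectory
#'
#' Evolution of the total distance (SARF) across iterations: the current
#' state's SARF and the best-so-far envelope.
#'
#' @param x an [anneal()] result.
#' @param ... passed to [plot()].
#' @export
plot.anneal <- function(x, ...) {
  tr <- x$trajectory
  if (nrow(tr) == 0L) stop("no trajectory was recorded")
  plot(tr$iteration, tr$current_sarf, type = "l", col = "grey60",
       xlab = "iteration", ylab = "SARF", ...)
  lines(tr$iteration, tr$best_sarf, col = "firebrick", lwd = 2)
  legend("topright", c("current", "best so far"),
         col = c("grey60", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Write an annealing trajectory to TSV
#'
#' @param x an [anneal()] result.
#' @param path output file.
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "anneal"))
  write.table(x$trajectory, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
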