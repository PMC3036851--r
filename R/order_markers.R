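#' Order the markers of a linkage group
#'
#' Unified front end to the orderers. Given a pairwise distance matrix,
#' estimates the marker order minimizing SARF by simulated annealing
#' (`method = "sa"`, stochastic; see [anneal()]), rapid chain delineation
#' (`method = "rcd"`, deterministic; see [rcd()]) or exhaustive enumeration
#' (`method = "exhaustive"`, small k only; see [exhaustive_best_order()]).
#'
#' @param D a [distance_matrix()].
#' @param method orderer to use.
#' @param ... passed on: `config`/`trajectory_thin` for `"sa"`,
#'   `max_passes` for `"rcd"`, `max_k` for `"exhaustive"`.
#' @return an object of class `marker_order_fit` with components `method`,
#'   `order` (canonical permutation), `markers` (names in fitted order),
#'   `sarf` and `fit` (the underlying method result). Methods: [print()],
#'   [summary()], [coef()] (the permutation), [plot()] (annealing
#'   trajectory, SA fits only).
#' @examples
#' D <- true_distance_matrix(demo_genome(), group = 3)
#' fit <- order_markers(D, "rcd")
#' coef(fit)
#' @export
order_markers <- function(D, method = c("sa", "rcd", "exhaustive"), ...) {
  method <- match.arg(method)
  stopifnot(inherits(D, "dist_matrix"))
  fit <- switch(method,
    sa = anneal(D, ...),
    rcd = rcd(D, ...),
    exhaustive = exhaustive_best_order(D, ...)
  )
  structure(list(method = method, order = fit$order,
                 markers = D$markers[fit$order],
                 sarf = sarf(fit$order, D), units = D$units, fit = fit),
            class = "marker_order_fit")
}

#' @export
print.marker_order_fit <- function(x, ...) {
  cat(sprintf("Marker ordering (%s): %d markers, SARF = %.4f %s\n",
              x$method, length(x$order), x$sarf, x$units))
  cat("Order:", paste(x$markers, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.marker_order_fit <- function(object, ...) {
  cat(sprintf("Marker ordering by %s\n", switch(object$method,
      sa = "simulated annealing", rcd = "rapid chain delineation",
      exhaustive = "exhaustive enumeration")))
  cat(sprintf("  markers: %d\n  SARF: %.4f %s\n", length(object$order),
              object$sarf, object$units))
  if (object$method == "sa") {
    f <- object$fit
    cat(sprintf("  evaluations: %d (accepted %d, %.1f%%)\n",
                f$evaluations, f$accepted, 100 * f$accepted / f$evaluations))
    cat(sprintf("  schedule: %s, A = %g, m = %d, L = %d, neighborhood = %s\n",
                f$config$schedule, f$config$A, f$m, f$L,
                f$config$neighborhood))
  }
  if (object$method == "rcd")
    cat(sprintf("  chain SARF before ripple: %.4f\n", object$fit$chain_sarf))
  cat("  order:", paste(object$markers, collapse = " "), "\n")
  invisible(object)
}

#' @export
coef.marker_order_fit <- function(object, ...) {
  setNames(object$order, object$markers)
}

#' @export
plot.marker_order_fit <- function(x, ...) {
  if (x$method != "sa")
    stop("trajectory plots are only available for simulated-annealing fits")
  plot(x$fit, ...)
}
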