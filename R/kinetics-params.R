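#' Kinetic parameters for the single-file pore simulator
#'
#' Bundles and validates the rates and run controls of the stochastic pore
#' model. Time is dimensionless: the rates set the scale. The two transport
#' mechanisms are (a) knock-on collisions — a solution molecule strikes the
#' molecule in an end slot and transmits momentum along the water column —
#' and (b) Brownian hops of pore molecules into an adjacent vacancy.
#' Collision and entry rates scale linearly with the water activity of the
#' adjacent reservoir, so an osmotic gradient is imposed as `a_L > a_R`.
#'
#' Default rates (all overridable): `k_coll = 1`, `k_hop = 1`,
#' `k_enter = 1`, `k_exit = 0.1`. The constraint `k_exit < k_hop` encodes
#' the usual barrier ordering — escaping a full pore into solution costs
#' more than moving into a vacancy inside the pore — which is what makes a
#' vacancy more likely to be refilled from within the pore than from
#' solution.
#'
#' @param i Number of slots (positive integer).
#' @param k_coll Base knock-on collision attempt rate per side; effective
#'   rate is `k_coll * a_L` (left) or `k_coll * a_R` (right).
#' @param k_hop Brownian hop rate of a pore molecule into an adjacent
#'   vacancy (per direction).
#' @param k_enter Rate at which a solution molecule fills a vacant end slot,
#'   per side, scaled by that side's activity.
#' @param k_exit Brownian escape rate of an end-slot molecule from a FULL
#'   pore into the adjacent solution; must be `< k_hop`.
#' @param a_L,a_R Dimensionless water activities of the left and right
#'   reservoirs (strictly positive).
#' @param tracer_fraction_L Probability that a molecule entering from the
#'   left is the tracer (applies only while no tracer is in the pore).
#' @param tracer_fraction_R Same for the right reservoir; 0 by default —
#'   the standard tracer experiment feeds tracer from the left only. A
#'   nonzero value is used for mirror-symmetry checks.
#' @param t_max Simulation horizon (must exceed `burn_in`).
#' @param burn_in Initial time discarded before statistics are collected
#'   (must be positive).
#' @param seed Integer seed for the stochastic simulator.
#' @param n_batches Number of non-overlapping batches used for batch-means
#'   standard errors (at least 20).
#' @return Object of class `kinetic_params` (a validated named list).
#' @examples
#' kinetic_params(i = 3, a_L = 2, seed = 42)
#' @export
kinetic_params <- function(i, k_coll = 1, k_hop = 1, k_enter = 1,
                           k_exit = 0.1, a_L = 1, a_R = 1,
                           tracer_fraction_L = 0.1, tracer_fraction_R = 0,
                           t_max = 5000, burn_in = t_max / 20, seed = 1L,
                           n_batches = 20L) {
  i <- check_pore_length(i)
  rates <- c(k_coll = k_coll, k_hop = k_hop, k_enter = k_enter,
             k_exit = k_exit)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rates must be finite and >= 0", call. = FALSE)
  }
  if (a_L <= 0 || a_R <= 0) stop("activities must be > 0", call. = FALSE)
  if (tracer_fraction_L < 0 || tracer_fraction_L > 1 ||
      tracer_fraction_R < 0 || tracer_fraction_R > 1) {
    stop("tracer fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!(k_exit < k_hop)) {
    stop("barrier ordering violated: k_exit must be < k_hop", call. = FALSE)
  }
  if (!(t_max > burn_in && burn_in > 0)) {
    stop("need t_max > burn_in > 0", call. = FALSE)
  }
  if (n_batches < 20L) stop("use at least 20 batches", call. = FALSE)
  structure(list(
    i = i, k_coll = k_coll, k_hop = k_hop, k_enter = k_enter,
    k_exit = k_exit, a_L = a_L, a_R = a_R,
    tracer_fraction_L = tracer_fraction_L,
    tracer_fraction_R = tracer_fraction_R,
    t_max = t_max, burn_in = burn_in, seed = as.integer(seed),
    n_batches = as.integer(n_batches)
  ), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters: i =", x$i,
      "| k_coll", x$k_coll, "k_hop", x$k_hop, "k_enter", x$k_enter,
      "k_exit", x$k_exit, "\n  activities a_L", x$a_L, "a_R", x$a_R,
      "| tracer fraction L", x$tracer_fraction_L, "R", x$tracer_fraction_R,
      "\n  t_max", x$t_max, "burn_in", x$burn_in, "seed", x$seed,
      "batches", x$n_batches, "\n")
  invisible(x)
}
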