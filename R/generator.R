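#' Master-equation generator of the kinetic pore model
#'
#' Builds the continuous-time Markov generator `Q` over the full kinetic
#' state space (every pore configuration, with tracer-bearing states tagged
#' by the tracer's reservoir of origin). Off-diagonal entries are the event
#' rates produced by the same transition rules as [event_set()]; each
#' diagonal entry is minus its row sum, so rows sum to zero. Restricted to
#' small pores, where the exact stationary solve is meant to serve as an
#' oracle for the stochastic simulator.
#'
#' With tracer supplied from one side only, the state count equals the
#' number of occupancy states, `i^2 + i + 1`.
#'
#' @param i Number of slots; must not exceed 6 (the exact solve is an
#'   oracle for small instances).
#' @param params A [kinetic_params()] object; its `i` must match.
#' @return Object of class `pore_generator`: list with `Q` (dense matrix,
#'   dimnames = state keys), `state_space` (internal transition structure)
#'   and `params`.
#' @seealso [solve_stationary()]
#' @export
build_generator <- function(i, params) {
  i <- check_pore_length(i)
  if (i > 6L) {
    stop("build_generator is an exact oracle for small pores; need i <= 6",
         call. = FALSE)
  }
  stopifnot(inherits(params, "kinetic_params"))
  if (params$i != i) stop("params$i does not match i", call. = FALSE)
  ss <- build_state_space(params)
  Q <- matrix(0, ss$n, ss$n, dimnames = list(ss$keys, ss$keys))
  for (s in seq_len(ss$n)) {
    tr <- ss$transitions[[s]]
    for (j in seq_along(tr$to)) {
      Q[s, tr$to[j]] <- Q[s, tr$to[j]] + tr$rate[j]
    }
    Q[s, s] <- Q[s, s] - tr$total
  }
  structure(list(Q = Q, state_space = ss, params = params),
            class = "pore_generator")
}

#' @export
print.pore_generator <- function(x, ...) {
  cat("Kinetic generator: ", nrow(x$Q), " states, i = ", x$params$i,
      " slots\n", sep = "")
  invisible(x)
}

#' Exact stationary distribution and boundary fluxes
#'
#' Solves the master equation `pi Q = 0`, `sum(pi) = 1` by linear algebra
#' and evaluates the exact expected rates of the observables the stochastic
#' simulator estimates: net water flux through the pore (tallied at the
#' exit-side boundary), unidirectional tracer translocation rates, and the
#' fraction of time the pore is full (no vacancy). These are the oracle
#' values against which Gillespie estimates are checked.
#'
#' @param gen A [build_generator()] result.
#' @return Object of class `stationary_solution`: list with `pi` (named
#'   stationary probabilities), `net_water_flux`
#'   (expected `water LR - water RL` crossings per unit time),
#'   `tracer_lr_rate`, `tracer_rl_rate` (translocations per unit time) and
#'   `full_pore_fraction`.
#' @export
solve_stationary <- function(gen) {
  stopifnot(inherits(gen, "pore_generator"))
  ss <- gen$state_space
  Q <- gen$Q
  n <- nrow(Q)
  unreachable <- reducibility_diagnostic(ss)
  if (length(unreachable) > 0L) {
    stop("generator is reducible; states outside the recurrent class: ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  }
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat <- as.numeric(pi_hat)
  names(pi_hat) <- ss$keys

  net_water <- 0; tr_lr <- 0; tr_rl <- 0
  for (s in seq_len(n)) {
    tr <- ss$transitions[[s]]
    if (length(tr$to) == 0L) next
    w <- pi_hat[s] * tr$rate
    net_water <- net_water + sum(w * (tr$stats[, 1] - tr$stats[, 2]))
    tr_lr <- tr_lr + sum(w * tr$stats[, 3])
    tr_rl <- tr_rl + sum(w * tr$stats[, 4])
  }
  structure(list(
    pi = pi_hat,
    net_water_flux = net_water,
    tracer_lr_rate = tr_lr,
    tracer_rl_rate = tr_rl,
    full_pore_fraction = sum(pi_hat[ss$full])
  ), class = "stationary_solution")
}

#' @export
print.stationary_solution <- function(x, ...) {
  cat("Stationary solution over", length(x$pi), "states\n")
  cat("  net water flux:      ", format(x$net_water_flux, digits = 6), "\n")
  cat("  tracer rate L->R:    ", format(x$tracer_lr_rate, digits = 6), "\n")
  cat("  tracer rate R->L:    ", format(x$tracer_rl_rate, digits = 6), "\n")
  cat("  full-pore fraction:  ", format(x$full_pore_fraction, digits = 6),
      "\n")
  invisible(x)
}

# States not strongly connected to the start state (full pore of water):
# reachable-from-start AND co-reachable are required. Returns the keys of
# offending states (empty when irreducible).
reducibility_diagnostic <- function(ss) {
  n <- ss$n
  adj <- lapply(ss$transitions, function(tr) unique(tr$to[tr$rate > 0]))
  radj <- vector("list", n)
  for (s in seq_len(n)) for (t in adj[[s]]) radj[[t]] <- c(radj[[t]], s)
  bfs <- function(edges, from) {
    seen <- logical(n); seen[from] <- TRUE
    queue <- from
    while (length(queue) > 0L) {
      s <- queue[[1L]]; queue <- queue[-1L]
      for (t in edges[[s]]) {
        if (!seen[t]) { seen[t] <- TRUE; queue <- c(queue, t) }
      }
    }
    seen
  }
  ok <- bfs(adj, ss$start) & bfs(radj, ss$start)
  ss$keys[!ok]
}
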