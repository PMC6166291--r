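#' Stochastic simulation of the single-file pore
#'
#' Exact Gillespie realization of the kinetic pore model: waiting times are
#' exponential in the total rate of the current state and events are chosen
#' with probability proportional to their rates, using the same transition
#' rules as [event_set()] and [build_generator()]. The run starts from a
#' full pore of (non-tracer) water; statistics are collected only after
#' `burn_in` and are additionally tallied in `n_batches` equal time batches
#' for batch-means standard errors.
#'
#' Counted observables: tracer translocations (entered one reservoir,
#' exited the other), water crossings of the exit-side boundary in each
#' direction, vacancy lifetimes (from creation of a vacancy by ejection or
#' Brownian escape to restoration of the full pore), and the fraction of
#' time the pore is full.
#'
#' @param params A [kinetic_params()] object.
#' @param trace_file Optional path for an event-level trace (gzip text, one
#'   line per event: time, kind, configuration); `NULL` disables tracing.
#' @return Object of class `trajectory_stats`: list with counts
#'   `n_tracer_LR`, `n_tracer_RL`, `n_water_LR`, `n_water_RL`,
#'   `vacancy_lifetimes` (numeric vector), `sim_time` (observation window),
#'   `full_pore_fraction`, `n_events`, plus `batch` (matrix of per-batch
#'   counts and full-pore time) and `batch_len` used for standard errors.
#' @examples
#' stats <- simulate_pore(kinetic_params(i = 3, t_max = 200, seed = 7))
#' stats$n_tracer_LR
#' @export
simulate_pore <- function(params, trace_file = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  p <- params
  ss <- build_state_space(p)
  set.seed(p$seed)

  trace_con <- NULL
  if (!is.null(trace_file)) {
    trace_con <- gzfile(trace_file, "w")
    on.exit(close(trace_con), add = TRUE)
    state_glyphs <- vapply(ss$states,
                           function(s) format(new_pore_config(s$codes)),
                           character(1))
  }

  T0 <- p$burn_in; T1 <- p$t_max
  nb <- p$n_batches
  blen <- (T1 - T0) / nb
  counts <- numeric(4)                       # waterLR, waterRL, tracerLR, tracerRL
  batch <- matrix(0, nb, 5,
                  dimnames = list(NULL, c("water_lr", "water_rl",
                                          "tracer_lr", "tracer_rl",
                                          "full_time")))
  full_time <- 0
  lifetimes <- numeric(256); n_life <- 0L
  vac_open <- NA_real_

  # Distribute an occupancy interval [t0, t1] (already clipped to the
  # observation window) over the time batches.
  add_full_time <- function(t0, t1) {
    if (t1 <= t0) return(invisible())
    full_time <<- full_time + (t1 - t0)
    b0 <- min(nb, max(1L, floor((t0 - T0) / blen) + 1L))
    b1 <- min(nb, max(1L, floor((t1 - T0) / blen) + 1L))
    if (b0 == b1) {
      batch[b0, 5] <<- batch[b0, 5] + (t1 - t0)
    } else {
      for (b in b0:b1) {
        lo <- max(t0, T0 + (b - 1L) * blen)
        hi <- min(t1, T0 + b * blen)
        if (hi > lo) batch[b, 5] <<- batch[b, 5] + (hi - lo)
      }
    }
  }

  s <- ss$start
  t <- 0
  n_events <- 0L
  trans <- ss$transitions
  full <- ss$full
  repeat {
    tr <- trans[[s]]
    tot <- tr$total
    if (tot <= 0) {
      stop("degenerate system: no event can fire from state ", ss$keys[s],
           call. = FALSE)
    }
    t2 <- t + stats::rexp(1L, tot)
    if (full[s]) add_full_time(max(t, T0), min(t2, T1))
    if (t2 > T1) break
    j <- findInterval(stats::runif(1L) * tot, tr$cum) + 1L
    if (j > length(tr$rate)) j <- length(tr$rate)  # guard fp edge
    n_events <- n_events + 1L
    if (t2 > T0) {
      ev <- tr$stats[j, ]
      counts <- counts + ev
      b <- min(nb, floor((t2 - T0) / blen) + 1L)
      batch[b, 1:4] <- batch[b, 1:4] + ev
    }
    if (tr$vac_create[j] > 0L) vac_open <- t2
    if (tr$vac_fill[j] > 0L && !is.na(vac_open)) {
      if (vac_open > T0 && t2 <= T1) {
        n_life <- n_life + 1L
        if (n_life > length(lifetimes)) {
          lifetimes <- c(lifetimes, numeric(length(lifetimes)))
        }
        lifetimes[n_life] <- t2 - vac_open
      }
      vac_open <- NA_real_
    }
    s <- tr$to[j]
    t <- t2
    if (!is.null(trace_con)) {
      writeLines(sprintf("%.6f\t%s\t%s", t, tr$kind[j], state_glyphs[s]),
                 trace_con)
    }
  }

  structure(list(
    n_tracer_LR = counts[3], n_tracer_RL = counts[4],
    n_water_LR = counts[1], n_water_RL = counts[2],
    vacancy_lifetimes = lifetimes[seq_len(n_life)],
    sim_time = T1 - T0,
    full_pore_fraction = full_time / (T1 - T0),
    n_events = n_events,
    batch = batch, batch_len = blen,
    params = p
  ), class = "trajectory_stats")
}

#' @export
print.trajectory_stats <- function(x, ...) {
  cat("Pore trajectory (", x$n_events, " events over ", x$sim_time,
      " time units after burn-in)\n", sep = "")
  cat("  tracer translocations L->R / R->L: ", x$n_tracer_LR, "/",
      x$n_tracer_RL, "\n")
  cat("  water boundary crossings L->R / R->L:", x$n_water_LR, "/",
      x$n_water_RL, "\n")
  cat("  full-pore fraction:", format(x$full_pore_fraction, digits = 4),
      "| vacancy lifetimes recorded:", length(x$vacancy_lifetimes), "\n")
  invisible(x)
}

# Batch-means standard error for a rate: per-batch counts divided by the
# batch length, sd over batches / sqrt(n_batches).
batch_rate_se <- function(batch_counts, batch_len) {
  rates <- batch_counts / batch_len
  stats::sd(rates) / sqrt(length(rates))
}

#' Permeability estimates from a trajectory
#'
#' Turns trajectory counts into permeability estimates. From an equilibrium
#' run (`a_L == a_R`) with a tracer source, the diffusion permeability is
#' the unidirectional tracer translocation rate normalized by the tracer
#' fraction: `p_d = (n_tracer_LR / sim_time) / tracer_fraction_L` (mirrored
#' if the tracer is fed from the right). From a gradient run
#' (`a_L != a_R`), the osmotic permeability is the net water flux per unit
#' activity difference:
#' `p_f = ((n_water_LR - n_water_RL) / sim_time) / (a_L - a_R)`.
#' Standard errors come from non-overlapping batch means. Both quantities
#' are in molecules per unit time, so their ratio is dimensionless and
#' directly comparable to the pore occupancy `N_p`.
#'
#' If fewer than 100 tracer translocations were observed the estimate is
#' flagged `low_precision = TRUE` (carried in the result, not raised as a
#' condition).
#'
#' @param stats A [simulate_pore()] result.
#' @param params The [kinetic_params()] used for that run (defaults to the
#'   parameters stored in `stats`).
#' @return Object of class `permeability_estimates`: list with `p_d`,
#'   `p_d_se`, `p_f`, `p_f_se` (each `NA` when not estimable from this
#'   run), `ratio`, `ratio_se` (filled by [permeability_ratio()]), and
#'   `low_precision`.
#' @seealso [permeability_ratio()], [simulate_pfpd()]
#' @export
estimate_permeabilities <- function(stats, params = stats$params) {
  stopifnot(inherits(stats, "trajectory_stats"))
  p <- params
  p_d <- NA_real_; p_d_se <- NA_real_
  p_f <- NA_real_; p_f_se <- NA_real_
  low_precision <- FALSE
  if (p$a_L == p$a_R) {
    if (p$tracer_fraction_L > 0) {
      p_d <- (stats$n_tracer_LR / stats$sim_time) / p$tracer_fraction_L
      p_d_se <- batch_rate_se(stats$batch[, "tracer_lr"], stats$batch_len) /
        p$tracer_fraction_L
      low_precision <- stats$n_tracer_LR < 100
    } else if (p$tracer_fraction_R > 0) {
      p_d <- (stats$n_tracer_RL / stats$sim_time) / p$tracer_fraction_R
      p_d_se <- batch_rate_se(stats$batch[, "tracer_rl"], stats$batch_len) /
        p$tracer_fraction_R
      low_precision <- stats$n_tracer_RL < 100
    }
  } else {
    da <- p$a_L - p$a_R
    p_f <- ((stats$n_water_LR - stats$n_water_RL) / stats$sim_time) / da
    p_f_se <- batch_rate_se(stats$batch[, "water_lr"] -
                              stats$batch[, "water_rl"],
                            stats$batch_len) / abs(da)
  }
  structure(list(p_d = p_d, p_d_se = p_d_se, p_f = p_f, p_f_se = p_f_se,
                 ratio = NA_real_, ratio_se = NA_real_,
                 low_precision = low_precision),
            class = "permeability_estimates")
}

#' Combine equilibrium and gradient runs into a Pf/Pd ratio
#'
#' @param est_eq [estimate_permeabilities()] result from an equilibrium run
#'   (supplies `p_d`).
#' @param est_grad [estimate_permeabilities()] result from a gradient run
#'   (supplies `p_f`).
#' @return A `permeability_estimates` object carrying `p_d`, `p_f`, their
#'   standard errors, and `ratio = p_f / p_d` with a delta-method standard
#'   error.
#' @export
permeability_ratio <- function(est_eq, est_grad) {
  stopifnot(inherits(est_eq, "permeability_estimates"),
            inherits(est_grad, "permeability_estimates"))
  p_d <- est_eq$p_d; p_f <- est_grad$p_f
  if (is.na(p_d) || is.na(p_f)) {
    stop("need p_d from an equilibrium run and p_f from a gradient run",
         call. = FALSE)
  }
  ratio <- p_f / p_d
  ratio_se <- abs(ratio) * sqrt((est_grad$p_f_se / p_f)^2 +
                                  (est_eq$p_d_se / p_d)^2)
  structure(list(p_d = p_d, p_d_se = est_eq$p_d_se,
                 p_f = p_f, p_f_se = est_grad$p_f_se,
                 ratio = ratio, ratio_se = ratio_se,
                 low_precision = isTRUE(est_eq$low_precision)),
            class = "permeability_estimates")
}

#' @export
print.permeability_estimates <- function(x, ...) {
  fmt <- function(v, se) {
    if (is.na(v)) return("NA")
    paste0(format(v, digits = 4),
           if (!is.na(se)) paste0(" (se ", format(se, digits = 3), ")"))
  }
  cat("Permeability estimates\n")
  cat("  p_d:  ", fmt(x$p_d, x$p_d_se), "\n")
  cat("  p_f:  ", fmt(x$p_f, x$p_f_se), "\n")
  cat("  ratio:", fmt(x$ratio, x$ratio_se), "\n")
  if (isTRUE(x$low_precision)) {
    cat("  note: fewer than 100 tracer translocations; low precision\n")
  }
  invisible(x)
}

#' Simulated Pf/Pd for one pore length
#'
#' Convenience wrapper: runs one equilibrium trajectory (for `p_d`) and one
#' osmotic-gradient trajectory (for `p_f`) with otherwise identical
#' parameters, and combines them with [permeability_ratio()]. The gradient
#' run scales the left activity by `gradient` and switches the tracer
#' source off; the two runs use seeds derived from `seed`.
#'
#' @param i Pore length in slots.
#' @param gradient Activity ratio `a_L / a_R` applied in the gradient run.
#' @param seed Integer seed; the two runs use `seed` and `seed + 1`.
#' @param ... Further arguments passed to [kinetic_params()] (e.g. `t_max`,
#'   rate overrides).
#' @return A `permeability_estimates` object with `ratio` filled in.
#' @export
simulate_pfpd <- function(i, gradient = 1.5, seed = 1L, ...) {
  p_eq <- kinetic_params(i = i, seed = seed, ...)
  if (p_eq$a_L != p_eq$a_R) {
    stop("base parameters must be an equilibrium setting (a_L == a_R)",
         call. = FALSE)
  }
  p_gr <- kinetic_params(i = i, seed = seed + 1L, a_L = p_eq$a_L * gradient,
                         a_R = p_eq$a_R, tracer_fraction_L = 0, ...)
  est_eq <- estimate_permeabilities(simulate_pore(p_eq))
  est_gr <- estimate_permeabilities(simulate_pore(p_gr))
  permeability_ratio(est_eq, est_gr)
}

#' Simulated Pf/Pd across pore lengths
#'
#' Repeats [simulate_pfpd()] for each pore length and replicate, and tables
#' the simulated ratio next to the combinatorial state-count prediction
#' (which is `i` itself). The simulated ratio is regime-dependent — it is
#' not asserted to equal `i` for arbitrary rates.
#'
#' @param i_values Pore lengths to scan.
#' @param reps Replicates per pore length.
#' @param seed Base seed; replicate `r` of pore length index `k` uses
#'   `seed + 1000 * k + 2 * r`.
#' @param ... Passed to [simulate_pfpd()] / [kinetic_params()].
#' @return Data frame with columns `i`, `rep`, `p_d`, `p_f`, `ratio`,
#'   `ratio_se`, `predicted`.
#' @export
ratio_scan <- function(i_values, reps = 3L, seed = 1L, ...) {
  rows <- list()
  for (k in seq_along(i_values)) {
    i <- i_values[k]
    for (r in seq_len(reps)) {
      est <- simulate_pfpd(i, seed = seed + 1000L * k + 2L * r, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, rep = r, p_d = est$p_d, p_f = est$p_f,
        ratio = est$ratio, ratio_se = est$ratio_se,
        predicted = pfpd_ratio(i, "TRACER_EXIT_STATES")$value
      )
    }
  }
  do.call(rbind, rows)
}

#' Summary of vacancy lifetimes
#'
#' A vacancy lifetime runs from the creation of a vacancy (knock-on
#' ejection or Brownian escape from a full pore) to the restoration of the
#' full pore. Under an osmotic gradient the vacancy is refilled faster than
#' at equilibrium, so its mean lifetime shrinks.
#'
#' @param stats A [simulate_pore()] result.
#' @return List with `n` (number of samples), `mean` and `median` (both
#'   `NA` when no lifetime was recorded — the empty-summary sentinel).
#' @export
vacancy_lifetime_summary <- function(stats) {
  stopifnot(inherits(stats, "trajectory_stats"))
  lt <- stats$vacancy_lifetimes
  if (length(lt) == 0L) {
    return(list(n = 0L, mean = NA_real_, median = NA_real_))
  }
  list(n = length(lt), mean = mean(lt), median = stats::median(lt))
}
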