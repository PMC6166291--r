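# Transition engine shared by the public event_set(), the master-equation
# generator and the Gillespie simulator.
#
# A kinetic state is a pore configuration plus the origin of the tracer
# currently in the pore (0 = no tracer, 1 = entered from the left,
# 2 = entered from the right); the origin is bookkeeping needed to count
# true translocations (entered one side, exited the other).
#
# Event rules (left side; the right side is mirrored):
#  * KNOCK_ON_L, rate k_coll * a_L:
#      - full pore: the exit-slot molecule is ejected to the right; the
#        striker does NOT enter, a vacancy appears at the exit slot;
#      - vacancy at slot v >= 2: the molecule at v-1 advances into it
#        (vacancy moves one slot toward the entrance);
#      - vacancy at slot 1: no entrance molecule to strike; no event.
#  * ENTER_L, rate k_enter * a_L, requires the entrance slot vacant: a
#    solution molecule fills it; it is the tracer with probability
#    tracer_fraction_L provided no tracer is already in the pore.
#  * HOP, rate k_hop per direction: a pore molecule adjacent to the vacancy
#    hops into it.
#  * EXIT_L, rate k_exit, only on a FULL pore: the entrance-slot molecule
#    escapes into the left solution (keeps the single-vacancy constraint).
#
# Water boundary crossings are tallied at the exit-side (right) boundary:
# water_lr = molecule leaves into the right reservoir, water_rl = molecule
# enters from the right reservoir. At stationarity the mean of
# (water_lr - water_rl) per unit time is the net water flux through the
# pore.

.transition <- function(kind, rate, codes, origin, entrant = NA_character_,
                        water_lr = 0L, water_rl = 0L,
                        tracer_lr = 0L, tracer_rl = 0L,
                        vac_create = 0L, vac_fill = 0L) {
  list(kind = kind, rate = rate, codes = codes, origin = origin,
       entrant = entrant, water_lr = water_lr, water_rl = water_rl,
       tracer_lr = tracer_lr, tracer_rl = tracer_rl,
       vac_create = vac_create, vac_fill = vac_fill)
}

transitions_from <- function(codes, origin, p) {
  i <- length(codes)
  v <- match(.OCC_VACANCY, codes)      # NA when the pore is full
  full <- is.na(v)
  has_tracer <- any(codes == .OCC_TRACER)
  out <- list()
  add <- function(tr) out[[length(out) + 1L]] <<- tr

  # Ejection of the occupant of an end slot into the adjacent reservoir.
  eject <- function(kind, rate, slot, to_right) {
    occ <- codes[slot]
    new <- codes
    new[slot] <- .OCC_VACANCY
    new_origin <- origin
    t_lr <- 0L; t_rl <- 0L
    if (occ == .OCC_TRACER) {
      if (to_right && origin == 1L) t_lr <- 1L   # entered L, exited R
      if (!to_right && origin == 2L) t_rl <- 1L  # entered R, exited L
      new_origin <- 0L
    }
    add(.transition(kind, rate, new, new_origin,
                    water_lr = if (to_right) 1L else 0L,
                    tracer_lr = t_lr, tracer_rl = t_rl,
                    vac_create = 1L))
  }
  # Advance of the molecule adjacent to the vacancy (knock-on with a
  # vacancy present, or a Brownian hop): occupant of `from` moves into the
  # vacancy at `v`.
  advance <- function(kind, rate, from) {
    new <- codes
    new[v] <- codes[from]
    new[from] <- .OCC_VACANCY
    add(.transition(kind, rate, new, origin))
  }
  # Entry from a reservoir into a vacant end slot (always refills the only
  # vacancy, so the pore becomes full).
  enter <- function(kind, rate, slot, side, frac) {
    from_right <- side == 2L
    w_rl <- if (from_right) 1L else 0L
    if (!has_tracer && frac > 0) {
      if (frac < 1) {
        new <- codes; new[slot] <- .OCC_WATER
        add(.transition(kind, rate * (1 - frac), new, origin,
                        entrant = "water", water_rl = w_rl, vac_fill = 1L))
      }
      new <- codes; new[slot] <- .OCC_TRACER
      add(.transition(kind, rate * frac, new, side,
                      entrant = "tracer", water_rl = w_rl, vac_fill = 1L))
    } else {
      new <- codes; new[slot] <- .OCC_WATER
      add(.transition(kind, rate, new, origin,
                      entrant = "water", water_rl = w_rl, vac_fill = 1L))
    }
  }

  r_coll_L <- p$k_coll * p$a_L
  r_coll_R <- p$k_coll * p$a_R
  if (full) {
    if (r_coll_L > 0) eject("KNOCK_ON_L", r_coll_L, i, to_right = TRUE)
    if (r_coll_R > 0) eject("KNOCK_ON_R", r_coll_R, 1L, to_right = FALSE)
    if (p$k_exit > 0) {
      eject("EXIT_L", p$k_exit, 1L, to_right = FALSE)
      eject("EXIT_R", p$k_exit, i, to_right = TRUE)
    }
  } else {
    if (v >= 2L && r_coll_L > 0) advance("KNOCK_ON_L", r_coll_L, v - 1L)
    if (v <= i - 1L && r_coll_R > 0) advance("KNOCK_ON_R", r_coll_R, v + 1L)
    if (p$k_hop > 0) {
      if (v >= 2L) advance("HOP_TOWARD_EXIT", p$k_hop, v - 1L)
      if (v <= i - 1L) advance("HOP_TOWARD_ENTRANCE", p$k_hop, v + 1L)
    }
    if (p$k_enter > 0) {
      if (v == 1L) enter("ENTER_L", p$k_enter * p$a_L, 1L, 1L,
                         p$tracer_fraction_L)
      if (v == i) enter("ENTER_R", p$k_enter * p$a_R, i, 2L,
                        p$tracer_fraction_R)
    }
  }
  out
}

#' Events available from a pore configuration
#'
#' Lists every kinetic event that can fire from the given configuration
#' under the supplied parameters, with its rate and the configuration it
#' produces. Entry events are split into a water branch and a tracer branch
#' whose rates are weighted by the tracer fraction, so the rows form the
#' complete set of simultaneously valid transitions.
#'
#' @param config A [pore_config()] object (or anything [pore_config()]
#'   accepts).
#' @param params A [kinetic_params()] object with matching pore length.
#' @return Data frame with columns `kind`, `rate`, `entrant` (`"water"`,
#'   `"tracer"` or `NA`), and `to` (glyph string of the resulting
#'   configuration).
#' @examples
#' p <- kinetic_params(i = 3)
#' event_set(parse_config("*O*O[]"), p)
#' @export
event_set <- function(config, params) {
  if (!inherits(config, "pore_config")) config <- pore_config(config)
  stopifnot(inherits(params, "kinetic_params"))
  if (length(config) != params$i) {
    stop("configuration length does not match params$i", call. = FALSE)
  }
  origin <- if (any(unclass(config) == .OCC_TRACER)) 1L else 0L
  trs <- transitions_from(unclass(config), origin, params)
  data.frame(
    kind = vapply(trs, `[[`, character(1), "kind"),
    rate = vapply(trs, `[[`, numeric(1), "rate"),
    entrant = vapply(trs, `[[`, character(1), "entrant"),
    to = vapply(trs, function(tr) format(new_pore_config(tr$codes)),
                character(1)),
    stringsAsFactors = FALSE
  )
}

# Full reachable kinetic state space for the given parameters: every
# enumerated configuration, with tracer-bearing configurations tagged by
# the reservoir(s) that can supply a tracer. Returns the state list, a
# lookup key -> index, and per-state transition tables pre-resolved to
# state indices (the structure consumed by both the generator and the
# Gillespie loop).
build_state_space <- function(params) {
  p <- params
  configs <- enumerate_configurations(p$i)
  origins_for <- function(codes) {
    if (!any(codes == .OCC_TRACER)) return(0L)
    c(if (p$tracer_fraction_L > 0) 1L, if (p$tracer_fraction_R > 0) 2L)
  }
  states <- list()
  for (cfg in configs) {
    for (o in origins_for(unclass(cfg))) {
      states[[length(states) + 1L]] <- list(codes = unclass(cfg), origin = o)
    }
  }
  key <- function(codes, origin) paste0(paste(codes, collapse = ""), ":", origin)
  keys <- vapply(states, function(s) key(s$codes, s$origin), character(1))
  idx <- stats::setNames(seq_along(keys), keys)
  n <- length(states)

  trans <- vector("list", n)
  for (s in seq_len(n)) {
    trs <- transitions_from(states[[s]]$codes, states[[s]]$origin, p)
    if (length(trs) == 0L) {
      trans[[s]] <- list(to = integer(0), rate = numeric(0),
                         kind = character(0), total = 0,
                         cum = numeric(0),
                         stats = matrix(0L, 0, 4),
                         vac_create = integer(0), vac_fill = integer(0))
      next
    }
    to <- vapply(trs, function(tr) {
      k <- key(tr$codes, tr$origin)
      j <- idx[[k]]
      if (is.null(j)) stop("internal: transition to unknown state ", k)
      j
    }, integer(1))
    rate <- vapply(trs, `[[`, numeric(1), "rate")
    stats_m <- t(vapply(trs, function(tr) {
      c(tr$water_lr, tr$water_rl, tr$tracer_lr, tr$tracer_rl)
    }, integer(4)))
    trans[[s]] <- list(
      to = to, rate = rate,
      kind = vapply(trs, `[[`, character(1), "kind"),
      total = sum(rate), cum = cumsum(rate),
      stats = stats_m,
      vac_create = vapply(trs, `[[`, integer(1), "vac_create"),
      vac_fill = vapply(trs, `[[`, integer(1), "vac_fill")
    )
  }
  full <- vapply(states, function(s) !any(s$codes == .OCC_VACANCY), logical(1))
  start <- idx[[key(rep(.OCC_WATER, p$i), 0L)]]
  list(states = states, keys = keys, index = idx, transitions = trans,
       full = full, start = start, n = n)
}
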