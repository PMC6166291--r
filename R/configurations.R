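# Slot occupants are coded as integers so that the natural ordering
# WATER < TRACER < VACANCY doubles as the lexicographic sort order:
#   0 = water (O), 1 = tracer (*O*), 2 = vacancy ([]).
.OCC_WATER <- 0L
.OCC_TRACER <- 1L
.OCC_VACANCY <- 2L

.OCC_LABELS <- c("water", "tracer", "vacancy")
.OCC_GLYPHS <- c("O", "*O*", "[]")

#' Slot occupant labels
#'
#' The three objects that can occupy a slot of a single-file pore:
#' an (indistinguishable) water molecule, the single tracer molecule,
#' and the single vacancy.
#'
#' @return Character vector `c("water", "tracer", "vacancy")`, in the
#'   ordering used for lexicographic enumeration (water < tracer < vacancy).
#' @export
occupant_labels <- function() .OCC_LABELS

#' Construct a pore configuration
#'
#' A pore configuration is the ordered occupancy of `i` slots, slot 1 being
#' the entrance (left) slot and slot `i` the exit (right) slot. Each slot is
#' one water-molecule diameter wide, so a pore of `i` slots has length
#' `i` diameters. At most one tracer and at most one vacancy are allowed.
#'
#' @param slots Occupants, entrance to exit: a character vector using the
#'   labels `"water"`, `"tracer"`, `"vacancy"` (or the glyphs `"O"`, `"*O*"`,
#'   `"[]"`), or an integer vector with codes 0 (water), 1 (tracer),
#'   2 (vacancy).
#' @return An object of class `pore_config`: an integer vector of occupant
#'   codes with the slot count retained as its length.
#' @examples
#' pore_config(c("tracer", "water", "water"))
#' pore_config(c("O", "[]", "O"))
#' @export
pore_config <- function(slots) {
  if (is.character(slots)) {
    codes <- match(slots, .OCC_LABELS) - 1L
    glyph <- match(slots, .OCC_GLYPHS) - 1L
    codes[is.na(codes)] <- glyph[is.na(codes)]
    if (anyNA(codes)) {
      stop("unknown occupant label(s): ",
           paste(unique(slots[is.na(codes)]), collapse = ", "),
           call. = FALSE)
    }
  } else if (is.numeric(slots)) {
    codes <- as.integer(slots)
    if (anyNA(codes) || any(codes < 0L | codes > 2L)) {
      stop("occupant codes must be 0 (water), 1 (tracer) or 2 (vacancy)",
           call. = FALSE)
    }
  } else {
    stop("`slots` must be a character or integer vector", call. = FALSE)
  }
  new_pore_config(codes)
}

# Internal constructor + validator; `codes` is an integer vector in 0:2.
new_pore_config <- function(codes) {
  if (length(codes) < 1L) {
    stop("a pore configuration needs at least one slot", call. = FALSE)
  }
  if (sum(codes == .OCC_TRACER) > 1L) {
    stop("at most one tracer is allowed in the pore", call. = FALSE)
  }
  if (sum(codes == .OCC_VACANCY) > 1L) {
    stop("at most one vacancy is allowed in the pore", call. = FALSE)
  }
  structure(codes, class = "pore_config")
}

#' Parse a configuration from its glyph string
#'
#' Reads the compact notation used throughout the package, e.g. `"*O*O[]"`
#' for a tracer in the entrance slot, water in the middle and a vacancy at
#' the exit of a 3-slot pore.
#'
#' @param x A single string built from the glyphs `O` (water), `*O*`
#'   (tracer) and `[]` (vacancy).
#' @return A [pore_config()] object.
#' @export
parse_config <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  rest <- x
  codes <- integer(0)
  while (nzchar(rest)) {
    if (startsWith(rest, "*O*")) {
      codes <- c(codes, .OCC_TRACER); rest <- substring(rest, 4L)
    } else if (startsWith(rest, "[]")) {
      codes <- c(codes, .OCC_VACANCY); rest <- substring(rest, 3L)
    } else if (startsWith(rest, "O")) {
      codes <- c(codes, .OCC_WATER); rest <- substring(rest, 2L)
    } else {
      stop("cannot parse configuration string at: ", rest, call. = FALSE)
    }
  }
  new_pore_config(codes)
}

#' @export
format.pore_config <- function(x, ...) {
  paste0(.OCC_GLYPHS[unclass(x) + 1L], collapse = "")
}

#' @export
print.pore_config <- function(x, ...) {
  cat("<pore_config i=", length(x), "> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.pore_config <- function(x, ...) format(x)

#' Enumerate all pore configurations of a given length
#'
#' Exhaustively enumerates every distinct occupancy state of an `i`-slot
#' single-file pore under the model constraints: slots hold water, at most
#' one tracer and at most one vacancy. The four mutually exclusive cases —
#' all water; one tracer; one vacancy; one tracer plus one vacancy — are
#' each enumerated over all slot placements. Water molecules are
#' indistinguishable, so there is a single way to fill the remaining slots.
#'
#' @param i Number of slots (positive integer).
#' @return A list of [pore_config()] objects, in lexicographic order over
#'   slots with water < tracer < vacancy. Its length is always
#'   `i^2 + i + 1`.
#' @examples
#' length(enumerate_configurations(3)) # 13
#' sapply(enumerate_configurations(1), format)
#' @export
enumerate_configurations <- function(i) {
  i <- check_pore_length(i)
  configs <- vector("list", i * i + i + 1L)
  k <- 1L
  base <- rep(.OCC_WATER, i)
  configs[[k]] <- base; k <- k + 1L                    # null state
  for (t in seq_len(i)) {                              # tracer only
    cfg <- base; cfg[t] <- .OCC_TRACER
    configs[[k]] <- cfg; k <- k + 1L
  }
  for (v in seq_len(i)) {                              # vacancy only
    cfg <- base; cfg[v] <- .OCC_VACANCY
    configs[[k]] <- cfg; k <- k + 1L
  }
  for (v in seq_len(i)) {                              # tracer + vacancy
    for (t in seq_len(i)[-v]) {
      cfg <- base; cfg[v] <- .OCC_VACANCY; cfg[t] <- .OCC_TRACER
      configs[[k]] <- cfg; k <- k + 1L
    }
  }
  m <- do.call(rbind, configs)
  ord <- do.call(order, split(m, col(m)))
  lapply(ord[seq_along(configs)], function(r) new_pore_config(m[r, ]))
}

#' Classify a pore configuration
#'
#' Assigns a configuration to the occupancy classes that drive the
#' permeability analysis. "Exit slot" always means the last slot (index
#' `i`); left-moving tracers are handled by mirror symmetry in the kinetic
#' simulator, not by a second set of classes.
#'
#' * diffusion tracer state: the tracer is in the pore (vacancy or not);
#' * diffusion tracer exit state: the tracer is in the exit slot;
#' * osmotic tracer state: the tracer is in the pore and the pore is full
#'   (no vacancy);
#' * osmotic tracer exit state: full pore with the tracer in the exit slot.
#'
#' @param config A [pore_config()] object.
#' @return An object of class `state_class`: a named logical list with
#'   elements `is_null`, `has_tracer`, `has_vacancy`,
#'   `is_diffusion_tracer_state`, `is_diffusion_tracer_exit_state`,
#'   `is_osmotic_tracer_state`, `is_osmotic_tracer_exit_state`.
#' @examples
#' classify_configuration(parse_config("OO*O*"))
#' @export
classify_configuration <- function(config) {
  if (!inherits(config, "pore_config")) config <- pore_config(config)
  codes <- unclass(config)
  i <- length(codes)
  has_tracer <- any(codes == .OCC_TRACER)
  has_vacancy <- any(codes == .OCC_VACANCY)
  tracer_at_exit <- codes[i] == .OCC_TRACER
  structure(list(
    is_null = !has_tracer && !has_vacancy,
    has_tracer = has_tracer,
    has_vacancy = has_vacancy,
    is_diffusion_tracer_state = has_tracer,
    is_diffusion_tracer_exit_state = tracer_at_exit,
    is_osmotic_tracer_state = has_tracer && !has_vacancy,
    is_osmotic_tracer_exit_state = tracer_at_exit && !has_vacancy
  ), class = "state_class")
}

#' @export
print.state_class <- function(x, ...) {
  on <- names(x)[vapply(x, isTRUE, logical(1))]
  cat("<state_class> ", paste(on, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Shared argument check: pore length must be a single integer >= 1.
check_pore_length <- function(i) {
  if (length(i) != 1L || !is.numeric(i) || is.na(i) || i != floor(i) || i < 1) {
    stop("`i` must be a single integer >= 1", call. = FALSE)
  }
  as.integer(i)
}
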