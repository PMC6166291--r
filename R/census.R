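.CENSUS_FIELDS <- c("i", "n_total", "n_null", "n_tracer_only", "n_vacancy_only",
                    "n_tracer_and_vacancy", "n_d", "n_dex", "n_f", "n_fex")

#' Census of pore occupancy states by enumeration
#'
#' Counts the occupancy-state classes of an `i`-slot single-file pore by
#' enumerating every configuration and classifying each one; no count is
#' taken from a closed form. The four partition cells (null, tracer only,
#' vacancy only, tracer + vacancy) always sum to the total, and the four
#' permeability-relevant classes are:
#' `n_d` diffusion tracer states, `n_dex` diffusion tracer exit states,
#' `n_f` osmotic tracer (full-pore) states, `n_fex` osmotic tracer exit
#' states.
#'
#' @param i Number of slots (positive integer).
#' @return An object of class `state_census`: a named list with fields
#'   `i, n_total, n_null, n_tracer_only, n_vacancy_only,
#'   n_tracer_and_vacancy, n_d, n_dex, n_f, n_fex`.
#' @seealso [closed_form_census()] for the algebraic counts,
#'   [census_table()] for several pore lengths at once.
#' @examples
#' census(3)  # 13 states in total, 9 diffusion tracer states
#' @export
census <- function(i) {
  i <- check_pore_length(i)
  configs <- enumerate_configurations(i)
  cls <- lapply(configs, classify_configuration)
  n_of <- function(field) sum(vapply(cls, `[[`, logical(1), field))
  out <- list(
    i = i,
    n_total = length(configs),
    n_null = n_of("is_null"),
    n_tracer_only = sum(vapply(cls, function(c) c$has_tracer && !c$has_vacancy,
                               logical(1))),
    n_vacancy_only = sum(vapply(cls, function(c) c$has_vacancy && !c$has_tracer,
                                logical(1))),
    n_tracer_and_vacancy = sum(vapply(cls, function(c) c$has_tracer && c$has_vacancy,
                                      logical(1))),
    n_d = n_of("is_diffusion_tracer_state"),
    n_dex = n_of("is_diffusion_tracer_exit_state"),
    n_f = n_of("is_osmotic_tracer_state"),
    n_fex = n_of("is_osmotic_tracer_exit_state")
  )
  structure(out, class = "state_census")
}

#' Census of pore occupancy states from closed forms
#'
#' The algebraic counterpart of [census()]: total states
#' `i^2 + i + 1`, one null state, `i` tracer-only states, `i` vacancy-only
#' states, `i * (i - 1)` states with both tracer and vacancy, `i^2`
#' diffusion tracer states, `i` diffusion tracer exit states, `i` osmotic
#' tracer states and a single osmotic tracer exit state.
#'
#' @inheritParams census
#' @return A `state_census` object (same fields as [census()]).
#' @examples
#' closed_form_census(10)$n_total  # 111
#' @export
closed_form_census <- function(i) {
  i <- check_pore_length(i)
  structure(list(
    i = i,
    n_total = i * i + i + 1L,
    n_null = 1L,
    n_tracer_only = i,
    n_vacancy_only = i,
    n_tracer_and_vacancy = i * (i - 1L),
    n_d = i * i,
    n_dex = i,
    n_f = i,
    n_fex = 1L
  ), class = "state_census")
}

#' @export
print.state_census <- function(x, ...) {
  cat("Pore state census (i = ", x$i, " slots)\n", sep = "")
  cat("  total states:          ", x$n_total, "\n")
  cat("  null / tracer-only / vacancy-only / tracer+vacancy: ",
      x$n_null, "/", x$n_tracer_only, "/", x$n_vacancy_only, "/",
      x$n_tracer_and_vacancy, "\n")
  cat("  diffusion tracer states (n_d):      ", x$n_d, "\n")
  cat("  diffusion tracer exit states (n_dex):", x$n_dex, "\n")
  cat("  osmotic tracer states (n_f):        ", x$n_f, "\n")
  cat("  osmotic tracer exit states (n_fex): ", x$n_fex, "\n")
  invisible(x)
}

#' @export
as.data.frame.state_census <- function(x, ...) {
  as.data.frame(unclass(x)[.CENSUS_FIELDS])
}

#' Census table over several pore lengths
#'
#' @param i_values Vector of pore lengths (positive integers).
#' @param method `"enumerate"` (default) counts by exhaustive enumeration
#'   and classification; `"closed_form"` uses the algebraic expressions.
#' @return A data frame with one row per pore length and the ten census
#'   columns in fixed order.
#' @examples
#' census_table(1:4)
#' @export
census_table <- function(i_values, method = c("enumerate", "closed_form")) {
  method <- match.arg(method)
  fun <- if (method == "enumerate") census else closed_form_census
  if (length(i_values) == 0L) {
    return(stats::setNames(as.data.frame(matrix(integer(0), 0, 10)),
                           .CENSUS_FIELDS))
  }
  do.call(rbind, lapply(i_values, function(i) as.data.frame(fun(i))))
}
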