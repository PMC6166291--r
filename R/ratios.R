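#' Available Pf/Pd ratio models
#'
#' Names the theoretical expressions for the osmotic-to-diffusive
#' permeability ratio of an `i`-slot single-file pore that the package can
#' evaluate:
#'
#' * `TRACER_STATES`: `(1/n_f) / (1/n_d)` — reciprocal counts of osmotic
#'   (full-pore) tracer states over diffusion tracer states; equals `i`.
#' * `TRACER_EXIT_STATES`: `(1/n_fex) / (1/n_dex)` — the same construction
#'   restricted to tracer exit states; equals `i`.
#' * `NP_MINUS_1`: `i - 1`.
#' * `NP_PLUS_1`: `i + 1` (the classical full-pore count of `i` tracer
#'   states plus the null state).
#' * `NP2P1_OVER_NPP1`: `(i^2 + 1) / (i + 1)`.
#' * `MEAN_OCC_PLUS_1`: `<n> + 1` with mean occupancy `<n> = i - 1` under
#'   the single-vacancy assumption; equals `i`.
#'
#' @return Character vector of model identifiers.
#' @export
ratio_models <- function() {
  c("TRACER_STATES", "TRACER_EXIT_STATES", "NP_MINUS_1", "NP_PLUS_1",
    "NP2P1_OVER_NPP1", "MEAN_OCC_PLUS_1")
}

#' Pf/Pd ratio under a given model
#'
#' Evaluates the permeability ratio for a pore of `i` slots. The two
#' state-counting models (`TRACER_STATES`, `TRACER_EXIT_STATES`) are
#' computed from the counts returned by [census()] — never from a
#' hard-coded closed form — so the ratio is traceable to the enumeration.
#' `MEAN_OCC_PLUS_1` derives the mean occupancy from the enumerated
#' single-vacancy configurations.
#'
#' @param i Number of slots (positive integer); equals the number of water
#'   molecules `N_p` when the pore is full.
#' @param model One of [ratio_models()].
#' @return An object of class `ratio_prediction`: list with `i`, `model`,
#'   `value` (dimensionless Pf/Pd) and `mean_occupancy` (`NA` except for
#'   `MEAN_OCC_PLUS_1`).
#' @examples
#' pfpd_ratio(3, "TRACER_STATES")$value       # 3
#' pfpd_ratio(7, "NP2P1_OVER_NPP1")$value     # 6.25
#' @export
pfpd_ratio <- function(i, model = ratio_models()) {
  i <- check_pore_length(i)
  model <- match.arg(model)
  mean_occ <- NA_real_
  value <- switch(model,
    TRACER_STATES = {
      # (1/n_f) / (1/n_d), simplified to the exact integer quotient
      cen <- census(i)
      cen$n_d / cen$n_f
    },
    TRACER_EXIT_STATES = {
      cen <- census(i)
      cen$n_dex / cen$n_fex
    },
    NP_MINUS_1 = i - 1,
    NP_PLUS_1 = i + 1,
    NP2P1_OVER_NPP1 = (i^2 + 1) / (i + 1),
    MEAN_OCC_PLUS_1 = {
      mean_occ <- mean_single_vacancy_occupancy(i)
      mean_occ + 1
    }
  )
  structure(list(i = i, model = model, value = value,
                 mean_occupancy = mean_occ),
            class = "ratio_prediction")
}

# Mean number of occupied slots over the enumerated configurations that
# contain the vacancy (the single-vacancy occupancy <n> = i - 1).
mean_single_vacancy_occupancy <- function(i) {
  configs <- enumerate_configurations(i)
  with_vac <- Filter(function(c) any(unclass(c) == .OCC_VACANCY), configs)
  mean(vapply(with_vac, function(c) sum(unclass(c) != .OCC_VACANCY),
              numeric(1)))
}

#' @export
print.ratio_prediction <- function(x, ...) {
  cat("Pf/Pd prediction [", x$model, "] at i = ", x$i, ": ",
      format_ratio_display(x$value), "\n", sep = "")
  invisible(x)
}

#' Comparison table of Pf/Pd expressions
#'
#' One row per pore length, one column per theoretical expression, in the
#' order: combinatorial state-count model (`state_count_model`, which equals both
#' the tracer-state and tracer-exit-state ratios), `i - 1`,
#' `(i^2 + 1)/(i + 1)`, `i + 1`. Values are kept at full precision; use
#' [format_model_table()] for display rounding.
#'
#' @param i_values Vector of pore lengths (positive integers). May be empty.
#' @return Data frame with columns `i`, `state_count_model`, `np_minus_1`,
#'   `np2p1_over_npp1`, `np_plus_1`.
#' @examples
#' model_table(c(1, 2, 3, 4, 7, 10))
#' @export
model_table <- function(i_values) {
  cols <- c("i", "state_count_model", "np_minus_1", "np2p1_over_npp1", "np_plus_1")
  if (length(i_values) == 0L) {
    return(stats::setNames(as.data.frame(matrix(numeric(0), 0, 5)), cols))
  }
  rows <- lapply(i_values, function(i) {
    data.frame(
      i = check_pore_length(i),
      state_count_model = pfpd_ratio(i, "TRACER_EXIT_STATES")$value,
      np_minus_1 = pfpd_ratio(i, "NP_MINUS_1")$value,
      np2p1_over_npp1 = pfpd_ratio(i, "NP2P1_OVER_NPP1")$value,
      np_plus_1 = pfpd_ratio(i, "NP_PLUS_1")$value
    )
  })
  do.call(rbind, rows)
}

#' Display-round a Pf/Pd value
#'
#' Human-readable formatting used in the comparison table: round half-up to
#' two decimals and trim trailing zeros (so `5/3` prints as `1.67`, `50/8`
#' as `6.25`, integers without a decimal point). Internal computations are
#' never rounded.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
format_ratio_display <- function(x) {
  half_up <- floor(round(x * 100, 6) + 0.5) / 100
  s <- sprintf("%.2f", half_up)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Display-rounded model comparison table
#'
#' @param tab A table from [model_table()].
#' @return Data frame of the same shape with ratio columns formatted by
#'   [format_ratio_display()].
#' @export
format_model_table <- function(tab) {
  out <- tab
  for (col in setdiff(names(tab), "i")) {
    out[[col]] <- format_ratio_display(tab[[col]])
  }
  out
}

#' Gap between the state-count model and (i^2+1)/(i+1)
#'
#' Returns `i - (i^2 + 1)/(i + 1)`, the amount by which the competing
#' expression falls short of the state-count prediction `i`. It is zero at
#' `i = 1`, positive for `i >= 2`, and approaches 1 from below as the pore
#' lengthens (algebraically the gap equals `(i - 1)/(i + 1)`).
#'
#' @inheritParams pfpd_ratio
#' @return Dimensionless numeric gap.
#' @examples
#' asymptotic_gap(7)  # 0.75
#' @export
asymptotic_gap <- function(i) {
  i <- check_pore_length(i)
  i - (i^2 + 1) / (i + 1)
}
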