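test_that("enumeration reproduces the brute-force state set, in order", {
  for (i in 1:7) {
    got <- do.call(rbind, lapply(enumerate_configurations(i), unclass))
    expect_equal(got, brute_force_configs(i), label = paste("i =", i))
  }
})

test_that("enumeration size follows the multiplicative case count", {
  for (i in 1:12) {
    configs <- enumerate_configurations(i)
    expect_length(configs, i^2 + i + 1)
    both <- sum(vapply(configs, function(c) {
      any(unclass(c) == 1L) && any(unclass(c) == 2L)
    }, logical(1)))
    expect_equal(both, i * (i - 1))
  }
})

test_that("configuration construction enforces the occupancy constraints", {
  expect_error(pore_config(c("tracer", "tracer", "water")), "one tracer")
  expect_error(pore_config(c("vacancy", "water", "vacancy")), "one vacancy")
  expect_error(pore_config(character(0)), "at least one slot")
  expect_error(enumerate_configurations(0), "integer >= 1")
  expect_error(enumerate_configurations(2.5), "integer >= 1")
})

test_that("glyph notation round-trips through parse and format", {
  for (cfg in enumerate_configurations(3)) {
    expect_identical(unclass(parse_config(format(cfg))), unclass(cfg))
  }
  expect_identical(format(parse_config("*O*[]O")), "*O*[]O")
})

test_that("classification matches the worked 3-slot examples", {
  entrance_tracer <- classify_configuration(parse_config("*O*OO"))
  expect_true(entrance_tracer$is_osmotic_tracer_state)
  expect_true(entrance_tracer$is_diffusion_tracer_state)
  expect_false(entrance_tracer$is_osmotic_tracer_exit_state)
  expect_false(entrance_tracer$is_diffusion_tracer_exit_state)

  exit_tracer <- classify_configuration(parse_config("OO*O*"))
  expect_true(exit_tracer$is_osmotic_tracer_state)
  expect_true(exit_tracer$is_osmotic_tracer_exit_state)
  expect_true(exit_tracer$is_diffusion_tracer_exit_state)

  vacancy_only <- classify_configuration(parse_config("O[]O"))
  expect_true(vacancy_only$has_vacancy)
  expect_false(vacancy_only$has_tracer)
  expect_false(vacancy_only$is_diffusion_tracer_state)
})

test_that("classification partitions every configuration into one cell", {
  for (i in 1:6) {
    for (cfg in enumerate_configurations(i)) {
      cls <- classify_configuration(cfg)
      cells <- c(cls$is_null,
                 cls$has_tracer && !cls$has_vacancy,
                 !cls$has_tracer && cls$has_vacancy,
                 cls$has_tracer && cls$has_vacancy)
      expect_equal(sum(cells), 1L)
      # class implications
      if (cls$is_osmotic_tracer_exit_state) {
        expect_true(cls$is_osmotic_tracer_state)
      }
      if (cls$is_osmotic_tracer_state) {
        expect_true(cls$has_tracer && !cls$has_vacancy)
      }
      if (cls$is_diffusion_tracer_exit_state) {
        expect_true(cls$is_diffusion_tracer_state)
      }
      expect_equal(cls$is_diffusion_tracer_state, cls$has_tracer)
    }
  }
})

test_that("census agrees with closed forms and brute force for i = 1..12", {
  for (i in 1:12) {
    cen <- census(i)
    expect_census_equal(cen, unclass(closed_form_census(i)))
    if (i <= 8) expect_census_equal(cen, brute_force_census(i))
    # the two equivalent ratio routes
    expect_equal(cen$n_dex / cen$n_fex, i)
    expect_equal(cen$n_d / cen$n_f, i)
    # partition identity
    expect_equal(cen$n_total,
                 cen$n_null + cen$n_tracer_only + cen$n_vacancy_only +
                   cen$n_tracer_and_vacancy)
    expect_equal(cen$n_d, cen$n_tracer_only + cen$n_tracer_and_vacancy)
    expect_true(cen$n_fex <= cen$n_f && cen$n_f <= cen$n_d)
    expect_true(cen$n_dex <= cen$n_d)
  }
})

test_that("census_table emits fixed columns and handles empty input", {
  tab <- census_table(1:3)
  expect_equal(names(tab),
               c("i", "n_total", "n_null", "n_tracer_only", "n_vacancy_only",
                 "n_tracer_and_vacancy", "n_d", "n_dex", "n_f", "n_fex"))
  expect_equal(tab$n_total, c(3L, 7L, 13L))
  expect_equal(census_table(2:4, method = "closed_form"), census_table(2:4))
  expect_equal(nrow(census_table(integer(0))), 0L)
})
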