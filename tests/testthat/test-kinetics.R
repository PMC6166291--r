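test_that("parameter validation enforces the physical constraints", {
  expect_error(kinetic_params(i = 3, k_exit = 2, k_hop = 1), "barrier")
  expect_error(kinetic_params(i = 3, a_L = 0), "activities")
  expect_error(kinetic_params(i = 3, k_coll = -1), "rates")
  expect_error(kinetic_params(i = 3, tracer_fraction_L = 1.5), "tracer")
  expect_error(kinetic_params(i = 3, t_max = 10, burn_in = 20), "t_max")
})

test_that("knock-on on a full pore ejects the exit molecule only", {
  p <- kinetic_params(i = 3, a_L = 2)
  ev <- event_set(parse_config("*O*OO"), p)
  ko <- ev[ev$kind == "KNOCK_ON_L", ]
  expect_equal(nrow(ko), 1L)
  expect_equal(ko$to, "*O*O[]")           # striker does not enter
  expect_equal(ko$rate, p$k_coll * p$a_L) # scales with left activity
  # full pore: both Brownian escapes available, no hops, no entries
  expect_setequal(ev$kind, c("KNOCK_ON_L", "KNOCK_ON_R", "EXIT_L", "EXIT_R"))
  expect_equal(ev$to[ev$kind == "EXIT_R"], "*O*O[]")
  expect_equal(ev$to[ev$kind == "EXIT_L"], "[]OO")
})

test_that("knock-on with a vacancy advances one molecule toward it", {
  p <- kinetic_params(i = 3)
  ev <- event_set(parse_config("*O*O[]"), p)
  expect_equal(ev$to[ev$kind == "KNOCK_ON_L"], "*O*[]O")
  # no ejection events while a vacancy exists
  expect_false(any(ev$kind %in% c("EXIT_L", "EXIT_R")))
  # repeated collisions walk the vacancy to the entrance
  ev2 <- event_set(parse_config("*O*[]O"), p)
  expect_equal(ev2$to[ev2$kind == "KNOCK_ON_L"], "[]*O*O")
})

test_that("a mid-pore vacancy offers two equal-rate Brownian hops", {
  p <- kinetic_params(i = 3)
  ev <- event_set(parse_config("O[]O"), p)
  hops <- ev[grepl("^HOP", ev$kind), ]
  expect_equal(nrow(hops), 2L)
  expect_equal(hops$rate, rep(p$k_hop, 2))
  expect_setequal(hops$to, c("[]OO", "OO[]"))
  # mid-pore vacancy cannot be filled from solution
  expect_false(any(grepl("^ENTER", ev$kind)))
})

test_that("entry fills a vacant end slot, tracer branch weighted by fraction", {
  p <- kinetic_params(i = 3, tracer_fraction_L = 0.25)
  ev <- event_set(parse_config("[]OO"), p)
  ent <- ev[ev$kind == "ENTER_L", ]
  expect_equal(sort(ent$entrant), c("tracer", "water"))
  expect_equal(sum(ent$rate), p$k_enter * p$a_L)
  expect_equal(ent$rate[ent$entrant == "tracer"], p$k_enter * p$a_L * 0.25)
  expect_equal(ent$to[ent$entrant == "tracer"], "*O*OO")
  # with the tracer already inside, only water can enter
  ev2 <- event_set(parse_config("[]O*O*"), p)
  ent2 <- ev2[ev2$kind == "ENTER_L", ]
  expect_equal(ent2$entrant, "water")
  expect_equal(ent2$rate, p$k_enter * p$a_L)
})

test_that("every event preserves configuration validity", {
  for (i in c(1, 3, 4)) {
    p <- kinetic_params(i = i, tracer_fraction_L = 0.3)
    for (cfg in enumerate_configurations(i)) {
      ev <- event_set(cfg, p)
      for (s in ev$to) {
        codes <- unclass(parse_config(s))  # parse_config validates
        expect_lte(sum(codes == 2L), 1L)
        expect_lte(sum(codes == 1L), 1L)
        expect_length(codes, i)
      }
    }
  }
})

test_that("generator rows sum to zero and dimension matches the census", {
  for (i in 2:4) {
    p <- kinetic_params(i = i)
    gen <- build_generator(i, p)
    expect_lt(max(abs(rowSums(gen$Q))), 1e-12)
    expect_equal(nrow(gen$Q), i^2 + i + 1)   # single tracer source
    expect_true(all(gen$Q - diag(diag(gen$Q)) >= 0))
  }
  expect_error(build_generator(7, kinetic_params(i = 7)), "i <= 6")
})

test_that("stationary solve is exact at equilibrium", {
  for (i in 2:3) {
    sol <- solve_stationary(build_generator(i, kinetic_params(i = i)))
    expect_equal(sum(sol$pi), 1, tolerance = 1e-12)
    expect_true(all(sol$pi > 0))
    expect_lt(abs(sol$net_water_flux), 1e-12)
    expect_equal(sol$tracer_rl_rate, 0)  # no tracer source on the right
  }
})

test_that("tracer-free equilibrium is mirror-symmetric with zero boundary flux", {
  p <- kinetic_params(i = 3, tracer_fraction_L = 0)
  sol <- solve_stationary(build_generator(3, p))
  expect_lt(abs(sol$net_water_flux), 1e-12)
  # stationary probability invariant under left-right reflection
  keys <- names(sol$pi)
  mirror_key <- vapply(strsplit(sub(":.*", "", keys), ""), function(ch) {
    paste0(paste(rev(ch), collapse = ""), ":0")
  }, character(1))
  expect_equal(unname(sol$pi[mirror_key]), unname(sol$pi), tolerance = 1e-12)
})

test_that("a chain that cannot refill the pore is flagged reducible", {
  p <- kinetic_params(i = 2, k_enter = 0, tracer_fraction_L = 0)
  expect_error(solve_stationary(build_generator(2, p)), "reducible")
})

test_that("simulation is reproducible and conserves its invariants", {
  p <- kinetic_params(i = 3, t_max = 300, seed = 11)
  s1 <- simulate_pore(p)
  s2 <- simulate_pore(p)
  expect_identical(s1$n_events, s2$n_events)
  expect_identical(s1$n_water_LR, s2$n_water_LR)
  expect_identical(s1$vacancy_lifetimes, s2$vacancy_lifetimes)
  expect_true(all(s1$vacancy_lifetimes > 0))
  expect_true(all(is.finite(s1$vacancy_lifetimes)))
  expect_gte(s1$full_pore_fraction, 0)
  expect_lte(s1$full_pore_fraction, 1)
  # batch tallies reconcile with the totals
  expect_equal(sum(s1$batch[, "tracer_lr"]), s1$n_tracer_LR)
  expect_equal(sum(s1$batch[, "water_lr"]), s1$n_water_LR)
  expect_equal(sum(s1$batch[, "full_time"]) / s1$sim_time,
               s1$full_pore_fraction)
})

test_that("no tracer source means no tracer translocations", {
  p <- kinetic_params(i = 3, tracer_fraction_L = 0, t_max = 300, seed = 5)
  st <- simulate_pore(p)
  expect_identical(st$n_tracer_LR, 0)
  expect_identical(st$n_tracer_RL, 0)
})

test_that("a system with no enabled events is reported as degenerate", {
  p <- kinetic_params(i = 3, k_coll = 0, k_enter = 0, k_exit = 0, k_hop = 1)
  expect_error(simulate_pore(p), "degenerate")
})

test_that("equilibrium net water flux vanishes within Monte Carlo error", {
  p <- kinetic_params(i = 3, t_max = 2000, seed = 3, n_batches = 20)
  st <- simulate_pore(p)
  net <- (st$n_water_LR - st$n_water_RL) / st$sim_time
  se <- sd((st$batch[, "water_lr"] - st$batch[, "water_rl"]) / st$batch_len) /
    sqrt(nrow(st$batch))
  expect_lt(abs(net), 3 * se)
})

test_that("p_d is symmetric under swapping the tracer-carrying side", {
  base <- list(i = 3, t_max = 6000, n_batches = 30)
  left <- do.call(kinetic_params, c(base, list(seed = 21)))
  right <- do.call(kinetic_params, c(base, list(
    seed = 22, tracer_fraction_L = 0, tracer_fraction_R = 0.1)))
  e_l <- estimate_permeabilities(simulate_pore(left))
  e_r <- estimate_permeabilities(simulate_pore(right))
  se <- sqrt(e_l$p_d_se^2 + e_r$p_d_se^2)
  expect_lt(abs(e_l$p_d - e_r$p_d), 3 * se)
})

test_that("instant-refill limit drives vacancy lifetimes to zero", {
  p <- kinetic_params(i = 3, k_enter = 1000, t_max = 500, seed = 9)
  st <- simulate_pore(p)
  lt <- vacancy_lifetime_summary(st)
  expect_gt(lt$n, 10)
  expect_lt(lt$mean, 0.02 / p$k_hop)
})

test_that("lifetime summary returns the empty sentinel without samples", {
  st <- structure(list(vacancy_lifetimes = numeric(0)),
                  class = "trajectory_stats")
  lt <- vacancy_lifetime_summary(st)
  expect_identical(lt$n, 0L)
  expect_true(is.na(lt$mean) && is.na(lt$median))
})

test_that("permeability estimators use the right run types", {
  eq <- kinetic_params(i = 2, t_max = 500, seed = 2)
  est_eq <- estimate_permeabilities(simulate_pore(eq))
  expect_true(is.na(est_eq$p_f))
  expect_false(is.na(est_eq$p_d))
  gr <- kinetic_params(i = 2, a_L = 1.5, tracer_fraction_L = 0,
                       t_max = 500, seed = 4)
  est_gr <- estimate_permeabilities(simulate_pore(gr))
  expect_true(is.na(est_gr$p_d))
  expect_false(is.na(est_gr$p_f))
  comb <- permeability_ratio(est_eq, est_gr)
  expect_equal(comb$ratio, est_gr$p_f / est_eq$p_d)
  expect_error(permeability_ratio(est_eq, est_eq), "gradient")
  # short equilibrium run carries the low-precision flag
  expect_true(est_eq$low_precision)
})

test_that("event trace log records one parsable line per event", {
  tf <- tempfile(fileext = ".gz")
  p <- kinetic_params(i = 2, t_max = 50, seed = 8)
  st <- simulate_pore(p, trace_file = tf)
  lines <- readLines(gzfile(tf))
  expect_gte(length(lines), st$n_events)
  parts <- strsplit(lines[[1]], "\t")[[1]]
  expect_length(parts, 3L)
  expect_false(is.na(as.numeric(parts[[1]])))
  unlink(tf)
})
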