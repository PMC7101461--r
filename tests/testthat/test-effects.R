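ws2 <- phase1_worksheet()

test_that("per-run averages and differences reproduce the recorded worksheet rows", {
  avg <- run_averages(ws2)
  expect_equal(unname(avg[c("A1", "A7")]), c(398.03, 195.13))
  # full rows agree with the recorded table at its printed precision
  expect_equal(unname(avg), printed_averages, tolerance = 0.0051)
  d <- run_differences(ws2, 1, 2)
  expect_equal(unname(d[c("A2", "A6")]), c(29.04, 28.63))
  expect_equal(unname(d), printed_differences, tolerance = 1e-10)
  expect_equal(unname(run_differences(ws2, 1, 1)), rep(0, 10))
  expect_error(run_differences(ws2, 1, 3), "cycle indices")
})

test_that("single-cycle averages equal that cycle", {
  f <- phase1_factors()
  ws1 <- attach_cycle(evop_worksheet(f$temperature, f$pH, f$wb_percent),
                      phase1_cycle1)
  expect_equal(unname(run_averages(ws1)), phase1_cycle1)
  expect_error(run_averages(evop_worksheet(f$temperature, f$pH, f$wb_percent)),
               "no cycles")
})

test_that("main and interaction effects match the brute-force contrast oracle", {
  # cycle-1 oracles, explicit run subsets
  expect_equal(main_effect(phase1_cycle1, ws2, "T"),
               contrast_oracle(phase1_cycle1,
                               c("A4", "A5", "A7", "A9"),
                               c("A2", "A3", "A8", "A10")))
  expect_equal(round(main_effect(phase1_cycle1, ws2, "T"), 2), 31.78)
  expect_equal(round(main_effect(phase1_cycle1, ws2, "R"), 2), -21.86)
  expect_equal(round(interaction_effect(phase1_cycle1, ws2, "TP"), 2), 65.58)
  expect_equal(interaction_effect(phase1_cycle1, ws2, "TP"),
               contrast_oracle(phase1_cycle1,
                               c("A2", "A8", "A5", "A7"),
                               c("A3", "A10", "A4", "A9")))
  # every effect, every cycle, against subsets read off the coding
  for (resp in list(phase1_cycle1, phase1_cycle2)) {
    for (f in c("T", "P", "R")) {
      signs <- ws2$runs[[paste0("coded_", f)]]
      expect_equal(main_effect(resp, ws2, f),
                   contrast_oracle(resp, ws2$runs$run_id[signs == 1],
                                   ws2$runs$run_id[signs == -1]))
    }
    for (pr in c("TP", "TR", "PR")) {
      prod_sign <- ws2$runs[[paste0("coded_", substr(pr, 1, 1))]] *
                   ws2$runs[[paste0("coded_", substr(pr, 2, 2))]]
      expect_equal(interaction_effect(resp, ws2, pr),
                   contrast_oracle(resp, ws2$runs$run_id[prod_sign == 1],
                                   ws2$runs$run_id[prod_sign == -1]))
    }
  }
  expect_equal(main_effect(rep(7, 10), ws2, "P"), 0)
  expect_equal(interaction_effect(rep(7, 10), ws2, "PR"), 0)
})

test_that("change-in-mean matches the recorded phase statistics", {
  expect_equal(change_in_mean(phase1_cycle2, ws2), -214.54, tolerance = 1e-3)
  expect_equal(change_in_mean(phase1_cycle1, ws2), -231.95, tolerance = 1e-3)
  expect_equal(change_in_mean(rep(42, 10), ws2), 0)
})

test_that("effects are affine-equivariant in the responses", {
  set.seed(11)
  for (rep in 1:5) {
    resp <- runif(10, 50, 400)
    a <- runif(1, 0.5, 3); b <- runif(1, -50, 50)
    for (f in c("T", "P", "R"))
      expect_equal(main_effect(a * resp + b, ws2, f),
                   a * main_effect(resp, ws2, f))
    for (pr in c("TP", "TR", "PR"))
      expect_equal(interaction_effect(a * resp + b, ws2, pr),
                   a * interaction_effect(resp, ws2, pr))
    expect_equal(change_in_mean(a * resp + b, ws2),
                 a * change_in_mean(resp, ws2))
  }
})

test_that("sd estimators behave as documented", {
  expect_equal(estimate_sd(ws2, "fixed", s = 100.65), 100.65)
  expect_equal(estimate_sd(ws2, "pooled"),
               sqrt(sum(run_differences(ws2, 1, 2)^2) / 20))
  expect_equal(estimate_sd(ws2, "pooled"), 12.00, tolerance = 0.001)
  d <- run_differences(ws2, 1, 2)
  expect_equal(estimate_sd(ws2, "range"), 0.23 * (max(d) - min(d)))
  # identical cycles -> zero noise under both data-driven methods
  f <- phase1_factors()
  ws_id <- attach_cycle(attach_cycle(
    evop_worksheet(f$temperature, f$pH, f$wb_percent), phase1_cycle1),
    phase1_cycle1)
  expect_equal(estimate_sd(ws_id, "range"), 0)
  expect_equal(estimate_sd(ws_id, "pooled"), 0)
  ws1 <- attach_cycle(evop_worksheet(f$temperature, f$pH, f$wb_percent),
                      phase1_cycle1)
  expect_error(estimate_sd(ws1, "pooled"), "at least 2 cycles")
  expect_error(estimate_sd(ws2, "fixed"), "'s'")
})

test_that("error limits scale with s, shrink with n, and vanish at s = 0", {
  lim <- error_limits(100.65, 2)
  expect_equal(lim$for_average, 2 * 100.65 / sqrt(2))
  expect_equal(lim$for_effects, 2 * 100.65 / 2)
  expect_equal(lim$for_change_in_mean, 1.78 * 100.65 / 2)
  z <- error_limits(0, 2)
  expect_equal(unlist(unclass(z)), c(for_average = 0, for_effects = 0,
                                     for_change_in_mean = 0))
  # homogeneous of degree 1 in s
  expect_equal(unlist(unclass(error_limits(2 * 93.03, 2))),
               2 * unlist(unclass(error_limits(93.03, 2))))
  # decreasing in n
  for (field in c("for_average", "for_effects", "for_change_in_mean"))
    expect_lt(error_limits(50, 4)[[field]], error_limits(50, 2)[[field]])
})

test_that("decision rule shifts on significant effects, stops on a dominant centre", {
  lim <- error_limits(100.65, 2)
  eff_small <- c(T = -26.05, P = 11.70, R = 30.50,
                 TP = 13.22, TR = 34.59, PR = 61.39)
  dec <- evop_decide(eff_small, lim, -231.94)
  expect_equal(dec$verdict, "optimum_reached")

  # effect exactly at the limit is NOT significant (strict inequality)
  eff_edge <- c(T = lim$for_effects, P = 0, R = 0, TP = 0, TR = 0, PR = 0)
  expect_equal(evop_decide(eff_edge, lim, 0)$verdict, "continue_cycles")

  eff_big <- c(T = 150, P = 0, R = -120, TP = 0, TR = 0, PR = 0)
  dec2 <- evop_decide(eff_big, lim, -10)
  expect_equal(dec2$verdict, "shift")
  expect_equal(dec2$shift_direction, c(T = 1, P = 0, R = -1))

  # neither significant effects nor a dominant centre -> keep cycling
  expect_equal(evop_decide(eff_small, lim, -50)$verdict, "continue_cycles")
})

test_that("decision is invariant to relabelling the factors", {
  lim <- error_limits(40, 2)
  eff <- c(T = 90, P = -100, R = 10, TP = 5, TR = 2, PR = 1)
  base <- evop_decide(eff, lim, 0)
  # swap T and P everywhere (main effects and the matching interactions)
  swapped <- c(T = -100, P = 90, R = 10, TP = 5, TR = 1, PR = 2)
  perm <- evop_decide(swapped, lim, 0)
  expect_equal(perm$verdict, base$verdict)
  expect_equal(unname(perm$shift_direction[c("P", "T", "R")]),
               unname(base$shift_direction[c("T", "P", "R")]))
})

test_that("evop_analysis bundles the phase statistics coherently", {
  fit <- evop_analysis(ws2, sd_method = "fixed", s = 100.65)
  expect_s3_class(fit, "evop_analysis")
  expect_equal(fit$n_cycles, 2L)
  expect_equal(fit$s, 100.65)
  # analysis of the averages equals the average of per-cycle analyses
  # (effects are linear in the responses)
  f1 <- evop_analysis(ws2, cycle = 1, sd_method = "fixed", s = 1)
  f2 <- evop_analysis(ws2, cycle = 2, sd_method = "fixed", s = 1)
  expect_equal(fit$effects, (f1$effects + f2$effects) / 2)
  expect_equal(coef(fit), fit$effects)
  expect_output(print(fit), "EVOP phase analysis")
  expect_output(summary(fit), "Run averages")
})
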