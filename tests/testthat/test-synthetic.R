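test_that("noiseless generation is deterministic and sits on the surface", {
  surf <- true_surface(reference_beta)
  pt <- data.frame(temperature_C = 30, wb_percent = 70, pH = 6)
  dat <- generate_dataset(surf, pt, seed = 1)
  expect_equal(dat$activity, 419.96)
  noisy <- true_surface(reference_beta, noise_sd = 10)
  design <- expand.grid(temperature_C = 26:30, wb_percent = c(70, 90),
                        pH = c(4, 6, 8))
  expect_identical(generate_dataset(noisy, design, seed = 5),
                   generate_dataset(noisy, design, seed = 5))
  expect_false(identical(generate_dataset(noisy, design, seed = 5),
                         generate_dataset(noisy, design, seed = 6)))
  sims <- simulate(noisy, nsim = 2, seed = 5, design = design)
  expect_identical(sims[[1]], generate_dataset(noisy, design, seed = 5))
})

test_that("polynomial refits recover each coefficient within 3 SEs almost always", {
  surf <- true_surface(reference_beta, noise_sd = 10)
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    design <- data.frame(temperature_C = runif(200, 26, 30),
                         wb_percent = runif(200, 70, 90),
                         pH = runif(200, 4, 8))
    dat <- generate_dataset(surf, design, seed = s)
    fit <- fit_quadratic_surface(dat)
    se <- summary(fit$fit)$coefficients[, "Std. Error"]
    if (all(abs(coef(fit) - reference_beta) <= 3 * se)) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("worksheets generated from analytic surfaces give analytic effects", {
  f <- phase1_factors()
  # pure coded-T main-effect surface: activity = 300 + 10 * coded_T
  # (beta1 = 10 / half_step in actual units)
  surf_T <- true_surface(c(300 - 10 / 2 * 28, 10 / 2, 0, 0, 0))
  ws <- generate_worksheet(surf_T, f$temperature, f$pH, f$wb_percent,
                           n_cycles = 2, seed = 1)
  expect_equal(main_effect(run_averages(ws), ws, "T"), 20)
  for (other in c("P", "R"))
    expect_equal(main_effect(run_averages(ws), ws, other), 0)
  for (pr in c("TP", "TR", "PR"))
    expect_equal(interaction_effect(run_averages(ws), ws, pr), 0)
  expect_equal(unname(run_differences(ws, 1, 2)), rep(0, 10))

  # pure interaction surface: gamma_TP * coded_T * coded_P with gamma = 5
  surf_TP <- true_surface(c(300, 0, 0, 0, 0), interactions = c(TP = 5))
  ws2 <- generate_worksheet(surf_TP, f$temperature, f$pH, f$wb_percent,
                            n_cycles = 1, seed = 1)
  resp <- ws2$cycles[1, ]
  expect_equal(interaction_effect(resp, ws2, "TP"), 10)
  expect_equal(main_effect(resp, ws2, "T"), 0)
  expect_equal(main_effect(resp, ws2, "P"), 0)
  expect_equal(interaction_effect(resp, ws2, "TR"), 0)
})

test_that("as noise vanishes the EVOP statistics converge to their analytic limits", {
  f <- phase1_factors()
  beta <- c(-1720, 3, -0.5, 840, -70)
  analytic <- NULL
  for (sd in c(10, 1, 0.1, 0)) {
    surf <- true_surface(beta, noise_sd = sd)
    ws <- generate_worksheet(surf, f$temperature, f$pH, f$wb_percent,
                             n_cycles = 2, seed = 2)
    an <- evop_analysis(ws, sd_method = "fixed", s = 1)
    if (sd == 0) analytic <- an$effects
  }
  # analytic limits: effect_T = 2 * h_T * beta1, effect_R = 2 * h_R * beta2,
  # effect_P = 2 * h_P * (beta3 + 2 * beta4 * centre_pH)
  expect_equal(unname(analytic["T"]), 2 * 2 * 3)
  expect_equal(unname(analytic["R"]), 2 * 10 * -0.5)
  expect_equal(unname(analytic["P"]), 2 * 2 * (840 + 2 * -70 * 6))
  # and the sd = 0.1 run is already within 1 U/gds of them
  surf <- true_surface(beta, noise_sd = 0.1)
  ws <- generate_worksheet(surf, f$temperature, f$pH, f$wb_percent,
                           n_cycles = 2, seed = 2)
  expect_equal(evop_analysis(ws, sd_method = "fixed", s = 1)$effects,
               analytic, tolerance = 1)
})

test_that("campaigns shift along the true gradient and stop at the optimum", {
  # flat surface, zero noise: nothing ever shifts
  flat <- true_surface(c(100, 0, 0, 0, 0))
  camp <- simulate_campaign(flat, evop_factor("temperature", 28, 2),
                            evop_factor("pH", 6, 1),
                            evop_factor("wb_percent", 80, 10),
                            max_phases = 4, seed = 1)
  expect_equal(camp$n_phases, 1L)
  expect_equal(camp$final_verdict, "continue_cycles")
  expect_equal(camp$final_factors$pH$centre, 6)

  # noiseless linear-in-T surface: first shift follows the sign of the gradient
  up <- true_surface(c(0, 5, 0, 0, 0), noise_sd = 0.01)
  camp_up <- simulate_campaign(up, evop_factor("temperature", 28, 1),
                               evop_factor("pH", 6, 1),
                               evop_factor("wb_percent", 80, 5),
                               max_phases = 2, seed = 3)
  expect_equal(camp_up$phases[[1]]$analysis$decision$shift_direction[["T"]], 1)
  expect_gt(camp_up$final_factors$temperature$centre, 28)

  # quadratic pH surface, start two half-steps low: walk up and stop
  quad <- true_surface(c(-1720, 0, 0, 840, -70), noise_sd = 5)
  camp_q <- simulate_campaign(quad, evop_factor("temperature", 28, 2),
                              evop_factor("pH", 4, 1),
                              evop_factor("wb_percent", 80, 10),
                              max_phases = 6, seed = 11)
  expect_lte(abs(camp_q$final_factors$pH$centre - 6), 1)
  expect_equal(unname(camp_q$true_optimum["pH"]), 6)
})

test_that("campaign phase centres move by exactly one half-step per shifted factor", {
  quad <- true_surface(c(-1720, 1, 0, 840, -70), noise_sd = 5)
  camp <- simulate_campaign(quad, evop_factor("temperature", 28, 2),
                            evop_factor("pH", 4, 1),
                            evop_factor("wb_percent", 80, 10),
                            max_phases = 6, seed = 2)
  if (camp$n_phases >= 2) {
    for (p in 2:camp$n_phases) {
      prev <- camp$phases[[p - 1]]
      cur <- camp$phases[[p]]
      dir <- prev$analysis$decision$shift_direction
      key <- c(T = "temperature", P = "pH", R = "wb_percent")
      for (fct in names(dir)) {
        step <- cur$factors[[key[[fct]]]]$centre -
          prev$factors[[key[[fct]]]]$centre
        expect_equal(step,
                     dir[[fct]] * prev$factors[[key[[fct]]]]$half_step)
      }
    }
  }
})

test_that("multiplicative noise scales with the response magnitude", {
  surf <- true_surface(c(0, 10, 0, 0, 0), noise_cv = 0.05)
  design <- data.frame(temperature_C = rep(c(10, 1000), each = 200),
                       wb_percent = 50, pH = 6)
  dat <- generate_dataset(surf, design, seed = 4)
  sd_small <- sd(dat$activity[1:200])
  sd_big <- sd(dat$activity[201:400])
  expect_gt(sd_big / sd_small, 50)
})
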