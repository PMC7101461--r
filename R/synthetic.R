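# Synthetic response surfaces and EVOP campaigns with known ground truth.
# Every downstream stage (worksheet arithmetic, effects, surrogates, grid
# search) can be exercised against analytic expectations.

#' Define a ground-truth response surface
#'
#' The surface mirrors the polynomial surrogate's form -- linear in
#' temperature and wheat-bran percentage, quadratic in pH -- optionally
#' augmented with two-factor interaction terms expressed in *coded* EVOP
#' units (they act on the products of coded levels when a worksheet is
#' generated, and are zero elsewhere).  Observation noise is additive
#' Gaussian by default; `noise_cv` switches to multiplicative noise with
#' that coefficient of variation.  `cycle_bias_sd` adds one shared Gaussian
#' offset per cycle, emulating batch-to-batch drift.
#'
#' @param beta Numeric length 5: `beta0..beta4` of
#'   `activity = b0 + b1*T + b2*WB% + b3*pH + b4*pH^2`.
#' @param interactions Named numeric, coded-unit interaction coefficients
#'   `TP`, `TR`, `PR` (default all 0).
#' @param noise_sd Homoscedastic Gaussian noise SD (>= 0), U/gds.
#' @param noise_cv If > 0, noise SD is `noise_cv * |true value|` instead.
#' @param cycle_bias_sd SD of the shared per-cycle offset (>= 0).
#' @return An object of class `true_surface`; supports [predict()].
#' @examples
#' s <- true_surface(c(-2299.6275, 7.896875, -0.591625, 839.270625,
#'                     -69.7646875))
#' predict(s, data.frame(temperature_C = 30, wb_percent = 70, pH = 6))
#' @export
true_surface <- function(beta, interactions = c(TP = 0, TR = 0, PR = 0),
                         noise_sd = 0, noise_cv = 0, cycle_bias_sd = 0) {
  beta <- as.numeric(beta)
  stopifnot(length(beta) == 5L, all(is.finite(beta)),
            noise_sd >= 0, noise_cv >= 0, cycle_bias_sd >= 0)
  names(beta) <- c("beta0", "beta1", "beta2", "beta3", "beta4")
  gam <- c(TP = 0, TR = 0, PR = 0)
  gam[names(interactions)] <- interactions
  structure(list(beta = beta, interactions = gam, noise_sd = noise_sd,
                 noise_cv = noise_cv, cycle_bias_sd = cycle_bias_sd),
            class = "true_surface")
}

#' @export
predict.true_surface <- function(object, newdata, ...) {
  x <- .input_matrix(newdata)
  b <- unname(object$beta)
  drop(b[1] + b[2] * x[, 1] + b[3] * x[, 2] + b[4] * x[, 3] + b[5] * x[, 3]^2)
}

#' @export
print.true_surface <- function(x, ...) {
  cat("Ground-truth surface, beta =", paste(signif(x$beta, 6), collapse = ", "), "\n")
  if (any(x$interactions != 0))
    cat("  coded interactions:", paste(names(x$interactions), x$interactions,
                                       sep = "=", collapse = ", "), "\n")
  cat(sprintf("  noise_sd = %g, noise_cv = %g, cycle_bias_sd = %g\n",
              x$noise_sd, x$noise_cv, x$cycle_bias_sd))
  invisible(x)
}

.surface_noise <- function(surface, mu) {
  if (surface$noise_cv > 0)
    stats::rnorm(length(mu), 0, surface$noise_cv * abs(mu))
  else if (surface$noise_sd > 0)
    stats::rnorm(length(mu), 0, surface$noise_sd)
  else rep(0, length(mu))
}

#' Sample a noisy training dataset from a true surface
#'
#' @param surface A [true_surface()].
#' @param design Data frame of evaluation points (`temperature_C`,
#'   `wb_percent`, `pH`).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return The design with an added `activity` column,
#'   `surface(x) + N(0, noise)`.
#' @export
generate_dataset <- function(surface, design, seed = 1L) {
  stopifnot(inherits(surface, "true_surface"))
  mu <- predict(surface, design)
  set.seed(seed)
  out <- as.data.frame(design)[, c("temperature_C", "wb_percent", "pH")]
  out$activity <- mu + .surface_noise(surface, mu)
  out
}

#' @rdname generate_dataset
#' @param object,nsim,... [stats::simulate()] interface: draws `nsim`
#'   datasets on `design`.
#' @export
simulate.true_surface <- function(object, nsim = 1, seed = 1L, design, ...) {
  lapply(seq_len(nsim), function(k) generate_dataset(object, design,
                                                     seed = seed + k - 1L))
}

#' Simulate a complete EVOP worksheet from a true surface
#'
#' Responses are the surface evaluated at each run's actual conditions,
#' plus coded-unit interaction terms, a shared per-cycle offset and
#' observation noise.
#'
#' @param surface A [true_surface()].
#' @param temperature,pH,wb_percent [evop_factor()] objects (the phase
#'   centre and half-steps).
#' @param n_cycles Number of cycles to simulate (>= 1).
#' @param seed Integer seed.
#' @return An [evop_worksheet()] with `n_cycles` cycles attached.
#' @export
generate_worksheet <- function(surface, temperature, pH, wb_percent,
                               n_cycles = 2L, seed = 1L) {
  stopifnot(inherits(surface, "true_surface"), n_cycles >= 1L)
  ws <- evop_worksheet(temperature, pH, wb_percent)
  mu <- predict(surface, ws$runs)
  gam <- surface$interactions
  mu <- mu + gam["TP"] * ws$runs$coded_T * ws$runs$coded_P +
             gam["TR"] * ws$runs$coded_T * ws$runs$coded_R +
             gam["PR"] * ws$runs$coded_P * ws$runs$coded_R
  set.seed(seed)
  for (cycle in seq_len(n_cycles)) {
    bias <- if (surface$cycle_bias_sd > 0)
      stats::rnorm(1, 0, surface$cycle_bias_sd) else 0
    ws <- attach_cycle(ws, pmax(mu + bias + .surface_noise(surface, mu), 0))
  }
  ws
}

# analytic box-constrained optimum of the polynomial part of a surface
.surface_optimum <- function(surface, bounds) {
  b <- surface$beta
  pick_edge <- function(coefficient, lim)
    if (coefficient > 0) lim[2] else if (coefficient < 0) lim[1] else mean(lim)
  ph <- if (b[5] < 0)
    min(max(-b[4] / (2 * b[5]), bounds$pH[1]), bounds$pH[2])
  else pick_edge(b[4] + b[5] * sum(bounds$pH), bounds$pH)  # monotone side
  opt <- c(temperature_C = pick_edge(b[2], bounds$temperature_C),
           wb_percent = pick_edge(b[3], bounds$wb_percent),
           pH = ph)
  c(opt, activity = unname(predict(surface, opt)))
}

#' Simulate a multi-phase EVOP campaign on a known surface
#'
#' Runs the full EVOP loop: simulate a worksheet at the current centre,
#' analyse it, and apply the decision rule.  On a `"shift"` verdict the
#' centre moves one half-step along each significant main effect and a new
#' phase begins; the campaign stops on `"optimum_reached"`,
#' `"continue_cycles"` (no signal) or the phase limit.
#'
#' @param surface A [true_surface()].
#' @param temperature,pH,wb_percent Starting [evop_factor()]s.
#' @param max_phases Phase limit (>= 1).
#' @param n_cycles Cycles per phase.
#' @param seed Master seed; phase p uses child seed `seed + 1000 * (p - 1)`.
#' @param sd_method,s Passed to [evop_analysis()].
#' @param bounds Named list of `c(low, high)` per axis used only to report
#'   the analytic `true_optimum`; default is the screening box
#'   (26..30, 70..90, 4..8).
#' @return An object of class `evop_campaign`: list with `phases` (each a
#'   list of `factors`, `worksheet`, `analysis`), `final_factors`,
#'   `final_verdict`, `true_optimum`, `n_phases`.
#' @examples
#' surf <- true_surface(c(-1720, 0, 0, 840, -70), noise_sd = 5)
#' camp <- simulate_campaign(surf,
#'   evop_factor("temperature", 28, 2, "degC"),
#'   evop_factor("pH", 4, 1, "pH"),
#'   evop_factor("wb_percent", 80, 10, "%WB"),
#'   max_phases = 6, seed = 7)
#' camp$final_factors$pH$centre
#' @export
simulate_campaign <- function(surface, temperature, pH, wb_percent,
                              max_phases = 5L, n_cycles = 2L, seed = 1L,
                              sd_method = c("range", "pooled", "fixed"),
                              s = NULL, bounds = NULL) {
  stopifnot(inherits(surface, "true_surface"), max_phases >= 1L)
  sd_method <- match.arg(sd_method)
  if (is.null(bounds))
    bounds <- list(temperature_C = c(26, 30), wb_percent = c(70, 90),
                   pH = c(4, 8))
  factors <- list(temperature = temperature, pH = pH, wb_percent = wb_percent)
  phases <- list()
  verdict <- "continue_cycles"
  for (phase in seq_len(max_phases)) {
    ws <- generate_worksheet(surface, factors$temperature, factors$pH,
                             factors$wb_percent, n_cycles = n_cycles,
                             seed = seed + 1000L * (phase - 1L))
    an <- evop_analysis(ws, sd_method = sd_method, s = s)
    phases[[phase]] <- list(factors = factors, worksheet = ws, analysis = an)
    verdict <- an$decision$verdict
    if (verdict != "shift") break
    dir <- an$decision$shift_direction       # named T, P, R
    key <- c(T = "temperature", P = "pH", R = "wb_percent")
    for (f in names(dir)) {
      if (dir[[f]] != 0) {
        fac <- factors[[key[[f]]]]
        fac$centre <- fac$centre + dir[[f]] * fac$half_step
        factors[[key[[f]]]] <- fac
      }
    }
  }
  structure(list(phases = phases, final_factors = factors,
                 final_verdict = verdict,
                 true_optimum = .surface_optimum(surface, bounds),
                 n_phases = length(phases)),
            class = "evop_campaign")
}

#' @export
print.evop_campaign <- function(x, ...) {
  cat(sprintf("EVOP campaign: %d phase(s), final verdict '%s'\n",
              x$n_phases, x$final_verdict))
  for (p in seq_along(x$phases)) {
    f <- x$phases[[p]]$factors
    d <- x$phases[[p]]$analysis$decision
    cat(sprintf("  phase %d: centre (T %g, pH %g, WB %g%%) -> %s\n", p,
                f$temperature$centre, f$pH$centre, f$wb_percent$centre,
                d$verdict))
  }
  f <- x$final_factors
  cat(sprintf("  final centre: T %g degC, pH %g, WB %g%%\n",
              f$temperature$centre, f$pH$centre, f$wb_percent$centre))
  to <- x$true_optimum
  cat(sprintf("  true optimum (box-constrained): T %g, WB %g%%, pH %g -> %.2f U/gds\n",
              to["temperature_C"], to["wb_percent"], to["pH"], to["activity"]))
  invisible(x)
}
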