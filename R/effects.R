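# EVOP phase statistics: per-run averages and differences, main and
# interaction effects of the 2^3 design, change-in-mean, noise estimate and
# error limits, and the shift/stop decision rule.

# Range-method factors f(k, n) from standard EVOP practice, used as
# s = f * range(per-run differences).  Rows: runs per cycle k; columns:
# cycles n = 2..10.
.EVOP_RANGE_F <- rbind(
  `5`  = c(0.30, 0.35, 0.37, 0.38, 0.39, 0.40, 0.40, 0.40, 0.41),
  `10` = c(0.23, 0.26, 0.28, 0.29, 0.30, 0.30, 0.30, 0.31, 0.31)
)
colnames(.EVOP_RANGE_F) <- as.character(2:10)

.check_responses <- function(responses) {
  responses <- as.numeric(responses)
  if (length(responses) != 10L || any(!is.finite(responses)))
    stop("'responses' must be 10 finite values aligned with runs A1..A10")
  responses
}

#' Per-run averages across cycles
#'
#' @param ws An [evop_worksheet()] with at least one cycle.
#' @return Named numeric vector (A1..A10) of arithmetic means across cycles,
#'   at full precision.
#' @export
run_averages <- function(ws) {
  stopifnot(inherits(ws, "evop_worksheet"))
  if (n_cycles(ws) < 1L) stop("worksheet has no cycles")
  colMeans(ws$cycles)
}

#' Per-run differences between two cycles
#'
#' The cycle-to-cycle differences are the raw material for the noise
#' (standard-deviation) estimate.
#'
#' @param ws An [evop_worksheet()].
#' @param i,j Cycle indices; the result is `cycle i - cycle j` per run.
#' @return Named numeric vector (A1..A10).
#' @export
run_differences <- function(ws, i = 1L, j = 2L) {
  stopifnot(inherits(ws, "evop_worksheet"))
  nc <- n_cycles(ws)
  if (i < 1L || i > nc || j < 1L || j > nc)
    stop("cycle indices must be in 1..", nc)
  ws$cycles[i, ] - ws$cycles[j, ]
}

# contrast helper: (sum of responses at sign +1) - (sum at sign -1), over
# the eight corner runs, divided by 4 (= mean(+) - mean(-))
.contrast <- function(responses, signs) {
  corner <- signs != 0L
  sum(responses[corner] * signs[corner]) / 4
}

#' Main effect of one factor
#'
#' The classical two-level factorial contrast: the mean response over the
#' four corner runs at the factor's high level minus the mean over the four
#' at its low level.  Centre runs do not enter.
#'
#' @param responses Numeric vector of 10 responses in run order A1..A10
#'   (a single cycle, or per-run averages).
#' @param ws The [evop_worksheet()] supplying the coding.
#' @param factor One of `"T"` (temperature), `"P"` (pH), `"R"` (WB%).
#' @return The effect, in response units (U/gds).
#' @export
main_effect <- function(responses, ws, factor = c("T", "P", "R")) {
  factor <- match.arg(factor)
  responses <- .check_responses(responses)
  signs <- ws$runs[[paste0("coded_", factor)]]
  .contrast(responses, signs)
}

#' Two-factor interaction effect
#'
#' Contrast on the sign product of two factors' coded levels: mean response
#' where the product is +1 minus mean where it is -1, over the eight corners.
#'
#' @inheritParams main_effect
#' @param pair One of `"TP"`, `"TR"`, `"PR"`.
#' @return The interaction effect in response units.
#' @export
interaction_effect <- function(responses, ws, pair = c("TP", "TR", "PR")) {
  pair <- match.arg(pair)
  responses <- .check_responses(responses)
  a <- ws$runs[[paste0("coded_", substr(pair, 1, 1))]]
  b <- ws$runs[[paste0("coded_", substr(pair, 2, 2))]]
  .contrast(responses, a * b)
}

#' Change-in-mean effect
#'
#' Mean response over all ten runs minus the mean of the two centre runs.
#' A strongly negative value means the current centre outperforms the
#' surrounding factorial corners -- evidence that the centre is (near) a
#' local optimum.
#'
#' @inheritParams main_effect
#' @return The change-in-mean effect in response units.
#' @export
change_in_mean <- function(responses, ws) {
  responses <- .check_responses(responses)
  centre <- ws$runs$coded_T == 0L & ws$runs$coded_P == 0L & ws$runs$coded_R == 0L
  mean(responses) - mean(responses[centre])
}

#' Estimate the run-to-run standard deviation
#'
#' Three estimators are available:
#' \describe{
#'   \item{`"range"`}{the classical EVOP shortcut
#'     `s = f(k, n) * range(per-run differences)` with the standard factor
#'     table for k = 10 runs; differences are taken between the last two
#'     cycles.}
#'   \item{`"pooled"`}{`sqrt(sum(d^2) / (2 k))` over the k = 10 per-run
#'     differences, the paired-replicate pooled estimate.}
#'   \item{`"fixed"`}{returns the supplied constant `s` unchanged, for
#'     reproducing an externally reported noise level.}
#' }
#'
#' @param ws An [evop_worksheet()]; `"range"` and `"pooled"` need >= 2 cycles.
#' @param method One of `"range"`, `"pooled"`, `"fixed"`.
#' @param s Non-negative constant, required for `method = "fixed"`.
#' @return The standard-deviation estimate (>= 0), in response units.
#' @export
estimate_sd <- function(ws, method = c("range", "pooled", "fixed"), s = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(s) || !is.finite(s) || s < 0)
      stop("method 'fixed' needs a non-negative constant 's'")
    return(as.numeric(s))
  }
  stopifnot(inherits(ws, "evop_worksheet"))
  nc <- n_cycles(ws)
  if (nc < 2L)
    stop("data-driven sd estimation needs at least 2 cycles (have ", nc, ")")
  d <- run_differences(ws, nc - 1L, nc)
  if (method == "pooled")
    return(sqrt(sum(d^2) / (2 * length(d))))
  # range method
  f <- .EVOP_RANGE_F["10", as.character(min(nc, 10L))]
  f * (max(d) - min(d))
}

#' Error limits for EVOP effects
#'
#' Half-widths of the approximate two-standard-error bands against which the
#' phase statistics are judged, for k = 10 runs and `n_cycles` completed
#' cycles:
#' \deqn{2s/\sqrt{n}\ \mathrm{(run\ averages)},\quad
#'       2s/\sqrt{2n}\ \mathrm{(effects)},\quad
#'       1.78\,s/\sqrt{2n}\ \mathrm{(change\ in\ mean)}.}
#'
#' @param s Non-negative standard deviation (from [estimate_sd()]).
#' @param n_cycles Number of completed cycles (>= 1).
#' @return An object of class `evop_error_limits`: list with elements
#'   `for_average`, `for_effects`, `for_change_in_mean`.
#' @export
error_limits <- function(s, n_cycles) {
  stopifnot(is.numeric(s), length(s) == 1L, is.finite(s), s >= 0,
            n_cycles >= 1L)
  n <- as.numeric(n_cycles)
  structure(list(for_average        = 2 * s / sqrt(n),
                 for_effects        = 2 * s / sqrt(2 * n),
                 for_change_in_mean = 1.78 * s / sqrt(2 * n)),
            class = "evop_error_limits")
}

#' @export
print.evop_error_limits <- function(x, ...) {
  cat(sprintf("Error limits: average +/- %.2f | effects +/- %.2f | change in mean +/- %.2f\n",
              x$for_average, x$for_effects, x$for_change_in_mean))
  invisible(x)
}

#' EVOP decision rule
#'
#' Compares effect magnitudes to the error limits.  If any of the six
#' effects (three main, three interaction) strictly exceeds the effects
#' limit in magnitude, the verdict is `"shift"`: the operating centre should
#' move one half-step in the direction favoured by each significant main
#' effect.  Otherwise, if the change-in-mean is more negative than its
#' (negated) limit, the centre demonstrably beats its neighbourhood and the
#' verdict is `"optimum_reached"`.  Otherwise more cycles are needed
#' (`"continue_cycles"`).
#'
#' @param effects Named numeric vector with elements `T`, `P`, `R`, `TP`,
#'   `TR`, `PR` (U/gds).
#' @param limits An [error_limits()] object.
#' @param change_in_mean The change-in-mean effect.
#' @return An object of class `evop_decision`: list with `verdict` (one of
#'   `"shift"`, `"optimum_reached"`, `"continue_cycles"`), `shift_direction`
#'   (named -1/0/+1 per factor) and `rationale` (text).
#' @export
evop_decide <- function(effects, limits, change_in_mean) {
  stopifnot(inherits(limits, "evop_error_limits"))
  needed <- c("T", "P", "R", "TP", "TR", "PR")
  if (!all(needed %in% names(effects)))
    stop("'effects' must be named with ", paste(needed, collapse = ", "))
  effects <- effects[needed]
  sig <- abs(effects) > limits$for_effects          # strict inequality
  direction <- c(T = 0, P = 0, R = 0)
  if (any(sig)) {
    main_sig <- sig[c("T", "P", "R")]
    direction[main_sig] <- sign(effects[c("T", "P", "R")][main_sig])
    verdict <- "shift"
    rationale <- paste0(
      "effect(s) ", paste(names(sig)[sig], collapse = ", "),
      " exceed the +/-", round(limits$for_effects, 2),
      " error limit; move the centre one half-step along each significant main effect")
  } else if (change_in_mean < -limits$for_change_in_mean) {
    verdict <- "optimum_reached"
    rationale <- paste0(
      "no effect exceeds its error limit and the change-in-mean (",
      round(change_in_mean, 2), ") is below -", round(limits$for_change_in_mean, 2),
      ": the centre outperforms its neighbourhood")
    } else {
    verdict <- "continue_cycles"
    rationale <- "no effect is distinguishable from noise yet; run another cycle"
  }
  structure(list(verdict = verdict, shift_direction = direction,
                 rationale = rationale),
            class = "evop_decision")
}

#' @export
print.evop_decision <- function(x, ...) {
  cat("EVOP decision:", x$verdict, "\n")
  if (x$verdict == "shift") {
    dir <- x$shift_direction[x$shift_direction != 0]
    cat("  shift:", paste(names(dir), ifelse(dir > 0, "+", "-"), collapse = ", "), "\n")
  }
  cat(" ", x$rationale, "\n")
  invisible(x)
}

#' Analyse one EVOP phase
#'
#' The one-stop fitting function for a worksheet: computes per-run averages
#' and cycle differences, the six factorial effects and the change-in-mean
#' (on a chosen response vector), estimates the noise level, derives the
#' error limits and applies the decision rule.
#'
#' @param ws An [evop_worksheet()] with at least one cycle.
#' @param cycle Which responses to analyse: a cycle index, or `NULL`
#'   (default) for the per-run averages across all cycles.
#' @param sd_method,s Passed to [estimate_sd()].  With a single cycle only
#'   `sd_method = "fixed"` is possible.
#' @return An object of class `evop_analysis`: list with `averages`,
#'   `differences` (last two cycles, or `NULL`), `effects` (named vector),
#'   `change_in_mean`, `s`, `limits`, `decision`, `n_cycles`, `responses`
#'   (the vector analysed) and `ws`.
#' @examples
#' ws <- protease_worksheet()
#' fit <- evop_analysis(ws, sd_method = "fixed", s = 100.65)
#' summary(fit)
#' @export
evop_analysis <- function(ws, cycle = NULL,
                          sd_method = c("range", "pooled", "fixed"), s = NULL) {
  stopifnot(inherits(ws, "evop_worksheet"))
  sd_method <- match.arg(sd_method)
  nc <- n_cycles(ws)
  if (nc < 1L) stop("worksheet has no cycles")
  responses <- if (is.null(cycle)) run_averages(ws) else {
    stopifnot(cycle >= 1L, cycle <= nc)
    ws$cycles[cycle, ]
  }
  effects <- c(T  = main_effect(responses, ws, "T"),
               P  = main_effect(responses, ws, "P"),
               R  = main_effect(responses, ws, "R"),
               TP = interaction_effect(responses, ws, "TP"),
               TR = interaction_effect(responses, ws, "TR"),
               PR = interaction_effect(responses, ws, "PR"))
  cim <- change_in_mean(responses, ws)
  s_hat <- estimate_sd(ws, sd_method, s)
  limits <- error_limits(s_hat, nc)
  structure(list(averages = run_averages(ws),
                 differences = if (nc >= 2L) run_differences(ws, nc - 1L, nc),
                 effects = effects,
                 change_in_mean = cim,
                 s = s_hat,
                 limits = limits,
                 decision = evop_decide(effects, limits, cim),
                 n_cycles = nc,
                 responses = responses,
                 ws = ws),
            class = "evop_analysis")
}

#' @export
print.evop_analysis <- function(x, ...) {
  cat(sprintf("EVOP phase analysis (%d cycle%s, s = %.2f)\n",
              x$n_cycles, if (x$n_cycles == 1L) "" else "s", x$s))
  eff <- round(x$effects, 2)
  cat("  effects (U/gds):",
      paste(sprintf("%s %.2f", names(eff), eff), collapse = " | "), "\n")
  cat(sprintf("  change in mean: %.2f\n", x$change_in_mean))
  print(x$limits)
  print(x$decision)
  invisible(x)
}

#' @export
summary.evop_analysis <- function(object, ...) {
  cat("Run averages (U/gds):\n")
  print(round(object$averages, 2))
  if (!is.null(object$differences)) {
    cat("Differences, last two cycles:\n")
    print(round(object$differences, 2))
  }
  print(object)
  invisible(object)
}

#' @export
coef.evop_analysis <- function(object, ...) object$effects

#' Plot EVOP effects against their error limits
#'
#' @param x An [evop_analysis()] object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.evop_analysis <- function(x, ...) {
  lim <- x$limits$for_effects
  bp <- graphics::barplot(x$effects, ylab = "effect (U/gds)",
                          main = "EVOP effects vs error limits",
                          ylim = range(c(x$effects, lim, -lim)) * 1.1, ...)
  graphics::abline(h = c(-lim, lim), lty = 2)
  invisible(bp)
}
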