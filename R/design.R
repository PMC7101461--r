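# Three-variable EVOP worksheet: coded 2^3 design plus duplicated centre runs.

# Fixed run coding, rows A1..A10, columns (T, P, R) = temperature, pH, WB%.
.EVOP_CODING <- matrix(
  c( 0L,  0L,  0L,   # A1 centre
    -1L, -1L, -1L,   # A2
    -1L, +1L, +1L,   # A3
    +1L, -1L, +1L,   # A4
    +1L, +1L, -1L,   # A5
     0L,  0L,  0L,   # A6 centre
    +1L, +1L, +1L,   # A7
    -1L, -1L, +1L,   # A8
    +1L, -1L, -1L,   # A9
    -1L, +1L, -1L),  # A10
  ncol = 3L, byrow = TRUE,
  dimnames = list(paste0("A", 1:10), c("T", "P", "R"))
)

.RUN_IDS <- paste0("A", 1:10)

#' Define a controllable EVOP factor
#'
#' A factor is described by its current operating centre and the half-step
#' (the "plus/minus" amplitude) used to place the low and high search levels
#' at `centre - half_step` and `centre + half_step`.
#'
#' @param name Short label, e.g. `"temperature"`.
#' @param centre Numeric centre (current best operating value), in `units`.
#' @param half_step Positive numeric search amplitude.
#' @param units Unit label used in printing (e.g. `"degC"`, `"pH"`, `"%WB"`).
#' @return An object of class `evop_factor`.
#' @examples
#' evop_factor("temperature", 28, 2, "degC")
#' @export
evop_factor <- function(name, centre, half_step, units = "") {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(centre), length(centre) == 1L, is.finite(centre),
            is.numeric(half_step), length(half_step) == 1L, is.finite(half_step))
  if (half_step <= 0)
    stop("'half_step' must be strictly positive (got ", half_step, ")")
  structure(list(name = name, units = units,
                 centre = as.numeric(centre),
                 half_step = as.numeric(half_step)),
            class = "evop_factor")
}

#' @export
print.evop_factor <- function(x, ...) {
  cat(sprintf("EVOP factor %s: %g +/- %g %s  [low %g, high %g]\n",
              x$name, x$centre, x$half_step, x$units,
              x$centre - x$half_step, x$centre + x$half_step))
  invisible(x)
}

# coded level in {-1, 0, +1} -> actual value in factor units
.coded_to_actual <- function(factor, coded) factor$centre + coded * factor$half_step

#' Build the three-variable EVOP worksheet
#'
#' Lays out the ten experimental runs of one EVOP phase: the duplicated
#' centre point (runs A1 and A6) and the eight corners of the full 2^3
#' factorial in temperature, pH and wheat-bran percentage, in the fixed run
#' order A1..A10.  The worksheet starts with no response cycles; append
#' measured responses with [attach_cycle()].
#'
#' @param temperature,pH,wb_percent [evop_factor()] objects for the
#'   incubation temperature (deg C), initial medium pH, and wheat-bran share
#'   of the wheat bran + soybean meal substrate mix (percent by mass).
#' @return An object of class `evop_worksheet` with components `factors`
#'   (named list of the three factors), `runs` (data frame of run id, coded
#'   levels and actual conditions) and `cycles` (numeric matrix, one row per
#'   completed cycle, one column per run).
#' @examples
#' ws <- evop_worksheet(evop_factor("temperature", 28, 2, "degC"),
#'                      evop_factor("pH", 6, 2, "pH"),
#'                      evop_factor("wb_percent", 80, 10, "%WB"))
#' ws$runs
#' @seealso [attach_cycle()], [evop_analysis()], [read_worksheet()]
#' @export
evop_worksheet <- function(temperature, pH, wb_percent) {
  factors <- list(temperature = temperature, pH = pH, wb_percent = wb_percent)
  for (f in factors)
    if (!inherits(f, "evop_factor"))
      stop("all three factors must be 'evop_factor' objects")
  runs <- data.frame(
    run_id = .RUN_IDS,
    coded_T = .EVOP_CODING[, "T"],
    coded_P = .EVOP_CODING[, "P"],
    coded_R = .EVOP_CODING[, "R"],
    temperature_C = .coded_to_actual(temperature, .EVOP_CODING[, "T"]),
    pH            = .coded_to_actual(pH,          .EVOP_CODING[, "P"]),
    wb_percent    = .coded_to_actual(wb_percent,  .EVOP_CODING[, "R"]),
    stringsAsFactors = FALSE
  )
  rownames(runs) <- NULL
  cycles <- matrix(numeric(0), nrow = 0L, ncol = 10L,
                   dimnames = list(NULL, .RUN_IDS))
  structure(list(factors = factors, runs = runs, cycles = cycles),
            class = "evop_worksheet")
}

#' Append one cycle of measured responses to a worksheet
#'
#' A cycle is one complete replicate of all ten runs.  Responses are enzyme
#' activities in U/gds, given in run order A1..A10.
#'
#' @param ws An `evop_worksheet`.
#' @param responses Numeric vector of exactly 10 finite, non-negative values.
#' @return The worksheet with the cycle appended; earlier cycles unchanged.
#' @export
attach_cycle <- function(ws, responses) {
  stopifnot(inherits(ws, "evop_worksheet"))
  responses <- as.numeric(responses)
  if (length(responses) != 10L)
    stop("a cycle must contain exactly 10 responses (got ",
         length(responses), ")")
  if (any(!is.finite(responses)))
    stop("responses must all be finite")
  if (any(responses < 0))
    stop("responses must be non-negative (activity in U/gds)")
  ws$cycles <- rbind(ws$cycles, responses)
  rownames(ws$cycles) <- paste0("cycle", seq_len(nrow(ws$cycles)))
  ws
}

#' Number of completed cycles in a worksheet
#' @param ws An `evop_worksheet`.
#' @return Integer cycle count.
#' @export
n_cycles <- function(ws) {
  stopifnot(inherits(ws, "evop_worksheet"))
  nrow(ws$cycles)
}

#' Convert a wheat-bran : soybean-meal mass ratio to percent wheat bran
#'
#' The substrate mix is specified either as grams of each component (e.g.
#' 4 g WB + 1 g SM) or as the wheat-bran share of the total; this is the
#' bridge between the two notations.
#'
#' @param wb_grams,sm_grams Non-negative masses with positive total.
#' @return `100 * wb_grams / (wb_grams + sm_grams)`.
#' @examples
#' ratio_to_percent(4, 1)      # 80
#' ratio_to_percent(4.5, 0.5)  # 90
#' @export
ratio_to_percent <- function(wb_grams, sm_grams) {
  stopifnot(is.numeric(wb_grams), is.numeric(sm_grams))
  if (any(wb_grams < 0) || any(sm_grams < 0))
    stop("masses must be non-negative")
  total <- wb_grams + sm_grams
  if (any(total <= 0))
    stop("total substrate mass must be positive")
  100 * wb_grams / total
}

#' @export
print.evop_worksheet <- function(x, ...) {
  cat("EVOP worksheet (2^3 factorial + duplicated centre)\n")
  for (f in x$factors)
    cat(sprintf("  %-12s %g +/- %g %s\n", f$name, f$centre, f$half_step, f$units))
  cat(sprintf("  cycles completed: %d\n", n_cycles(x)))
  print(as.data.frame(x), digits = 6)
  invisible(x)
}

#' @export
as.data.frame.evop_worksheet <- function(x, ...) {
  df <- x$runs[, c("run_id", "temperature_C", "pH", "wb_percent")]
  if (n_cycles(x) > 0) {
    resp <- t(x$cycles)
    colnames(resp) <- paste0("cycle", seq_len(ncol(resp)))
    df <- cbind(df, as.data.frame(resp))
    rownames(df) <- NULL
  }
  df
}
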