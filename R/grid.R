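# Constrained lattice enumeration and exhaustive surrogate optimization.
# The iteration index runs pH outermost, temperature in the middle and
# wheat-bran percentage innermost:
#   iteration = i_pH * (nT * nWB) + i_T * nWB + i_WB + 1   (0-based indices)

#' Define the constrained search grid
#'
#' Each axis is a regular lattice `low, low + step, ..., <= high` (values
#' rounded to 10 decimals so axis membership is bit-stable).  The default
#' box is the screening search region: temperature 26..30 degC in steps of
#' 1, wheat-bran percentage 70..90 in steps of 2.5, pH 4..8 in steps of 0.1
#' (41 x 5 x 9 = 1845 points).
#'
#' @param temperature,wb_percent,pH Numeric `c(low, high, step)` per axis.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec()                     # the default 1845-point grid
#' grid_spec(pH = c(4, 8, 0.2))    # coarser pH lattice
#' @export
grid_spec <- function(temperature = c(26, 30, 1),
                      wb_percent = c(70, 90, 2.5),
                      pH = c(4, 8, 0.1)) {
  axes <- list(temperature_C = temperature, wb_percent = wb_percent, pH = pH)
  values <- lapply(names(axes), function(nm) {
    ax <- axes[[nm]]
    if (length(ax) != 3L || any(!is.finite(ax)))
      stop("axis '", nm, "' must be c(low, high, step)")
    if (ax[3] <= 0) stop("axis '", nm, "' has non-positive step")
    if (ax[1] > ax[2]) stop("axis '", nm, "' has low > high")
    n <- floor((ax[2] - ax[1]) / ax[3] + 1e-9) + 1L
    round(ax[1] + (seq_len(n) - 1L) * ax[3], 10L)
  })
  names(values) <- names(axes)
  structure(list(axes = axes, values = values,
                 counts = vapply(values, length, integer(1))),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("Search grid (", prod(x$counts), " points):\n", sep = "")
  for (nm in names(x$axes))
    cat(sprintf("  %-13s %g..%g step %g (%d values)\n", nm,
                x$axes[[nm]][1], x$axes[[nm]][2], x$axes[[nm]][3],
                x$counts[[nm]]))
  invisible(x)
}

#' Enumerate the grid in iteration order
#'
#' @param g A [grid_spec()].
#' @return Data frame with columns `iteration` (1-based), `temperature_C`,
#'   `wb_percent`, `pH`; row r holds iteration r.  The mapping is a
#'   bijection onto `1..prod(counts)` with pH varying slowest and WB%
#'   fastest.
#' @examples
#' g <- enumerate_grid(grid_spec())
#' g[g$iteration == 1027, ]   # T 30, WB 70, pH 6.2
#' @export
enumerate_grid <- function(g) {
  stopifnot(inherits(g, "grid_spec"))
  # expand.grid varies its first argument fastest
  pts <- expand.grid(wb_percent = g$values$wb_percent,
                     temperature_C = g$values$temperature_C,
                     pH = g$values$pH,
                     KEEP.OUT.ATTRS = FALSE)
  data.frame(iteration = seq_len(nrow(pts)),
             temperature_C = pts$temperature_C,
             wb_percent = pts$wb_percent,
             pH = pts$pH)
}

#' Exhaustively optimize a surrogate over the grid
#'
#' Evaluates the surrogate at every lattice point and locates the maximum
#' predicted activity.  Ties are broken toward the lowest iteration number.
#' The reported `window` is the ten-iteration decade block
#' (`10m+1 .. 10m+10`) containing the argmax, the conventional zoomed-in
#' view of the region of maximum response.
#'
#' @param model A fitted surrogate with a [predict()] method accepting a
#'   data frame of `temperature_C`, `wb_percent`, `pH` (e.g. [mfnn()],
#'   [fit_quadratic_surface()], [reference_surface()], [true_surface()]),
#'   or a function of such a data frame returning predictions.
#' @param grid A [grid_spec()]; default is the screening region.
#' @return An object of class `grid_result`: list with `points` (the grid
#'   plus a `predicted` column), `argmax` (its best row), `window`
#'   (data frame, see above) and `grid`.
#' @examples
#' res <- grid_optimize(reference_surface())
#' res$argmax
#' @export
grid_optimize <- function(model, grid = grid_spec()) {
  pts <- enumerate_grid(grid)
  pred <- if (is.function(model)) model(pts) else
    suppressWarnings(predict(model, pts))
  pred <- as.numeric(pred)
  stopifnot(length(pred) == nrow(pts))
  if (any(!is.finite(pred))) {
    bad <- pts[which(!is.finite(pred))[1L], ]
    stop(sprintf("non-finite prediction at iteration %d (T %g, WB%% %g, pH %g)",
                 bad$iteration, bad$temperature_C, bad$wb_percent, bad$pH))
  }
  pts$predicted <- pred
  best <- which.max(pred)                 # first maximum = lowest iteration
  win_start <- ((best - 1L) %/% 10L) * 10L + 1L
  win <- pts[win_start:min(win_start + 9L, nrow(pts)), ]
  rownames(win) <- NULL
  structure(list(points = pts, argmax = pts[best, ], window = win,
                 grid = grid),
            class = "grid_result")
}

#' Tabulate the window around the grid maximum
#'
#' @param res A [grid_optimize()] result.
#' @return Data frame with columns `iteration`, `temperature_C`,
#'   `wb_percent`, `pH`, `predicted` for the decade block containing the
#'   argmax.
#' @export
top_window_table <- function(res) {
  stopifnot(inherits(res, "grid_result"))
  res$window
}

#' @export
print.grid_result <- function(x, ...) {
  a <- x$argmax
  cat(sprintf("Grid optimization over %d points\n", nrow(x$points)))
  cat(sprintf("  maximum predicted activity %.2f U/gds at iteration %d:\n",
              a$predicted, a$iteration))
  cat(sprintf("  temperature %g degC, WB %g%%, pH %g\n",
              a$temperature_C, a$wb_percent, a$pH))
  cat("  window around the maximum:\n")
  print(x$window, digits = 6, row.names = FALSE)
  invisible(x)
}

#' Plot the predicted response along the iteration index
#'
#' @param x A [grid_optimize()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.grid_result <- function(x, ...) {
  graphics::plot(x$points$iteration, x$points$predicted, type = "l",
                 xlab = "iteration", ylab = "predicted activity (U/gds)",
                 main = "Surrogate response over the search grid", ...)
  graphics::points(x$argmax$iteration, x$argmax$predicted, pch = 19,
                   col = "red")
  invisible(x)
}
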