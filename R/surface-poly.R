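# Quadratic-in-pH polynomial response surface:
#   activity = b0 + b1*temperature + b2*wb_percent + b3*pH + b4*pH^2
# fitted by ordinary least squares, plus the fixed reference coefficient set
# shipped with the package.

.POLY_TERMS <- c("(Intercept)", "temperature_C", "wb_percent", "pH", "I(pH^2)")

.as_surface_poly <- function(beta, fit = NULL, data = NULL) {
  beta <- as.numeric(beta)
  stopifnot(length(beta) == 5L, all(is.finite(beta)))
  names(beta) <- c("beta0", "beta1", "beta2", "beta3", "beta4")
  structure(list(beta = beta, fit = fit, data = data),
            class = "surface_poly")
}

#' Fit the quadratic-in-pH response surface by least squares
#'
#' Fits `activity ~ temperature_C + wb_percent + pH + I(pH^2)` by OLS.  The
#' surface is linear in temperature and wheat-bran percentage and quadratic
#' in pH, so (for a negative curvature coefficient) it has an interior
#' stationary pH but attains its temperature/WB optimum on the boundary of
#' any box constraint.
#'
#' @param data Data frame with numeric columns `temperature_C`,
#'   `wb_percent`, `pH`, `activity` (at least 5 rows).  Duplicated design
#'   points with distinct responses are allowed.
#' @return An object of class `surface_poly` with coefficients `beta0..beta4`;
#'   supports [coef()], [predict()], [residuals()], [fitted()] and
#'   [stationary_ph()].
#' @examples
#' fit <- fit_quadratic_surface(protease_training())
#' coef(fit)
#' @export
fit_quadratic_surface <- function(data) {
  data <- validate_dataset(data)
  if (nrow(data) < 5L)
    stop("need at least 5 records to fit 5 coefficients (got ", nrow(data), ")")
  mm <- stats::model.matrix(~ temperature_C + wb_percent + pH + I(pH^2), data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(activity ~ temperature_C + wb_percent + pH + I(pH^2),
                   data = data)
  .as_surface_poly(stats::coef(fit)[.POLY_TERMS], fit = fit, data = data)
}

#' The reference polynomial surface for the protease screening data
#'
#' The fixed coefficient set
#' `(-2299.6275, 7.896875, -0.591625, 839.270625, -69.7646875)` that ships
#' with the package as the reference regression for the packaged
#' alkaline-protease screening dataset (see [protease_training()]).  Note it
#' is kept distinct from [fit_quadratic_surface()] refits of that dataset:
#' an OLS refit differs slightly (the reference residuals do not sum to
#' zero), so both surfaces are exposed.
#'
#' @return A `surface_poly` object.
#' @examples
#' predict(reference_surface(), data.frame(temperature_C = 28,
#'                                         wb_percent = 80, pH = 6))
#' @export
reference_surface <- function() {
  .as_surface_poly(c(-2299.6275, 7.896875, -0.591625, 839.270625, -69.7646875))
}

#' @export
coef.surface_poly <- function(object, ...) object$beta

#' Predict activity from a polynomial surface
#'
#' @param object A `surface_poly`.
#' @param newdata Data frame with columns `temperature_C`, `wb_percent`,
#'   `pH`, or a numeric vector/matrix of the three inputs in that order.
#' @param ... Unused.
#' @return Numeric vector of predicted activities (U/gds).
#' @export
predict.surface_poly <- function(object, newdata, ...) {
  x <- .input_matrix(newdata)
  b <- unname(object$beta)
  drop(b[1] + b[2] * x[, 1] + b[3] * x[, 2] + b[4] * x[, 3] + b[5] * x[, 3]^2)
}

#' @export
fitted.surface_poly <- function(object, ...) {
  if (is.null(object$data)) stop("surface carries no training data")
  predict(object, object$data)
}

#' @export
residuals.surface_poly <- function(object, ...) {
  if (is.null(object$data)) stop("surface carries no training data")
  object$data$activity - fitted(object)
}

#' Stationary pH of a polynomial surface
#'
#' The pH at which the quadratic term's derivative vanishes,
#' `-beta3 / (2 beta4)`; a maximum when `beta4 < 0`.
#'
#' @param object A `surface_poly`.
#' @return The stationary pH (may lie outside any constraint box).
#' @export
stationary_ph <- function(object) {
  stopifnot(inherits(object, "surface_poly"))
  b <- object$beta
  if (b[5] == 0) stop("surface has no pH curvature (beta4 = 0)")
  unname(-b[4] / (2 * b[5]))
}

#' @export
print.surface_poly <- function(x, ...) {
  b <- x$beta
  cat("Polynomial response surface (U/gds):\n")
  cat(sprintf("  activity = %.4f + %.6f*T + %.6f*WB%% + %.6f*pH + %.7f*pH^2\n",
              b[1], b[2], b[3], b[4], b[5]))
  if (b[5] < 0)
    cat(sprintf("  stationary pH: %.3f\n", stationary_ph(x)))
  if (!is.null(x$data))
    cat(sprintf("  fitted to %d records, residual SD %.3f\n",
                nrow(x$data), stats::sd(residuals(x))))
  invisible(x)
}

# coerce predict() inputs to a 3-column matrix (T, WB%, pH)
.input_matrix <- function(newdata) {
  if (is.data.frame(newdata)) {
    need <- c("temperature_C", "wb_percent", "pH")
    miss <- setdiff(need, names(newdata))
    if (length(miss))
      stop("newdata lacks column(s): ", paste(miss, collapse = ", "))
    x <- as.matrix(newdata[, need])
  } else if (is.matrix(newdata)) {
    stopifnot(ncol(newdata) == 3L)
    x <- newdata
  } else {
    stopifnot(is.numeric(newdata), length(newdata) == 3L)
    x <- matrix(newdata, nrow = 1L)
  }
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("inputs must be finite")
  x
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`.  Returns `NA` with a warning when the
#' observations have zero variance (the ratio is undefined).
#'
#' @param predictions,observations Equal-length numeric vectors (>= 2).
#' @return A single number (1 for a perfect fit), or `NA`.
#' @export
r_squared <- function(predictions, observations) {
  stopifnot(length(predictions) == length(observations),
            length(observations) >= 2L)
  ss_tot <- sum((observations - mean(observations))^2)
  if (ss_tot == 0) {
    warning("observations have zero variance; R^2 undefined")
    return(NA_real_)
  }
  1 - sum((observations - predictions)^2) / ss_tot
}
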