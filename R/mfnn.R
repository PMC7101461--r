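# 3-10-1 multilayer feed-forward regression network trained by
# Levenberg-Marquardt with seeded random restarts.
#
# Parameter vector layout (p = hidden*(3+1) + hidden + 1):
#   W1 (hidden x 3, column-major), b1 (hidden), w2 (hidden), b2 (1).

.sigmoid <- function(z) 1 / (1 + exp(-z))

.mfnn_unpack <- function(theta, hidden) {
  i <- hidden * 3L
  list(W1 = matrix(theta[seq_len(i)], nrow = hidden),
       b1 = theta[i + seq_len(hidden)],
       w2 = theta[i + hidden + seq_len(hidden)],
       b2 = theta[i + 2L * hidden + 1L])
}

# forward pass on normalized inputs; Xn is n x 3
.mfnn_forward <- function(theta, Xn, hidden) {
  w <- .mfnn_unpack(theta, hidden)
  H <- .sigmoid(sweep(Xn %*% t(w$W1), 2L, w$b1, `+`))   # n x hidden
  list(yhat = drop(H %*% w$w2 + w$b2), H = H, w = w)
}

# Jacobian of the network output wrt theta, via backpropagation; n x p
.mfnn_jacobian <- function(theta, Xn, hidden) {
  fwd <- .mfnn_forward(theta, Xn, hidden)
  H <- fwd$H
  Hd <- H * (1 - H)                                      # sigmoid'
  S <- sweep(Hd, 2L, fwd$w$w2, `*`)                      # dy/db1, n x hidden
  J_W1 <- do.call(cbind, lapply(1:3, function(k) S * Xn[, k]))
  cbind(J_W1, S, H, 1)
}

# min-max map to [-1, 1]; constant columns map to 0
.norm_fit <- function(x) {
  lo <- apply(x, 2L, min); hi <- apply(x, 2L, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, hi = hi, span = span)
}
.norm_apply <- function(x, nm) sweep(sweep(x, 2L, nm$lo), 2L, nm$span, `/`) * 2 - 1
.norm_undo_y <- function(yn, nm) (yn + 1) / 2 * nm$span + nm$lo

# One Levenberg-Marquardt run.  Damping lambda is divided by 10 on an
# accepted step and multiplied by 10 on a rejected one; stops on small
# gradient, small MSE, lambda blow-up or the epoch cap.  When a validation
# set is supplied the run additionally early-stops after `max_fail`
# consecutive epochs of rising validation error and returns the weights at
# the validation minimum.
.lm_train <- function(theta, Xn, tn, hidden, epochs = 1000L,
                      lambda0 = 1e-3, grad_tol = 1e-7, mse_tol = 1e-10,
                      lambda_max = 1e10, Xn_val = NULL, tn_val = NULL,
                      max_fail = 6L) {
  p <- length(theta)
  n <- length(tn)
  r <- .mfnn_forward(theta, Xn, hidden)$yhat - tn
  sse <- sum(r^2)
  if (!is.finite(sse)) return(NULL)                      # doomed start
  validate <- !is.null(Xn_val)
  val_sse <- function(th)
    sum((.mfnn_forward(th, Xn_val, hidden)$yhat - tn_val)^2)
  if (validate) {
    best_val <- val_sse(theta)
    best_theta <- theta
    best_mse <- sse / n
    n_fail <- 0L
  }
  lambda <- lambda0
  mse_path <- sse / n
  for (epoch in seq_len(epochs)) {
    J <- .mfnn_jacobian(theta, Xn, hidden)
    g <- drop(crossprod(J, r))
    if (max(abs(g)) < grad_tol) break
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (lambda <= lambda_max) {
      delta <- tryCatch(solve(JtJ + diag(lambda, p), g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        theta_new <- theta - delta
        r_new <- .mfnn_forward(theta_new, Xn, hidden)$yhat - tn
        sse_new <- sum(r_new^2)
        if (is.finite(sse_new) && sse_new < sse) {
          theta <- theta_new; r <- r_new; sse <- sse_new
          lambda <- lambda / 10
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) break                                 # lambda exhausted
    mse_path <- c(mse_path, sse / n)
    if (validate) {
      v <- val_sse(theta)
      if (v < best_val) {
        best_val <- v; best_theta <- theta; best_mse <- sse / n
        n_fail <- 0L
      } else {
        n_fail <- n_fail + 1L
        if (n_fail >= max_fail) break
      }
    }
    if (sse / n < mse_tol) break
  }
  if (validate)
    return(list(theta = best_theta, mse = best_mse, mse_path = mse_path))
  list(theta = theta, mse = sse / n, mse_path = mse_path)
}

#' Train the 3-10-1 feed-forward surrogate by Levenberg-Marquardt
#'
#' Fits a fully connected single-hidden-layer regression network (sigmoid
#' hidden units, linear output) to the screening data.  Inputs and target
#' are min-max scaled to \[-1, 1\]; training minimizes the mean squared
#' error by damped Gauss-Newton (Levenberg-Marquardt) steps with the
#' Jacobian obtained by backpropagation.  Training is repeated from
#' `restarts` seeded random initializations (weights uniform in
#' \[-0.5, 0.5\], restart r seeded with `seed + r`) and the restart with the
#' best overall R-squared on the full dataset is kept, so results are fully
#' deterministic given `seed`.
#'
#' @param data Data frame with columns `temperature_C`, `wb_percent`, `pH`,
#'   `activity` (>= 2 rows).
#' @param hidden Number of hidden neurons (default 10).
#' @param restarts Number of random restarts (default 64).
#' @param seed Integer seed controlling all randomness.
#' @param epochs Maximum Levenberg-Marquardt iterations per restart.
#' @param split `"none"` (default) trains on all records to convergence;
#'   `"holdout"` sets aside one validation and one test record at random
#'   (seeded), early-stops each restart once the validation error has risen
#'   for 6 consecutive accepted steps (keeping the weights at the
#'   validation minimum), and reports the held-out errors.  With a dataset
#'   this small the holdout policy is the regularized variant: early
#'   stopping keeps the 51-parameter network from interpolating all
#'   records, at the price of a seed-dependent split.
#' @param lambda0 Initial damping (default 1e-3; factor-10 schedule).
#' @return An object of class `mfnn`: weights, normalization ranges, the
#'   training `data`, and `report` (list with `r2_overall`, and for
#'   `"holdout"` also `r2_train`, `r2_validation`, `r2_test`; plus
#'   `restart`, `mse`, `mse_path`, `n_failed`).  Supports [predict()],
#'   [residuals()], [fitted()], [coef()], [print()] and [summary()].
#' @examples
#' \donttest{
#' net <- mfnn(protease_training(), restarts = 8, seed = 1)
#' net$report$r2_overall
#' }
#' @export
mfnn <- function(data, hidden = 10L, restarts = 64L, seed = 1L,
                 epochs = 1000L, split = c("none", "holdout"),
                 lambda0 = 1e-3) {
  split <- match.arg(split)
  data <- validate_dataset(data)
  if (nrow(data) < 2L) stop("need at least 2 records")
  stopifnot(restarts >= 1L, hidden >= 1L)
  X <- as.matrix(data[, c("temperature_C", "wb_percent", "pH")])
  y <- data$activity
  nm_x <- .norm_fit(X)
  nm_y <- .norm_fit(matrix(y, ncol = 1L))
  Xn_all <- .norm_apply(X, nm_x)
  tn_all <- drop(.norm_apply(matrix(y, ncol = 1L), nm_y))

  idx_train <- seq_len(nrow(data))
  idx_val <- idx_test <- integer(0)
  if (split == "holdout") {
    if (nrow(data) < 4L) stop("holdout split needs at least 4 records")
    set.seed(seed)
    perm <- sample.int(nrow(data))
    idx_val <- perm[1L]
    idx_test <- perm[2L]
    idx_train <- perm[-(1:2)]
  }

  p <- hidden * 5L + 1L
  best <- NULL
  n_failed <- 0L
  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    theta0 <- stats::runif(p, -0.5, 0.5)
    run <- .lm_train(theta0, Xn_all[idx_train, , drop = FALSE],
                     tn_all[idx_train], hidden, epochs = epochs,
                     lambda0 = lambda0,
                     Xn_val = if (split == "holdout")
                       Xn_all[idx_val, , drop = FALSE],
                     tn_val = if (split == "holdout") tn_all[idx_val])
    if (is.null(run)) { n_failed <- n_failed + 1L; next }
    r2 <- r_squared(.norm_undo_y(.mfnn_forward(run$theta, Xn_all, hidden)$yhat,
                                 nm_y), y)
    if (is.null(best) || (is.finite(r2) && r2 > best$r2)) {
      best <- list(theta = run$theta, r2 = r2, mse = run$mse,
                   mse_path = run$mse_path, restart = r)
    }
  }
  if (is.null(best))
    stop("all ", restarts, " restarts failed with non-finite loss")

  object <- structure(
    c(.mfnn_unpack(best$theta, hidden),
      list(hidden = hidden, theta = best$theta,
           norm = list(x = nm_x, y = nm_y), data = data,
           report = list(r2_overall = best$r2, restart = best$restart,
                         mse = best$mse, mse_path = best$mse_path,
                         n_failed = n_failed),
           seed = seed, restarts = restarts, split = split)),
    class = "mfnn")
  if (split == "holdout") {
    pred <- predict(object, data)
    object$report$r2_train <- r_squared(pred[idx_train], y[idx_train])
    # single held-out points: report squared error instead of an undefined
    # one-point R^2
    object$report$r2_validation <- if (length(idx_val) >= 2L)
      r_squared(pred[idx_val], y[idx_val]) else NA_real_
    object$report$r2_test <- if (length(idx_test) >= 2L)
      r_squared(pred[idx_test], y[idx_test]) else NA_real_
    object$report$holdout_sq_err <- c(validation = (pred[idx_val] - y[idx_val])^2,
                                      test = (pred[idx_test] - y[idx_test])^2)
    object$report$split_indices <- list(train = idx_train, validation = idx_val,
                                        test = idx_test)
  }
  object
}

#' Predict activity from a trained network
#'
#' Deterministic forward pass; inputs outside the training range are allowed
#' (the surrogate extrapolates) but flagged with a warning.
#'
#' @param object An [mfnn()] model.
#' @param newdata Data frame with columns `temperature_C`, `wb_percent`,
#'   `pH`, or a numeric vector/matrix of the three inputs in that order.
#' @param ... Unused.
#' @return Numeric vector of predicted activities (U/gds).
#' @export
predict.mfnn <- function(object, newdata, ...) {
  x <- .input_matrix(newdata)
  nm <- object$norm$x
  if (any(sweep(x, 2L, nm$lo, `<`)) || any(sweep(x, 2L, nm$hi, `>`)))
    warning("some inputs lie outside the training range; extrapolating")
  yn <- .mfnn_forward(object$theta, .norm_apply(x, nm), object$hidden)$yhat
  .norm_undo_y(yn, object$norm$y)
}

#' @export
fitted.mfnn <- function(object, ...) predict(object, object$data)

#' @export
residuals.mfnn <- function(object, ...) object$data$activity - fitted(object)

#' @export
coef.mfnn <- function(object, ...) object$theta

#' @export
print.mfnn <- function(x, ...) {
  cat(sprintf("Feed-forward surrogate 3-%d-1 (sigmoid hidden, linear output)\n",
              x$hidden))
  cat(sprintf("  trained by Levenberg-Marquardt, best of %d restarts (restart %d, seed %d)\n",
              x$restarts, x$report$restart, x$seed))
  cat(sprintf("  overall R^2 = %.5f, training MSE (normalized) = %.3g\n",
              x$report$r2_overall, x$report$mse))
  invisible(x)
}

#' @export
summary.mfnn <- function(object, ...) {
  print(object)
  cat(sprintf("  records: %d | parameters: %d | accepted LM steps: %d | failed restarts: %d\n",
              nrow(object$data), length(object$theta),
              length(object$report$mse_path) - 1L, object$report$n_failed))
  if (object$split == "holdout")
    cat(sprintf("  holdout: train R^2 %.5f, held-out squared errors %s\n",
                object$report$r2_train,
                paste(signif(object$report$holdout_sq_err, 4), collapse = ", ")))
  invisible(object)
}
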