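# In-code copies of the printed screening data, independent of the packaged
# CSV fixtures (so reader round-trips are checked against a second source).

phase1_cycle1 <- c(406.17, 158.97, 48.63, 88.80, 153.34,
                   412.79, 189.32, 107.69, 110.26, 99.30)
phase1_cycle2 <- c(389.89, 129.93, 50.12, 98.69, 134.86,
                   384.16, 200.94, 122.02, 103.69, 110.53)

printed_averages <- c(398.03, 144.45, 49.38, 93.74, 144.10,
                      398.47, 195.13, 114.85, 106.97, 104.91)
printed_differences <- c(16.28, 29.04, -1.49, -9.89, 18.48,
                         28.63, -11.62, -14.33, 6.57, -11.23)

reference_beta <- c(-2299.6275, 7.896875, -0.591625, 839.270625, -69.7646875)

phase1_factors <- function() list(
  temperature = evop_factor("temperature", 28, 2, "degC"),
  pH          = evop_factor("pH", 6, 2, "pH"),
  wb_percent  = evop_factor("wb_percent", 80, 10, "%WB"))

phase1_worksheet <- function() {
  f <- phase1_factors()
  ws <- evop_worksheet(f$temperature, f$pH, f$wb_percent)
  ws <- attach_cycle(ws, phase1_cycle1)
  attach_cycle(ws, phase1_cycle2)
}

training_data <- function() data.frame(
  temperature_C = c(28, 26, 26, 30, 30, 28, 30, 26, 30),
  wb_percent    = c(80, 70, 90, 90, 70, 80, 90, 90, 70),
  pH            = c(6, 4, 8, 4, 8, 6, 8, 4, 4),
  activity      = c(398.03, 144.45, 49.38, 93.74, 144.12,
                    398.47, 195.13, 114.85, 106.97))

# brute-force contrast oracle: mean over an explicit run subset at the high
# level minus mean over the subset at the low level
contrast_oracle <- function(responses, plus_runs, minus_runs) {
  idx <- function(ids) match(ids, paste0("A", 1:10))
  mean(responses[idx(plus_runs)]) - mean(responses[idx(minus_runs)])
}

# central finite differences of the network forward map wrt theta
numeric_jacobian <- function(theta, Xn, hidden, h = 1e-6) {
  n <- nrow(Xn)
  J <- matrix(NA_real_, n, length(theta))
  for (k in seq_along(theta)) {
    up <- theta; up[k] <- up[k] + h
    dn <- theta; dn[k] <- dn[k] - h
    J[, k] <- (evopann:::.mfnn_forward(up, Xn, hidden)$yhat -
               evopann:::.mfnn_forward(dn, Xn, hidden)$yhat) / (2 * h)
  }
  J
}
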