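# CSV readers/writers, packaged fixtures, and the end-to-end pipeline.
# CSV dialect: comma separator, dot decimal, UTF-8, header row mandatory.

.DATASET_COLS <- c("temperature_C", "wb_percent", "pH", "activity")

#' Validate a screening dataset
#'
#' @param data Data frame; must contain numeric, finite columns
#'   `temperature_C`, `wb_percent`, `pH`, `activity`, with `wb_percent` in
#'   \[0, 100\].  Duplicated design points with distinct responses are
#'   allowed (centre replicates).
#' @return The validated data frame (extra columns dropped, canonical
#'   column order).
#' @export
validate_dataset <- function(data) {
  if (!is.data.frame(data)) stop("dataset must be a data frame")
  miss <- setdiff(.DATASET_COLS, names(data))
  if (length(miss))
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)[, .DATASET_COLS]
  if (nrow(data) < 1L) stop("dataset has no records")
  for (col in .DATASET_COLS) {
    v <- data[[col]]
    if (!is.numeric(v))
      stop("column '", col, "' is not numeric")
    if (any(!is.finite(v)))
      stop("column '", col, "' contains non-finite values (rows ",
           paste(which(!is.finite(v)), collapse = ", "), ")")
  }
  if (any(data$wb_percent < 0 | data$wb_percent > 100))
    stop("'wb_percent' must lie in [0, 100]")
  rownames(data) <- NULL
  data
}

#' Read / write a screening dataset CSV
#'
#' Columns `temperature_C`, `wb_percent`, `pH`, `activity`.
#'
#' @param path File path.
#' @return `read_dataset()`: a validated data frame.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("dataset file '", path, "' has no records")
  validate_dataset(df)
}

#' @rdname read_dataset
#' @param data A dataset data frame.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(validate_dataset(data), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write an EVOP worksheet CSV
#'
#' Schema: `run_id, temperature_C, pH, wb_percent, cycle1, ..., cycleN`;
#' rows in run order A1..A10.  On reading, the three factors are
#' reconstructed from the actual conditions (centre from A1, half-step from
#' the corner levels) and the layout is validated against the 2^3 design.
#'
#' @param path File path.
#' @return `read_worksheet()`: an [evop_worksheet()] with all cycles
#'   attached.
#' @examples
#' ws <- read_worksheet(system.file("extdata", "evop_worksheet.csv",
#'                                  package = "evopann"))
#' n_cycles(ws)
#' @export
read_worksheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8",
                        stringsAsFactors = FALSE)
  need <- c("run_id", "temperature_C", "pH", "wb_percent")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("worksheet lacks column(s): ", paste(miss, collapse = ", "))
  missing_runs <- setdiff(.RUN_IDS, df$run_id)
  if (length(missing_runs))
    stop("worksheet must contain runs A1..A10; missing: ",
         paste(missing_runs, collapse = ", "))
  if (nrow(df) != 10L || !identical(df$run_id, .RUN_IDS))
    stop("worksheet rows must be exactly A1..A10 in order")
  for (col in c("temperature_C", "pH", "wb_percent"))
    if (!is.numeric(df[[col]]))
      stop("column '", col, "' is not numeric")
  centre_rows <- df[c(1L, 6L), ]
  if (!all(centre_rows[2, need[-1]] == centre_rows[1, need[-1]]))
    stop("centre runs A1 and A6 disagree on conditions")
  factor_from <- function(col, name, units) {
    lv <- sort(unique(df[[col]]))
    if (length(lv) != 3L)
      stop("column '", col, "' must have exactly 3 levels (low, centre, high)")
    if (!isTRUE(all.equal(lv[2] - lv[1], lv[3] - lv[2])))
      stop("levels of '", col, "' are not symmetric about the centre")
    evop_factor(name, lv[2], lv[2] - lv[1], units)
  }
  ws <- evop_worksheet(factor_from("temperature_C", "temperature", "degC"),
                       factor_from("pH", "pH", "pH"),
                       factor_from("wb_percent", "wb_percent", "%WB"))
  mism <- which(abs(ws$runs$temperature_C - df$temperature_C) > 1e-8 |
                abs(ws$runs$pH - df$pH) > 1e-8 |
                abs(ws$runs$wb_percent - df$wb_percent) > 1e-8)
  if (length(mism))
    stop("run condition(s) inconsistent with the 2^3 design coding: ",
         paste(df$run_id[mism], collapse = ", "))
  cyc_cols <- grep("^cycle[0-9]+$", names(df), value = TRUE)
  cyc_cols <- cyc_cols[order(as.integer(sub("cycle", "", cyc_cols)))]
  for (col in cyc_cols) {
    if (!is.numeric(df[[col]]))
      stop("column '", col, "' is not numeric")
    ws <- attach_cycle(ws, df[[col]])
  }
  ws
}

#' @rdname read_worksheet
#' @param ws An [evop_worksheet()].
#' @export
write_worksheet <- function(ws, path) {
  stopifnot(inherits(ws, "evop_worksheet"))
  utils::write.csv(as.data.frame(ws), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged alkaline-protease screening fixtures
#'
#' `protease_worksheet()` returns the phase-I EVOP worksheet (10 runs,
#' 2 cycles of measured activities, U/gds) for the wheat bran + soybean meal
#' screening of *Rhizopus oryzae* protease, centre (28 degC, pH 6, 80% WB)
#' with half-steps (2, 2, 10).  `protease_training()` returns the 9-record
#' training dataset assembled from that campaign's run averages (the centre
#' appears twice, once per cycle average source; one corner was not carried
#' over), used to fit the surrogates.
#'
#' @return An [evop_worksheet()], or a dataset data frame.
#' @export
protease_worksheet <- function() {
  read_worksheet(system.file("extdata", "evop_worksheet.csv",
                             package = "evopann", mustWork = TRUE))
}

#' @rdname protease_worksheet
#' @export
protease_training <- function() {
  read_dataset(system.file("extdata", "protease_training.csv",
                           package = "evopann", mustWork = TRUE))
}

#' Assemble a surrogate training dataset from a worksheet
#'
#' Each run contributes one record: its actual conditions and the per-run
#' average response across cycles.
#'
#' @param ws An [evop_worksheet()] with >= 1 cycle.
#' @return A dataset data frame (10 records).
#' @export
worksheet_to_dataset <- function(ws) {
  stopifnot(inherits(ws, "evop_worksheet"))
  validate_dataset(data.frame(temperature_C = ws$runs$temperature_C,
                              wb_percent = ws$runs$wb_percent,
                              pH = ws$runs$pH,
                              activity = unname(run_averages(ws))))
}

#' Run the full screening pipeline
#'
#' Chains the stages end to end: EVOP phase analysis of the worksheet,
#' assembly of the surrogate training set from its run averages, surrogate
#' fitting, and constrained grid optimization of the predicted yield.  The
#' returned bundle is a pure function of (inputs, configuration, seed), so
#' re-running with identical arguments reproduces it exactly.
#'
#' @param worksheet An [evop_worksheet()] or a path to a worksheet CSV.
#' @param model `"polynomial"` (OLS refit), `"mfnn"` (network surrogate) or
#'   `"reference"` (the fixed reference polynomial).
#' @param seed,restarts Passed to [mfnn()] when `model = "mfnn"`.
#' @param grid A [grid_spec()].
#' @param sd_method,s Passed to [evop_analysis()].
#' @param training Optional dataset data frame overriding the
#'   worksheet-derived training set (e.g. [protease_training()]).
#' @return A list of class `evop_pipeline` with `provenance` (package
#'   version, configuration, seed, and md5 digest of the worksheet file if
#'   one was read), `analysis`, `training`, `model`, `optimization`.
#' @examples
#' bundle <- run_pipeline(protease_worksheet(), model = "reference",
#'                        sd_method = "fixed", s = 100.65)
#' bundle$optimization$argmax
#' @export
run_pipeline <- function(worksheet, model = c("polynomial", "mfnn", "reference"),
                         seed = 1L, restarts = 64L, grid = grid_spec(),
                         sd_method = "pooled", s = NULL, training = NULL) {
  model <- match.arg(model)
  digest <- NULL
  if (is.character(worksheet)) {
    digest <- unname(tools::md5sum(worksheet))
    worksheet <- read_worksheet(worksheet)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  analysis <- stage("evop_analysis",
                    evop_analysis(worksheet, sd_method = sd_method, s = s))
  training <- stage("dataset_assembly",
                    if (is.null(training)) worksheet_to_dataset(worksheet)
                    else validate_dataset(training))
  fit <- stage("surrogate_fit", switch(model,
    polynomial = fit_quadratic_surface(training),
    reference  = reference_surface(),
    mfnn       = mfnn(training, restarts = restarts, seed = seed)))
  opt <- stage("grid_optimize", grid_optimize(fit, grid))
  structure(list(
    provenance = list(package = "evopann",
                      version = as.character(utils::packageVersion("evopann")),
                      model = model, seed = seed, sd_method = sd_method,
                      worksheet_md5 = digest),
    analysis = analysis, training = training, model = fit,
    optimization = opt), class = "evop_pipeline")
}

#' @export
print.evop_pipeline <- function(x, ...) {
  cat("Screening pipeline bundle (", x$provenance$model, " surrogate)\n",
      sep = "")
  print(x$analysis)
  print(x$model)
  a <- x$optimization$argmax
  cat(sprintf("Optimized: %.2f U/gds at T %g degC, WB %g%%, pH %g\n",
              a$predicted, a$temperature_C, a$wb_percent, a$pH))
  invisible(x)
}

#' Serialize a pipeline bundle to JSON
#'
#' Writes the bundle's provenance, the phase statistics (full precision
#' plus a 2-decimal display block), the surrogate coefficients or weights,
#' and the optimization argmax/window.
#'
#' @param bundle A [run_pipeline()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_json <- function(bundle, path) {
  stopifnot(inherits(bundle, "evop_pipeline"))
  an <- bundle$analysis
  report <- list(
    per_run_average = as.list(an$averages),
    per_run_difference = as.list(an$differences),
    effects = as.list(an$effects),
    change_in_mean = an$change_in_mean,
    standard_deviation = an$s,
    n_cycles = an$n_cycles,
    error_limits = unclass(an$limits),
    decision = list(verdict = an$decision$verdict,
                    shift_direction = as.list(an$decision$shift_direction),
                    rationale = an$decision$rationale),
    display = lapply(c(as.list(round(an$effects, 2)),
                       change_in_mean = round(an$change_in_mean, 2),
                       standard_deviation = round(an$s, 2)), identity))
  model <- if (inherits(bundle$model, "surface_poly"))
    list(type = "polynomial", coefficients = as.list(bundle$model$beta))
  else list(type = "mfnn", hidden = bundle$model$hidden,
            weights = bundle$model$theta,
            r2_overall = bundle$model$report$r2_overall,
            restart = bundle$model$report$restart)
  out <- list(provenance = bundle$provenance, analysis = report,
              model = model,
              optimization = list(argmax = as.list(bundle$optimization$argmax),
                                  window = bundle$optimization$window))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
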