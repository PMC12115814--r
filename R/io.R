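#' Read a sampled time series from CSV
#'
#' Reads a two-column CSV with header `t,v` (time in seconds, voltage in
#' arbitrary units) and validates it: equal-length numeric columns and
#' strictly increasing times. Violations raise an error naming the first
#' offending line (1-based, counting the header).
#'
#' @param path path to the CSV file.
#' @return A [time_series()] object.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("parse error in '", path, "': ",
                                          conditionMessage(e)))
  if (nrow(df) == 0L) stop("parse error: '", path, "' contains no data rows")
  if (!all(c("t", "v") %in% names(df)))
    stop("parse error: header must contain columns 't' and 'v'")
  if (anyNA(df$t) || anyNA(df$v)) {
    bad <- which(is.na(df$t) | is.na(df$v))[1L]
    stop("parse error at line ", bad + 1L, ": non-numeric or missing value")
  }
  nonmono <- which(diff(df$t) <= 0)
  if (length(nonmono))
    stop("parse error at line ", nonmono[1L] + 2L,
         ": times must be strictly increasing")
  meta <- list(provenance = paste0("read_timeseries:", path))
  time_series(df$t, df$v, meta = meta)
}

#' Write a time series to CSV
#'
#' Inverse of [read_timeseries()]: writes the two columns `t,v` at full
#' precision so a read/write round trip is value-identical.
#'
#' @param series a [time_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  stopifnot(inherits(series, "time_series"))
  utils::write.csv(data.frame(t = series$t, v = series$v), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the standard analysis pipeline
#'
#' Executes the package's three standing computations with one seeded
#' configuration: the tiling band table, the memory stability ledger, and
#' a simulate-then-fit round trip on a synthetic two-pulse spike train.
#' Any stage failure is captured in the report with the stage name and
#' the partial results collected so far.
#'
#' @param config list with optional entries `base_frequency`,
#'   `base_amplitude`, `constants` (argument list for
#'   [memory_constants()]), `strand` (argument list for
#'   [memory_strand()]), `W`, `seed`, `fs`, `duration`, `noise_sd` and
#'   `pulses` (data frame with columns a, b, c, V0).
#' @return List of class `"surfnet_report"` with components `config`,
#'   `tiling_table`, `memory_ledger`, `fit` and `errors` (named list of
#'   failed stages, empty on success).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    base_frequency = 1, base_amplitude = 200,
    constants = list(), strand = list(), W = 5L,
    seed = 1L, fs = 200, duration = 10, noise_sd = 0.05,
    pulses = data.frame(a = c(1.0, 1.5), b = c(1.0, 1.5),
                        c = c(3.0, 9.0), V0 = c(1.0, 0.8))),
    config)
  report <- list(config = cfg, errors = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  report$tiling_table <- run_stage("tiling_table",
    platonic_tiling_table(cfg$base_frequency, cfg$base_amplitude))
  report$memory_ledger <- run_stage("memory_ledger", {
    consts <- do.call(memory_constants, cfg$constants)
    strand <- do.call(memory_strand, cfg$strand)
    memory_ledger(strand, consts, W = cfg$W)
  })
  report$fit <- run_stage("fit", {
    pl <- cfg$pulses
    train <- soliton_train(lapply(seq_len(nrow(pl)), function(i)
      pinch_pulse(pl$a[i], pl$b[i], pl$c[i], pl$V0[i])))
    series <- synth_spike_train(train, fs = cfg$fs, duration = cfg$duration,
                                noise_sd = cfg$noise_sd, seed = cfg$seed)
    fit <- fit_spike_train(series, n_pulses = nrow(pl))
    list(true = pl, estimate = fit$parameters, rms = fit$rms,
         converged = fit$converged, seed = cfg$seed)
  })
  class(report) <- "surfnet_report"
  report
}

#' @export
print.surfnet_report <- function(x, ...) {
  cat("surfnet pipeline report\n")
  if (length(x$errors)) {
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  } else cat("  all stages completed\n")
  if (!is.null(x$tiling_table)) {
    cat("\nTiling band table:\n")
    print(x$tiling_table)
  }
  if (!is.null(x$memory_ledger)) {
    cat("\n")
    print(x$memory_ledger)
  }
  if (!is.null(x$fit)) {
    cat(sprintf("\nSpike fit (seed %d): rms %.4g, converged %s\n",
                x$fit$seed, x$fit$rms, x$fit$converged))
  }
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' @param report a `"surfnet_report"` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "surfnet_report"))
  out <- list(
    config = report$config[setdiff(names(report$config), "pulses")],
    pulses = report$config$pulses,
    tiling_table = report$tiling_table,
    memory = if (!is.null(report$memory_ledger)) list(
      Nc = report$memory_ledger$Nc,
      field = report$memory_ledger$field,
      interaction = report$memory_ledger$interaction,
      alignment = report$memory_ledger$alignment,
      frequency = report$memory_ledger$frequency,
      thermal = report$memory_ledger$thermal,
      engram = report$memory_ledger$engram),
    fit = report$fit,
    errors = report$errors)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
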