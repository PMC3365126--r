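# CSV readers/writers and run-record metadata.
#
# CSV schemas (documented in the README):
#   sweep:      freq_hz, amplitude_norm[, phase_rad]   (header required)
#   timecourse: t_s, q_C_per_m2
# Frequencies are Hz on disk and converted to rad/s on load. Every writer
# can emit a JSON run record alongside its output for reproducibility.

#' Read a force-frequency sweep from CSV
#'
#' Expects columns `freq_hz` and `amplitude_norm` (optional `phase_rad`),
#' with strictly increasing positive frequencies and positive amplitudes;
#' violations raise an error naming the first offending row. Frequencies
#' are converted to angular frequencies (rad/s).
#'
#' @param path CSV path.
#' @return A [frequency_sweep()].
#' @export
read_sweep_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#")
  for (col in c("freq_hz", "amplitude_norm"))
    if (!col %in% names(d))
      stop("sweep CSV is missing required column '", col, "'", call. = FALSE)
  if (nrow(d) < 1L) stop("sweep CSV has no data rows", call. = FALSE)
  bad <- which(d$freq_hz <= 0 | !is.finite(d$freq_hz))
  if (length(bad)) stop("non-positive frequency at row ", bad[1], call. = FALSE)
  bad <- which(diff(d$freq_hz) <= 0)
  if (length(bad))
    stop("frequencies not strictly increasing at row ", bad[1] + 1L,
         call. = FALSE)
  bad <- which(d$amplitude_norm <= 0 | !is.finite(d$amplitude_norm))
  if (length(bad)) stop("non-positive amplitude at row ", bad[1], call. = FALSE)
  frequency_sweep(2 * pi * d$freq_hz, d$amplitude_norm,
                  if ("phase_rad" %in% names(d)) d$phase_rad else NULL)
}

#' Write a force-frequency sweep to CSV
#'
#' Writes columns `freq_hz`, `amplitude_norm`, `phase_rad` (Hz on disk).
#' Round-trips through [read_sweep_csv()] within float formatting.
#'
#' @param sweep A [frequency_sweep()].
#' @param path Output path.
#' @param run_record Also write a JSON run record next to the output.
#' @param seed Seed to record, if any.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path, run_record = FALSE, seed = NULL) {
  stopifnot(inherits(sweep, "frequency_sweep"))
  d <- data.frame(freq_hz = sweep$omega / (2 * pi),
                  amplitude_norm = sweep$amplitude,
                  phase_rad = sweep$phase)
  .write_csv_units(d, path, "# freq_hz: Hz; amplitude_norm: dimensionless; phase_rad: rad")
  if (run_record)
    write_run_record(path, seed = if (is.null(seed)) attr(sweep, "seed")
                     else seed)
  invisible(path)
}

#' Write a charge time course to CSV
#'
#' Column header is `t_s,q_C_per_m2` (SI units in the names) preceded by a
#' `#` units comment line.
#'
#' @param tc A [charge_timecourse()] (must be non-empty).
#' @param path Output path.
#' @inheritParams write_sweep_csv
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path, run_record = FALSE, seed = NULL) {
  if (!inherits(tc, "charge_timecourse") || nrow(tc) < 1L)
    stop("tc must be a non-empty charge_timecourse", call. = FALSE)
  d <- data.frame(t_s = tc$t, q_C_per_m2 = tc$q)
  .write_csv_units(d, path, "# t_s: seconds; q_C_per_m2: C/m^2 (signed)")
  if (run_record) write_run_record(path, seed = seed)
  invisible(path)
}

#' Read a charge time course from CSV
#'
#' Inverse of [write_timecourse_csv()].
#'
#' @param path CSV path.
#' @return A [charge_timecourse()].
#' @export
read_timecourse_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  for (col in c("t_s", "q_C_per_m2"))
    if (!col %in% names(d))
      stop("timecourse CSV is missing required column '", col, "'",
           call. = FALSE)
  charge_timecourse(d$t_s, d$q_C_per_m2)
}

.write_csv_units <- function(d, path, comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
}

#' Write a reproducibility run record
#'
#' Emits `<out>.run.json` describing how an output file was produced:
#' command line, config file hash, seed, package version, timestamp and the
#' output path. Stochastic CLI commands always produce one.
#'
#' @param out_path The output file the record describes.
#' @param config_path Optional config file whose MD5 is recorded.
#' @param seed Integer seed used (or NULL).
#' @param command Character vector of the command-line arguments.
#' @return The record path, invisibly.
#' @export
write_run_record <- function(out_path, config_path = NULL, seed = NULL,
                             command = commandArgs(trailingOnly = FALSE)) {
  rec <- list(
    command = paste(command, collapse = " "),
    config = if (!is.null(config_path))
      list(path = config_path,
           md5 = unname(tools::md5sum(config_path))) else NULL,
    seed = seed,
    package = "prestinmem",
    version = as.character(utils::packageVersion("prestinmem")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = out_path)
  path <- paste0(out_path, ".run.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
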