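# Tidy CSV / JSON output. Numbers are written with 17 significant digits so
# a written record reads back bit-identically.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

write_precise_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
}

config_to_list <- function(config) {
  x <- unclass(config)
  x$species <- lapply(x$species, unclass)
  x
}

#' Hash of a configuration
#'
#' MD5 over the canonical JSON serialization; changes if and only if some
#' parameter changes.
#'
#' @param config A [sim_config()].
#' @return Hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(config_to_list(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write trial or batch outputs to a directory
#'
#' For a `trial_record`: `daily.csv` (one row per day x species),
#' `resources.csv` (grid totals per step boundary), `ledger.csv`,
#' `snapshot.csv`, and `events.json` (events plus a config echo, seed, config
#' hash, and package version). For a `batch_summary`: `trials.csv` and
#' `batch.json`.
#'
#' @param x A `trial_record` or `batch_summary`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "trial_record")) {
    paths <- file.path(out_dir, c("daily.csv", "resources.csv",
                                  "ledger.csv", "snapshot.csv",
                                  "events.json"))
    write_precise_csv(x$daily, paths[1])
    res <- as.data.frame(x$resources)
    names(res) <- paste0("step_", seq_len(ncol(res)))
    res <- cbind(day = 0:(nrow(res) - 1), res)
    write_precise_csv(res, paths[2])
    write_precise_csv(x$ledger, paths[3])
    write_precise_csv(x$snapshot, paths[4])
    jsonlite::write_json(
      list(seed = x$seed,
           events = list(
             exclusion_day = as.list(x$events$exclusion_day),
             speciation_day = x$events$speciation_day),
           config = config_to_list(x$config),
           config_hash = config_hash(x$config),
           package_version = as.character(utils::packageVersion(
             "chrononiche"))),
      paths[5], auto_unbox = TRUE, digits = NA, na = "null")
  } else if (inherits(x, "batch_summary")) {
    paths <- file.path(out_dir, c("trials.csv", "batch.json"))
    write_precise_csv(x$trials, paths[1])
    jsonlite::write_json(
      list(base_seed = x$base_seed, aggregates = x$aggregates,
           config = config_to_list(x$config),
           config_hash = config_hash(x$config),
           package_version = as.character(utils::packageVersion(
             "chrononiche"))),
      paths[2], auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    stop("`x` must be a trial_record or batch_summary")
  }
  invisible(paths)
}

#' Read back a written daily record
#'
#' @param path Path to a `daily.csv` written by [write_outputs()].
#' @return Data frame with the same columns and values as the in-memory
#'   `daily` component.
#' @export
read_daily_csv <- function(path) {
  utils::read.csv(path, colClasses = c(
    day = "integer", species = "integer", pop = "integer",
    mean_amplitude = "numeric", phase_mean = "numeric",
    phase_sd = "numeric", cgm = "numeric"))
}
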