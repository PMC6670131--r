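#' Stable hash of a parameter set
#'
#' MD5 of a canonical full-precision serialization of the 42 parameter
#' values; stable under re-serialization and used to stamp output files.
#'
#' @param params a [WntParameterSet-class].
#' @return character MD5 string.
#' @export
parameterHash <- function(params) {
  v <- paramValues(params)
  canon <- paste(names(v), sprintf("%.17g", v), sep = "=", collapse = ";")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canon, tf)
  unname(tools::md5sum(tf))
}

# leveled logging to stderr; numeric outputs never go to the log stream
.log <- function(level, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S"),
                  paste0(..., collapse = "")))
}
.logInfo <- function(...) .log("INFO", ...)
.logError <- function(...) .log("ERROR", ...)

#' Write a run manifest
#'
#' Records the configuration snapshot, parameter hash, package version,
#' timestamp and the inventory of files a command produced.
#'
#' @param path manifest output path (JSON).
#' @param params a [WntParameterSet-class].
#' @param settings settings list.
#' @param outputs character vector of produced file paths.
#' @param command name of the command that ran.
#' @return the path, invisibly.
#' @export
writeRunManifest <- function(path, params, settings, outputs,
                             command = "run") {
  manifest <- list(
    command = command,
    tool_version = as.character(utils::packageVersion("HotairWnt")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameter_hash = parameterHash(params),
    parameters = as.list(paramValues(params)),
    settings = settings[!vapply(settings, is.null, TRUE)],
    outputs = lapply(outputs, function(f) list(
      path = f, exists = file.exists(f),
      md5 = if (file.exists(f)) unname(tools::md5sum(f)) else NA)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
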