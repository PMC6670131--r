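# YAML configuration: sections `parameters`, `initial_state`, `settings`,
# `scenarios`. All quantities are nM and minutes; numbers are serialized at
# full double precision so that write -> load round-trips exactly.

.SETTING_KEYS <- c("tStart", "tEnd", "outputStep", "atol", "rtol",
                   "solver", "mmp13Hill", "seed")

.fullPrecision <- function(x) {
  if (is.numeric(x)) {
    # shortest decimal string that parses back to the identical double
    vapply(x, function(v) {
      for (d in 1:17) {
        s <- formatC(v, digits = d, format = "g")
        if (as.numeric(s) == v) return(s)
      }
      formatC(v, digits = 17, format = "g")
    }, character(1))
  } else x
}

#' Write a model configuration file
#'
#' Serializes a parameter set, initial state and simulation settings (plus
#' optional scenario definitions) to YAML. Numeric values are written with
#' enough digits that [loadConfig()] reproduces them bit-for-bit.
#'
#' @param path output file path.
#' @param params a [WntParameterSet-class].
#' @param init named initial-state vector.
#' @param settings list from [simulationSettings()].
#' @param scenarios optional named list of scenario definitions (each a
#'   list with optional `parameters`, `initial_state` override maps).
#' @return the path, invisibly.
#' @export
writeConfig <- function(path, params = defaultParameters(),
                        init = initialState(),
                        settings = simulationSettings(),
                        scenarios = NULL) {
  cfg <- list(
    parameters = as.list(.fullPrecision(paramValues(params))),
    initial_state = as.list(.fullPrecision(init)),
    settings = lapply(settings[.SETTING_KEYS], function(v)
      if (is.numeric(v)) .fullPrecision(v) else v))
  cfg$settings <- cfg$settings[!vapply(cfg$settings, is.null, TRUE)]
  if (!is.null(scenarios)) cfg$scenarios <- scenarios
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Load a model configuration file
#'
#' Reads a YAML configuration; missing keys fall back to the package
#' defaults, unknown parameter/species/setting keys are rejected by name,
#' and non-positive parameter values are rejected. Printed-style aliases
#' (`"k-11"`, `"LRP5/6"`, `"beta-catenin"`, ...) are accepted.
#'
#' @param path file path.
#' @return list with `params` ([WntParameterSet-class]), `init` (named
#'   numeric), `settings` (list), `scenarios` (list, possibly empty).
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed config file: ", conditionMessage(e), call. = FALSE))
  if (is.null(cfg)) cfg <- list()
  known <- c("parameters", "initial_state", "settings", "scenarios")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  pOv <- lapply(cfg$parameters, as.numeric)
  if (length(pOv)) {
    if (any(vapply(pOv, function(v) !is.finite(v) || v <= 0, TRUE)))
      stop("non-positive parameter value in config", call. = FALSE)
  }
  params <- wntParameters(overrides = pOv)

  iOv <- lapply(cfg$initial_state, as.numeric)
  init <- initialState(overrides = iOv)

  sCfg <- cfg$settings
  if (length(sCfg)) {
    badS <- setdiff(names(sCfg), .SETTING_KEYS)
    if (length(badS))
      stop("unknown settings key(s): ", paste(badS, collapse = ", "),
           call. = FALSE)
    num <- intersect(names(sCfg),
                     c("tStart", "tEnd", "outputStep", "atol", "rtol",
                       "seed"))
    sCfg[num] <- lapply(sCfg[num], as.numeric)
  }
  settings <- do.call(simulationSettings, as.list(sCfg))

  list(params = params, init = init, settings = settings,
       scenarios = if (is.null(cfg$scenarios)) list() else cfg$scenarios)
}
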