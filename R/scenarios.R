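#' HOTAIR knockout scenario
#'
#' Removes HOTAIR from the system by setting its synthesis rate k1 to zero
#' together with a zero initial HOTAIR concentration; because HOTAIR obeys
#' simple first-order turnover this is equivalent to clamping it at zero,
#' while keeping the system autonomous. Everything else is untouched: with
#' no HOTAIR the Hill repression of WIF-1 synthesis is fully released, so
#' the WIF-1 synthesis flux is constant at V3.
#'
#' @param params a [WntParameterSet-class] (default: Table defaults).
#' @param init named initial state (default [initialState()]).
#' @return list with elements `name`, `params`, `init`.
#' @examples
#' ko <- hotairKnockout()
#' ko$params["k1"]; ko$init[["Hotair"]]
#' @export
hotairKnockout <- function(params = defaultParameters(),
                           init = initialState()) {
  pv <- paramValues(params)
  pv["k1"] <- 0
  init <- .checkState(init)[1, ]
  init["Hotair"] <- 0
  list(name = "hotair_knockout",
       params = new("WntParameterSet", values = pv,
                    units = paramUnits(params)),
       init = init)
}

# simulate from either a WntParameterSet or a raw named value vector
# (scenarios may carry zeroed rates that a valid parameter set forbids)
.simulateValues <- function(pv, init, settings) {
  if (is(pv, "WntParameterSet")) return(simulateWnt(pv, init, settings))
  params <- new("WntParameterSet", values = pv,
                units = defaultParameters()@units)
  simulateWnt(params, init, settings)
}

#' Run a scenario definition
#'
#' @param scenario list with `params` (parameter set or named value
#'   vector) and `init`, e.g. from [hotairKnockout()].
#' @param settings simulation settings.
#' @return a [WntTrajectory-class].
#' @export
runScenario <- function(scenario, settings = simulationSettings()) {
  .simulateValues(scenario$params, scenario$init, settings)
}

#' Fold-change scan over one parameter
#'
#' Re-simulates the model with a single parameter multiplied by each fold
#' in turn (fold 1 reproduces the baseline exactly) and attaches per-species
#' oscillation summaries. A solver failure on one fold is reported in that
#' element's `error` field; the other folds are still returned.
#'
#' @param params baseline [WntParameterSet-class].
#' @param paramName the parameter to scale (aliases accepted).
#' @param folds positive numeric vector of fold-changes.
#' @param init,settings simulation inputs.
#' @param species species to summarize (default: all).
#' @param transientEnd transient cut for the summaries (min).
#' @return named list (one element per fold) with `fold`, `value`,
#'   `trajectory`, `summary` (or `error`).
#' @examples
#' sc <- foldChangeScan(folds = c(1), species = "Axin",
#'                      settings = simulationSettings(tEnd = 400))
#' sc[["1"]]$summary
#' @export
foldChangeScan <- function(params = defaultParameters(),
                           paramName = "k24", folds = c(0.01, 1, 100),
                           init = initialState(),
                           settings = simulationSettings(),
                           species = speciesNames(),
                           transientEnd = 300) {
  paramName <- .resolveParamNames(paramName)
  stopifnot(all(folds > 0))
  base <- paramValues(params)
  out <- lapply(folds, function(f) {
    pv <- base
    pv[paramName] <- pv[paramName] * f
    res <- list(fold = f, value = unname(pv[paramName]))
    tr <- tryCatch(.simulateValues(pv, init, settings),
                   error = function(e) e)
    if (inherits(tr, "error")) {
      res$error <- conditionMessage(tr)
    } else {
      res$trajectory <- tr
      res$summary <- summarizeOscillations(tr, species,
                                           transientEnd = transientEnd)
    }
    res
  })
  names(out) <- as.character(folds)
  out
}

#' Preset parameter scans for the Axin-related rates
#'
#' The three 100-fold scans of the rates governing Axin turnover and the
#' release of phosphorylated beta-catenin, around their basal values:
#' k16 in {0.005, 0.5, 50}, k19 in {0.00167, 0.167, 16.7} and
#' k24 in {0.0002, 0.02, 2}.
#'
#' @return named list of scan definitions (`param`, `values`, `folds`).
#' @export
axinScanPresets <- function() {
  base <- paramValues(defaultParameters())
  mk <- function(p) list(param = p,
                         values = base[[p]] * c(0.01, 1, 100),
                         folds = c(0.01, 1, 100))
  list(k16 = mk("k16"), k19 = mk("k19"), k24 = mk("k24"))
}

#' Compare a variant trajectory against a reference
#'
#' Per species: the oscillation summaries of both runs, the relative
#' amplitude change 100 * (A_variant - A_ref) / A_ref, the relative change
#' of the post-transient mean level, and the regime transition. Amplitude
#' changes are NA when either regime is non-oscillatory.
#'
#' @param reference,variant [WntTrajectory-class] objects on the same time
#'   grid.
#' @param species species to compare (default: all).
#' @param transientEnd transient cut (min).
#' @return data.frame with one row per species.
#' @export
compareTrajectories <- function(reference, variant,
                                species = speciesNames(),
                                transientEnd = 300) {
  stopifnot(is(reference, "WntTrajectory"), is(variant, "WntTrajectory"))
  if (!isTRUE(all.equal(reference@time, variant@time)))
    stop("trajectories are on different time grids", call. = FALSE)
  sRef <- summarizeOscillations(reference, species,
                                transientEnd = transientEnd)
  sVar <- summarizeOscillations(variant, species,
                                transientEnd = transientEnd)
  ampChange <- ifelse(
    sRef$regime == "oscillatory" & sVar$regime == "oscillatory",
    100 * (sVar$amplitude_nM - sRef$amplitude_nM) / sRef$amplitude_nM,
    NA_real_)
  meanChange <- 100 * (sVar$mean_nM - sRef$mean_nM) / sRef$mean_nM
  data.frame(species = sRef$species,
             regime_ref = sRef$regime, regime_var = sVar$regime,
             period_ref = sRef$period_min, period_var = sVar$period_min,
             amplitude_ref = sRef$amplitude_nM,
             amplitude_var = sVar$amplitude_nM,
             amplitude_change_pct = ampChange,
             mean_change_pct = meanChange,
             stringsAsFactors = FALSE)
}
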