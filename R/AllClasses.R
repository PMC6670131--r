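#' @import methods
NULL

#' Kinetic parameter set for the HOTAIR/Wnt/beta-catenin network
#'
#' Holds the 42 kinetic parameters of the pathway model: 37 per-reaction rate
#' constants, three half-saturation constants (K3, K8, K27) and two Hill
#' exponents (m3, m27). Values are in nM and minutes throughout. Construct
#' with [wntParameters()] or [defaultParameters()].
#'
#' @slot values named numeric vector of length 42.
#' @slot units named character vector of unit strings, same names as `values`.
#'
#' @seealso [wntParameters()], [paramValues()], [paramUnits()]
#' @export
setClass("WntParameterSet",
  representation(values = "numeric", units = "character"))

setValidity("WntParameterSet", function(object) {
  ref <- parameterNames()
  if (!identical(names(object@values), ref))
    return("parameter names/order must match parameterNames()")
  if (!identical(names(object@units), ref))
    return("unit names must match parameterNames()")
  if (any(!is.finite(object@values)))
    return("all parameter values must be finite")
  # zero is admitted so that knockout scenarios (k1 = 0) are representable;
  # the user-facing constructors require strictly positive values
  if (any(object@values < 0))
    return(paste0("negative parameter(s): ",
                  paste(ref[object@values < 0], collapse = ", ")))
  TRUE
})

#' Simulated trajectory of the pathway model
#'
#' Time grid (minutes) and the 25-species concentration matrix (nM) produced
#' by [simulateWnt()], together with snapshots of the parameters and solver
#' settings and the solver diagnostics. The raw solver output is retained;
#' tiny negative round-off values are clipped to zero only on export
#' (see [as.data.frame()] and [writeTrajectory()]).
#'
#' @slot time numeric vector, output time grid in minutes (monotone).
#' @slot states numeric matrix, length(time) x 25, columns named by species.
#' @slot parameters the [WntParameterSet-class] used.
#' @slot settings list, the simulation settings snapshot.
#' @slot diagnostics list with solver step counts and success flag.
#'
#' @seealso [simulateWnt()], [checkTrajectory()], [summarizeOscillations()]
#' @export
setClass("WntTrajectory",
  representation(time = "numeric", states = "matrix",
                 parameters = "WntParameterSet", settings = "list",
                 diagnostics = "list"))

setValidity("WntTrajectory", function(object) {
  if (nrow(object@states) != length(object@time))
    return("states must have one row per time point")
  if (!identical(colnames(object@states), speciesNames()))
    return("state columns must match speciesNames()")
  if (is.unsorted(object@time, strictly = TRUE))
    return("time grid must be strictly increasing")
  TRUE
})

#' Scaled local sensitivities of reaction fluxes to parameters
#'
#' A 37 (reaction flux) x 42 (parameter) matrix of dimensionless scaled
#' sensitivity indices produced by [fluxSensitivity()]. Each entry is the
#' time-aggregated scaled sensitivity S of one flux with respect to one
#' parameter; its sign records the direction of the dominant response
#' (negative: the flux decreases as the parameter increases). Entries whose
#' baseline flux stays below the near-zero floor throughout the analysis
#' window are masked (NA, `masked` TRUE).
#'
#' @slot S numeric 37 x 42 matrix, rows = reaction ids, cols = parameters.
#' @slot masked logical matrix of the same shape.
#' @slot protocol list recording delta, window, aggregation rule, flux floor
#'   and solver settings used.
#'
#' @seealso [fluxSensitivity()], [screenParameters()]
#' @export
setClass("FluxSensitivity",
  representation(S = "matrix", masked = "matrix", protocol = "list"))

setValidity("FluxSensitivity", function(object) {
  if (!identical(dim(object@S), c(37L, 42L)))
    return("sensitivity matrix must be 37 x 42")
  if (!identical(dim(object@masked), dim(object@S)))
    return("masked must have the same shape as S")
  TRUE
})
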