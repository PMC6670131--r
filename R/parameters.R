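# Parameter universe: 37 per-reaction rate constants followed by the three
# half-saturation constants and the two Hill exponents (42 in total).
.PARAM_TABLE <- local({
  df <- function(name, value, unit, process) data.frame(
    name = name, value = value, unit = unit, process = process,
    stringsAsFactors = FALSE)
  rbind(
    df("k1",   0.2,      "nM/min",      "Synthesis of HOTAIR"),
    df("k2",   0.1,      "1/min",       "Degradation of HOTAIR"),
    df("V3",   1,        "nM/min",      "Maximal WIF-1 synthesis (Hill-repressed by HOTAIR)"),
    df("k4",   1,        "1/(nM*min)",  "Binding of WIF-1 to Wnt"),
    df("km4",  1,        "1/min",       "Dissociation of the WIF-1.Wnt complex"),
    df("k5",   0.1,      "1/(nM*min)",  "Binding of LRP5/6 to Fzl"),
    df("km5",  1,        "1/min",       "Dissociation of Fzl.LRP5/6"),
    df("k6",   1,        "1/(nM*min)",  "Binding of Wnt to Fzl.LRP5/6"),
    df("km6",  1,        "1/min",       "Dissociation of Wnt.Fzl.LRP5/6"),
    df("k7",   1,        "1/(nM*min)",  "Binding of Axin to LRP5/6"),
    df("km7",  1,        "1/min",       "Dissociation of Axin.LRP5/6"),
    df("k8",   0.182,    "1/min",       "Activation of Dsh by the active receptor complex"),
    df("k9",   0.0182,   "1/min",       "Deactivation of Dsh"),
    df("k10",  0.05,     "1/(nM*min)",  "Dsh_a-driven release of GSK3 from the destruction complex"),
    df("k11",  0.0909,   "1/(nM*min)",  "Binding of GSK3 to APC.Axin"),
    df("km11", 100,      "1/min",       "Dissociation of GSK3 from APC.Axin.GSK3"),
    df("k12",  0.267,    "1/min",       "Phosphorylation of APC and Axin in the complex"),
    df("km12", 1,        "1/min",       "Dephosphorylation of APC* and Axin*"),
    df("k13",  1,        "1/(nM*min)",  "Binding of APC to Axin"),
    df("km13", 100,      "1/min",       "Dissociation of APC.Axin"),
    df("k14",  120,      "1/(nM*min)",  "Binding of beta-catenin to the phosphorylated complex"),
    df("km14", 1,        "1/min",       "Dissociation of beta-catenin from the complex"),
    df("k15",  206,      "1/min",       "Phosphorylation of beta-catenin"),
    df("k16",  0.5,      "1/min",       "Release of phosphorylated beta-catenin"),
    df("k17",  0.417,    "1/min",       "Degradation of phosphorylated beta-catenin"),
    df("k18",  8.22e-5,  "nM/min",      "Basal synthesis of Axin"),
    df("k19",  0.167,    "1/min",       "Degradation of Axin"),
    df("k20",  1,        "1/(nM*min)",  "Binding of APC to beta-catenin"),
    df("km20", 120,      "1/min",       "Dissociation of beta-catenin.APC"),
    df("k21",  0.423,    "nM/min",      "Synthesis of beta-catenin"),
    df("k22",  0.000257, "1/min",       "Degradation of beta-catenin"),
    df("k23",  2,        "1/(nM*min)",  "Binding of TCF to beta-catenin"),
    df("km23", 20,       "1/min",       "Dissociation of beta-catenin.TCF"),
    df("k24",  0.02,     "1/min",       "Axin synthesis induced by beta-catenin/TCF"),
    df("k25",  0.1,      "nM/min",      "Basal synthesis of MMP-13"),
    df("k26",  0.1,      "1/min",       "Degradation of MMP-13"),
    df("V27",  0.1,      "nM/min",      "Maximal beta-catenin.TCF-driven MMP-13 synthesis"),
    df("K3",   0.1,      "nM",          "Half-repression constant of WIF-1 synthesis by HOTAIR"),
    df("K8",   10,       "nM",          "Michaelis constant of Dsh activation"),
    df("K27",  1,        "nM",          "Half-activation constant of MMP-13 synthesis"),
    df("m3",   4,        "dimensionless", "Hill exponent, WIF-1 repression by HOTAIR"),
    df("m27",  4,        "dimensionless", "Hill exponent, MMP-13 regulation by beta-catenin.TCF")
  )
})

.N_RATE_CONSTANTS <- 37L

# printed-style aliases accepted in configuration input
.PARAM_ALIASES <- c(
  "k+4" = "k4", "k-4" = "km4", "k+5" = "k5", "k-5" = "km5",
  "k+6" = "k6", "k-6" = "km6", "k+7" = "k7", "k-7" = "km7",
  "k+11" = "k11", "k-11" = "km11", "k+12" = "k12", "k-12" = "km12",
  "k+13" = "k13", "k-13" = "km13", "k+14" = "k14", "k-14" = "km14",
  "k+20" = "k20", "k-20" = "km20", "k+23" = "k23", "k-23" = "km23")

.resolveParamNames <- function(nm) {
  hit <- match(nm, names(.PARAM_ALIASES))
  nm[!is.na(hit)] <- .PARAM_ALIASES[hit[!is.na(hit)]]
  bad <- setdiff(nm, .PARAM_TABLE$name)
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  nm
}

#' Names of the 42 model parameters
#'
#' The first 37 entries are the per-reaction rate constants (the screening
#' universe of the sensitivity analysis); the remainder are the
#' half-saturation constants K3, K8, K27 and the Hill exponents m3, m27.
#' Reverse rate constants use an ASCII `km` prefix (`km4` is the printed
#' k-4); the printed spellings are accepted as aliases wherever parameter
#' names are taken as input.
#'
#' @param rateConstantsOnly logical; if TRUE return only the 37 rate
#'   constants.
#' @return character vector.
#' @export
parameterNames <- function(rateConstantsOnly = FALSE) {
  nm <- .PARAM_TABLE$name
  if (rateConstantsOnly) nm[seq_len(.N_RATE_CONSTANTS)] else nm
}

#' Construct a parameter set
#'
#' Returns the model's default kinetic parameters (units nM, min), optionally
#' with named overrides applied. All values must be strictly positive.
#'
#' @param ... named overrides, e.g. `wntParameters(k24 = 2)`; printed-style
#'   aliases such as `"k-11"` are accepted (quote them).
#' @param overrides optional named numeric vector/list, merged after `...`.
#' @return a [WntParameterSet-class].
#' @examples
#' p <- defaultParameters()
#' paramValues(p)[["k1"]]
#' p2 <- wntParameters(k24 = 2)
#' @export
wntParameters <- function(..., overrides = NULL) {
  v <- stats::setNames(.PARAM_TABLE$value, .PARAM_TABLE$name)
  u <- stats::setNames(.PARAM_TABLE$unit, .PARAM_TABLE$name)
  ov <- c(list(...), as.list(overrides))
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("parameter overrides must be named", call. = FALSE)
    nm <- .resolveParamNames(names(ov))
    val <- vapply(ov, function(x) as.numeric(x)[1], numeric(1))
    if (any(!is.finite(val) | val <= 0))
      stop("non-positive parameter value(s) for: ",
           paste(nm[!is.finite(val) | val <= 0], collapse = ", "),
           call. = FALSE)
    v[nm] <- val
  }
  new("WntParameterSet", values = v, units = u)
}

#' @rdname wntParameters
#' @export
defaultParameters <- function() wntParameters()

#' Access parameter values, units and descriptions
#'
#' @param object a [WntParameterSet-class].
#' @return `paramValues`: named numeric vector (length 42); `paramUnits`:
#'   named character vector; `paramDescriptions`: data.frame of name, value,
#'   unit and the biological process each parameter governs.
#' @export
paramValues <- function(object) {
  stopifnot(is(object, "WntParameterSet"))
  object@values
}

#' @rdname paramValues
#' @export
paramUnits <- function(object) {
  stopifnot(is(object, "WntParameterSet"))
  object@units
}

#' @rdname paramValues
#' @export
paramDescriptions <- function(object = defaultParameters()) {
  out <- .PARAM_TABLE
  out$value <- unname(object@values[out$name])
  out
}

#' Modify a parameter set
#'
#' Returns a copy of `object` with the named parameters replaced.
#'
#' @param object a [WntParameterSet-class].
#' @param ... named replacements (aliases accepted).
#' @return a new [WntParameterSet-class].
#' @export
setParameters <- function(object, ...) {
  stopifnot(is(object, "WntParameterSet"))
  ov <- list(...)
  if (!length(ov)) return(object)
  nm <- .resolveParamNames(names(ov))
  val <- vapply(ov, function(x) as.numeric(x)[1], numeric(1))
  if (any(!is.finite(val) | val <= 0))
    stop("non-positive parameter value(s) for: ",
         paste(nm[!is.finite(val) | val <= 0], collapse = ", "),
         call. = FALSE)
  v <- object@values
  v[nm] <- val
  new("WntParameterSet", values = v, units = object@units)
}

#' @describeIn WntParameterSet number of parameters (42)
#' @param x a `WntParameterSet`.
#' @export
setMethod("length", "WntParameterSet", function(x) length(x@values))

#' @describeIn WntParameterSet extract parameter values by name or index
#' @param i name(s) or index(es).
#' @export
setMethod("[", "WntParameterSet", function(x, i) {
  if (is.character(i)) i <- .resolveParamNames(i)
  x@values[i]
})

setMethod("show", "WntParameterSet", function(object) {
  cat("WntParameterSet: 42 parameters (37 rate constants,",
      "3 half-saturation constants, 2 Hill exponents)\n")
  dev <- which(object@values != .PARAM_TABLE$value)
  if (!length(dev)) {
    cat("  all at default values (nM, min)\n")
  } else {
    cat("  deviations from defaults:\n")
    for (i in dev)
      cat(sprintf("    %-5s %g (default %g) %s\n", .PARAM_TABLE$name[i],
                  object@values[i], .PARAM_TABLE$value[i],
                  .PARAM_TABLE$unit[i]))
  }
  invisible(object)
})
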