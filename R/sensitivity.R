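#' Scaled finite-difference sensitivity of a model output
#'
#' Generic central-difference engine: runs `runFn` at `(1 - delta) * x` and
#' `(1 + delta) * x` for the single parameter `paramName` and returns the
#' dimensionless scaled sensitivity (relative output change per relative
#' parameter change) against the baseline output,
#' `S = (Y(+) - Y(-)) / (2 * delta * Y(baseline))`.
#' Entries where the baseline output magnitude is below `floor` are NA.
#'
#' This is the engine behind [localSensitivity()] and [fluxSensitivity()];
#' it is exported so the protocol can be exercised on small closed-form
#' systems.
#'
#' @param runFn function taking a named numeric parameter vector and
#'   returning a numeric vector or matrix of outputs.
#' @param params named numeric baseline parameter vector.
#' @param paramName which parameter to perturb.
#' @param delta relative perturbation, in (0, 0.5] (default 0.01).
#' @param floor near-zero baseline floor (default 1e-9).
#' @param baseline optional precomputed `runFn(params)`.
#' @return scaled sensitivities, same shape as the output of `runFn`.
#' @examples
#' # birth-death system dX/dt = a - b X at equilibrium: the equilibrium
#' # degradation flux b * X* = a is sensitive to a (S = 1) but not to b.
#' eqFlux <- function(p) p[["b"]] * (p[["a"]] / p[["b"]])
#' scaledSensitivity(eqFlux, c(a = 2, b = 0.5), "a")
#' scaledSensitivity(eqFlux, c(a = 2, b = 0.5), "b")
#' @export
scaledSensitivity <- function(runFn, params, paramName, delta = 0.01,
                              floor = 1e-9, baseline = NULL) {
  stopifnot(delta > 0, delta <= 0.5, paramName %in% names(params))
  if (is.null(baseline)) baseline <- runFn(params)
  up <- params; up[paramName] <- up[paramName] * (1 + delta)
  dn <- params; dn[paramName] <- dn[paramName] * (1 - delta)
  S <- (runFn(up) - runFn(dn)) / (2 * delta * baseline)
  S[abs(baseline) < floor] <- NA_real_
  if (any(!is.finite(S) & !is.na(S)))
    warning("non-finite sensitivity entries for parameter ", paramName)
  S
}

# flux trajectories for one parameter vector (rows = times, cols = fluxes)
.fluxRun <- function(pv, init, settings) {
  params <- new("WntParameterSet", values = pv,
                units = defaultParameters()@units)
  traj <- simulateWnt(params, init, settings)
  st <- pmax(traj@states, 0)
  evaluateFluxes(st, params, mmp13Hill = settings$mmp13Hill)
}

#' Time-resolved local sensitivity of one reaction flux
#'
#' Central finite difference of a flux trajectory under a +/- `delta`
#' perturbation of one parameter, scaled by the baseline flux at each
#' output time. Times where the baseline flux magnitude is below
#' `fluxFloor` are NA.
#'
#' @param params a [WntParameterSet-class].
#' @param fluxId one of [reactionIds()].
#' @param paramName one of [parameterNames()] (aliases accepted).
#' @param delta relative perturbation (default 0.01).
#' @param init,settings simulation inputs, as in [simulateWnt()].
#' @param fluxFloor near-zero baseline-flux floor (default 1e-9 nM/min).
#' @return data.frame with columns `time_min` and `S`.
#' @export
localSensitivity <- function(params, fluxId, paramName, delta = 0.01,
                             init = initialState(),
                             settings = simulationSettings(),
                             fluxFloor = 1e-9) {
  stopifnot(fluxId %in% reactionIds())
  paramName <- .resolveParamNames(paramName)
  pv <- paramValues(params)
  S <- scaledSensitivity(function(p) .fluxRun(p, init, settings)[, fluxId],
                         pv, paramName, delta = delta, floor = fluxFloor)
  times <- seq(settings$tStart, settings$tEnd, by = settings$outputStep)
  data.frame(time_min = times, S = unname(S))
}

#' Full flux-by-parameter sensitivity matrix
#'
#' Computes, for every one of the 37 reaction fluxes and every one of the
#' 42 parameters (1554 entries), the time-aggregated scaled local
#' sensitivity under the documented protocol: central finite differences at
#' `delta` (default 1%), flux trajectories as the output, and aggregation
#' of S(t) over the post-transient window. The default aggregation takes
#' the entry of largest magnitude (keeping its sign: negative means the
#' flux decreases as the parameter increases); `"mean"` and `"end"`
#' (end-time value) are the alternative shipped rules. Hill exponents m3
#' and m27 are perturbed multiplicatively like every other parameter.
#' Entries whose baseline flux stays below `fluxFloor` across the window
#' are masked. A failed perturbed run masks its column and raises a
#' warning rather than aborting the matrix.
#'
#' @inheritParams localSensitivity
#' @param window length-2 numeric, aggregation window in minutes (default
#'   c(300, 1000), i.e. post-transient).
#' @param aggregate `"max"` (default), `"mean"` or `"end"`.
#' @return a [FluxSensitivity-class].
#' @export
fluxSensitivity <- function(params = defaultParameters(), delta = 0.01,
                            window = c(300, 1000),
                            aggregate = c("max", "mean", "end"),
                            init = initialState(),
                            settings = simulationSettings(),
                            fluxFloor = 1e-9) {
  aggregate <- match.arg(aggregate)
  stopifnot(delta > 0, delta <= 0.5)
  pv <- paramValues(params)
  Fb <- .fluxRun(pv, init, settings)
  times <- seq(settings$tStart, settings$tEnd, by = settings$outputStep)
  inWin <- times >= window[1] & times <= window[2]
  if (!any(inWin)) stop("aggregation window outside the simulated span",
                        call. = FALSE)
  aggFun <- switch(aggregate,
    max = function(s) { s <- s[is.finite(s)]
      if (!length(s)) NA_real_ else s[which.max(abs(s))] },
    mean = function(s) { s <- s[is.finite(s)]
      if (!length(s)) NA_real_ else mean(s) },
    end = function(s) { s <- s[is.finite(s)]
      if (!length(s)) NA_real_ else s[length(s)] })
  nm <- parameterNames()
  S <- matrix(NA_real_, 37L, 42L, dimnames = list(reactionIds(), nm))
  masked <- matrix(FALSE, 37L, 42L, dimnames = dimnames(S))
  for (j in nm) {
    St <- tryCatch(
      scaledSensitivity(function(p) .fluxRun(p, init, settings), pv, j,
                        delta = delta, floor = fluxFloor, baseline = Fb),
      error = function(e) {
        warning("perturbed run failed for ", j, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(St)) { masked[, j] <- TRUE; next }
    Sw <- St[inWin, , drop = FALSE]
    S[, j] <- apply(Sw, 2, aggFun)
    masked[, j] <- colSums(is.finite(Sw)) == 0L
  }
  new("FluxSensitivity", S = S, masked = masked,
      protocol = list(delta = delta, window = window,
                      aggregate = aggregate, fluxFloor = fluxFloor,
                      output = "reaction fluxes",
                      scheme = "central difference",
                      settings = settings))
}

#' Access the sensitivity matrix and protocol
#'
#' @param object a [FluxSensitivity-class].
#' @return `sensValues`: the signed 37 x 42 matrix; `sensProtocol`: the
#'   protocol metadata list.
#' @export
sensValues <- function(object) {
  stopifnot(is(object, "FluxSensitivity"))
  object@S
}

#' @rdname sensValues
#' @export
sensProtocol <- function(object) {
  stopifnot(is(object, "FluxSensitivity"))
  object@protocol
}

setMethod("show", "FluxSensitivity", function(object) {
  cat("FluxSensitivity: 37 fluxes x 42 parameters (1554 entries)\n")
  cat(sprintf("  protocol: %s, delta = %g, %s over [%g, %g] min\n",
              object@protocol$scheme, object@protocol$delta,
              object@protocol$aggregate, object@protocol$window[1],
              object@protocol$window[2]))
  cat(sprintf("  masked entries: %d\n", sum(object@masked)))
  invisible(object)
})

#' Screen parameters by the number of reactions they affect
#'
#' Counts, for every parameter, the reaction fluxes whose aggregated
#' sensitivity magnitude exceeds `threshold` (default 2, the conventional
#' "major influence" screen), and ranks parameters by that count
#' (descending), breaking ties by the largest |S| and then by name.
#'
#' @param sens a [FluxSensitivity-class].
#' @param threshold screening threshold on |S| (default 2).
#' @return data.frame with columns `parameter`, `nAffected`, `maxAbsS`,
#'   `rank`, one row per parameter, sorted.
#' @export
screenParameters <- function(sens, threshold = 2) {
  stopifnot(is(sens, "FluxSensitivity"))
  A <- abs(sens@S)
  cnt <- apply(A, 2, function(a) sum(a > threshold, na.rm = TRUE))
  mx <- apply(A, 2, function(a) if (all(is.na(a))) NA_real_
                                else max(a, na.rm = TRUE))
  out <- data.frame(parameter = colnames(A), nAffected = as.integer(cnt),
                    maxAbsS = unname(mx), stringsAsFactors = FALSE)
  out <- out[order(-out$nAffected, -out$maxAbsS, out$parameter), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Export a sensitivity matrix to CSV
#'
#' Rows are reactions (step labels), columns parameters; a header comment
#' records the protocol.
#'
#' @param sens a [FluxSensitivity-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSensitivity <- function(sens, path) {
  pr <- sens@protocol
  hdr <- sprintf("# scaled flux sensitivities; delta=%g window=[%g,%g] aggregate=%s floor=%g",
                 pr$delta, pr$window[1], pr$window[2], pr$aggregate,
                 pr$fluxFloor)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(reaction = rownames(sens@S), sens@S,
                              check.names = FALSE),
                   con, row.names = FALSE)
  invisible(path)
}

#' Export a screening report to JSON
#'
#' @param screening data.frame from [screenParameters()].
#' @param path output file path.
#' @param protocol optional protocol list recorded alongside the table.
#' @return the path, invisibly.
#' @export
writeScreening <- function(screening, path, protocol = NULL) {
  payload <- list(screening = screening)
  if (!is.null(protocol))
    payload$protocol <- protocol[c("delta", "window", "aggregate",
                                   "fluxFloor")]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
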