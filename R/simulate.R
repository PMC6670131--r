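#' Simulation settings
#'
#' Time grid, solver tolerances and solver choice for [simulateWnt()]. The
#' 1-minute output step is the reporting resolution (internal solver steps
#' are adaptive); the default 1000-minute horizon covers the initial
#' transient plus several oscillation cycles. The default absolute
#' tolerance of 1e-8 is applied to all variables; the stiff (BDF) solver is
#' the default because the rate constants span nine orders of magnitude
#' (8.22e-5 to 206 per minute).
#'
#' @param tStart,tEnd simulation window, minutes.
#' @param outputStep output grid spacing, minutes.
#' @param atol,rtol absolute and relative solver tolerances.
#' @param solver `"stiff"` (BDF), `"nonstiff"` (Adams) or `"auto"` (lsoda).
#' @param mmp13Hill regulatory form of MMP-13 synthesis, see
#'   [evaluateFluxes()].
#' @param seed integer or NULL; unused by the deterministic core but
#'   recorded in the settings snapshot.
#' @return a list of class-checked settings.
#' @export
simulationSettings <- function(tStart = 0, tEnd = 1000, outputStep = 1,
                               atol = 1e-8, rtol = 1e-6,
                               solver = c("stiff", "nonstiff", "auto"),
                               mmp13Hill = c("activating", "printed"),
                               seed = NULL) {
  solver <- match.arg(solver)
  mmp13Hill <- match.arg(mmp13Hill)
  stopifnot(tEnd > tStart, outputStep > 0, atol > 0, rtol > 0)
  list(tStart = tStart, tEnd = tEnd, outputStep = outputStep,
       atol = atol, rtol = rtol, solver = solver,
       mmp13Hill = mmp13Hill, seed = seed)
}

.deSolveMethod <- function(solver)
  switch(solver, stiff = "bdf", nonstiff = "adams", auto = "lsoda")

#' Simulate the pathway model
#'
#' Integrates the 25-species network with an adaptive stiff-capable solver
#' from deSolve and returns the solution on a uniform output grid. Solver
#' failure (step-size underflow, too many steps) raises an error carrying
#' the solver diagnostic; a truncated trajectory is never returned
#' silently.
#'
#' @param params a [WntParameterSet-class]; default [defaultParameters()].
#' @param init named numeric initial state (nM); default [initialState()].
#' @param settings list from [simulationSettings()].
#' @return a [WntTrajectory-class].
#' @examples
#' tr <- simulateWnt(settings = simulationSettings(tEnd = 50))
#' head(as.data.frame(tr))[, 1:4]
#' @export
simulateWnt <- function(params = defaultParameters(),
                        init = initialState(),
                        settings = simulationSettings()) {
  stopifnot(is(params, "WntParameterSet"))
  init <- .checkState(init)[1, ]
  times <- seq(settings$tStart, settings$tEnd, by = settings$outputStep)
  pv <- paramValues(params)
  mmpAct <- settings$mmp13Hill == "activating"
  derivs <- function(t, y, parms) {
    y <- pmax(y, 0)  # guard the Hill terms against round-off undershoot
    list(.rhsFast(y, pv, mmpAct))
  }
  out <- withCallingHandlers(
    deSolve::ode(y = init, times = times, func = derivs, parms = NULL,
                 method = .deSolveMethod(settings$solver),
                 atol = settings$atol, rtol = settings$rtol,
                 maxsteps = 50000),
    warning = function(w) invokeRestart("muffleWarning"))
  istate <- attr(out, "istate")
  ok <- !is.null(istate) && istate[1] >= 0 && nrow(out) == length(times)
  if (!ok)
    stop("ODE solver failed (istate = ", istate[1], ", returned ",
         nrow(out), "/", length(times), " time points); ",
         "consider the stiff solver or looser tolerances", call. = FALSE)
  diag <- list(success = TRUE,
               steps = unname(istate[3]),
               rhsEvaluations = unname(istate[4]),
               jacobianEvaluations = unname(istate[5]),
               method = .deSolveMethod(settings$solver))
  states <- unname(out[, -1, drop = FALSE])
  colnames(states) <- speciesNames()
  new("WntTrajectory", time = as.numeric(out[, 1]), states = states,
      parameters = params, settings = settings, diagnostics = diag)
}

# mass-action RHS in plain vectors, no name lookups: the solver hot path
.rhsFast <- function(y, p, mmpAct) {
  hill3 <- p[["V3"]] * p[["K3"]]^p[["m3"]] /
    (p[["K3"]]^p[["m3"]] + y[1]^p[["m3"]])
  dsh <- p[["k8"]] * y[8] * y[11] / (p[["K8"]] + y[11])
  bt <- y[23]
  hill27 <- if (mmpAct)
    p[["V27"]] * bt^p[["m27"]] / (p[["K27"]]^p[["m27"]] + bt^p[["m27"]])
  else
    p[["V27"]] * p[["K27"]]^p[["m27"]] /
      (p[["K27"]]^p[["m27"]] + bt^p[["m27"]])
  b4 <- p[["k4"]] * y[2] * y[3];  u4 <- p[["km4"]] * y[4]
  b5 <- p[["k5"]] * y[5] * y[6];  u5 <- p[["km5"]] * y[7]
  b6 <- p[["k6"]] * y[3] * y[7];  u6 <- p[["km6"]] * y[8]
  b7 <- p[["k7"]] * y[10] * y[5]; u7 <- p[["km7"]] * y[9]
  rel10 <- p[["k10"]] * y[13] * y[12]
  b11 <- p[["k11"]] * y[15] * y[16]; u11 <- p[["km11"]] * y[13]
  ph12 <- p[["k12"]] * y[13]; dp12 <- p[["km12"]] * y[14]
  b13 <- p[["k13"]] * y[17] * y[10]; u13 <- p[["km13"]] * y[16]
  b14 <- p[["k14"]] * y[14] * y[21]; u14 <- p[["km14"]] * y[18]
  ph15 <- p[["k15"]] * y[18]
  rel16 <- p[["k16"]] * y[19]
  b20 <- p[["k20"]] * y[17] * y[21]; u20 <- p[["km20"]] * y[24]
  b23 <- p[["k23"]] * y[21] * y[22]; u23 <- p[["km23"]] * y[23]
  c(
    p[["k1"]] - p[["k2"]] * y[1],                       # HOTAIR
    hill3 + u4 - b4,                                    # WIF-1
    u4 - b4 + u6 - b6,                                  # Wnt
    b4 - u4,                                            # WIF-1.Wnt
    u5 - b5 + u7 - b7,                                  # LRP5/6
    u5 - b5,                                            # Fzl
    b5 - u5 + u6 - b6,                                  # Fzl.LRP5/6
    b6 - u6,                                            # Wnt.Fzl.LRP5/6
    b7 - u7,                                            # Axin.LRP5/6
    p[["k18"]] - p[["k19"]] * y[10] + u13 - b13 + u7 - b7 +
      p[["k24"]] * (y[23] + y[21]),                     # Axin
    p[["k9"]] * y[12] - dsh,                            # Dsh_i
    dsh - p[["k9"]] * y[12],                            # Dsh_a
    -rel10 - u11 - ph12 + dp12 + b11,                   # APC.Axin.GSK3
    rel16 + ph12 - dp12 + u14 - b14,                    # APC*.Axin*.GSK3
    rel10 + u11 - b11,                                  # GSK3
    rel10 + u11 - b11 - u13 + b13,                      # APC.Axin
    -b20 + u20 + u13 - b13,                             # APC
    -ph15 - u14 + b14,                                  # Bcat.APC*.Axin*.GSK3
    ph15 - rel16,                                       # Bcatp complex
    rel16 - p[["k17"]] * y[20],                         # Bcatp
    p[["k21"]] - p[["k22"]] * y[21] - b23 + u23 - b20 + u20 +
      u14 - b14,                                        # Bcat
    u23 - b23,                                          # TCF
    b23 - u23,                                          # Bcat.TCF
    b20 - u20,                                          # Bcat.APC
    p[["k25"]] + hill27 - p[["k26"]] * y[25])           # MMP-13
}

#' Accessors for trajectories
#'
#' @param traj a [WntTrajectory-class].
#' @param species a species name (aliases accepted).
#' @return `trajTime`: the time grid (min); `trajStates`: the raw
#'   concentration matrix (nM); `speciesSeries`: one species' time course.
#' @export
trajTime <- function(traj) { stopifnot(is(traj, "WntTrajectory")); traj@time }

#' @rdname trajTime
#' @export
trajStates <- function(traj) {
  stopifnot(is(traj, "WntTrajectory"))
  traj@states
}

#' @rdname trajTime
#' @export
speciesSeries <- function(traj, species) {
  stopifnot(is(traj, "WntTrajectory"))
  traj@states[, .resolveSpeciesNames(species)]
}

#' @rdname trajTime
#' @export
trajParameters <- function(traj) {
  stopifnot(is(traj, "WntTrajectory"))
  traj@parameters
}

#' @rdname trajTime
#' @export
trajSettings <- function(traj) {
  stopifnot(is(traj, "WntTrajectory"))
  traj@settings
}

setMethod("show", "WntTrajectory", function(object) {
  cat(sprintf(
    "WntTrajectory: %d time points over [%g, %g] min, 25 species\n",
    length(object@time), min(object@time), max(object@time)))
  cat(sprintf("  solver %s, atol %g, rtol %g, %d internal steps\n",
              object@diagnostics$method, object@settings$atol,
              object@settings$rtol, object@diagnostics$steps))
  invisible(object)
})

#' Coerce a trajectory to a data.frame (wide format)
#'
#' @param x a [WntTrajectory-class].
#' @param row.names,optional ignored (S3 signature).
#' @param clip clip negative round-off values to zero (default TRUE; the
#'   raw solution in the object is untouched).
#' @param ... ignored.
#' @return data.frame with `time_min` plus one column per species.
#' @export
as.data.frame.WntTrajectory <- function(x, row.names = NULL,
                                        optional = FALSE, clip = TRUE, ...) {
  st <- x@states
  if (clip) st[st < 0] <- 0
  data.frame(time_min = x@time, st, check.names = FALSE)
}

#' Long-format view of a trajectory
#'
#' @inheritParams as.data.frame.WntTrajectory
#' @param traj a [WntTrajectory-class].
#' @return data.frame with columns `time_min`, `species`,
#'   `concentration_nM`.
#' @export
tidyTrajectory <- function(traj, clip = TRUE) {
  st <- traj@states
  if (clip) st[st < 0] <- 0
  data.frame(
    time_min = rep(traj@time, times = ncol(st)),
    species = rep(colnames(st), each = nrow(st)),
    concentration_nM = as.vector(st),
    stringsAsFactors = FALSE)
}

#' Write a trajectory to CSV
#'
#' The header comment records the parameter hash and solver settings so a
#' file can be traced back to the run that produced it.
#'
#' @param traj a [WntTrajectory-class].
#' @param path output file path.
#' @param format `"wide"` (time + 25 species columns) or `"tidy"`
#'   (time_min, species, concentration_nM).
#' @return the path, invisibly.
#' @export
writeTrajectory <- function(traj, path, format = c("wide", "tidy")) {
  format <- match.arg(format)
  df <- if (format == "wide") as.data.frame(traj) else tidyTrajectory(traj)
  hdr <- sprintf(
    "# params_md5=%s solver=%s atol=%g rtol=%g t=[%g,%g] step=%g",
    parameterHash(traj@parameters), traj@settings$solver,
    traj@settings$atol, traj@settings$rtol, traj@settings$tStart,
    traj@settings$tEnd, traj@settings$outputStep)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Validate a trajectory
#'
#' Reports the maximum drift of each conserved-moiety total from its initial
#' value, the most negative concentration, and the solver diagnostics, and
#' flags violations (drift above `100 * atol`; concentrations below
#' `-10 * atol`).
#'
#' @param traj a [WntTrajectory-class].
#' @return list with elements `conservation` (named drift vector),
#'   `violatedMoieties`, `minConcentration`, `nonNegativeOK`,
#'   `conservationOK`, `solver`, and overall `ok`.
#' @export
checkTrajectory <- function(traj) {
  stopifnot(is(traj, "WntTrajectory"))
  tot <- conservedTotals(traj@states)
  drift <- apply(tot, 2, function(v) max(abs(v - v[1])))
  atol <- traj@settings$atol
  consOK <- drift <= 100 * atol
  minC <- min(traj@states)
  nonNegOK <- minC >= -10 * atol
  list(conservation = drift,
       violatedMoieties = names(drift)[!consOK],
       conservationOK = all(consOK),
       minConcentration = minC,
       nonNegativeOK = nonNegOK,
       solver = traj@diagnostics,
       ok = all(consOK) && nonNegOK && isTRUE(traj@diagnostics$success))
}
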