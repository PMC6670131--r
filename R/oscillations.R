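# local maxima / minima on a uniform grid; plateaus (exact ties between
# neighbouring samples) count once, at their midpoint
.localExtrema <- function(x, what = c("max", "min")) {
  what <- match.arg(what)
  d <- sign(diff(x))
  i <- which(d != 0)
  if (length(i) < 2L) return(integer())
  ds <- d[i]
  from <- if (what == "max") 1 else -1
  chg <- which(ds[-length(ds)] == from & ds[-1] == -from)
  as.integer(round((i[chg] + 1L + i[chg + 1L]) / 2))
}
.localMaxima <- function(x) .localExtrema(x, "max")
.localMinima <- function(x) .localExtrema(x, "min")

# quadratic (three-point parabola) refinement of an extremum location
.refineExtremum <- function(time, x, i) {
  if (i <= 1L || i >= length(x)) return(time[i])
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (denom == 0) return(time[i])
  h <- (time[i + 1] - time[i - 1]) / 2
  time[i] + 0.5 * h * (x[i - 1] - x[i + 1]) / denom
}

.windowed <- function(time, x, window) {
  if (window[2] <= window[1])
    stop("window must have positive length", call. = FALSE)
  if (window[1] < min(time) || window[2] > max(time))
    stop("series is shorter than the requested window", call. = FALSE)
  keep <- time >= window[1] & time <= window[2]
  list(time = time[keep], x = x[keep])
}

#' Classify the dynamic regime of a time course
#'
#' A series is `"oscillatory"` when it shows at least three alternating
#' local extrema with consistent peak spacing and a relative peak-to-trough
#' above the steady threshold; `"growing"` when the linear trend over the
#' window moves the level by more than `growthTol` of the mean (monotone
#' drift, in either direction); `"steady"` when the relative peak-to-trough
#' is below `steadyTol`; otherwise `"undetermined"`. All thresholds are
#' relative, so the classification is invariant to uniform rescaling.
#'
#' @param time,x numeric vectors, the time grid (min) and the series (nM).
#' @param window length-2 numeric, analysis window in min (default: the
#'   whole series); the series must cover it.
#' @param steadyTol relative peak-to-trough below which the series is
#'   steady (default 0.01).
#' @param growthTol relative level change over the window above which a
#'   trend is flagged (default 0.05).
#' @param spacingTol maximum coefficient of variation of peak spacings for
#'   an oscillation to count as regular (default 0.2).
#' @return one of `"steady"`, `"oscillatory"`, `"growing"`,
#'   `"undetermined"`.
#' @examples
#' t <- 0:700
#' classifyRegime(t, 10 + 3 * sin(2 * pi * t / 180))
#' classifyRegime(t, rep(5, length(t)))
#' @export
classifyRegime <- function(time, x, window = range(time),
                           steadyTol = 0.01, growthTol = 0.05,
                           spacingTol = 0.2) {
  w <- .windowed(time, x, window)
  time <- w$time; x <- w$x
  scale <- max(abs(mean(x)), max(abs(x)), .Machine$double.eps)
  relP2T <- (max(x) - min(x)) / scale
  pk <- .localMaxima(x); tr <- .localMinima(x)
  nExtrema <- length(pk) + length(tr)
  if (nExtrema >= 3L && length(pk) >= 2L && relP2T >= steadyTol) {
    spacing <- diff(time[pk])
    if (length(spacing) == 1L ||
        stats::sd(spacing) / mean(spacing) <= spacingTol)
      return("oscillatory")
  }
  slope <- unname(stats::coef(stats::lm(x ~ time))[2])
  span <- diff(range(time))
  if (abs(slope) * span > growthTol * scale) return("growing")
  if (relP2T < steadyTol) return("steady")
  "undetermined"
}

#' Oscillation period from peak spacing
#'
#' Locates the local maxima after the transient cut, refines each peak
#' position with a three-point parabola between grid points, and returns
#' the mean peak-to-peak spacing.
#'
#' @param time,x numeric vectors (min, nM).
#' @param transientEnd discard times before this cut (min, default 300).
#' @return period in minutes, or `NA_real_` when fewer than two
#'   post-transient peaks exist.
#' @examples
#' t <- 0:1000
#' measurePeriod(t, 10 + sin(2 * pi * t / 180), transientEnd = 0)
#' @export
measurePeriod <- function(time, x, transientEnd = 300) {
  keep <- time >= transientEnd
  time <- time[keep]; x <- x[keep]
  pk <- .localMaxima(x)
  if (length(pk) < 2L) return(NA_real_)
  tpk <- vapply(pk, function(i) .refineExtremum(time, x, i), numeric(1))
  mean(diff(tpk))
}

#' Oscillation amplitude (half peak-to-trough)
#'
#' Half of the max-minus-min of the series over a post-transient window
#' trimmed to an integer number of cycles (first to last refined peak).
#'
#' @inheritParams measurePeriod
#' @return amplitude in nM, or `NA_real_` when fewer than two
#'   post-transient peaks exist.
#' @examples
#' t <- 0:1000
#' measureAmplitude(t, 10 + 3 * sin(2 * pi * t / 180), transientEnd = 0)
#' @export
measureAmplitude <- function(time, x, transientEnd = 300) {
  keep <- time >= transientEnd
  time <- time[keep]; x <- x[keep]
  pk <- .localMaxima(x)
  if (length(pk) < 2L) return(NA_real_)
  tpk <- vapply(pk, function(i) .refineExtremum(time, x, i), numeric(1))
  inside <- time >= min(tpk) & time <= max(tpk)
  (max(x[inside]) - min(x[inside])) / 2
}

#' Detect the end of the initial transient
#'
#' First peak time after which every consecutive pair of peak heights
#' differs by less than `tol` relatively; falls back to `fallback` when no
#' such settling point exists (e.g. non-oscillatory series).
#'
#' @inheritParams measurePeriod
#' @param tol relative cycle-to-cycle peak-height tolerance (default 0.01).
#' @param fallback value returned when settling is not detected.
#' @return time in minutes.
#' @export
detectTransient <- function(time, x, tol = 0.01, fallback = 300) {
  pk <- .localMaxima(x)
  if (length(pk) < 3L) return(fallback)
  h <- x[pk]
  relDiff <- abs(diff(h)) / pmax(abs(h[-length(h)]), .Machine$double.eps)
  settled <- which(rev(cumprod(rev(relDiff < tol))) == 1)
  if (!length(settled)) return(fallback)
  time[pk[settled[1]]]
}

#' Summarize the oscillatory features of a trajectory
#'
#' For each requested species: the dynamic regime over the post-transient
#' window, the transient cut used, and (for oscillatory series) the period
#' and half peak-to-trough amplitude, plus the post-transient mean level.
#' Steady series get amplitude 0 and an undefined (NA) period.
#'
#' @param traj a [WntTrajectory-class].
#' @param species character vector (default: all 25 species).
#' @param transientEnd numeric cut in minutes (default 300), or `"auto"`
#'   to use [detectTransient()] per species.
#' @param ... thresholds passed to [classifyRegime()].
#' @return data.frame with one row per species: `species`, `regime`,
#'   `transient_end`, `period_min`, `amplitude_nM`, `mean_nM`.
#' @examples
#' tr <- simulateWnt(settings = simulationSettings(tEnd = 600))
#' summarizeOscillations(tr, c("Axin", "WIF1"))
#' @export
summarizeOscillations <- function(traj, species = speciesNames(),
                                  transientEnd = 300, ...) {
  stopifnot(is(traj, "WntTrajectory"))
  species <- .resolveSpeciesNames(species)
  time <- traj@time
  rows <- lapply(species, function(sp) {
    x <- traj@states[, sp]
    te <- if (identical(transientEnd, "auto"))
      detectTransient(time, x) else transientEnd
    te <- min(te, max(time) - 2 * diff(time[1:2]))
    regime <- classifyRegime(time, x, window = c(te, max(time)), ...)
    per <- amp <- NA_real_
    if (regime == "oscillatory") {
      per <- measurePeriod(time, x, transientEnd = te)
      amp <- measureAmplitude(time, x, transientEnd = te)
    } else if (regime == "steady") {
      amp <- 0
    }
    data.frame(species = sp, regime = regime, transient_end = te,
               period_min = per, amplitude_nM = amp,
               mean_nM = mean(x[time >= te]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an oscillation summary to JSON
#'
#' @param summary data.frame from [summarizeOscillations()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeOscillationSummary <- function(summary, path) {
  recs <- split(summary[setdiff(names(summary), "species")],
                summary$species)
  recs <- lapply(recs, function(r) as.list(r[1, ]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
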