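# shared fixtures: all generated in code, nothing read from disk

shortSettings <- function(tEnd = 400, ...) {
  simulationSettings(tEnd = tEnd, ...)
}

# random non-negative state vectors on a fixed seed, roughly on the scale
# of the model's concentrations
randomStates <- function(n, seed = 42, scale = 20) {
  set.seed(seed)
  m <- matrix(stats::runif(n * 25, 0, scale), nrow = n)
  colnames(m) <- speciesNames()
  m
}

# hand-built trajectory object around an arbitrary state matrix
fakeTrajectory <- function(states, time = seq_len(nrow(states)) - 1,
                           settings = simulationSettings()) {
  new("WntTrajectory", time = as.numeric(time), states = states,
      parameters = defaultParameters(), settings = settings,
      diagnostics = list(success = TRUE, steps = 0L, method = "none"))
}

# trajectory carrying a single synthetic series in one species column
sineTrajectory <- function(amplitude, period = 180, tEnd = 1000,
                           level = 10, species = "Axin") {
  t <- 0:tEnd
  st <- matrix(0, length(t), 25, dimnames = list(NULL, speciesNames()))
  st[, species] <- level + amplitude * sin(2 * pi * t / period)
  fakeTrajectory(st, t)
}
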