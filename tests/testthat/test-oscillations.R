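test_that("period estimator is grid-exact on pure sinusoids", {
  t <- seq(0, 1440, by = 1)
  for (P in c(30, 90, 180, 360)) {
    for (phase in c(0, 1, 2.5)) {
      x <- 10 + sin(2 * pi * t / P + phase)
      expect_lt(abs(measurePeriod(t, x, transientEnd = 0) - P), 0.5)
    }
  }
  # fewer than two post-transient peaks: period undetermined
  expect_true(is.na(measurePeriod(t, 10 + sin(2 * pi * t / 3000),
                                  transientEnd = 0)))
})

test_that("amplitude estimator recovers half peak-to-trough", {
  t <- 0:1000
  x <- 10 + 3 * sin(2 * pi * t / 180)
  expect_lt(abs(measureAmplitude(t, x, transientEnd = 0) - 3), 0.01)
  # unbiased under a mild linear trend (below the steady threshold)
  xt <- x + 2e-5 * t
  expect_lt(abs(measureAmplitude(t, xt, transientEnd = 0) - 3), 0.05)
  # the 30% relative-change comparison statistic on synthetic signals
  a1 <- measureAmplitude(t, 10 + 3.0 * sin(2 * pi * t / 180), 0)
  a2 <- measureAmplitude(t, 10 + 3.9 * sin(2 * pi * t / 180), 0)
  expect_equal(100 * (a2 - a1) / a1, 30, tolerance = 0.01)
})

test_that("regime classification separates steady, growing and oscillatory", {
  t <- 0:600
  expect_equal(classifyRegime(t, rep(5, length(t))), "steady")
  expect_equal(classifyRegime(t, 5 + 0.001 * t), "growing")
  tOsc <- seq(0, 630, by = 1)  # 3.5 cycles at period 180
  expect_equal(classifyRegime(tOsc, 10 + sin(2 * pi * tOsc / 180)),
               "oscillatory")
  # decline is a trend too
  expect_equal(classifyRegime(t, 5 - 0.001 * t), "growing")
  # irregular bursts: inconsistent spacing stays undetermined
  set.seed(1)
  spiky <- rep(1, length(t))
  spiky[c(50, 80, 300, 320, 590)] <- 5
  expect_equal(classifyRegime(t, spiky), "undetermined")
})

test_that("classification is invariant to uniform rescaling", {
  t <- 0:700
  signals <- list(rep(5, length(t)), 5 + 0.001 * t,
                  10 + sin(2 * pi * t / 180))
  for (x in signals)
    expect_equal(classifyRegime(t, x * 1000), classifyRegime(t, x))
})

test_that("trajectory summaries compose regime, period and amplitude", {
  tr <- sineTrajectory(amplitude = 3, period = 180, species = "Axin")
  s <- summarizeOscillations(tr, c("Axin", "MMP13"), transientEnd = 300)
  axin <- s[s$species == "Axin", ]
  expect_equal(axin$regime, "oscillatory")
  expect_equal(axin$period_min, 180, tolerance = 0.5)
  expect_equal(axin$amplitude_nM, 3, tolerance = 0.01)
  flat <- s[s$species == "MMP13", ]
  expect_equal(flat$regime, "steady")
  expect_equal(flat$amplitude_nM, 0)
  expect_true(is.na(flat$period_min))
  # JSON export round-trips the fields
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeOscillationSummary(s, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$Axin$regime, "oscillatory")
  expect_equal(parsed$MMP13$amplitude_nM, 0)
})

test_that("transient detection finds the settling time of a damped onset", {
  t <- 0:2000
  x <- 10 + (1 + 3 * exp(-t / 150)) * sin(2 * pi * t / 180)
  te <- detectTransient(t, x)
  expect_gt(te, 300)
  expect_lt(te, 1800)
  # constant series falls back
  expect_equal(detectTransient(t, rep(1, length(t))), 300)
})
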