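test_that("the HOTAIR knockout zeroes synthesis and the initial pool only", {
  ko <- hotairKnockout()
  expect_equal(unname(ko$params["k1"]), 0)
  expect_equal(ko$init[["Hotair"]], 0)
  base <- paramValues(defaultParameters())
  kov <- paramValues(ko$params)
  expect_equal(kov[names(kov) != "k1"], base[names(base) != "k1"])
  expect_equal(ko$init[names(ko$init) != "Hotair"],
               initialState()[names(ko$init) != "Hotair"])
  # WIF-1 synthesis is pinned at V3 throughout a knockout run
  tr <- runScenario(ko, shortSettings(tEnd = 200))
  fl <- evaluateFluxes(pmax(trajStates(tr), 0), trajParameters(tr))
  expect_true(all(abs(fl[, "r3"] - 1) < 1e-12))
})

test_that("a fold-change of 1 reproduces the baseline run exactly", {
  sett <- shortSettings(tEnd = 300)
  base <- simulateWnt(settings = sett)
  sc <- foldChangeScan(paramName = "k24", folds = c(1, 2),
                       settings = sett, species = "Axin")
  expect_identical(trajStates(sc[["1"]]$trajectory), trajStates(base))
  expect_false(identical(trajStates(sc[["2"]]$trajectory),
                         trajStates(base)))
  expect_equal(sc[["2"]]$value, 0.04)
})

test_that("preset scans carry the printed rate values", {
  pre <- axinScanPresets()
  expect_equal(unname(pre$k16$values), c(0.005, 0.5, 50))
  expect_equal(unname(pre$k19$values), c(0.00167, 0.167, 16.7))
  expect_equal(unname(pre$k24$values), c(0.0002, 0.02, 2))
})

test_that("trajectory comparison reports relative changes", {
  a <- sineTrajectory(amplitude = 3)
  expect_equal(
    compareTrajectories(a, a, "Axin")$amplitude_change_pct, 0,
    tolerance = 1e-10)
  b <- sineTrajectory(amplitude = 3.9)
  cmp <- compareTrajectories(a, b, "Axin")
  expect_equal(cmp$amplitude_change_pct, 30, tolerance = 0.1)
  # non-oscillatory branch is explicit, not a number
  flat <- sineTrajectory(amplitude = 0)
  cmp2 <- compareTrajectories(a, flat, "Axin")
  expect_true(is.na(cmp2$amplitude_change_pct))
  expect_equal(cmp2$regime_var, "steady")
  # different grids are rejected
  short <- sineTrajectory(amplitude = 3, tEnd = 500)
  expect_error(compareTrajectories(a, short, "Axin"), "grid")
})
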