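test_that("HOTAIR follows its first-order closed form", {
  # tolerances one notch below the 1e-6 agreement band, so the comparison
  # measures the model, not the requested solver accuracy
  tr <- simulateWnt(settings = shortSettings(tEnd = 300, atol = 1e-10,
                                             rtol = 1e-8))
  t <- trajTime(tr)
  h <- speciesSeries(tr, "Hotair")
  expect_lt(max(abs(h - 2 * (1 - exp(-0.1 * t)))), 1e-6)
  expect_lt(abs(h[t == 200] - 2), 1e-6)
})

test_that("conserved totals drift below 1e-5 nM over 1000 minutes", {
  tr <- simulateWnt()
  rep <- checkTrajectory(tr)
  expect_true(rep$ok)
  expect_true(all(rep$conservation < 1e-5))
  expect_gte(rep$minConcentration, -10 * trajSettings(tr)$atol)
})

test_that("solution is stable under tolerance refinement", {
  a <- simulateWnt(settings = shortSettings(tEnd = 600))
  b <- simulateWnt(settings = shortSettings(tEnd = 600, atol = 5e-9,
                                            rtol = 5e-7))
  xa <- trajStates(a)[601, ]
  xb <- trajStates(b)[601, ]
  expect_lt(max(abs(xa - xb) / pmax(abs(xa), 1e-6)), 1e-4)
})

test_that("total WIF-1 grows at exactly the maximal synthesis rate without HOTAIR", {
  ko <- hotairKnockout()
  tr <- runScenario(ko, shortSettings(tEnd = 300))
  tot <- rowSums(trajStates(tr)[, c("WIF1", "WIF1_Wnt")])
  slopes <- diff(tot) / diff(trajTime(tr))
  expect_lt(max(abs(slopes - 1)), 1e-4)
})

test_that("trajectory export formats are consistent", {
  tr <- simulateWnt(settings = shortSettings(tEnd = 50))
  wide <- as.data.frame(tr)
  expect_equal(dim(wide), c(51L, 26L))
  expect_equal(names(wide)[1], "time_min")
  tall <- tidyTrajectory(tr)
  expect_equal(nrow(tall), 51 * 25)
  expect_setequal(unique(tall$species), speciesNames())
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  writeTrajectory(tr, f)
  expect_match(readLines(f, n = 1), "params_md5=")
  reread <- utils::read.csv(f, comment.char = "#", check.names = FALSE)
  expect_equal(dim(reread), dim(wide))
})

test_that("trajectory validation flags injected violations", {
  tr <- simulateWnt(settings = shortSettings(tEnd = 200))
  expect_true(checkTrajectory(tr)$ok)
  # perturb the GSK3 column: the GSK3 moiety total must be flagged
  st <- trajStates(tr)
  st[100, "GSK3"] <- st[100, "GSK3"] + 1
  bad <- fakeTrajectory(st, trajTime(tr), settings = trajSettings(tr))
  rep <- checkTrajectory(bad)
  expect_false(rep$conservationOK)
  expect_true("GSK3" %in% rep$violatedMoieties)
  # a clearly negative concentration must be flagged
  st2 <- trajStates(tr)
  st2[100, "Axin"] <- -1
  rep2 <- checkTrajectory(fakeTrajectory(st2, trajTime(tr),
                                         settings = trajSettings(tr)))
  expect_false(rep2$nonNegativeOK)
})
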