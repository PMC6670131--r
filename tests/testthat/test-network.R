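test_that("default parameter set matches the published kinetic constants", {
  p <- defaultParameters()
  v <- paramValues(p)
  expect_length(v, 42)
  expect_length(parameterNames(rateConstantsOnly = TRUE), 37)
  expect_equal(v[["k1"]], 0.2)
  expect_equal(v[["k2"]], 0.1)
  expect_equal(v[["V3"]], 1)
  expect_equal(v[["k14"]], 120)
  expect_equal(v[["k15"]], 206)
  expect_equal(v[["k18"]], 8.22e-5)
  expect_equal(v[["k21"]], 0.423)
  expect_equal(v[["k22"]], 0.000257)
  expect_equal(v[["k24"]], 0.02)
  expect_equal(v[["K3"]], 0.1)
  expect_equal(v[["K8"]], 10)
  expect_equal(v[["m3"]], 4)
  expect_equal(v[["m27"]], 4)
  u <- paramUnits(p)
  expect_equal(u[["k1"]], "nM/min")
  expect_equal(u[["k14"]], "1/(nM*min)")
  # alias access and override validation
  expect_equal(p["k-11"], c(km11 = 100))
  expect_equal(paramValues(wntParameters(k24 = 2))[["k24"]], 2)
  expect_error(wntParameters(k99 = 1), "k99")
  expect_error(wntParameters(k24 = -1), "non-positive")
})

test_that("initial state carries the published concentrations and overrides", {
  s <- initialState()
  expect_length(s, 25)
  expect_equal(s[["Wnt"]], 10)
  expect_equal(s[["Fzl"]], 10)
  expect_equal(s[["WIF1"]], 10)
  expect_equal(s[["Dsh_i"]], 100)
  expect_equal(s[["APC"]], 100)
  expect_equal(s[["TCF"]], 15)
  expect_equal(s[["GSK3"]], 50)
  complexes <- c("WIF1_Wnt", "Fzl_LRP56", "Wnt_Fzl_LRP56", "Axin_LRP56",
                 "APC_Axin_GSK3", "APCp_Axinp_GSK3", "APC_Axin",
                 "Bcat_APCp_Axinp_GSK3", "Bcatp_APCp_Axinp_GSK3",
                 "Bcat_TCF", "Bcat_APC")
  expect_true(all(s[complexes] == 0))
  s2 <- initialState(c(Wnt = 0))
  expect_equal(s2[["Wnt"]], 0)
  expect_equal(s2[-match("Wnt", names(s2))], s[-match("Wnt", names(s))])
  expect_equal(initialState(list("LRP5/6" = 3))[["LRP56"]], 3)
  expect_error(initialState(c(Wnt9 = 1)), "Wnt9")
})

test_that("network dimensions are 25 species, 37 reactions, 42 parameters", {
  expect_length(speciesNames(), 25)
  expect_length(reactionIds(), 37)
  expect_length(parameterNames(), 42)
  N <- stoichiometryMatrix()
  expect_equal(dim(N), c(25L, 37L))
  expect_equal(nrow(reactionTable()), 37)
  # every reaction is tied to exactly one distinct rate constant
  expect_equal(sort(reactionTable()$parameter),
               sort(parameterNames(rateConstantsOnly = TRUE)))
})

test_that("fluxes at reference states match hand evaluation", {
  p <- defaultParameters()
  zero <- setNames(numeric(25), speciesNames())
  f <- evaluateFluxes(zero, p)
  expect_equal(f[["r1"]], 0.2)
  expect_equal(f[["r18"]], 8.22e-5)
  expect_equal(f[["r21"]], 0.423)
  expect_equal(f[["r25"]], 0.1)
  expect_equal(f[["r3"]], 1)  # Hill repression fully released at zero HOTAIR
  expect_equal(f[["r27"]], 0) # activating Hill at zero beta-catenin.TCF
  others <- setdiff(reactionIds(), c("r1", "r18", "r21", "r25", "r3"))
  expect_true(all(f[others] == 0))
  # Hill half-saturation: HOTAIR at K3 halves the WIF-1 synthesis flux
  half <- zero; half["Hotair"] <- 0.1
  expect_equal(evaluateFluxes(half, p)[["r3"]], 0.5)
  # printed (repressive) MMP-13 form: full rate V27 at zero complex
  expect_equal(evaluateFluxes(zero, p, mmp13Hill = "printed")[["r27"]], 0.1)
  expect_error(evaluateFluxes(zero - 1, p), "negative")
})

test_that("right-hand side matches hand-computed derivatives", {
  p <- defaultParameters()
  zero <- setNames(numeric(25), speciesNames())
  d <- evaluateRHS(zero, p)
  expect_equal(d[["Hotair"]], 0.2)
  expect_equal(d[["WIF1"]], 1.0)
  expect_equal(d[["Axin"]], 8.22e-5)
  expect_equal(d[["Bcat"]], 0.423)
  # fixed point of the HOTAIR equation at k1/k2
  fp <- zero; fp["Hotair"] <- 2
  expect_equal(evaluateRHS(fp, p)[["Hotair"]], 0)
})

test_that("stoichiometry x flux and direct transcription agree on random states", {
  p <- defaultParameters()
  states <- randomStates(1000)
  for (i in seq_len(nrow(states))) {
    d1 <- evaluateRHS(states[i, ], p, method = "stoichiometry")
    d2 <- evaluateRHS(states[i, ], p, method = "direct")
    expect_lt(max(abs(d1 - d2)) / max(abs(d2), 1e-300), 1e-12)
  }
})

test_that("the seven conserved moieties are invariant", {
  N <- stoichiometryMatrix()
  mo <- conservedMoieties()
  expect_length(mo, 7)
  # zero net stoichiometry in every reaction, per moiety
  for (m in names(mo)) {
    cvec <- as.numeric(speciesNames() %in% mo[[m]])
    expect_equal(unname(drop(cvec %*% N)), rep(0, 37))
  }
  # hence zero time derivative of each total on random states
  p <- defaultParameters()
  states <- randomStates(50, seed = 7)
  for (i in seq_len(nrow(states))) {
    d <- evaluateRHS(states[i, ], p)
    f <- evaluateFluxes(states[i, ], p)
    for (m in names(mo))
      expect_lte(abs(sum(d[mo[[m]]])), 1e-12 * max(abs(f)))
  }
  # totals at the default initial state
  tot <- conservedTotals(initialState())
  expect_equal(tot[["Wnt"]], 10)
  expect_equal(tot[["Dsh"]], 100)
  expect_equal(tot[["GSK3"]], 50)
  expect_equal(tot[["APC"]], 100)
  expect_equal(tot[["TCF"]], 15)
  expect_true(all(conservedTotals(setNames(numeric(25), speciesNames()))
                  == 0))
})

test_that("all fluxes are non-negative on non-negative states", {
  p <- defaultParameters()
  states <- randomStates(200, seed = 11)
  F <- evaluateFluxes(states, p)
  expect_true(all(F >= 0))
})
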