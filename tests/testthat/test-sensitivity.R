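test_that("scaled sensitivities match closed forms on a birth-death system", {
  # dX/dt = a - b X; equilibrium X* = a/b, equilibrium degradation flux
  # b X* = a: sensitivity 1 to the birth rate, 0 to the decay rate
  eqFlux <- function(p) p[["b"]] * (p[["a"]] / p[["b"]])
  p0 <- c(a = 2, b = 0.5)
  expect_lt(abs(scaledSensitivity(eqFlux, p0, "a") - 1), 0.01)
  expect_lt(abs(scaledSensitivity(eqFlux, p0, "b")), 0.01)
  # same law integrated as an ODE rather than in closed form
  decayFluxEnd <- function(p) {
    tr <- deSolve::ode(c(X = 0), seq(0, 40, 1),
                       function(t, y, q) list(q[["a"]] - q[["b"]] * y),
                       p, atol = 1e-10, rtol = 1e-8)
    p[["b"]] * tr[nrow(tr), "X"]
  }
  expect_lt(abs(scaledSensitivity(decayFluxEnd, p0, "a") - 1), 0.01)
  expect_lt(abs(scaledSensitivity(decayFluxEnd, p0, "b")), 0.01)
})

test_that("HOTAIR turnover flux has unit sensitivity to its synthesis rate", {
  # at equilibrium the degradation flux k2 [HOTAIR] equals k1: the scaled
  # sensitivity of that flux is 1 for k1 and 0 for k2
  p <- defaultParameters()
  sett <- shortSettings(tEnd = 400)
  s1 <- localSensitivity(p, "r2", "k1", settings = sett)
  s2 <- localSensitivity(p, "r2", "k2", settings = sett)
  expect_lt(abs(tail(s1$S, 1) - 1), 1e-3)
  expect_lt(abs(tail(s2$S, 1)), 1e-3)
})

test_that("structurally independent parameters have zero sensitivity", {
  # HOTAIR synthesis flux cannot depend on the MMP-13 degradation rate
  p <- defaultParameters()
  s <- localSensitivity(p, "r1", "k26", settings = shortSettings(tEnd = 100))
  expect_true(all(s$S == 0))
})

test_that("finite-difference sensitivities converge as delta shrinks", {
  sett <- simulationSettings(tEnd = 500)
  pv <- paramValues(defaultParameters())
  run <- function(p) HotairWnt:::.fluxRun(p, initialState(), sett)
  base <- run(pv)
  win <- seq(0, 500, 1) >= 300
  aggMax <- function(S) apply(S[win, , drop = FALSE], 2, function(s) {
    s <- s[is.finite(s)]
    if (!length(s)) NA_real_ else s[which.max(abs(s))]
  })
  a1 <- aggMax(scaledSensitivity(run, pv, "k24", delta = 0.01,
                                 baseline = base))
  a2 <- aggMax(scaledSensitivity(run, pv, "k24", delta = 0.005,
                                 baseline = base))
  keep <- is.finite(a1) & is.finite(a2) & (abs(a1) > 0.5 | abs(a2) > 0.5)
  expect_gt(sum(keep), 5)
  expect_lt(max(abs(a1[keep] - a2[keep]) / pmax(abs(a1[keep]),
                                                abs(a2[keep]))), 0.05)
})

test_that("time-resolved sensitivities are deterministic", {
  p <- defaultParameters()
  sett <- shortSettings(tEnd = 200)
  s1 <- localSensitivity(p, "r19", "k24", settings = sett)
  s2 <- localSensitivity(p, "r19", "k24", settings = sett)
  expect_identical(s1, s2)
})

test_that("screening counts, ordering and tie-breaks follow the rules", {
  # hand-built matrix: exercises screenParameters without simulation
  S <- matrix(0, 37, 42,
              dimnames = list(reactionIds(), parameterNames()))
  masked <- matrix(FALSE, 37, 42, dimnames = dimnames(S))
  S[1:5, "k24"] <- 4        # 5 fluxes above threshold, max 4
  S[1:5, "k16"] <- -3.5     # tie on count, smaller magnitude
  S[1:2, "k19"] <- 10
  fs <- new("FluxSensitivity", S = S, masked = masked,
            protocol = list(delta = 0.01, window = c(300, 1000),
                            aggregate = "max", fluxFloor = 1e-9,
                            scheme = "central difference"))
  sc <- screenParameters(fs, threshold = 2)
  expect_equal(sc$parameter[1:3], c("k24", "k16", "k19"))
  expect_equal(sc$nAffected[1:3], c(5L, 5L, 2L))
  expect_equal(sc$rank, seq_len(42))
  # monotone in the threshold
  sc3 <- screenParameters(fs, threshold = 3)
  expect_true(all(sc3$nAffected[match(sc$parameter, sc3$parameter)] <=
                  sc$nAffected))
  # all-zero matrix: every count zero
  fs0 <- new("FluxSensitivity", S = S * 0, masked = masked,
             protocol = fs@protocol)
  expect_true(all(screenParameters(fs0)$nAffected == 0))
})

test_that("sensitivity exports carry the matrix and the protocol", {
  S <- matrix(rnorm(37 * 42), 37, 42,
              dimnames = list(reactionIds(), parameterNames()))
  fs <- new("FluxSensitivity", S = S,
            masked = matrix(FALSE, 37, 42, dimnames = dimnames(S)),
            protocol = list(delta = 0.01, window = c(300, 1000),
                            aggregate = "max", fluxFloor = 1e-9,
                            scheme = "central difference"))
  fcsv <- tempfile(fileext = ".csv")
  fjson <- tempfile(fileext = ".json")
  on.exit(unlink(c(fcsv, fjson)))
  writeSensitivity(fs, fcsv)
  m <- utils::read.csv(fcsv, comment.char = "#", check.names = FALSE)
  expect_equal(dim(m), c(37L, 43L))
  expect_equal(m$reaction, reactionIds())
  writeScreening(screenParameters(fs), fjson, protocol = sensProtocol(fs))
  parsed <- jsonlite::read_json(fjson)
  expect_length(parsed$screening, 42)
  expect_equal(parsed$protocol$aggregate, "max")
})
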