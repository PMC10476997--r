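test_that("alpha collapses to the anoxic and aerobic fit constants", {
  # p = 0: a3 + a4 * L
  expect_equal(alphaOer(10, 0), 0.010 + 0.0100 * 10, tolerance = 1e-12)
  # p -> Inf: a1 + a2 * L
  expect_equal(alphaOer(0, 1e6), 0.10, tolerance = 1e-4)
  expect_equal(alphaOer(5, 3), ((0.10 + 0.0010 * 5) * 3 +
                                  (0.010 + 0.0100 * 5) * 3) / 6,
               tolerance = 1e-12)
  expect_error(alphaOer(-1, 5), "nonnegative")
  expect_error(alphaOer(1, -5), "nonnegative")
})

test_that("beta honors both parametrization conventions", {
  lin <- oerParams(betaConvention = "linear")
  sq <- oerParams(betaConvention = "sqrt")
  expect_equal(betaOer(0, lin), 0.273, tolerance = 1e-12)
  expect_equal(betaOer(1e6, lin), 0.765, tolerance = 1e-4)
  expect_equal(betaOer(3, sq), ((0.765 * 3 + 0.273 * 3) / 6)^2,
               tolerance = 1e-12)
  expect_error(betaOer(-2), "nonnegative")
})

test_that("OER is exactly 1 at the reference pressure and under normoxia", {
  for (L in c(0, 2, 5, 10, 15)) {
    expect_identical(oer(L, 30), 1)
    expect_identical(oer(L, 65), 1)
    expect_identical(oer(L, 200), 1)
  }
  # between the reference pressure and the normoxia threshold the floor
  # keeps the OER at >= 1
  expect_true(all(oer(2, c(35, 45, 55)) >= 1))
})

test_that("OER equals independently computed D10 ratios to 1e-12", {
  for (conv in c("sqrt", "linear")) {
    pr <- oerParams(betaConvention = conv, clampFloorOne = FALSE)
    for (L in c(0, 2, 5, 10, 15)) {
      for (p in c(0.5, 2.5, 5, 11, 30)) {
        expect_equal(oer(L, p, pr), oracleOer(L, p, conv),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("OER falls with oxygen pressure and with LET", {
  ps <- c(0.25, 0.5, 1, 2.5, 5, 11, 20, 30)
  for (L in c(0, 2, 5, 10, 15)) {
    vals <- oer(L, ps)
    expect_true(all(diff(vals) <= 1e-12),
                info = sprintf("monotone in p at L = %g", L))
  }
  Ls <- seq(0, 20, by = 2.5)
  for (p in c(0.5, 2.5, 5, 11)) {
    vals <- oer(Ls, p)
    expect_true(all(diff(vals) <= 1e-12),
                info = sprintf("monotone in L at p = %g", p))
  }
})

test_that("constant RBE 1.1 scales photon parameters", {
  got <- rbeParamsAerobic(rbeModel("constant_1p1"), 7,
                          tissueParams(0.1, 0.01))
  expect_equal(got$alpha, 0.11, tolerance = 1e-12)
  expect_equal(got$beta, 0.0121, tolerance = 1e-12)
})

test_that("variable RBE models evaluate their coefficient sets", {
  mcn <- rbeModel("MCN")
  tis <- tissueParams()
  at0 <- rbeParamsAerobic(mcn, 0, tis)
  # LET-zero intercepts straight from the coefficient file
  cf <- jsonlite::fromJSON(system.file("extdata", "rbe_coefficients.json",
                                       package = "rowdplan"))
  expect_equal(at0$alpha, tis@alphaX * cf$models$MCN$alpha_coeffs$intercept)
  expect_equal(at0$beta, tis@betaX * cf$models$MCN$beta_coeffs$intercept^2)
  # alpha strictly nondecreasing in LET (affine form)
  Ls <- seq(0, 15, by = 1)
  expect_true(all(diff(rbeParamsAerobic(mcn, Ls, tis)$alpha) >= 0))
  ror <- rbeModel("ROR_approx")
  expect_true(all(diff(rbeParamsAerobic(ror, Ls, tis)$alpha) >= 0))
  # beta of the ROR approximation is unscaled
  expect_equal(rbeParamsAerobic(ror, 8, tis)$beta, tis@betaX)
  expect_error(rbeModel("made_up"))
  expect_error(validObject(new("RbeModel", kind = "MCN",
                               alphaCoeffs = numeric(),
                               betaCoeffs = numeric(), provenance = "")),
               "coefficients")
})

test_that("hypoxic parameters scale aerobic ones by the OER", {
  expect_identical(hypoxicParams(0.11, 0.0121, 1),
                   list(alpha = 0.11, beta = 0.0121))
  got <- hypoxicParams(0.11, 0.0121, 2)
  expect_equal(got$alpha, 0.055)
  expect_equal(got$beta, 0.003025)
  big <- hypoxicParams(0.11, 0.0121, 1e12)
  expect_lt(big$alpha, 1e-10)
  expect_lt(big$beta, 1e-22)
  expect_error(hypoxicParams(0.1, 0.01, 0), "positive")
  expect_error(hypoxicParams(0.1, 0.01, -2), "positive")
})

test_that("aerobic parameters are reproduced bitwise at OER = 1", {
  tis <- tissueParams()
  for (kind in c("constant_1p1", "MCN", "ROR_approx")) {
    aero <- rbeParamsAerobic(rbeModel(kind), c(0, 3, 9), tis)
    hyp <- hypoxicParams(aero$alpha, aero$beta, 1)
    expect_identical(hyp$alpha, aero$alpha)
    expect_identical(hyp$beta, aero$beta)
  }
})

test_that("parameter containers enforce their invariants", {
  expect_error(oerParams(K = -1))
  expect_error(oerParams(pA = 2))          # below K
  expect_error(oerParams(survivalLevel = 1.2))
  expect_error(oerParams(normoxiaThreshold = 10))  # below pA
  expect_error(tissueParams(alphaX = 0))
  expect_error(tissueParams(betaX = -1))
  expect_equal(alphaBetaRatio(tissueParams(0.105, 0.035)), 3)
})
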