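test_that("gate rates evaluate their removable singularities by the limit", {
  expect_equal(gateRates(25)[["alpha_m"]], 1)
  expect_equal(gateRates(10)[["alpha_n"]], 0.1)
  # continuity across the singular points
  expect_equal(gateRates(25 + 1e-9)[["alpha_m"]], 1, tolerance = 1e-6)
  expect_equal(gateRates(10 - 1e-9)[["alpha_n"]], 0.1, tolerance = 1e-6)
})

test_that("gate rates at rest match the shifted-frame formulas", {
  r <- gateRates(0)
  expect_equal(r[["beta_n"]], 0.125)
  expect_equal(r[["beta_m"]], 4)
  expect_equal(r[["alpha_h"]], 0.07)
  expect_equal(r[["alpha_m"]], 2.5 / (exp(2.5) - 1))
  for (v in seq(-40, 130, by = 10)) expect_true(all(gateRates(v) >= 0))
  expect_error(gateRates(NaN), "finite")
})

test_that("the resting state is an approximate fixed point of the neuron", {
  r <- gateRates(0)
  st <- c(v = 0,
          m = r[["alpha_m"]] / (r[["alpha_m"]] + r[["beta_m"]]),
          h = r[["alpha_h"]] / (r[["alpha_h"]] + r[["beta_h"]]),
          n = r[["alpha_n"]] / (r[["alpha_n"]] + r[["beta_n"]]))
  d <- neuronRhs(st, Iapplied = 0)
  expect_lt(abs(d[["v"]]), 0.1)
  expect_equal(unname(d[c("m", "h", "n")]), c(0, 0, 0), tolerance = 1e-12)
})

test_that("transmitter release is a monotone sigmoid with the right anchors", {
  expect_equal(transmitterConcentration(85), 0.5)
  expect_lt(transmitterConcentration(0), 1e-15)
  expect_equal(transmitterConcentration(100), 1 / (1 + exp(-7.5)))
  v <- seq(-20, 120, by = 1)
  expect_true(all(diff(transmitterConcentration(v)) > 0))
})

test_that("synaptic gate kinetics have the expected fixed points", {
  expect_equal(synapseRhs(0, 0), 0)
  expect_equal(synapseRhs(1, 0), -0.05)
  # with transmitter saturated the gate settles at alpha/(alpha+beta)
  sStar <- 0.1 / 0.15
  expect_equal(synapseRhs(sStar, 1), 0, tolerance = 1e-15)
})

test_that("synaptic currents vanish at closed gates and at reversal", {
  p <- modelParams()
  expect_equal(unname(synapticCurrents(0, 0, 0, 0, p)), c(0, 0))
  expect_equal(synapticCurrents(0, p$Eexc, 1, 0, p)[["Is2"]], 0)
  p65 <- modelParams(gse = 0.9, Eexc = 65)
  expect_equal(synapticCurrents(0, 0, 1, 0, p65)[["Is2"]], 58.5)
})

test_that("astrocyte IP3 relaxes to baseline and calcium balances at C_ER", {
  p <- modelParams(vc = 0)
  # P below baseline rises, above baseline falls (trigger off at rest)
  dLow <- astrocyteRhs(c(C = 0.1, q = 0.7, P = 0.05), v1 = 0, p)
  dHigh <- astrocyteRhs(c(C = 0.1, q = 0.7, P = 0.5), v1 = 0, p)
  expect_gt(dLow[["P"]], 0)
  expect_lt(dHigh[["P"]], 0)
  # channel and leak fluxes vanish when cytosol and ER concentrations match
  cEq <- p$c0 / (1 + p$c1)
  d <- astrocyteRhs(c(C = cEq, q = 0.5, P = 0.3), v1 = 0, p)
  expect_equal(d[["C"]], 0, tolerance = 1e-15)
})

test_that("with the neuron at rest the astrocyte settles below threshold", {
  p <- modelParams(Ie1 = 0, Ie2 = 0, gse = 0, gsi = 0, lambda = 0, rP = 0.8)
  tr <- simulateModel(p, duration = 200000, recordStride = 200)
  cFinal <- tr$C[nrow(tr)]
  expect_lt(cFinal * 1000, 196.69)
  expect_equal(astroFeedbackCurrent(cFinal, p), 0)
})

test_that("the feedback current is thresholded, continuous and monotone", {
  expect_equal(astroFeedbackCurrent(0.19669), 0)  # y = 0
  expect_equal(astroFeedbackCurrent(0.19769), 0)  # y = 1, ln(1) boundary
  expect_equal(astroFeedbackCurrent(0.5), 2.11 * log(0.5 * 1000 - 196.69))
  expect_equal(astroFeedbackCurrent(0.5), 12.058, tolerance = 1e-3)
  cGrid <- seq(0.01, 1.5, by = 0.01)
  iGrid <- astroFeedbackCurrent(cGrid)
  expect_true(all(iGrid >= 0))
  expect_true(all(diff(iGrid) >= 0))
  expect_true(all(iGrid[cGrid <= 0.19769] == 0))
})

test_that("feedback currents inhibit N1 and excite N2, scaled by lambda", {
  expect_equal(unname(feedbackCurrents(5, 0)), c(0, 0))
  expect_equal(unname(feedbackCurrents(5, 1)), c(-5, 5))
  expect_equal(unname(feedbackCurrents(12.06, 0.5)), c(-6.03, 6.03))
})

test_that("the assembled right-hand side satisfies the current identity", {
  set.seed(11)
  p <- modelParams(Ie1 = 10, gse = 1.2, gsi = 0.1, lambda = 0.7, rP = 0.5)
  for (i in 1:20) {
    st <- randomState()
    out <- systemRhs(st, p)
    cur <- out$currents
    expect_identical(cur[["Itot1"]],
                     p$Ie1 + cur[["Ia1"]] + cur[["Is1"]])
    expect_gte(cur[["Iastro"]], 0)
    if (p$lambda > 0) {
      expect_lte(cur[["Ia1"]], 0)
      expect_gte(cur[["Ia2"]], 0)
    }
  }
})

test_that("a decoupled resting interneuron has near-zero derivatives", {
  p <- modelParams(Ie1 = 10, Ie2 = 0, gse = 0, gsi = 0, lambda = 0)
  st <- defaultInitialState(p)
  st["v1"] <- 40  # N1 mid-spike must not leak into N2 when decoupled
  d <- systemRhs(st, p)$deriv
  expect_lt(abs(d[["v2"]]), 0.01)
  expect_equal(unname(d[c("m2", "h2", "n2")]), c(0, 0, 0), tolerance = 1e-12)
})

test_that("the pure-R right-hand side matches the compiled kernel", {
  set.seed(42)
  p <- modelParams(Ie1 = 10, gse = 1.2, gsi = 0.1, lambda = 0.7, rP = 0.5)
  pv <- tripartite:::packParams(p)
  for (i in 1:25) {
    st <- randomState()
    rR <- systemRhs(st, p)
    rC <- tripartite:::systemDerivCpp(st, pv)
    expect_equal(rR$deriv, rC$deriv, tolerance = 1e-13)
    expect_equal(rR$currents, rC$currents, tolerance = 1e-13)
  }
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(modelParams(lambda = 1.5), "lambda")
  expect_error(modelParams(gNa = -1), "gNa")
  expect_error(modelParams(Ie1 = NaN), "Ie1")
})
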