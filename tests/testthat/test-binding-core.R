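test_that("bound fraction matches the mass-action examples and limits", {
  # no ligand, no binding
  expect_equal(boundFraction(bindingParameters(2), concentrationPair(1, 0)), 0)
  # stoichiometric limit: kd = 0 with excess ligand saturates the target
  expect_equal(boundFraction(bindingParameters(0), concentrationPair(1, 2)), 1)
  # kd = u0 = l0 = 1: analytic root (3 - sqrt(5))/2, cross-checked by the
  # bracketing oracle
  fb <- boundFraction(bindingParameters(1), concentrationPair(1, 1))
  expect_equal(fb, (3 - sqrt(5)) / 2, tolerance = 1e-12)
  expect_equal(fb, fbOracle(1, 1, 1), tolerance = 1e-9)
})

test_that("bound fraction is bounded and monotone in titrant", {
  l0 <- seq(0, 10, by = 0.25)
  for (kd in c(1e-3, 0.1, 1, 10)) {
    for (u0 in c(0.05, 0.5, 1)) {
      fb <- boundFraction(bindingParameters(kd),
                          concentrationPair(u0, l0))
      expect_true(all(fb >= 0 & fb <= pmin(1, ifelse(l0 == 0, 0, l0 / u0) + 1e-12)))
      expect_true(all(diff(fb) >= -1e-12))
    }
  }
})

test_that("predicted response scales with deltaMax and saturates", {
  conc <- concentrationPair(1, 1)
  expect_equal(predictedResponse(bindingParameters(1, deltaMax = 1), conc),
               (3 - sqrt(5)) / 2, tolerance = 1e-12)
  expect_equal(predictedResponse(bindingParameters(1, deltaMax = 0), conc), 0)
  # saturation limit: l0 >> kd, u0
  expect_equal(predictedResponse(bindingParameters(0.1, deltaMax = 0.5),
                                 concentrationPair(1, 1e7)),
               0.5, tolerance = 1e-6)
})

test_that("unit tags are enforced in joint use", {
  expect_error(boundFraction(bindingParameters(1, unit = "uM"),
                             concentrationPair(1, 1, unit = "mol%")),
               "unit mismatch")
  expect_error(concentrationPair(1, -0.5), "non-negative|>= 0")
  expect_error(concentrationPair(0, 1), "u0 > 0")
  expect_error(bindingParameters(1, unit = "nM"), "unknown concentration unit")
  # µM spelling is canonicalized, not rejected
  expect_identical(bindingParameters(1, unit = "µM")@unit, "uM")
})

test_that("hybrid shift follows the adopted weighted-rms form", {
  expect_equal(hybridShift(shiftPerturbation(0, 0)), 0)
  expect_equal(hybridShift(shiftPerturbation(0.2, 0)), 0.2 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(hybridShift(shiftPerturbation(0, 1.0)), 0.154 / sqrt(2),
               tolerance = 1e-12)
  # sign symmetry
  p <- shiftPerturbation(c(-0.1, 0.1), c(0.8, -0.8))
  expect_equal(hybridShift(p)[1], hybridShift(p)[2])
  # alternative quadrature strategy
  expect_equal(hybridShift(shiftPerturbation(0.3, 0.5), form = "quadrature"),
               sqrt(0.3^2 + (0.154 * 0.5)^2), tolerance = 1e-12)
})

test_that("mol% conversion and bicelle mass balance are consistent", {
  expect_equal(molPercent(1, 100), 1.0)
  expect_equal(molPercent(150e-6, 88e-3), 0.1704545, tolerance = 1e-6)
  # 20% w/v q=0.3 DMPC/D6PC: ~91 mM DMPC; 0.5 mM protein is then ~0.55
  # mol%, within 10% of the rounded 0.57 reported for that preparation
  lip <- bicelleLipidMolarity(20, 0.3, 677.9, 453.5)
  expect_equal(lip, 0.0913, tolerance = 0.01)
  expect_equal(molPercent(0.5e-3, lip), 0.57, tolerance = 0.1)
  # linearity in total amphiphile
  expect_equal(bicelleLipidMolarity(40, 0.3), 2 * bicelleLipidMolarity(20, 0.3))
  # scale invariance of mol%
  expect_equal(molPercent(3e-4, 0.09), molPercent(3e-7, 9e-5))
  expect_error(molPercent(1, 0), "positive")
  expect_error(bicelleLipidMolarity(0, 0.3), "positive")
})
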