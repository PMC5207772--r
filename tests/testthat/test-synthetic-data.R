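test_that("every generator is deterministic in (truth, design, seed)", {
  des <- simulationDesign("slow_exchange_intensity", noiseSd = 0.05)
  t1 <- simulateTitration(bindingParameters(0.2, unit = "mol%"), des, seed = 9)
  t2 <- simulateTitration(bindingParameters(0.2, unit = "mol%"), des, seed = 9)
  expect_identical(SummarizedExperiment::assay(t1),
                   SummarizedExperiment::assay(t2))
  t3 <- simulateTitration(bindingParameters(0.2, unit = "mol%"), des, seed = 10)
  expect_false(identical(SummarizedExperiment::assay(t1),
                         SummarizedExperiment::assay(t3)))

  p1 <- simulatePreProfiles(beta1Fixture(), noiseSd = 0.05, seed = 9)
  p2 <- simulatePreProfiles(beta1Fixture(), noiseSd = 0.05, seed = 9)
  expect_identical(ratios(p1$hydrophilic), ratios(p2$hydrophilic))

  d1 <- simulateR2Decay(c(5, 15), noiseSd = 0.03, seed = 9)
  d2 <- simulateR2Decay(c(5, 15), noiseSd = 0.03, seed = 9)
  expect_identical(SummarizedExperiment::assay(d1),
                   SummarizedExperiment::assay(d2))

  a1 <- simulateAnisotropy(bindingParameters(0.1, unit = "mol%"), seed = 9)
  a2 <- simulateAnisotropy(bindingParameters(0.1, unit = "mol%"), seed = 9)
  expect_identical(a1@anisotropy, a2@anisotropy)

  expect_error(simulateTitration(bindingParameters(0.2, unit = "mol%"), des),
               "seed is mandatory")
})

test_that("zero-noise output lies exactly on the generating model", {
  des <- simulationDesign("fast_exchange_shift", noiseSd = 0)
  ts <- simulateTitration(bindingParameters(0.4, unit = "mol%"), des,
                          seed = 12)
  truth <- S4Vectors::metadata(ts)$truth
  conc <- concentrationPair(0.23, titrantConcentrations(ts), unit = "mol%")
  for (p in seq_len(nrow(ts))) {
    expected <- predictedResponse(
      bindingParameters(truth$kd, deltaMax = truth$amplitudes[p],
                        unit = "mol%"), conc)
    expect_equal(unname(SummarizedExperiment::assay(ts)[p, ]),
                 unname(expected), tolerance = 1e-12)
  }
})

test_that("noisy ensembles average onto the model within Monte-Carlo error", {
  des <- simulationDesign("slow_exchange_intensity", noiseSd = 0.05)
  nSeeds <- 400
  acc <- 0
  for (s in seq_len(nSeeds)) {
    ts <- simulateTitration(bindingParameters(0.3, unit = "mol%"), des,
                            nPeaks = 1, seed = s)
    model <- S4Vectors::metadata(ts)$truth$amplitudes *
      BicelleNMR:::.titrShape(0.3, 0.17, titrantConcentrations(ts),
                              "slow_exchange_intensity")
    acc <- acc + SummarizedExperiment::assay(ts)[1, ] / model
  }
  # mean multiplicative factor ~ 1 within ~4 sd / sqrt(n)
  expect_true(all(abs(acc / nSeeds - 1) < 4 * 0.05 / sqrt(nSeeds)))
})

test_that("noise enters only through the seeded noise stream", {
  quiet <- simulatePreProfiles(beta1Fixture(), noiseSd = 0, seed = 33)
  noisy <- simulatePreProfiles(beta1Fixture(), noiseSd = 0.05, seed = 33)
  # same seed: noisy ratios deviate from the noiseless ones by < 3 sd
  dev <- abs(ratios(noisy$hydrophilic) - ratios(quiet$hydrophilic))
  expect_true(all(dev <= 3 * 0.05 * ratios(quiet$hydrophilic) + 1e-12))
})

test_that("generators restore the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulateTitration(bindingParameters(0.2, unit = "mol%"),
                              simulationDesign(), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("fixture invariants are enforced", {
  expect_error(topologyFixture("bad", c(1, 50), c(10, 30), c(12, 40)),
               "tmSpan must lie within helixSpan")
  expect_error(topologyFixture("bad", c(1, 50), c(10, 30), c(5, 60)),
               "helixSpan must lie within residueRange")
  fx <- beta1Fixture()
  expect_identical(tmSpan(fx), c(732L, 757L))
  expect_identical(helixSpan(fx), c(732L, 765L))
  expect_identical(tmSpan(beta3Fixture()), c(693L, 721L))
})
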