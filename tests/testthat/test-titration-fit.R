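test_that("noiseless titrations are recovered exactly in both regimes", {
  for (regime in c("slow_exchange_intensity", "fast_exchange_shift")) {
    des <- simulationDesign(regime, noiseSd = 0)
    kdTrue <- if (regime == "slow_exchange_intensity") 0.15 else 0.5
    ts <- simulateTitration(bindingParameters(kdTrue, unit = "mol%"), des,
                            seed = 11)
    fit <- fitBinding(ts)
    expect_equal(kdEstimate(fit), kdTrue, tolerance = 1e-6)
    # per-peak amplitudes recovered too
    truthAmps <- S4Vectors::metadata(ts)$truth$amplitudes
    expect_equal(perPeakParameters(fit)[[3]], truthAmps, tolerance = 1e-6)
  }
})

test_that("global single-peak fit equals an independent single-curve fit", {
  des <- simulationDesign("slow_exchange_intensity", noiseSd = 0.05)
  ts <- simulateTitration(bindingParameters(0.3, unit = "mol%"), des,
                          nPeaks = 1, seed = 21)
  expect_warning(fitGlobal <- fitSlowExchangeGlobal(ts), "single peak")
  # independent check: profile the amplitude and minimize over Kd in 1-D
  y <- as.vector(SummarizedExperiment::assay(ts, "observables"))
  l0 <- titrantConcentrations(ts)
  rss1d <- function(kd) {
    s <- 1 - boundFraction(bindingParameters(kd, unit = "mol%"),
                           concentrationPair(0.17, l0, unit = "mol%"))
    a <- sum(y * s) / sum(s^2)
    sum((y - a * s)^2)
  }
  kd1d <- optimize(rss1d, c(1e-4, 10), tol = 1e-10)$minimum
  expect_equal(kdEstimate(fitGlobal), kd1d, tolerance = 1e-4)
})

test_that("fit objective is invariant to peak and point relabeling", {
  des <- simulationDesign("fast_exchange_shift", noiseSd = 0.03)
  ts <- simulateTitration(bindingParameters(0.4, unit = "mol%"), des,
                          nPeaks = 5, seed = 31)
  fit <- fitFastExchangeGlobal(ts)
  shuf <- ts[c(3, 1, 5, 2, 4), ]
  fitShuf <- fitFastExchangeGlobal(shuf)
  expect_equal(kdEstimate(fitShuf), kdEstimate(fit), tolerance = 1e-6)
  expect_equal(fitShuf@fitInfo$deviance, fit@fitInfo$deviance,
               tolerance = 1e-8)
})

test_that("parameter recovery holds across the Kd grid in both regimes", {
  seeds <- 1:50
  for (regime in c("slow_exchange_intensity", "fast_exchange_shift")) {
    des <- simulationDesign(regime, u0 = 0.17, noiseSd = 0.05)
    for (kdTrue in c(0.05, 0.15)) {
      est <- se <- numeric(length(seeds))
      for (i in seq_along(seeds)) {
        ts <- simulateTitration(bindingParameters(kdTrue, unit = "mol%"),
                                des, seed = seeds[i])
        fit <- fitBinding(ts)
        est[i] <- kdEstimate(fit); se[i] <- kdStdError(fit)
      }
      expect_lt(abs(median(est) - kdTrue) / kdTrue, 0.15)
      # +/- 1 SE interval covers the truth at least half the time
      covg <- mean(abs(est - kdTrue) <= se, na.rm = TRUE)
      expect_gte(covg, 0.5)
    }
  }
})

test_that("slow- and fast-exchange fits of matched truths agree", {
  kdTrue <- 0.5
  seeds <- 1:30
  ratios <- c(0, 0.5, 1, 2, 3, 4)
  recover <- function(regime) {
    des <- simulationDesign(regime, moleRatios = ratios, u0 = 0.17)
    vapply(seeds, function(s) {
      kdEstimate(fitBinding(simulateTitration(
        bindingParameters(kdTrue, unit = "mol%"), des, seed = s)))
    }, numeric(1))
  }
  estSlow <- recover("slow_exchange_intensity")
  estFast <- recover("fast_exchange_shift")
  # two-sample location check: the recovery distributions of the two
  # regimes are statistically indistinguishable
  expect_gt(wilcox.test(estSlow, estFast)$p.value, 0.01)
})

test_that("unsaturated titrations are flagged as Kd lower bounds", {
  # slow exchange, Kd 50x the largest titrant concentration
  des <- simulationDesign("slow_exchange_intensity", noiseSd = 0.02)
  maxL0 <- max(des$moleRatios) * des$u0
  ts <- simulateTitration(bindingParameters(50 * maxL0, unit = "mol%"), des,
                          seed = 41)
  fit <- fitSlowExchangeGlobal(ts)
  expect_identical(boundFlag(fit), "lower_bound")
  expect_equal(lowerBoundValue(fit), maxL0)
  # weak fast-exchange binder at the extended ratio schedule
  desf <- simulationDesign("fast_exchange_shift", u0 = 0.23, noiseSd = 0.02)
  tsf <- simulateTitration(bindingParameters(5, unit = "mol%"), desf,
                           seed = 42)
  fitf <- fitFastExchangeGlobal(tsf)
  expect_identical(boundFlag(fitf), "lower_bound")
  expect_equal(lowerBoundValue(fitf), 7.5 * 0.23)
  # the reported bound is configurable
  fit2 <- assessSaturation(fitf, tsf, lowerBoundFun = function(x) 2 * x)
  expect_equal(lowerBoundValue(fit2), 2 * 7.5 * 0.23)
})

test_that("saturation exactly at the threshold stays quantified", {
  des <- simulationDesign("slow_exchange_intensity", noiseSd = 0)
  ts <- simulateTitration(bindingParameters(0.3, unit = "mol%"), des,
                          seed = 51)
  fit <- fitSlowExchangeGlobal(ts)
  satF <- saturationFraction(fit)
  # strict less-than: a fit sitting on the threshold is not downgraded
  at <- assessSaturation(fit, ts, threshold = satF, ciMultiple = Inf)
  expect_identical(boundFlag(at), "quantified")
  below <- assessSaturation(fit, ts, threshold = satF + 1e-9,
                            ciMultiple = Inf)
  expect_identical(boundFlag(below), "lower_bound")
})

test_that("outlier exclusion refits behave as documented", {
  des <- simulationDesign("slow_exchange_intensity", noiseSd = 0)
  ts <- simulateTitration(bindingParameters(0.2, unit = "mol%"), des,
                          nPeaks = 4, seed = 61)
  fit <- fitSlowExchangeGlobal(ts)
  # excluding nothing reproduces the original fit
  expect_equal(kdEstimate(refitExcluding(ts)), kdEstimate(fit),
               tolerance = 1e-10)
  # excluding a clean peak from noiseless data leaves Kd unchanged
  fitMinus <- refitExcluding(ts, "peak2")
  expect_equal(kdEstimate(fitMinus), kdEstimate(fit), tolerance = 1e-6)
  expect_identical(excludedPeaks(fitMinus), "peak2")

  # a peak contaminated by an additive concentration-linear drift biases
  # the global fit; dropping it moves Kd by < 25% and cuts the residual
  # variance
  desN <- simulationDesign("slow_exchange_intensity", noiseSd = 0.02)
  tsN <- simulateTitration(bindingParameters(0.2, unit = "mol%"), desN,
                           nPeaks = 4, seed = 62)
  Y <- SummarizedExperiment::assay(tsN, "observables")
  l0 <- titrantConcentrations(tsN)
  Y[1, ] <- Y[1, ] + 0.15 * l0 / max(l0)
  tsBad <- titrationSeries(Y, conc = l0, u0 = 0.17,
                           regime = "slow_exchange_intensity",
                           assignments = paste0("peak", 1:4))
  fitAll <- fitSlowExchangeGlobal(tsBad)
  fitClean <- refitExcluding(tsBad, "peak1")
  expect_lt(abs(kdEstimate(fitClean) - kdEstimate(fitAll)) /
              kdEstimate(fitAll), 0.25)
  varAll <- fitAll@fitInfo$deviance / fitAll@fitInfo$df
  varClean <- fitClean@fitInfo$deviance / fitClean@fitInfo$df
  expect_lt(varClean, varAll)
})

test_that("degenerate inputs raise informative errors", {
  des <- simulationDesign("slow_exchange_intensity", noiseSd = 0)
  ts <- simulateTitration(bindingParameters(0.2, unit = "mol%"), des,
                          seed = 71)
  zero <- titrationSeries(matrix(0, 2, 6), conc = titrantConcentrations(ts),
                          u0 = 0.17, regime = "slow_exchange_intensity")
  expect_error(fitSlowExchangeGlobal(zero), "all intensities are zero")
  flat <- titrationSeries(matrix(0, 2, 6), conc = titrantConcentrations(ts),
                          u0 = 0.23, regime = "fast_exchange_shift")
  expect_error(fitFastExchangeGlobal(flat, noise = 0), "no binding signal")
  expect_error(refitExcluding(ts, paste0("peak", 1:4)), "every peak")
  expect_error(refitExcluding(ts, "nope"), "unknown peak")
  expect_error(fitFastExchangeGlobal(ts), "regime")
})
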