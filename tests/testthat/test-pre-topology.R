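## small helper: peak tables for paired paramagnetic/diamagnetic spectra
peakTab <- function(residues, intensities, condition = "dia") {
  data.frame(assignment = paste0("A", residues), residue = residues,
             h_ppm = 8, n_ppm = 120, intensity = intensities,
             condition = condition)
}

test_that("intensity ratios apply the matched-peak and error rules", {
  dia <- peakTab(1:12, rep(100, 12))
  # identical tables: all ratios 1
  pr <- intensityRatioProfile(dia, dia, noise = 0)
  expect_true(all(ratios(pr) == 1))
  # one peak broadened beyond detection: ratio 0, error = noise / I_dia
  para <- peakTab(c(1:5, 7:12), rep(80, 11), "para")
  pr2 <- intensityRatioProfile(para, dia, noise = 5)
  expect_equal(ratios(pr2)[6], 0)
  expect_equal(profileErrors(pr2)[6], 5 / 100)
  # 5%-of-value floor: I_para 80, I_dia 100 with small noise-derived error
  expect_equal(ratios(pr2)[1], 0.8)
  expect_equal(profileErrors(pr2)[1], max(0.05 * 0.8,
    0.8 * sqrt((5 / 80)^2 + (5 / 100)^2)))
  pr3 <- intensityRatioProfile(peakTab(1:12, rep(80, 12), "para"), dia,
                               noise = 1)
  # noise-derived 0.8*sqrt((1/80)^2+(1/100)^2) ~ 0.0128 < 0.04 -> 5% rule
  expect_equal(profileErrors(pr3), rep(0.04, 12))
  expect_error(intensityRatioProfile(peakTab(1:12, rep(-1, 12)), dia),
               "negative")
  expect_error(intensityRatioProfile(peakTab(50:60, rep(1, 11)), dia),
               "no matched")
})

test_that("zero-noise fixture profiles reproduce the annotated TM spans", {
  for (fx in list(beta1Fixture(), beta3Fixture())) {
    pr <- simulatePreProfiles(fx, noiseSd = 0, seed = 1)
    call <- callTmBoundaries(pr$hydrophilic, pr$lipophilic)
    expect_identical(tmSpan(call), tmSpan(fx))
  }
  # relocated TM round-trips through the caller
  fxMoved <- topologyFixture("moved", c(690, 780), c(700, 725), c(700, 733))
  pr <- simulatePreProfiles(fxMoved, noiseSd = 0, seed = 2)
  expect_identical(tmSpan(callTmBoundaries(pr$hydrophilic, pr$lipophilic)),
                   c(700L, 725L))
})

test_that("a uniformly exposed profile yields no membrane-embedded span", {
  res <- 1:40
  hyd <- accessibilityProfile(res, rep(0.2, 40), rep(0.01, 40),
                              probe = "hydrophilic")
  lip <- accessibilityProfile(res, rep(0.9, 40), rep(0.045, 40),
                              probe = "lipophilic")
  call <- callTmBoundaries(hyd, lip)
  expect_true(call@noSpan)
  expect_length(tmSpan(call), 0)
})

test_that("boundary calls are invariant to common intensity rescaling", {
  dia <- peakTab(719:798, 90 + 20 * ratios(
    simulatePreProfiles(beta1Fixture(), noiseSd = 0, seed = 3)$hydrophilic))
  # build para/dia pairs whose ratio traces the fixture shapes
  shapes <- simulatePreProfiles(beta1Fixture(), noiseSd = 0, seed = 3)
  diaI <- rep(100, 80)
  mk <- function(scale) {
    d <- peakTab(719:798, scale * diaI)
    h <- peakTab(719:798, scale * diaI * ratios(shapes$hydrophilic), "para")
    l <- peakTab(719:798, scale * diaI * ratios(shapes$lipophilic), "para")
    callTmBoundaries(
      intensityRatioProfile(h, d, probe = "hydrophilic"),
      intensityRatioProfile(l, d, probe = "lipophilic"))
  }
  expect_identical(tmSpan(mk(1)), tmSpan(mk(537.2)))
  expect_identical(tmSpan(mk(1)), tmSpan(beta1Fixture()))
})

test_that("profile comparison is symmetric and calibrated", {
  a <- simulatePreProfiles(beta1Fixture(), noiseSd = 0.05, seed = 5)
  b <- simulatePreProfiles(beta1Fixture(), noiseSd = 0.05, seed = 6)
  # self-comparison: nothing significant
  self <- compareProfiles(a$hydrophilic, a$hydrophilic)
  expect_identical(self@nSignificant, 0L)
  expect_identical(verdict(self), "unchanged")
  # symmetry: deltas negate, verdict preserved
  ab <- compareProfiles(a$hydrophilic, b$hydrophilic)
  ba <- compareProfiles(b$hydrophilic, a$hydrophilic)
  expect_equal(ab@delta, -ba@delta)
  expect_identical(verdict(ab), verdict(ba))
  expect_error(compareProfiles(a$hydrophilic, a$lipophilic),
               "different probe classes")
  # a 10-residue TM shift is called changed
  shifted <- topologyFixture("sh", c(719, 798), c(742, 767), c(742, 775))
  c1 <- simulatePreProfiles(shifted, noiseSd = 0.05, seed = 7)
  expect_identical(verdict(compareProfiles(a$hydrophilic, c1$hydrophilic)),
                   "changed")
})

test_that("chelate-artifact mode perturbs only the hydrophilic profile", {
  clean <- simulatePreProfiles(beta1Fixture(), noiseSd = 0.05, seed = 8)
  art <- simulatePreProfiles(beta1Fixture(), noiseSd = 0.05, seed = 9,
                             artifactSite = 752)
  expect_identical(verdict(compareProfiles(clean$hydrophilic,
                                           art$hydrophilic)), "changed")
  expect_identical(verdict(compareProfiles(clean$lipophilic,
                                           art$lipophilic)), "unchanged")
})
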