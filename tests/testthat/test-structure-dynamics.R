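coil <- randomCoilShifts()

test_that("shifts at random-coil values are called coil throughout", {
  aa <- c("A", "L", "K", "E", "I", "V", "S", "T", "G", "F")
  idx <- match(aa, coil$aa)
  st <- shiftTable(1:10, aa, ca = coil$ca[idx], cb = coil$cb[idx],
                   co = coil$co[idx])
  res <- csiSecondaryStructure(st)
  expect_true(all(res$perResidue$consensus == "coil"))
  expect_length(res$helixSegments, 0)
})

test_that("a downfield-CA stretch is called helix over its full span", {
  n <- 50
  aa <- rep(c("A", "L", "E", "K", "I"), 10)
  idx <- match(aa, coil$aa)
  ca <- coil$ca[idx]
  co <- coil$co[idx]
  ca[10:40] <- ca[10:40] + 3.0       # helix-typical CA deviation
  co[10:40] <- co[10:40] + 1.5
  st <- shiftTable(1:n, aa, ca = ca, co = co)
  res <- csiSecondaryStructure(st)
  seg <- res$helixSegments
  expect_length(seg, 1)
  expect_identical(c(IRanges::start(seg), IRanges::end(seg)), c(10L, 40L))
})

test_that("csi calls are invariant to a common referencing offset", {
  aa <- rep(c("A", "L", "E", "K"), 10)
  idx <- match(aa, coil$aa)
  ca <- coil$ca[idx] + c(rep(0, 12), rep(3, 16), rep(0, 12))
  st1 <- csiSecondaryStructure(shiftTable(1:40, aa, ca = ca))
  ref2 <- coil
  ref2$ca <- ref2$ca + 0.37          # re-referenced coil table
  st2 <- csiSecondaryStructure(shiftTable(1:40, aa, ca = ca + 0.37),
                               reference = ref2)
  expect_identical(st1$perResidue$consensus, st2$perResidue$consensus)
})

test_that("empty or aa-less shift tables fail cleanly", {
  expect_error(csiSecondaryStructure(shiftTable(integer(), character())),
               "empty")
  expect_warning(shiftTable(1, "A", ca = 100), "plausible")
})

test_that("cleanex ratios are raw per-residue ratios", {
  mix <- setNames(c(10, 5, 0, 8), 1:4)
  ref <- setNames(c(10, 10, 10, 16), 1:4)
  r <- cleanexRatio(mix, ref)
  expect_equal(unname(r), c(1, 0.5, 0, 0.5))
  expect_error(cleanexRatio(setNames(1, "9"), setNames(1, "7")),
               "no matched")
  # monotone protection gradient along a frayed helix round-trips
  grad <- seq(0.05, 0.95, length.out = 10)
  r2 <- cleanexRatio(setNames(100 * grad, 1:10), setNames(rep(100, 10), 1:10))
  expect_true(all(diff(r2) > 0))
})

test_that("R2 fits recover truth and respect invariances", {
  # constant intensities: no decay
  d0 <- relaxationDecay(matrix(3, 1, 8), c(17, 35, 52, 69, 86, 104, 138, 173))
  expect_equal(fitR2(d0)$r2, 0, tolerance = 1e-9)
  # noiseless decays at the standard delay list
  d <- simulateR2Decay(c(10, 25, 40), noiseSd = 0, seed = 1)
  expect_equal(fitR2(d)$r2, c(10, 25, 40), tolerance = 1e-6)
  # estimates invariant to uniform intensity scaling
  Y <- SummarizedExperiment::assay(d, "intensities")
  dScaled <- relaxationDecay(Y * 1e4, d$delay_ms,
                             residues = residueNumbers(d))
  expect_equal(fitR2(dScaled)$r2, fitR2(d)$r2, tolerance = 1e-8)
})
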