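## Seeded generators for every input class, with known ground truth.
## Each generator is a deterministic function of (truth, design, seed), and
## its zero-noise output lies exactly on the generating model.

.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed))
    stop("a seed is mandatory for any stochastic output")
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(as.integer(seed))
  expr
}

.logUnif <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

#' Titration simulation design
#'
#' Bundles the experimental design of an NMR-monitored titration: the
#' titrant/observed mole-ratio schedule, the fixed observed-subunit
#' concentration, the multiplicative noise level and the exchange regime.
#' Defaults reproduce the two standard designs: slow exchange at mole
#' ratios 0, 0.5, 1, 2, 3, 4 with the observed subunit at 0.17 mol%, and
#' fast exchange at ratios 0, 1.25, 2.5, 3.75, 5, 7.5 with 0.23 mol%.
#'
#' @param regime exchange regime of the simulated titration
#' @param moleRatios titrant/observed mole ratios (default per regime)
#' @param u0 fixed observed-subunit concentration (default per regime)
#' @param noiseSd multiplicative Gaussian noise sd (default 0.05)
#' @param unit concentration unit (default \code{"mol%"})
#' @param seed default seed recorded in the design (may be overridden at
#'   simulation time; simulation without any seed is an error)
#' @return a list of class \code{"SimulationDesign"}
#' @export
simulationDesign <- function(regime = c("slow_exchange_intensity",
                                        "fast_exchange_shift"),
                             moleRatios = NULL, u0 = NULL, noiseSd = 0.05,
                             unit = "mol%", seed = NA_integer_) {
  regime <- match.arg(regime)
  if (is.null(moleRatios))
    moleRatios <- if (regime == "slow_exchange_intensity")
      c(0, 0.5, 1, 2, 3, 4) else c(0, 1.25, 2.5, 3.75, 5, 7.5)
  if (is.null(u0))
    u0 <- if (regime == "slow_exchange_intensity") 0.17 else 0.23
  structure(list(regime = regime, moleRatios = moleRatios, u0 = u0,
                 noiseSd = noiseSd, unit = .canonUnit(unit), seed = seed),
            class = "SimulationDesign")
}

#' Simulate a multi-peak NMR titration
#'
#' Per-peak amplitudes (starting intensities for slow exchange, saturation
#' shifts for fast exchange) are drawn log-uniformly over \code{ampRange}
#' and then fixed by the seed; observables follow the 1:1
#' ligand-depletion model with multiplicative Gaussian noise.
#'
#' @param truth generating \linkS4class{BindingParameters} (only
#'   \code{kd} and the unit are used; amplitudes are drawn per peak)
#' @param design a \code{\link{simulationDesign}}
#' @param nPeaks number of peaks (default 4)
#' @param seed RNG seed (defaults to the design's seed)
#' @param ampRange log-uniform amplitude range; defaults to 0.5-2
#'   intensity units (slow) or 0.02-0.2 ppm (fast)
#' @return a \linkS4class{TitrationSeries} with the generating metadata in
#'   \code{metadata()}
#' @examples
#' des <- simulationDesign("slow_exchange_intensity", noiseSd = 0)
#' ts <- simulateTitration(bindingParameters(0.15, unit = "mol%"), des,
#'                         seed = 7)
#' kdEstimate(fitSlowExchangeGlobal(ts))
#' @export
simulateTitration <- function(truth, design, nPeaks = 4, seed = design$seed,
                              ampRange = NULL) {
  stopifnot(is(truth, "BindingParameters"), nPeaks >= 1,
            inherits(design, "SimulationDesign"))
  .checkSameUnit(truth@unit, design$unit)
  if (is.null(ampRange))
    ampRange <- if (design$regime == "slow_exchange_intensity")
      c(0.5, 2) else c(0.02, 0.2)
  .withSeed(seed, {
    l0 <- design$moleRatios * design$u0
    amps <- .logUnif(nPeaks, ampRange)
    shape <- .titrShape(truth@kd, design$u0, l0, design$regime)
    model <- amps %o% shape
    noise <- matrix(rnorm(length(model)), nrow = nPeaks)
    obs <- model * (1 + design$noiseSd * noise)
    ts <- titrationSeries(obs, conc = l0, u0 = design$u0,
                          regime = design$regime, unit = design$unit,
                          residues = seq_len(nPeaks),
                          assignments = paste0("peak", seq_len(nPeaks)))
    S4Vectors::metadata(ts) <- list(truth = list(kd = truth@kd,
                                                 amplitudes = amps),
                                    seed = seed, noiseSd = design$noiseSd)
    ts
  })
}

#' Packaged topology fixture: integrin beta1 TM/CT
#'
#' Residues 719-798 with the transmembrane span at 732-757 and the helix
#' extending to 765; notable sites include the snorkeling lysine K752.
#'
#' @return a \linkS4class{TopologyFixture}
#' @export
beta1Fixture <- function() {
  topologyFixture("integrin_beta1_TMCT", residueRange = c(719L, 798L),
                  tmSpan = c(732L, 757L), helixSpan = c(732L, 765L),
                  notableSites = c(I732 = 732L, K752 = 752L, I757 = 757L,
                                   K765 = 765L))
}

#' Packaged topology fixture: integrin beta3 TM/CT
#'
#' Residues 685-762 with the transmembrane span at 693-721 and the helix
#' extending to 737; notable sites include the snorkeling lysine K716.
#'
#' @return a \linkS4class{TopologyFixture}
#' @export
beta3Fixture <- function() {
  topologyFixture("integrin_beta3_TMCT", residueRange = c(685L, 762L),
                  tmSpan = c(693L, 721L), helixSpan = c(693L, 737L),
                  notableSites = c(I693 = 693L, K716 = 716L, I721 = 721L,
                                   A737 = 737L))
}

## noise-free probe accessibility shapes.  m is the distance inside the TM
## from its nearest boundary (negative outside).  The hydrophilic profile
## is a logistic plateau protected inside the TM; the lipophilic profile a
## logistic trough.  Offsets place the default 0.7/0.5 thresholds exactly
## between the last exposed and first protected residue, so the zero-noise
## boundary call reproduces the fixture spans exactly.
.preShapes <- function(residues, tm, steepness = 1.5) {
  m <- pmin(residues - tm[1], tm[2] - residues)
  hyd <- 0.2 + 0.7 * stats::plogis((m + 2) / steepness)
  lip <- 0.9 - 0.8 * stats::plogis((m + 0.5) / steepness)
  list(hydrophilic = hyd, lipophilic = lip)
}

#' Simulate paired probe accessibility profiles from a topology fixture
#'
#' Emulates the complementary reading of membrane topology by a
#' water-soluble and a lipid-partitioning paramagnetic probe: the
#' hydrophilic-probe I/I0 rises to a protected plateau inside the
#' fixture's TM span, the lipophilic-probe I/I0 dips to a trough centered
#' on it, both with logistic flanks.  Multiplicative Gaussian noise is
#' applied, then the error rule (noise-derived error or 5\% of value,
#' whichever is larger).  The optional chelate-artifact mode depresses
#' hydrophilic ratios around a designated carboxylate-bearing residue,
#' emulating transient association of an open chelate coordination site
#' with Glu/Asp side chains.
#'
#' @param fixture a \linkS4class{TopologyFixture}
#' @param noiseSd multiplicative noise sd (default 0.05)
#' @param seed RNG seed (mandatory)
#' @param steepness logistic flank steepness in residues (default 1.5)
#' @param artifactSite residue number of a carboxylate site for the
#'   chelate-artifact mode, or NULL (default) for no artifact
#' @return list with elements \code{hydrophilic} and \code{lipophilic}
#'   (\linkS4class{AccessibilityProfile}s)
#' @export
simulatePreProfiles <- function(fixture, noiseSd = 0.05, seed,
                                steepness = 1.5, artifactSite = NULL) {
  stopifnot(is(fixture, "TopologyFixture"))
  residues <- seq(fixture@residueRange[1], fixture@residueRange[2])
  shapes <- .preShapes(residues, fixture@tmSpan, steepness)
  if (!is.null(artifactSite))
    shapes$hydrophilic <- shapes$hydrophilic *
      (1 - 0.6 * exp(-0.5 * ((residues - artifactSite) / 3)^2))
  .withSeed(seed, {
    mk <- function(ratio, probe, name) {
      noisy <- pmax(ratio * (1 + noiseSd * rnorm(length(ratio))), 0)
      err <- pmax(noiseSd * noisy, 0.05 * noisy)
      accessibilityProfile(residues, noisy, err, probe = probe,
                           probeName = name)
    }
    list(hydrophilic = mk(shapes$hydrophilic, "hydrophilic", "Gd-DTPA"),
         lipophilic = mk(shapes$lipophilic, "lipophilic", "16-DSA"))
  })
}

#' Simulate per-residue CPMG relaxation decays
#'
#' Monoexponential decays at the standard delay list with per-residue
#' starting intensities drawn log-uniformly, then multiplicative Gaussian
#' noise.
#'
#' @param r2Truth generating R2 rates in 1/s (one per residue)
#' @param delays relaxation delays in msec
#'   (default \code{c(17, 35, 52, 69, 86, 104, 138, 173)})
#' @param noiseSd multiplicative noise sd (default 0.03)
#' @param seed RNG seed (mandatory)
#' @param residues residue numbers (default sequential)
#' @param i0Range log-uniform starting-intensity range
#' @return a \linkS4class{RelaxationDecay}
#' @export
simulateR2Decay <- function(r2Truth,
                            delays = c(17, 35, 52, 69, 86, 104, 138, 173),
                            noiseSd = 0.03, seed,
                            residues = seq_along(r2Truth),
                            i0Range = c(0.5, 2)) {
  .withSeed(seed, {
    i0 <- .logUnif(length(r2Truth), i0Range)
    model <- i0 * exp(-outer(r2Truth, delays / 1000))
    noise <- matrix(rnorm(length(model)), nrow = length(r2Truth))
    relaxationDecay(pmax(model * (1 + noiseSd * noise), 0), delays,
                    residues = residues)
  })
}

#' Simulate a fluorescence anisotropy titration
#'
#' The observed anisotropy interpolates between the free and bound values
#' with the 1:1 depletion-model bound fraction of the labeled species;
#' additive Gaussian noise emulates the scatter of replicate-averaged
#' anisotropy readings.  The default titrant schedule is 12 points, zero
#' plus 11 log-spaced up to 3.2 mol%; the default labeled-species
#' concentration corresponds to 0.2 uM labeled protein in 2\% w/v q = 0.3
#' POPC/POPS/D6PC bicelles.
#'
#' @param truth generating \linkS4class{BindingParameters}
#' @param u0 fixed labeled-species concentration (same unit as truth)
#' @param titrantConc titrant schedule (default as described)
#' @param rFree,rBound generating free/bound anisotropy (defaults 0.12 and
#'   0.22, typical of a dansyl-type label on a bicelle-bound peptide)
#' @param noiseSd additive anisotropy noise sd (default 0.003)
#' @param seed RNG seed (mandatory)
#' @return an \linkS4class{AnisotropyTitration}
#' @export
simulateAnisotropy <- function(truth,
                               u0 = molPercent(0.2e-6,
                                 bicelleLipidMolarity(2, 0.3,
                                   mwLong = (2 * 760.08 + 783.99) / 3)),
                               titrantConc = c(0, 10^seq(log10(0.02),
                                                         log10(3.2),
                                                         length.out = 11)),
                               rFree = 0.12, rBound = 0.22,
                               noiseSd = 0.003, seed) {
  stopifnot(is(truth, "BindingParameters"))
  .withSeed(seed, {
    r <- rFree + (rBound - rFree) * .fb(truth@kd, u0, titrantConc)
    robs <- r + noiseSd * rnorm(length(r))
    anisotropyTitration(u0, titrantConc, robs,
                        replicateSd = rep(noiseSd, length(r)),
                        unit = truth@unit)
  })
}
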