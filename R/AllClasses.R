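#' @import methods
#' @import SummarizedExperiment
#' @importClassesFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges start end width
#' @importFrom stats median pnorm qbinom runif rnorm setNames
#' @importFrom utils read.csv write.csv
NULL

## canonical concentration units: mol% (protein per long-chain lipid) and
## micromolar ("uM", accepted spellings "uM", "µM", "umol/L")
.UNITS <- c("mol%", "uM")

.canonUnit <- function(unit) {
  if (length(unit) != 1L || is.na(unit) || !nzchar(unit))
    stop("concentration unit tag is required (one of 'mol%', 'uM')")
  u <- c("mol%" = "mol%", "uM" = "uM", "µM" = "uM", "umol/L" = "uM")[unit]
  if (is.na(u))
    stop("unknown concentration unit '", unit, "' (expected 'mol%' or 'uM')")
  unname(u)
}

.checkSameUnit <- function(a, b) {
  if (.canonUnit(a) != .canonUnit(b))
    stop("concentration unit mismatch: '", a, "' vs '", b,
         "' (silent unit mixing is not allowed)")
  invisible(.canonUnit(a))
}

## ---------------------------------------------------------------------------
## Value classes for the closed-form binding mathematics
## ---------------------------------------------------------------------------

#' Parameters of a 1:1 ligand-depletion binding model
#'
#' Holds the dissociation constant and the saturation response of a single
#' reporter.  The unit tag (\code{"mol%"} for membrane-embedded association,
#' \code{"uM"} for aqueous-ligand titrations) travels with the Kd and must
#' match the unit of any concentrations it is combined with.
#'
#' @slot kd dissociation constant (>= 0), in \code{unit}
#' @slot deltaMax saturation response of the reporter (ppm for shifts,
#'   intensity units for peak heights, anisotropy units for anisotropy)
#' @slot unit one of \code{"mol%"}, \code{"uM"}
#' @exportClass BindingParameters
setClass("BindingParameters",
         representation(kd = "numeric", deltaMax = "numeric", unit = "character"),
         validity = function(object) {
           msg <- character()
           if (length(object@kd) != 1L || is.na(object@kd) || object@kd < 0)
             msg <- c(msg, "kd must be a single non-negative number")
           if (length(object@deltaMax) != 1L || !is.finite(object@deltaMax))
             msg <- c(msg, "deltaMax must be a single finite number")
           if (!identical(object@unit, .canonUnit(object@unit)))
             msg <- c(msg, "unit must be canonical ('mol%' or 'uM')")
           if (length(msg)) msg else TRUE
         })

#' @param kd,deltaMax,unit see slot documentation
#' @rdname BindingParameters-class
#' @export
bindingParameters <- function(kd, deltaMax = 1, unit = "mol%") {
  new("BindingParameters", kd = as.numeric(kd), deltaMax = as.numeric(deltaMax),
      unit = .canonUnit(unit))
}

#' Fixed-species / titrant concentration pair
#'
#' @slot u0 concentration of the fixed (observed, depletable) species; > 0
#' @slot l0 titrant concentration(s); >= 0, may be a vector
#' @slot unit one of \code{"mol%"}, \code{"uM"}
#' @exportClass ConcentrationPair
setClass("ConcentrationPair",
         representation(u0 = "numeric", l0 = "numeric", unit = "character"),
         validity = function(object) {
           msg <- character()
           if (length(object@u0) != 1L || is.na(object@u0) || object@u0 <= 0)
             msg <- c(msg, "u0 must be a single positive number")
           if (length(object@l0) < 1L || anyNA(object@l0) || any(object@l0 < 0))
             msg <- c(msg, "l0 must be non-negative")
           if (!identical(object@unit, .canonUnit(object@unit)))
             msg <- c(msg, "unit must be canonical ('mol%' or 'uM')")
           if (length(msg)) msg else TRUE
         })

#' @param u0,l0,unit see slot documentation
#' @rdname ConcentrationPair-class
#' @export
concentrationPair <- function(u0, l0, unit = "mol%") {
  if (any(l0 < 0) || u0 <= 0) stop("concentrations must satisfy u0 > 0, l0 >= 0")
  new("ConcentrationPair", u0 = as.numeric(u0), l0 = as.numeric(l0),
      unit = .canonUnit(unit))
}

#' Amide 1H/15N chemical-shift perturbation of one peak
#'
#' @slot deltaH amide 1H shift change (ppm)
#' @slot deltaN amide 15N shift change (ppm)
#' @slot wH,wN nucleus weights used by the hybrid-shift statistic
#'   (defaults 1 and 0.154)
#' @exportClass ShiftPerturbation
setClass("ShiftPerturbation",
         representation(deltaH = "numeric", deltaN = "numeric",
                        wH = "numeric", wN = "numeric"),
         validity = function(object) {
           if (object@wH <= 0 || object@wN <= 0)
             "weights wH and wN must be positive" else TRUE
         })

#' @param deltaH,deltaN,wH,wN see slot documentation
#' @rdname ShiftPerturbation-class
#' @export
shiftPerturbation <- function(deltaH, deltaN, wH = 1, wN = 0.154) {
  stopifnot(length(deltaH) == length(deltaN))
  new("ShiftPerturbation", deltaH = as.numeric(deltaH),
      deltaN = as.numeric(deltaN), wH = wH, wN = wN)
}

## ---------------------------------------------------------------------------
## Titration container (SummarizedExperiment: peaks x titration points)
## ---------------------------------------------------------------------------

#' Multi-peak NMR titration series
#'
#' A \linkS4class{SummarizedExperiment} whose single assay
#' (\code{"observables"}) holds one row per NMR peak and one column per
#' titration point.  Row metadata carries residue numbers and assignment
#' labels; column metadata carries the titrant concentration.  Depending on
#' the exchange regime the observables are raw peak intensities
#' (slow exchange: peaks fade as the bound population grows) or hybrid
#' chemical-shift changes relative to the zero-titrant point (fast
#' exchange: peaks move continuously).
#'
#' @slot regime \code{"slow_exchange_intensity"} or \code{"fast_exchange_shift"}
#' @slot u0 fixed observed-subunit concentration, in \code{concUnit}
#' @slot concUnit concentration unit tag
#' @exportClass TitrationSeries
setClass("TitrationSeries",
         contains = "SummarizedExperiment",
         representation(regime = "character", u0 = "numeric",
                        concUnit = "character"),
         validity = function(object) {
           msg <- character()
           if (!object@regime %in%
               c("slow_exchange_intensity", "fast_exchange_shift"))
             msg <- c(msg, "regime must be 'slow_exchange_intensity' or 'fast_exchange_shift'")
           if (length(object@u0) != 1L || object@u0 <= 0)
             msg <- c(msg, "u0 must be a single positive concentration")
           if (!"observables" %in% SummarizedExperiment::assayNames(object))
             msg <- c(msg, "assay 'observables' is required")
           cc <- object$conc
           if (is.null(cc)) {
             msg <- c(msg, "colData must contain a 'conc' column")
           } else {
             if (length(cc) < 3L)
               msg <- c(msg, "at least 3 titration points are required")
             if (!any(cc == 0))
               msg <- c(msg, "a zero-titrant point is required")
             if (is.unsorted(cc))
               msg <- c(msg, "titration points must be sorted by concentration")
           }
           if (length(msg)) msg else TRUE
         })

#' Construct a TitrationSeries
#'
#' @param observables numeric matrix, peaks (rows) by titration points
#'   (columns): intensities (slow exchange) or hybrid shift changes (fast
#'   exchange, zero at the first point)
#' @param conc titrant concentrations, one per column
#' @param u0 fixed observed-subunit concentration
#' @param regime \code{"slow_exchange_intensity"} or
#'   \code{"fast_exchange_shift"}
#' @param unit concentration unit (\code{"mol%"} or \code{"uM"})
#' @param residues integer residue numbers, one per row
#' @param assignments peak assignment labels, one per row
#' @return a \linkS4class{TitrationSeries}; columns are sorted by
#'   concentration on ingest
#' @examples
#' ts <- titrationSeries(matrix(1, 2, 4), conc = c(0, 1, 2, 3), u0 = 0.17,
#'                       regime = "slow_exchange_intensity")
#' titrantConcentrations(ts)
#' @export
titrationSeries <- function(observables, conc, u0,
                            regime = c("slow_exchange_intensity",
                                       "fast_exchange_shift"),
                            unit = "mol%",
                            residues = seq_len(nrow(observables)),
                            assignments = NULL) {
  regime <- match.arg(regime)
  observables <- as.matrix(observables)
  if (ncol(observables) != length(conc))
    stop("ncol(observables) must equal length(conc)")
  if (is.null(assignments))
    assignments <- paste0("R", residues)
  o <- order(conc)
  observables <- observables[, o, drop = FALSE]
  conc <- conc[o]
  colnames(observables) <- paste0("pt", seq_along(conc))
  rownames(observables) <- make.unique(as.character(assignments))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(observables = observables),
    rowData = S4Vectors::DataFrame(residue = as.integer(residues),
                                   assignment = as.character(assignments)),
    colData = S4Vectors::DataFrame(conc = as.numeric(conc)))
  new("TitrationSeries", se, regime = regime, u0 = as.numeric(u0),
      concUnit = .canonUnit(unit))
}

## ---------------------------------------------------------------------------
## Relaxation decay container (residues x CPMG delays)
## ---------------------------------------------------------------------------

#' Per-residue transverse relaxation decay
#'
#' A \linkS4class{SummarizedExperiment} with assay \code{"intensities"}
#' (residues x relaxation delays) and column metadata \code{delay_ms}.
#' The delay list is data; no particular number of delays is assumed
#' beyond the minimum of three needed for a monoexponential fit.
#'
#' @exportClass RelaxationDecay
setClass("RelaxationDecay",
         contains = "SummarizedExperiment",
         validity = function(object) {
           msg <- character()
           if (!"intensities" %in% SummarizedExperiment::assayNames(object))
             msg <- c(msg, "assay 'intensities' is required")
           d <- object$delay_ms
           if (is.null(d) || length(d) < 3L)
             msg <- c(msg, "at least 3 delays are required (colData$delay_ms)")
           a <- SummarizedExperiment::assay(object, "intensities")
           if (any(a < 0, na.rm = TRUE))
             msg <- c(msg, "intensities must be non-negative")
           if (length(msg)) msg else TRUE
         })

#' @param intensities numeric matrix, residues x delays
#' @param delays relaxation delays in msec, one per column
#' @param residues integer residue numbers, one per row
#' @rdname RelaxationDecay-class
#' @export
relaxationDecay <- function(intensities, delays,
                            residues = seq_len(nrow(intensities))) {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(delays))
    stop("ncol(intensities) must equal length(delays)")
  rownames(intensities) <- paste0("R", residues)
  colnames(intensities) <- paste0("d", seq_along(delays))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensities = intensities),
    rowData = S4Vectors::DataFrame(residue = as.integer(residues)),
    colData = S4Vectors::DataFrame(delay_ms = as.numeric(delays)))
  new("RelaxationDecay", se)
}

## ---------------------------------------------------------------------------
## Binding fit result
## ---------------------------------------------------------------------------

#' Result of a global 1:1 binding fit
#'
#' @slot kd Kd estimate, in \code{unit}
#' @slot kdSe standard error of the Kd from the Jacobian-based covariance
#' @slot unit concentration unit of the fit
#' @slot regime the data regime the fit was run on
#' @slot perPeak data.frame of per-peak nuisance parameters (\code{I0} for
#'   slow exchange, \code{deltaMax} for fast exchange / anisotropy span)
#'   with standard errors
#' @slot residuals matrix of fit residuals (peaks x points)
#' @slot saturationFraction bound fraction of the observed species at the
#'   highest titrant concentration
#' @slot boundFlag \code{"quantified"} or \code{"lower_bound"}
#' @slot lowerBoundValue Kd lower bound; present only when
#'   \code{boundFlag == "lower_bound"}
#' @slot excludedPeaks labels of peaks excluded before fitting
#' @slot fitInfo list of optimizer diagnostics (deviance, df, convergence,
#'   multistart table)
#' @exportClass BindingFitResult
setClass("BindingFitResult",
         representation(kd = "numeric", kdSe = "numeric", unit = "character",
                        regime = "character", perPeak = "data.frame",
                        residuals = "matrix",
                        saturationFraction = "numeric", boundFlag = "character",
                        lowerBoundValue = "numeric",
                        excludedPeaks = "character", fitInfo = "list"),
         validity = function(object) {
           msg <- character()
           if (!object@boundFlag %in% c("quantified", "lower_bound"))
             msg <- c(msg, "boundFlag must be 'quantified' or 'lower_bound'")
           if (object@boundFlag == "quantified" &&
               (length(object@kd) != 1L || object@kd <= 0))
             msg <- c(msg, "a quantified fit must have kd > 0")
           if (length(object@saturationFraction) == 1L &&
               (object@saturationFraction < 0 || object@saturationFraction > 1 + 1e-8))
             msg <- c(msg, "saturationFraction must lie in [0, 1]")
           if (object@boundFlag == "lower_bound" &&
               length(object@lowerBoundValue) != 1L)
             msg <- c(msg, "lowerBoundValue must be present iff boundFlag == 'lower_bound'")
           if (object@boundFlag == "quantified" &&
               length(object@lowerBoundValue) != 0L)
             msg <- c(msg, "lowerBoundValue must be absent for a quantified fit")
           if (length(msg)) msg else TRUE
         })

## ---------------------------------------------------------------------------
## Paramagnetic accessibility profile, topology call, profile comparison
## ---------------------------------------------------------------------------

#' Per-residue paramagnetic-probe accessibility profile
#'
#' I/I0 intensity ratios between matched paramagnetic and diamagnetic
#' TROSY peak lists.  Low ratios mean high probe access (broadening);
#' undetectable paramagnetic peaks are encoded as ratio 0.  The reported
#' per-residue error is \code{max(noise-derived error, 0.05 * ratio)}.
#'
#' @slot residues ordered residue numbers (gaps allowed)
#' @slot ratio I/I0 per residue, >= 0
#' @slot error per-residue uncertainty
#' @slot probe probe class, \code{"hydrophilic"} or \code{"lipophilic"}
#' @slot probeName free-text probe identity (e.g. "Gd-DTPA", "16-DSA")
#' @exportClass AccessibilityProfile
setClass("AccessibilityProfile",
         representation(residues = "integer", ratio = "numeric",
                        error = "numeric", probe = "character",
                        probeName = "character"),
         validity = function(object) {
           msg <- character()
           n <- length(object@residues)
           if (length(object@ratio) != n || length(object@error) != n)
             msg <- c(msg, "residues, ratio and error must have equal length")
           if (any(object@ratio < 0, na.rm = TRUE))
             msg <- c(msg, "ratios must be non-negative")
           if (is.unsorted(object@residues, strictly = TRUE))
             msg <- c(msg, "residues must be strictly increasing")
           if (!object@probe %in% c("hydrophilic", "lipophilic"))
             msg <- c(msg, "probe must be 'hydrophilic' or 'lipophilic'")
           if (length(msg)) msg else TRUE
         })

#' @param residues,ratio,error,probe,probeName see slot documentation
#' @rdname AccessibilityProfile-class
#' @export
accessibilityProfile <- function(residues, ratio, error,
                                 probe = c("hydrophilic", "lipophilic"),
                                 probeName = "") {
  probe <- match.arg(probe)
  o <- order(residues)
  new("AccessibilityProfile", residues = as.integer(residues[o]),
      ratio = as.numeric(ratio[o]), error = as.numeric(error[o]),
      probe = probe, probeName = probeName)
}

#' Membrane-topology call from complementary probe profiles
#'
#' @slot tmStart,tmEnd first/last residue of the called transmembrane span
#'   (\code{integer(0)} when no span qualifies)
#' @slot protectedSegments,exposedSegments residue intervals
#'   (\linkS4class{IRanges}, reported 1-based inclusive)
#' @slot evidence per-probe summary statistics
#' @slot noSpan TRUE when no membrane-embedded span was found
#' @exportClass TopologyCall
setClass("TopologyCall",
         representation(tmStart = "integer", tmEnd = "integer",
                        protectedSegments = "IRanges",
                        exposedSegments = "IRanges",
                        evidence = "list", noSpan = "logical"),
         validity = function(object) {
           if (length(object@tmStart) == 1L && length(object@tmEnd) == 1L &&
               object@tmStart > object@tmEnd)
             "tmStart must be <= tmEnd" else TRUE
         })

#' Comparison of two accessibility profiles
#'
#' @slot residues shared residues
#' @slot delta per-residue ratio difference (a - b)
#' @slot combinedError per-residue errors combined in quadrature
#' @slot k sigma multiplier used for significance
#' @slot nSignificant number of residues with |delta| > k * combinedError
#' @slot allowed maximum significant count compatible with "unchanged"
#' @slot verdict \code{"unchanged"} or \code{"changed"}
#' @exportClass ProfileComparison
setClass("ProfileComparison",
         representation(residues = "integer", delta = "numeric",
                        combinedError = "numeric", k = "numeric",
                        nSignificant = "integer", allowed = "integer",
                        verdict = "character"),
         validity = function(object) {
           msg <- character()
           if (object@nSignificant < 0)
             msg <- c(msg, "nSignificant must be >= 0")
           if (!object@verdict %in% c("unchanged", "changed"))
             msg <- c(msg, "verdict must be 'unchanged' or 'changed'")
           if (length(msg)) msg else TRUE
         })

## ---------------------------------------------------------------------------
## Topology fixture (simulator ground truth)
## ---------------------------------------------------------------------------

#' Annotated residue range with ground-truth membrane topology
#'
#' Used by the simulator as generating truth and by tests as the reference
#' against which topology calls are scored.  Spans are 1-based inclusive.
#'
#' @slot name fixture name
#' @slot residueRange first and last residue number of the construct
#' @slot tmSpan transmembrane span (subset of helixSpan)
#' @slot helixSpan helical span (subset of residueRange)
#' @slot notableSites named integer vector of labeled residues
#' @exportClass TopologyFixture
setClass("TopologyFixture",
         representation(name = "character", residueRange = "integer",
                        tmSpan = "integer", helixSpan = "integer",
                        notableSites = "integer"),
         validity = function(object) {
           msg <- character()
           ok <- function(x) length(x) == 2L && x[1] <= x[2]
           if (!ok(object@residueRange) || !ok(object@tmSpan) ||
               !ok(object@helixSpan))
             msg <- c(msg, "residueRange, tmSpan, helixSpan must be increasing pairs")
           else {
             if (object@tmSpan[1] < object@helixSpan[1] ||
                 object@tmSpan[2] > object@helixSpan[2])
               msg <- c(msg, "tmSpan must lie within helixSpan")
             if (object@helixSpan[1] < object@residueRange[1] ||
                 object@helixSpan[2] > object@residueRange[2])
               msg <- c(msg, "helixSpan must lie within residueRange")
           }
           if (length(msg)) msg else TRUE
         })

#' @param name,residueRange,tmSpan,helixSpan,notableSites see slots
#' @rdname TopologyFixture-class
#' @export
topologyFixture <- function(name, residueRange, tmSpan, helixSpan,
                            notableSites = integer()) {
  new("TopologyFixture", name = name,
      residueRange = as.integer(residueRange), tmSpan = as.integer(tmSpan),
      helixSpan = as.integer(helixSpan),
      notableSites = setNames(as.integer(notableSites), names(notableSites)))
}

## ---------------------------------------------------------------------------
## Anisotropy titration
## ---------------------------------------------------------------------------

#' Steady-state fluorescence anisotropy titration
#'
#' @slot labeledConc fixed labeled-species concentration (the depletable
#'   observed species), in \code{unit}
#' @slot unit concentration unit tag
#' @slot titrantConc titrant concentrations
#' @slot anisotropy observed anisotropy r per point
#' @slot replicateSd optional per-point replicate standard deviation
#' @exportClass AnisotropyTitration
setClass("AnisotropyTitration",
         representation(labeledConc = "numeric", unit = "character",
                        titrantConc = "numeric", anisotropy = "numeric",
                        replicateSd = "numeric"),
         validity = function(object) {
           msg <- character()
           if (length(object@titrantConc) < 5L)
             msg <- c(msg, "at least 5 titration points are required")
           if (length(object@anisotropy) != length(object@titrantConc))
             msg <- c(msg, "anisotropy and titrantConc lengths differ")
           if (length(object@replicateSd) &&
               length(object@replicateSd) != length(object@titrantConc))
             msg <- c(msg, "replicateSd must be empty or one value per point")
           if (length(msg)) msg else TRUE
         })

#' @param labeledConc,titrantConc,anisotropy,replicateSd,unit see slots
#' @rdname AnisotropyTitration-class
#' @export
anisotropyTitration <- function(labeledConc, titrantConc, anisotropy,
                                replicateSd = numeric(), unit = "mol%") {
  o <- order(titrantConc)
  if (any(anisotropy < -0.05 | anisotropy > 0.4))
    warning("anisotropy values outside the plausible 0-0.4 range")
  new("AnisotropyTitration", labeledConc = as.numeric(labeledConc),
      unit = .canonUnit(unit), titrantConc = as.numeric(titrantConc[o]),
      anisotropy = as.numeric(anisotropy[o]),
      replicateSd = if (length(replicateSd)) as.numeric(replicateSd[o])
                    else numeric())
}

## ---------------------------------------------------------------------------
## Backbone chemical-shift table
## ---------------------------------------------------------------------------

#' Backbone 13C chemical-shift table
#'
#' Per-residue CA/CB/CO shifts (ppm, NA allowed) plus one-letter amino-acid
#' codes, as needed by chemical-shift-index analysis.  Shifts far outside
#' physically plausible ranges are flagged with a warning at construction.
#'
#' @slot residues residue numbers
#' @slot aa one-letter amino-acid codes
#' @slot ca,cb,co shifts in ppm (NA where unassigned)
#' @slot source \code{"csv"}, \code{"nmr-star"} or \code{"synthetic"}
#' @exportClass ShiftTable
setClass("ShiftTable",
         representation(residues = "integer", aa = "character",
                        ca = "numeric", cb = "numeric", co = "numeric",
                        source = "character"),
         validity = function(object) {
           n <- length(object@residues)
           if (any(lengths(list(object@aa, object@ca, object@cb,
                                object@co)) != n))
             "all per-residue fields must have equal length" else TRUE
         })

#' @param residues,aa,ca,cb,co,source see slot documentation
#' @rdname ShiftTable-class
#' @export
shiftTable <- function(residues, aa, ca = NA_real_, cb = NA_real_,
                       co = NA_real_, source = "csv") {
  n <- length(residues)
  rec <- function(x) rep_len(as.numeric(x), n)
  ca <- rec(ca); cb <- rec(cb); co <- rec(co)
  if (any(ca < 38 | ca > 72, na.rm = TRUE))
    warning("some CA shifts fall outside the plausible 38-72 ppm range")
  if (any(co < 165 | co > 185, na.rm = TRUE))
    warning("some CO shifts fall outside the plausible 165-185 ppm range")
  o <- order(residues)
  new("ShiftTable", residues = as.integer(residues[o]),
      aa = toupper(as.character(aa))[o], ca = ca[o], cb = cb[o], co = co[o],
      source = source)
}
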