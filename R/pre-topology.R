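## Paramagnetic-probe accessibility analysis: per-residue I/I0 ratios from
## paired peak lists, transmembrane boundary calling from complementary
## hydrophilic/lipophilic probe profiles, and profile comparison between
## protein variants.

#' Per-residue paramagnetic/diamagnetic intensity-ratio profile
#'
#' Computes I/I0 per matched assignment between a probe-containing
#' (paramagnetic) and a probe-free (diamagnetic) peak table.  A low ratio
#' means high probe access.  Peaks present in the diamagnetic table but
#' broadened beyond detection in the paramagnetic one get ratio 0 with an
#' error of \code{noise / I_dia}.  The per-residue error is
#' \code{max(noise-derived error, 0.05 * ratio)}: whichever of the
#' spectral noise estimate and 5\% of the value is larger.
#'
#' @param paramagneticPeaks,diamagneticPeaks peak tables (data.frames with
#'   at least \code{assignment}, \code{residue}, \code{intensity}; see
#'   \code{\link{readPeakTable}})
#' @param noise spectral noise floor, in intensity units (>= 0)
#' @param probe probe class, \code{"hydrophilic"} or \code{"lipophilic"}
#' @param probeName free-text probe identity for the record
#' @return an \linkS4class{AccessibilityProfile}
#' @export
intensityRatioProfile <- function(paramagneticPeaks, diamagneticPeaks,
                                  noise = 0,
                                  probe = c("hydrophilic", "lipophilic"),
                                  probeName = "") {
  probe <- match.arg(probe)
  if (noise < 0) stop("noise floor must be non-negative")
  for (tab in list(paramagneticPeaks, diamagneticPeaks))
    if (any(tab$intensity < 0)) stop("negative intensities are not allowed")
  dia <- diamagneticPeaks
  para <- paramagneticPeaks
  idx <- match(dia$assignment, para$assignment)
  if (all(is.na(idx)) && nrow(dia))
    stop("no matched assignments between the two peak tables")
  iDia <- dia$intensity
  iPara <- para$intensity[idx]
  detected <- !is.na(iPara)
  ratio <- ifelse(detected, iPara / iDia, 0)
  noiseErr <- ifelse(detected,
                     ratio * sqrt((noise / pmax(iPara, noise))^2 +
                                  (noise / iDia)^2),
                     noise / iDia)
  err <- pmax(noiseErr, 0.05 * ratio)
  accessibilityProfile(dia$residue, ratio, err, probe = probe,
                       probeName = probeName)
}

## maximal runs of consecutive residue numbers where mask is TRUE;
## returns IRanges in residue coordinates
.maskRuns <- function(residues, mask) {
  if (!any(mask)) return(IRanges::IRanges())
  res <- residues[mask]
  brk <- c(0, which(diff(res) != 1L), length(res))
  starts <- res[brk[-length(brk)] + 1L]
  ends <- res[brk[-1L]]
  IRanges::IRanges(start = starts, end = ends)
}

#' Call transmembrane boundaries from complementary probe profiles
#'
#' The membrane-embedded span is protected from the water-soluble probe
#' (high I/I0 plateau) while maximally accessible to the lipid-partitioning
#' probe (low I/I0 trough).  After moving-median smoothing of both
#' profiles, the TM is called as the longest contiguous residue run where
#' the hydrophilic ratio is at or above \code{highThreshold} and the
#' lipophilic ratio at or below \code{lowThreshold}, subject to a minimum
#' run length.  When no run qualifies the call carries a
#' no-membrane-embedded-span flag.
#'
#' @param hydrophilic,lipophilic \linkS4class{AccessibilityProfile}s of the
#'   matching probe classes, overlapping on at least 10 residues
#' @param highThreshold hydrophilic plateau threshold (default 0.7)
#' @param lowThreshold lipophilic trough threshold (default 0.5)
#' @param window moving-median window, odd (default 3)
#' @param minRun minimum TM run length in residues (default 12)
#' @return a \linkS4class{TopologyCall}
#' @examples
#' pr <- simulatePreProfiles(beta1Fixture(), noiseSd = 0, seed = 1)
#' tmSpan(callTmBoundaries(pr$hydrophilic, pr$lipophilic))
#' @export
callTmBoundaries <- function(hydrophilic, lipophilic, highThreshold = 0.7,
                             lowThreshold = 0.5, window = 3, minRun = 12) {
  stopifnot(is(hydrophilic, "AccessibilityProfile"),
            is(lipophilic, "AccessibilityProfile"))
  if (probeType(hydrophilic) != "hydrophilic" ||
      probeType(lipophilic) != "lipophilic")
    stop("arguments must be a hydrophilic and a lipophilic profile, ",
         "in that order")
  shared <- intersect(residueNumbers(hydrophilic), residueNumbers(lipophilic))
  if (length(shared) < 10L)
    stop("profiles overlap on fewer than 10 residues")
  shared <- sort(shared)
  h <- ratios(hydrophilic)[match(shared, residueNumbers(hydrophilic))]
  l <- ratios(lipophilic)[match(shared, residueNumbers(lipophilic))]
  sm <- function(x) if (window > 1)
    stats::runmed(x, window, endrule = "keep") else x
  h <- sm(h); l <- sm(l)
  mask <- h >= highThreshold & l <= lowThreshold
  runs <- .maskRuns(shared, mask)
  runs <- runs[IRanges::width(runs) >= minRun]
  evidence <- list(
    hydrophilic = c(name = hydrophilic@probeName,
                    meanInMask = mean(h[mask]), meanOutside = mean(h[!mask])),
    lipophilic = c(name = lipophilic@probeName,
                   meanInMask = mean(l[mask]), meanOutside = mean(l[!mask])),
    thresholds = c(high = highThreshold, low = lowThreshold,
                   window = window, minRun = minRun))
  if (!length(runs)) {
    return(new("TopologyCall", tmStart = integer(), tmEnd = integer(),
               protectedSegments = IRanges::IRanges(),
               exposedSegments = .maskRuns(shared, rep(TRUE, length(shared))),
               evidence = evidence, noSpan = TRUE))
  }
  tm <- runs[which.max(IRanges::width(runs))]
  inTm <- shared >= IRanges::start(tm) & shared <= IRanges::end(tm)
  new("TopologyCall", tmStart = IRanges::start(tm), tmEnd = IRanges::end(tm),
      protectedSegments = .maskRuns(shared, mask),
      exposedSegments = .maskRuns(shared, !inTm),
      evidence = evidence, noSpan = FALSE)
}

#' Compare two accessibility profiles
#'
#' Per-residue ratio differences with errors combined in quadrature.  A
#' residue is significantly different when |delta| exceeds \code{k} times
#' its combined error.  The verdict is \code{"unchanged"} when the count
#' of significant residues stays within what chance alone produces at the
#' chosen \code{k}: the larger of 5\% of the shared residues (rounded up)
#' and the 95th percentile of the binomial null count.
#'
#' @param a,b \linkS4class{AccessibilityProfile}s of the same probe class
#'   sharing at least 10 residues
#' @param k sigma multiplier for per-residue significance (default 2)
#' @return a \linkS4class{ProfileComparison}
#' @export
compareProfiles <- function(a, b, k = 2) {
  stopifnot(is(a, "AccessibilityProfile"), is(b, "AccessibilityProfile"))
  if (probeType(a) != probeType(b))
    stop("cannot compare profiles of different probe classes ('",
         probeType(a), "' vs '", probeType(b), "')")
  shared <- sort(intersect(residueNumbers(a), residueNumbers(b)))
  if (length(shared) < 10L) stop("fewer than 10 shared residues")
  ia <- match(shared, residueNumbers(a))
  ib <- match(shared, residueNumbers(b))
  delta <- ratios(a)[ia] - ratios(b)[ib]
  combErr <- sqrt(profileErrors(a)[ia]^2 + profileErrors(b)[ib]^2)
  sig <- abs(delta) > k * combErr & combErr > 0
  n <- length(shared)
  allowed <- max(ceiling(0.05 * n),
                 qbinom(0.95, n, 2 * pnorm(-k)))
  nSig <- sum(sig)
  new("ProfileComparison", residues = as.integer(shared), delta = delta,
      combinedError = combErr, k = k, nSignificant = as.integer(nSig),
      allowed = as.integer(allowed),
      verdict = if (nSig <= allowed) "unchanged" else "changed")
}
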