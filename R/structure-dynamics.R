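## Secondary structure from backbone 13C shifts (chemical shift index),
## CLEANEX hydrogen-exchange ratios, and per-residue CPMG R2 fits.

#' Random-coil 13C reference shifts
#'
#' Standard published random-coil CA/CB/CO chemical shifts per amino acid,
#' shipped as a plain-text table and used as the default reference for
#' \code{\link{csiSecondaryStructure}}.
#'
#' @return data.frame with columns \code{aa}, \code{ca}, \code{cb},
#'   \code{co}
#' @export
randomCoilShifts <- function() {
  path <- system.file("extdata", "random_coil_shifts.csv",
                      package = "BicelleNMR", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

## per-atom CSI index: +1 above coil + threshold, -1 below coil - threshold
.csiIndex <- function(shift, coil, threshold) {
  d <- shift - coil
  idx <- integer(length(d))
  idx[!is.na(d) & d > threshold] <- 1L
  idx[!is.na(d) & d < -threshold] <- -1L
  idx[is.na(d)] <- NA_integer_
  idx
}

#' Chemical-shift-index secondary-structure calling
#'
#' Classifies each residue as helix, sheet or coil from the deviation of
#' its backbone 13C shifts from random-coil values.  Per atom, a deviation
#' beyond the threshold gives an index of +1 (downfield) or -1 (upfield);
#' helix is indicated by +1 for CA and CO and -1 for CB, sheet by the
#' opposite signs.  The consensus is the majority over the atoms observed
#' for that residue (ties are coil).  Helix segments are runs of at least
#' \code{minHelix} consecutive helix residues with CA coverage of at least
#' 70\%.  This rule-based caller approximates a full dihedral-database
#' analysis and is intended for well-resolved helical membrane-protein
#' data.
#'
#' @param shifts a \linkS4class{ShiftTable}
#' @param reference random-coil table (default \code{randomCoilShifts()});
#'   data.frame with columns \code{aa}, \code{ca}, \code{cb}, \code{co}
#' @param thresholds named vector of per-atom deviation thresholds in ppm
#'   (defaults CA 0.7, CB 0.7, CO 0.5)
#' @param minHelix minimum helix run length (default 4)
#' @return list with \code{perResidue} (data.frame: residue, aa, per-atom
#'   indices, consensus) and \code{helixSegments} (\linkS4class{IRanges}
#'   in residue coordinates), plus the reference used
#' @export
csiSecondaryStructure <- function(shifts, reference = randomCoilShifts(),
                                  thresholds = c(ca = 0.7, cb = 0.7,
                                                 co = 0.5),
                                  minHelix = 4) {
  stopifnot(is(shifts, "ShiftTable"))
  if (!length(shifts@residues)) stop("empty shift table")
  ref <- reference[match(shifts@aa, reference$aa), ]
  idxCa <- .csiIndex(shifts@ca, ref$ca, thresholds["ca"])
  idxCb <- .csiIndex(shifts@cb, ref$cb, thresholds["cb"])
  idxCo <- .csiIndex(shifts@co, ref$co, thresholds["co"])
  ## helix-consistent index sign per atom: CA +1, CO +1, CB -1
  votes <- cbind(helixCa = idxCa == 1L, helixCo = idxCo == 1L,
                 helixCb = idxCb == -1L)
  sheet <- cbind(idxCa == -1L, idxCo == -1L, idxCb == 1L)
  nh <- rowSums(votes, na.rm = TRUE)
  ns <- rowSums(sheet, na.rm = TRUE)
  avail <- rowSums(!is.na(cbind(idxCa, idxCo, idxCb)))
  consensus <- rep("coil", length(nh))
  consensus[avail > 0 & nh > avail / 2] <- "helix"
  consensus[avail > 0 & ns > avail / 2] <- "sheet"
  runs <- .maskRuns(shifts@residues, consensus == "helix")
  runs <- runs[IRanges::width(runs) >= minHelix]
  if (length(runs)) {                       # CA coverage >= 70% per segment
    cov <- vapply(seq_along(runs), function(i) {
      inSeg <- shifts@residues >= IRanges::start(runs)[i] &
               shifts@residues <= IRanges::end(runs)[i]
      mean(!is.na(shifts@ca[inSeg]))
    }, numeric(1))
    runs <- runs[cov >= 0.7]
  }
  list(perResidue = data.frame(residue = shifts@residues, aa = shifts@aa,
                               idxCa = idxCa, idxCb = idxCb, idxCo = idxCo,
                               consensus = consensus),
       helixSegments = runs,
       reference = "random_coil_shifts.csv")
}

#' CLEANEX hydrogen-exchange intensity ratios
#'
#' Ratio of per-residue peak intensities after the water-exchange mixing
#' period to matched no-mixing reference intensities.  Low I/I0 marks
#' exchange-resistant (typically membrane-embedded or stably hydrogen-
#' bonded) amides; interpretation is left to the caller, no thresholding
#' is applied.
#'
#' @param mixIntensities,referenceIntensities numeric vectors named by
#'   residue number
#' @return named numeric vector of I/I0 over the matched residues
#' @export
cleanexRatio <- function(mixIntensities, referenceIntensities) {
  shared <- intersect(names(mixIntensities), names(referenceIntensities))
  if (!length(shared)) stop("no matched residues")
  r <- mixIntensities[shared] / referenceIntensities[shared]
  r[order(as.integer(shared))]
}

#' Per-residue monoexponential R2 relaxation fits
#'
#' Fits \code{I(t) = I0 * exp(-R2 t)} to each residue's transverse
#' magnetization decay by least squares (log-linear start, bounded
#' Levenberg-Marquardt refinement with R2 >= 0).  Delays are taken from
#' the decay object in msec; rates are returned in 1/s.  Residues whose
#' fits do not converge, or with fewer than 3 positive-intensity delays,
#' are flagged and excluded with a warning.
#'
#' @param decay a \linkS4class{RelaxationDecay}
#' @return data.frame with columns \code{residue}, \code{r2} (1/s),
#'   \code{r2_se}, \code{i0}, \code{i0_se}
#' @examples
#' d <- simulateR2Decay(c(A10 = 10), noiseSd = 0, seed = 1)
#' fitR2(d)$r2
#' @export
fitR2 <- function(decay) {
  stopifnot(is(decay, "RelaxationDecay"))
  tSec <- decay$delay_ms / 1000
  Y <- SummarizedExperiment::assay(decay, "intensities")
  res <- lapply(seq_len(nrow(Y)), function(i) {
    y <- Y[i, ]
    pos <- y > 0
    if (sum(pos) < 3L) return(NULL)
    sl <- unname(stats::coef(stats::lm(log(y[pos]) ~ tSec[pos])))
    init <- c(exp(sl[1]), max(0, -sl[2]))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = init,
                         fn = function(p) y - p[1] * exp(-p[2] * tSec),
                         lower = c(0, 0),
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info == 0) return(NULL)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 2))
    c(i0 = fit$par[1], r2 = fit$par[2], i0_se = unname(se[1]),
      r2_se = unname(se[2]))
  })
  bad <- vapply(res, is.null, logical(1))
  if (any(bad))
    warning(sum(bad), " residue(s) excluded (non-convergent or too few ",
            "positive-intensity delays)")
  out <- do.call(rbind, res[!bad])
  data.frame(residue = residueNumbers(decay)[!bad],
             r2 = out[, "r2"], r2_se = out[, "r2_se"],
             i0 = out[, "i0"], i0_se = out[, "i0_se"])
}
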