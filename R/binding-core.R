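## Closed-form mathematics of the 1:1 ligand-depletion binding model,
## the hybrid 1H/15N shift statistic, and concentration-unit conversions.
## These primitives are shared by every fitting module.

## bound fraction of the fixed species U for the equilibrium U + L <-> UL:
##   f_b = [(Kd+L0+U0) - sqrt((Kd+L0+U0)^2 - 4 U0 L0)] / (2 U0)
## evaluated in the algebraically equivalent, cancellation-free form
##   f_b = 2 L0 / (S + sqrt(S^2 - 4 U0 L0)),  S = Kd + L0 + U0
.fb <- function(kd, u0, l0) {
  s <- kd + u0 + l0
  disc <- s * s - 4 * u0 * l0
  disc[disc < 0] <- 0                    # guard against roundoff at kd ~ 0
  denom <- s + sqrt(disc)
  fb <- ifelse(l0 == 0, 0, 2 * l0 / denom)
  pmin(pmax(fb, 0), 1)
}

#' Bound fraction under the 1:1 ligand-depletion model
#'
#' Computes the equilibrium fraction of the fixed (observed) species bound
#' by the titrant, from the closed-form root of the mass-action quadratic.
#' Ligand depletion is fully accounted for, so the result is valid when the
#' fixed-species concentration is comparable to the Kd, as is typical for
#' NMR-detected titrations of membrane-protein domains in bicelles.
#'
#' @param params a \linkS4class{BindingParameters} (only \code{kd} and the
#'   unit tag are used)
#' @param conc a \linkS4class{ConcentrationPair}; \code{l0} may be a vector
#' @return bound fraction(s) in \code{[0, min(1, l0/u0)]}
#' @examples
#' boundFraction(bindingParameters(kd = 1), concentrationPair(1, 1))
#' # (3 - sqrt(5))/2
#' @export
setGeneric("boundFraction", function(params, conc)
  standardGeneric("boundFraction"))

#' @rdname boundFraction
setMethod("boundFraction", signature("BindingParameters", "ConcentrationPair"),
          function(params, conc) {
  .checkSameUnit(params@unit, conc@unit)
  .fb(params@kd, conc@u0, conc@l0)
})

#' Predicted observable change for a 1:1 binding titration
#'
#' The observed response is the saturation response scaled by the bound
#' fraction: \code{deltaMax * boundFraction(...)}.  It is monotone
#' non-decreasing in the titrant concentration and approaches
#' \code{deltaMax} at saturation.
#'
#' @inheritParams boundFraction
#' @return predicted observable change(s), same length as \code{conc@l0}
#' @export
setGeneric("predictedResponse", function(params, conc)
  standardGeneric("predictedResponse"))

#' @rdname predictedResponse
setMethod("predictedResponse",
          signature("BindingParameters", "ConcentrationPair"),
          function(params, conc) {
  params@deltaMax * boundFraction(params, conc)
})

#' Hybrid 1H/15N amide chemical-shift change
#'
#' Collapses the 1H and 15N components of a peak movement into a single
#' scalar.  The default form is the weighted root-mean-square
#' \deqn{\Delta(HN) = \sqrt{(W_H^2 \Delta H^2 + W_N^2 \Delta N^2)/2}}
#' with \eqn{W_H = 1} and \eqn{W_N = 0.154}.  The alternative
#' \code{"quadrature"} form \eqn{\sqrt{\Delta H^2 + (W_N \Delta N)^2}} is
#' also common in the chemical-shift-perturbation literature and is
#' exposed as a strategy; both are symmetric in the sign of the inputs and
#' zero iff both components are zero.
#'
#' @param p a \linkS4class{ShiftPerturbation} (vectorized over peaks)
#' @param form \code{"rms"} (default) or \code{"quadrature"}
#' @return hybrid shift(s) in ppm, >= 0
#' @examples
#' hybridShift(shiftPerturbation(0.2, 0))   # 0.2/sqrt(2)
#' hybridShift(shiftPerturbation(0, 1.0))   # 0.154/sqrt(2)
#' @export
hybridShift <- function(p, form = c("rms", "quadrature")) {
  form <- match.arg(form)
  switch(form,
    rms = sqrt((p@wH^2 * p@deltaH^2 + p@wN^2 * p@deltaN^2) / 2),
    quadrature = sqrt(p@deltaH^2 + (p@wN * p@deltaN)^2))
}

#' Protein concentration in mol% of long-chain lipid
#'
#' The natural concentration unit for association of membrane-embedded
#' species: (moles protein x 100) / (moles long-chain lipid).  The
#' short-chain detergent rimming the bicelle is not a lipid and must be
#' excluded from \code{lipidMolar} by the caller (see
#' \code{\link{bicelleLipidMolarity}}).
#'
#' @param proteinMolar protein concentration (any molar unit)
#' @param lipidMolar long-chain lipid concentration (same unit)
#' @return concentration in mol%
#' @examples
#' molPercent(150e-6, 88e-3)  # ~0.17 mol%
#' @export
molPercent <- function(proteinMolar, lipidMolar) {
  if (any(lipidMolar <= 0)) stop("lipid concentration must be positive")
  if (any(proteinMolar < 0)) stop("protein concentration must be non-negative")
  proteinMolar * 100 / lipidMolar
}

#' Long-chain lipid molarity of a two-component bicelle mixture
#'
#' Solves the mass balance \code{mwLong * x + mwShort * x / q = 10 * w}
#' g/L for the long-chain lipid molarity \code{x}, where \code{w} is the
#' total amphiphile content in \% w/v and \code{q} the long-chain to
#' short-chain mole ratio.  For mixed long-chain compositions pass the
#' mole-weighted mean molecular weight.
#'
#' @param totalWvPercent total amphiphile content, \% w/v (g per 100 mL)
#' @param q long-chain / short-chain mole ratio
#' @param mwLong,mwShort molecular weights, g/mol (defaults: DMPC 677.9,
#'   D6PC 453.5)
#' @return long-chain lipid concentration in mol/L
#' @examples
#' bicelleLipidMolarity(20, 0.3)  # ~0.091 M DMPC in 20% q=0.3 DMPC/D6PC
#' @export
bicelleLipidMolarity <- function(totalWvPercent, q, mwLong = 677.9,
                                 mwShort = 453.5) {
  if (any(c(totalWvPercent, q, mwLong, mwShort) <= 0))
    stop("all inputs must be positive")
  10 * totalWvPercent / (mwLong + mwShort / q)
}
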