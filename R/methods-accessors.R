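#' Accessors for BicelleNMR classes
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{kdEstimate}/\code{kdStdError}/\code{boundFlag}/
#' \code{saturationFraction}/\code{lowerBoundValue}/\code{perPeakParameters}/
#' \code{excludedPeaks} for fit results; \code{residueNumbers},
#' \code{ratios}, \code{profileErrors}, \code{probeType} for accessibility
#' profiles; \code{tmSpan}/\code{helixSpan} for topology calls and
#' fixtures; \code{titrantConcentrations}, \code{fixedConcentration},
#' \code{concentrationUnit}, \code{exchangeRegime} for titrations.
#'
#' @param object an object of the documented class
#' @return the corresponding component
#' @name accessors
NULL

#' @rdname accessors
setMethod("kdEstimate", "BindingFitResult", function(object) object@kd)

#' @rdname accessors
setMethod("kdStdError", "BindingFitResult", function(object) object@kdSe)

#' @rdname accessors
setMethod("concentrationUnit", "BindingFitResult",
          function(object) object@unit)

#' @rdname accessors
setMethod("concentrationUnit", "TitrationSeries",
          function(object) object@concUnit)

#' @rdname accessors
setMethod("concentrationUnit", "AnisotropyTitration",
          function(object) object@unit)

#' @rdname accessors
setMethod("exchangeRegime", "TitrationSeries", function(object) object@regime)

#' @rdname accessors
setMethod("exchangeRegime", "BindingFitResult", function(object) object@regime)

#' @rdname accessors
setMethod("boundFlag", "BindingFitResult", function(object) object@boundFlag)

#' @rdname accessors
setMethod("saturationFraction", "BindingFitResult",
          function(object) object@saturationFraction)

#' @rdname accessors
setMethod("lowerBoundValue", "BindingFitResult",
          function(object) object@lowerBoundValue)

#' @rdname accessors
setMethod("perPeakParameters", "BindingFitResult",
          function(object) object@perPeak)

#' @rdname accessors
setMethod("excludedPeaks", "BindingFitResult",
          function(object) object@excludedPeaks)

#' @rdname accessors
setMethod("residueNumbers", "TitrationSeries",
          function(object) SummarizedExperiment::rowData(object)$residue)

#' @rdname accessors
setMethod("residueNumbers", "RelaxationDecay",
          function(object) SummarizedExperiment::rowData(object)$residue)

#' @rdname accessors
setMethod("residueNumbers", "AccessibilityProfile",
          function(object) object@residues)

#' @rdname accessors
setMethod("residueNumbers", "ShiftTable", function(object) object@residues)

#' @rdname accessors
setMethod("residueNumbers", "ProfileComparison",
          function(object) object@residues)

#' @rdname accessors
setMethod("ratios", "AccessibilityProfile", function(object) object@ratio)

#' @rdname accessors
setMethod("profileErrors", "AccessibilityProfile",
          function(object) object@error)

#' @rdname accessors
setMethod("probeType", "AccessibilityProfile", function(object) object@probe)

#' @rdname accessors
setMethod("tmSpan", "TopologyCall", function(object) {
  if (object@noSpan) integer(0) else c(object@tmStart, object@tmEnd)
})

#' @rdname accessors
setMethod("tmSpan", "TopologyFixture", function(object) object@tmSpan)

#' @rdname accessors
setMethod("helixSpan", "TopologyFixture", function(object) object@helixSpan)

#' @rdname accessors
setMethod("verdict", "ProfileComparison", function(object) object@verdict)

#' @rdname accessors
setMethod("titrantConcentrations", "TitrationSeries",
          function(object) object$conc)

#' @rdname accessors
setMethod("titrantConcentrations", "AnisotropyTitration",
          function(object) object@titrantConc)

#' @rdname accessors
setMethod("fixedConcentration", "TitrationSeries", function(object) object@u0)

#' @rdname accessors
setMethod("fixedConcentration", "AnisotropyTitration",
          function(object) object@labeledConc)

## -- show methods -----------------------------------------------------------

setMethod("show", "BindingFitResult", function(object) {
  cat("BindingFitResult (", object@regime, ")\n", sep = "")
  if (object@boundFlag == "quantified") {
    cat(sprintf("  Kd = %.4g +/- %.3g %s\n", object@kd, object@kdSe,
                object@unit))
  } else {
    cat(sprintf("  Kd not quantifiable: lower bound %.4g %s (estimate %.4g)\n",
                object@lowerBoundValue, object@unit, object@kd))
  }
  cat(sprintf("  %d peak(s); saturation at max titrant: %.3f\n",
              nrow(object@perPeak), object@saturationFraction))
  if (length(object@excludedPeaks))
    cat("  excluded:", paste(object@excludedPeaks, collapse = ", "), "\n")
})

setMethod("show", "AccessibilityProfile", function(object) {
  cat(sprintf("AccessibilityProfile: %s probe%s, %d residues (%d-%d)\n",
              object@probe,
              if (nzchar(object@probeName))
                paste0(" (", object@probeName, ")") else "",
              length(object@residues), min(object@residues),
              max(object@residues)))
  cat(sprintf("  I/I0 range %.3f-%.3f, %d undetectable peak(s)\n",
              min(object@ratio), max(object@ratio), sum(object@ratio == 0)))
})

setMethod("show", "TopologyCall", function(object) {
  if (object@noSpan) {
    cat("TopologyCall: no membrane-embedded span\n")
  } else {
    cat(sprintf("TopologyCall: TM %d-%d (%d residues)\n", object@tmStart,
                object@tmEnd, object@tmEnd - object@tmStart + 1L))
  }
})

setMethod("show", "ProfileComparison", function(object) {
  cat(sprintf("ProfileComparison: %d shared residues, %d significant at %.3g sigma (allowed %d) -> %s\n",
              length(object@residues), object@nSignificant, object@k,
              object@allowed, object@verdict))
})

setMethod("show", "TopologyFixture", function(object) {
  cat(sprintf("TopologyFixture '%s': residues %d-%d, TM %d-%d, helix %d-%d\n",
              object@name, object@residueRange[1], object@residueRange[2],
              object@tmSpan[1], object@tmSpan[2], object@helixSpan[1],
              object@helixSpan[2]))
})

setMethod("show", "AnisotropyTitration", function(object) {
  cat(sprintf("AnisotropyTitration: %d points, titrant 0-%.4g %s, labeled species %.4g %s\n",
              length(object@titrantConc), max(object@titrantConc),
              object@unit, object@labeledConc, object@unit))
})

setMethod("show", "ShiftTable", function(object) {
  cat(sprintf("ShiftTable (%s): %d residues, CA/CB/CO coverage %d/%d/%d\n",
              object@source, length(object@residues), sum(!is.na(object@ca)),
              sum(!is.na(object@cb)), sum(!is.na(object@co))))
})
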