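#' @rdname accessors
#' @export
setGeneric("kdEstimate", function(object) standardGeneric("kdEstimate"))

#' @rdname accessors
#' @export
setGeneric("kdStdError", function(object) standardGeneric("kdStdError"))

#' @rdname accessors
#' @export
setGeneric("concentrationUnit",
           function(object) standardGeneric("concentrationUnit"))

#' @rdname accessors
#' @export
setGeneric("exchangeRegime", function(object) standardGeneric("exchangeRegime"))

#' @rdname accessors
#' @export
setGeneric("boundFlag", function(object) standardGeneric("boundFlag"))

#' @rdname accessors
#' @export
setGeneric("saturationFraction",
           function(object) standardGeneric("saturationFraction"))

#' @rdname accessors
#' @export
setGeneric("lowerBoundValue", function(object) standardGeneric("lowerBoundValue"))

#' @rdname accessors
#' @export
setGeneric("perPeakParameters",
           function(object) standardGeneric("perPeakParameters"))

#' @rdname accessors
#' @export
setGeneric("excludedPeaks", function(object) standardGeneric("excludedPeaks"))

#' @rdname accessors
#' @export
setGeneric("residueNumbers", function(object) standardGeneric("residueNumbers"))

#' @rdname accessors
#' @export
setGeneric("ratios", function(object) standardGeneric("ratios"))

#' @rdname accessors
#' @export
setGeneric("profileErrors", function(object) standardGeneric("profileErrors"))

#' @rdname accessors
#' @export
setGeneric("probeType", function(object) standardGeneric("probeType"))

#' @rdname accessors
#' @export
setGeneric("tmSpan", function(object) standardGeneric("tmSpan"))

#' @rdname accessors
#' @export
setGeneric("helixSpan", function(object) standardGeneric("helixSpan"))

#' @rdname accessors
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setGeneric("titrantConcentrations",
           function(object) standardGeneric("titrantConcentrations"))

#' @rdname accessors
#' @export
setGeneric("fixedConcentration",
           function(object) standardGeneric("fixedConcentration"))

#' Fit the 1:1 binding model appropriate to an object's regime
#'
#' For a \linkS4class{TitrationSeries} this dispatches to
#' \code{\link{fitSlowExchangeGlobal}} or
#' \code{\link{fitFastExchangeGlobal}} according to the series' exchange
#' regime; for an \linkS4class{AnisotropyTitration} it calls
#' \code{\link{fitAnisotropy}}.
#'
#' @param object the titration to fit
#' @param ... passed to the regime-specific fitter
#' @return a \linkS4class{BindingFitResult}
#' @export
setGeneric("fitBinding", function(object, ...) standardGeneric("fitBinding"))
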