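## Global multi-peak fitting of NMR-monitored titrations.
##
## Both regimes share one engine: a single global Kd plus one nuisance
## amplitude per peak (starting intensity I0 for slow exchange, saturation
## shift deltaMax for fast exchange), minimized jointly over all peaks by
## bounded Levenberg-Marquardt least squares (minpack.lm) with a
## multistart over Kd, because the isotherm's likelihood is nearly flat in
## Kd when binding does not approach saturation.

.kdStarts <- function(maxL0) c(0.1, 1, 10) * maxL0

## profiled residual sum of squares over a log-spaced Kd grid: for fixed
## Kd the per-peak amplitudes are linear and optimized in closed form, so
## a cheap 1-D scan locates the global basin before Levenberg-Marquardt
## refinement (the isotherm's likelihood has a flat shoulder towards
## large Kd and a local minimum at Kd -> 0 in strong-depletion designs)
.kdGridBest <- function(Y, u0, l0, regime, maxL0, nonneg) {
  grid <- maxL0 * 10^seq(-4, 3, length.out = 71)
  rss <- vapply(grid, function(kd) {
    s <- .titrShape(kd, u0, l0, regime)
    ss <- sum(s^2)
    if (ss == 0) return(sum(Y^2))
    a <- as.vector(Y %*% s) / ss
    if (nonneg) a <- pmax(a, 0)
    sum((Y - a %o% s)^2)
  }, numeric(1))
  grid[which.min(rss)]
}

## model matrix for a given kd: amps %o% shape(L0)
.titrShape <- function(kd, u0, l0, regime) {
  fb <- .fb(kd, u0, l0)
  if (regime == "slow_exchange_intensity") 1 - fb else fb
}

## core engine: returns list(kd, kdSe, amps, ampSe, residuals, info)
.fitGlobalEngine <- function(Y, l0, u0, regime,
                             kdStarts = .kdStarts(max(l0))) {
  P <- nrow(Y)
  kdStarts <- unique(c(.kdGridBest(Y, u0, l0, regime, max(l0),
                                   regime == "slow_exchange_intensity"),
                       kdStarts))
  ampInit <- if (regime == "slow_exchange_intensity") {
    Y[, which.min(l0)]                       # zero-titrant intensities
  } else {
    apply(Y, 1, function(y) max(abs(y)) * sign(y[which.max(abs(y))]))
  }
  residFun <- function(par) {
    shape <- .titrShape(par[1], u0, l0, regime)
    as.vector(Y - par[-1] %o% shape)
  }
  lower <- c(1e-10 * max(l0), rep(if (regime == "slow_exchange_intensity")
                                    0 else -Inf, P))
  fits <- lapply(kdStarts, function(k0) {
    tryCatch(
      minpack.lm::nls.lm(par = c(k0, ampInit), fn = residFun, lower = lower,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok))
    stop("global 1:1 fit failed to converge from every start; ",
         "diagnostics: ",
         paste(vapply(fits, conditionMessage, character(1)), collapse = "; "))
  dev <- vapply(fits[ok], stats::deviance, numeric(1))
  best <- fits[ok][[which.min(dev)]]
  par <- unname(best$par)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(par)))
  res <- matrix(residFun(par), nrow = P)
  list(kd = par[1], kdSe = unname(se[1]), amps = par[-1],
       ampSe = unname(se[-1]), residuals = res,
       info = list(deviance = min(dev), df = length(Y) - length(par),
                   convergence = best$info, message = best$message,
                   multistart = data.frame(kd0 = kdStarts[ok],
                                           deviance = dev)))
}

.buildFitResult <- function(eng, series, excluded = character()) {
  l0 <- titrantConcentrations(series)
  regime <- exchangeRegime(series)
  ampName <- if (regime == "slow_exchange_intensity") "I0" else "deltaMax"
  perPeak <- data.frame(
    peak = SummarizedExperiment::rowData(series)$assignment,
    residue = SummarizedExperiment::rowData(series)$residue,
    estimate = eng$amps, se = eng$ampSe)
  names(perPeak)[3] <- ampName
  names(perPeak)[4] <- paste0(ampName, "_se")
  res <- new("BindingFitResult", kd = eng$kd, kdSe = eng$kdSe,
             unit = concentrationUnit(series), regime = regime,
             perPeak = perPeak, residuals = eng$residuals,
             saturationFraction = .fb(eng$kd, fixedConcentration(series),
                                      max(l0)),
             boundFlag = "quantified", lowerBoundValue = numeric(),
             excludedPeaks = excluded, fitInfo = eng$info)
  assessSaturation(res, series)
}

#' Global slow-exchange intensity fit of an NMR titration
#'
#' In slow exchange, complex formation removes intensity from the
#' free-state peaks, so each peak decays as
#' \code{I(L0) = I0 * (1 - f_b(Kd, U0, L0))}.  All peaks are fit jointly
#' with a single global Kd and free per-peak starting intensities; Kd
#' standard errors come from the Jacobian-based covariance at the optimum.
#' The saturation diagnostic of \code{\link{assessSaturation}} is applied
#' with its defaults before the result is returned.
#'
#' @param series a \linkS4class{TitrationSeries} with regime
#'   \code{"slow_exchange_intensity"}
#' @return a \linkS4class{BindingFitResult}
#' @seealso \code{\link{fitFastExchangeGlobal}}, \code{\link{refitExcluding}}
#' @export
fitSlowExchangeGlobal <- function(series) {
  stopifnot(is(series, "TitrationSeries"))
  if (exchangeRegime(series) != "slow_exchange_intensity")
    stop("series regime is not 'slow_exchange_intensity'")
  Y <- SummarizedExperiment::assay(series, "observables")
  if (all(Y == 0)) stop("all intensities are zero; nothing to fit")
  if (nrow(Y) < 2L)
    warning("global fit with a single peak: Kd rests on one trace only")
  eng <- .fitGlobalEngine(Y, titrantConcentrations(series),
                          fixedConcentration(series),
                          "slow_exchange_intensity")
  .buildFitResult(eng, series)
}

#' Global fast-exchange chemical-shift fit of an NMR titration
#'
#' In fast exchange, peaks move continuously; the observables are hybrid
#' shift changes relative to the zero-titrant point and follow
#' \code{delta(L0) = deltaMax * f_b(Kd, U0, L0)} with a global Kd and one
#' free saturation shift per peak.
#'
#' @param series a \linkS4class{TitrationSeries} with regime
#'   \code{"fast_exchange_shift"}
#' @param noise shift-measurement noise floor (ppm); if no peak moves by
#'   more than this the fit aborts with "no binding signal"
#' @return a \linkS4class{BindingFitResult}
#' @export
fitFastExchangeGlobal <- function(series, noise = 0) {
  stopifnot(is(series, "TitrationSeries"))
  if (exchangeRegime(series) != "fast_exchange_shift")
    stop("series regime is not 'fast_exchange_shift'")
  Y <- SummarizedExperiment::assay(series, "observables")
  if (max(abs(Y)) <= noise)
    stop("no binding signal: all shift changes are within the noise floor")
  eng <- .fitGlobalEngine(Y, titrantConcentrations(series),
                          fixedConcentration(series), "fast_exchange_shift")
  .buildFitResult(eng, series)
}

#' @rdname fitBinding
setMethod("fitBinding", "TitrationSeries", function(object, ...) {
  if (exchangeRegime(object) == "slow_exchange_intensity")
    fitSlowExchangeGlobal(object)
  else fitFastExchangeGlobal(object, ...)
})

#' Saturation diagnostic and lower-bound Kd reporting
#'
#' A titration that does not approach saturation cannot pin down the Kd;
#' only a lower limit is defensible.  The fit is downgraded to a lower
#' bound when the bound fraction at the highest titrant concentration is
#' strictly below \code{threshold}, or when the upper edge of the
#' approximate 95\% Kd confidence interval exceeds \code{ciMultiple} times
#' the highest titrant concentration.  A fit sitting exactly at the
#' threshold stays quantified (strict inequality, the documented
#' tie-break).  The reported bound defaults to the highest titrant
#' concentration and is configurable via \code{lowerBoundFun}.
#'
#' @param result a completed \linkS4class{BindingFitResult}
#' @param series the \linkS4class{TitrationSeries} the result came from
#'   (source of U0 and the concentration schedule)
#' @param threshold saturation-fraction threshold (default 0.5)
#' @param ciMultiple Kd-CI multiple of max(L0) above which only a bound is
#'   reported (default 3)
#' @param lowerBoundFun function of max(L0) giving the reported bound
#'   (default: identity)
#' @return the updated \linkS4class{BindingFitResult}
#' @export
assessSaturation <- function(result, series, threshold = 0.5,
                             ciMultiple = 3, lowerBoundFun = identity) {
  stopifnot(is(result, "BindingFitResult"))
  maxL0 <- max(titrantConcentrations(series))
  satF <- .fb(result@kd, fixedConcentration(series), maxL0)
  ciUpper <- if (is.na(result@kdSe)) Inf else result@kd + 1.96 * result@kdSe
  result@saturationFraction <- satF
  if (satF < threshold || ciUpper > ciMultiple * maxL0) {
    result@boundFlag <- "lower_bound"
    result@lowerBoundValue <- lowerBoundFun(maxL0)
  } else {
    result@boundFlag <- "quantified"
    result@lowerBoundValue <- numeric()
  }
  validObject(result)
  result
}

#' Refit a titration after excluding outlier peaks
#'
#' Non-ideal traces (e.g. peaks also reporting on a second
#' concentration-dependent process) can be dropped and the global fit
#' repeated on the reduced peak set; the exclusions are recorded in the
#' result.
#'
#' @param series a \linkS4class{TitrationSeries}
#' @param exclude assignment labels of peaks to drop (must leave at least
#'   one peak)
#' @param ... passed to the regime-specific fitter
#' @return a \linkS4class{BindingFitResult} with \code{excludedPeaks} set
#' @export
refitExcluding <- function(series, exclude = character(), ...) {
  stopifnot(is(series, "TitrationSeries"))
  labels <- SummarizedExperiment::rowData(series)$assignment
  exclude <- as.character(exclude)
  unknown <- setdiff(exclude, labels)
  if (length(unknown))
    stop("unknown peak label(s): ", paste(unknown, collapse = ", "))
  keep <- !(labels %in% exclude)
  if (!any(keep)) stop("cannot exclude every peak")
  sub <- series[keep, ]
  res <- fitBinding(sub, ...)
  res@excludedPeaks <- exclude
  res
}
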