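## 1:1 binding fits of steady-state fluorescence anisotropy titrations.
## The labeled species is the depletable observed species; the observable
## interpolates between the free and bound anisotropy with the bound
## fraction from the shared ligand-depletion model.

#' Fit a 1:1 binding isotherm to an anisotropy titration
#'
#' Models the observed anisotropy as
#' \code{r(L0) = r_free + (r_bound - r_free) * f_b(Kd, U0, L0)} where U0
#' is the fixed labeled-species concentration, and fits Kd, r_free and
#' r_bound by bounded Levenberg-Marquardt least squares with the same Kd
#' multistart and saturation/lower-bound diagnostics as the NMR titration
#' fits.  Points with replicate standard deviations are weighted
#' inversely by them when available for every point.
#'
#' @param t an \linkS4class{AnisotropyTitration}
#' @param threshold,ciMultiple,lowerBoundFun forwarded to
#'   \code{\link{assessSaturation}}-equivalent lower-bound logic
#' @return a \linkS4class{BindingFitResult}; \code{perPeakParameters}
#'   holds \code{r_free} and \code{r_bound}
#' @examples
#' tt <- simulateAnisotropy(bindingParameters(0.09, unit = "mol%"),
#'                          u0 = 0.0023, noiseSd = 0, seed = 1)
#' kdEstimate(fitAnisotropy(tt))
#' @export
fitAnisotropy <- function(t, threshold = 0.5, ciMultiple = 3,
                          lowerBoundFun = identity) {
  stopifnot(is(t, "AnisotropyTitration"))
  l0 <- t@titrantConc
  r <- t@anisotropy
  u0 <- t@labeledConc
  if (stats::cor(l0, r) < 0 && r[which.max(l0)] < r[which.min(l0)])
    stop("no binding signal or inverted labeling: anisotropy decreases ",
         "with titrant")
  w <- if (length(t@replicateSd) && all(t@replicateSd > 0))
         1 / t@replicateSd else rep(1, length(l0))
  residFun <- function(par) {
    w * (r - (par[2] + (par[3] - par[2]) * .fb(par[1], u0, l0)))
  }
  ## profiled grid start: for fixed Kd the model is linear in
  ## (r_free, r_bound), so scan Kd over a log grid first
  grid <- max(l0) * 10^seq(-4, 3, length.out = 71)
  rss <- vapply(grid, function(kd) {
    fb <- .fb(kd, u0, l0)
    sum(stats::lm.fit(cbind(1, fb), r)$residuals^2)
  }, numeric(1))
  init <- c(NA, unname(r[which.min(l0)]), max(r))
  fits <- lapply(unique(c(grid[which.min(rss)], .kdStarts(max(l0)))),
                 function(k0) {
    p0 <- init; p0[1] <- k0
    tryCatch(
      minpack.lm::nls.lm(par = p0, fn = residFun,
                         lower = c(1e-10 * max(l0), -Inf, -Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop("anisotropy 1:1 fit failed to converge from every start")
  dev <- vapply(fits[ok], stats::deviance, numeric(1))
  best <- fits[ok][[which.min(dev)]]
  par <- unname(best$par)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  maxL0 <- max(l0)
  satF <- .fb(par[1], u0, maxL0)
  ciUpper <- if (is.na(se[1])) Inf else par[1] + 1.96 * se[1]
  lower <- satF < threshold || ciUpper > ciMultiple * maxL0
  new("BindingFitResult", kd = par[1], kdSe = unname(se[1]), unit = t@unit,
      regime = "anisotropy",
      perPeak = data.frame(parameter = c("r_free", "r_bound"),
                           estimate = par[2:3], se = unname(se[2:3])),
      residuals = matrix(r - (par[2] + (par[3] - par[2]) *
                                .fb(par[1], u0, l0)), nrow = 1),
      saturationFraction = satF,
      boundFlag = if (lower) "lower_bound" else "quantified",
      lowerBoundValue = if (lower) lowerBoundFun(maxL0) else numeric(),
      excludedPeaks = character(),
      fitInfo = list(deviance = min(dev), df = length(l0) - 3,
                     convergence = best$info, message = best$message))
}

#' @rdname fitBinding
setMethod("fitBinding", "AnisotropyTitration", function(object, ...) {
  fitAnisotropy(object, ...)
})
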