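## Independent numeric oracle for the 1:1 mass-action equilibrium
## U + L <-> UL with Kd = [U][L]/[UL]: solve (u0 - x)(l0 - x) = kd * x
## for the complex concentration x by root bracketing, then f_b = x / u0.
## Deliberately avoids the closed-form quadratic used by the package.
fbOracle <- function(kd, u0, l0) {
  if (l0 == 0) return(0)
  g <- function(x) (u0 - x) * (l0 - x) - kd * x
  upper <- min(u0, l0)
  if (kd == 0) return(upper / u0)
  x <- uniroot(g, c(0, upper), tol = 1e-14)$root
  x / u0
}

## median recovered Kd over seeded synthetic titrations
medianRecoveredKd <- function(kdTrue, design, seeds, nPeaks = 4) {
  est <- vapply(seeds, function(s) {
    ts <- simulateTitration(bindingParameters(kdTrue, unit = design$unit),
                            design, nPeaks = nPeaks, seed = s)
    kdEstimate(fitBinding(ts))
  }, numeric(1))
  median(est)
}
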