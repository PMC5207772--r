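---
title: "Models and methods behind BicelleNMR"
author: "BicelleNMR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind BicelleNMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BicelleNMR)
```

# Scope

BicelleNMR quantifies how strongly membrane-protein domains associate in
bicelle model membranes, and where those domains sit relative to the
bilayer, from solution-NMR observables and fluorescence anisotropy.  The
motivating application is the transmembrane/cytosolic (TM/CT) domains of
integrin α and β subunits, whose heterodimerization affinities, membrane
topologies and backbone dynamics differ between subunit families, but
nothing in the code is integrin-specific: any single-pass membrane
domain titrated in a membrane mimetic fits the same containers.

# The 1:1 ligand-depletion binding model

All binding fits share one physical model.  For the equilibrium
$U + L \rightleftharpoons UL$ with dissociation constant $K_d$, fixed
observed-species concentration $[U_0]$ and titrant concentration
$[L_0]$, the bound fraction of $U$ is the closed-form root of the
mass-action quadratic,

$$
f_b = \frac{(K_d + [L_0] + [U_0]) -
      \sqrt{(K_d + [L_0] + [U_0])^2 - 4[U_0][L_0]}}{2[U_0]},
$$

evaluated internally in the algebraically equivalent form
$f_b = 2[L_0]\big/\big(S + \sqrt{S^2 - 4[U_0][L_0]}\big)$ with
$S = K_d + [L_0] + [U_0]$, which avoids catastrophic cancellation when
$4[U_0][L_0] \ll S^2$.  Ligand depletion is never neglected: in
NMR-detected titrations the observed species sits at concentrations
comparable to $K_d$, so the hyperbolic approximation
$f_b \approx [L_0]/(K_d+[L_0])$ would bias $K_d$ upward.  The test suite
checks the closed form against an independent bracketing root of the
mass-action equation to $10^{-9}$ over a wide parameter grid.

## Concentration units

Association of membrane-embedded species is governed by concentrations
*in the membrane*, so $K_d$ for subunit heterodimerization is expressed
in mol% — (moles protein × 100)/(moles long-chain lipid), with the
short-chain detergent that rims the bicelle excluded because it does not
partition into the planar bilayer region.  `bicelleLipidMolarity()`
solves the two-component mass balance of a q-value bicelle preparation
(total w/v content and long/short mole ratio q) for the long-chain lipid
molarity, and `molPercent()` converts protein molarity to mol%.  Fits of
aqueous ligands (such as a talin F3 domain titrated against a
membrane-anchored tail) are instead performed in µM.  Every
concentration-bearing object carries a unit tag, and mixing mol% with µM
in a single computation is a hard error rather than a silent
conversion — the two scales differ by orders of magnitude and a silent
mix would produce plausible-looking nonsense.

# Global titration fits

An NMR titration yields one trace per assigned amide peak.  In **slow
exchange**, free and bound species give separate peaks and the free-state
peak intensity decays as $I(L_0) = I_0\,(1 - f_b)$; in **fast exchange**
peaks move continuously and the hybrid shift change follows
$\Delta(L_0) = \Delta_{max} f_b$.  The hybrid shift collapses the ¹H and
¹⁵N components of a peak movement into
$\Delta(HN) = \sqrt{(W_H^2\Delta H^2 + W_N^2\Delta N^2)/2}$ with
$W_H = 1$, $W_N = 0.154$; the nitrogen weight compensates the wider ¹⁵N
shift dispersion.  Printed renderings of this statistic vary in where
the weights and the normalizing factor sit, so the functional form is a
configurable strategy (`hybridShift(..., form = "quadrature")` gives the
common alternative $\sqrt{\Delta H^2 + (W_N \Delta N)^2}$); the default
was chosen to keep both printed weights and the $\sqrt{2}$
normalization.  Because all forms are monotone transforms of each other
up to weighting, the fitted $K_d$ is insensitive to the choice at the
noise levels considered; only $\Delta_{max}$ rescales.

All peaks are fit **jointly**: a single global $K_d$ with one free
nuisance amplitude per peak ($I_0$ or $\Delta_{max}$).  Amplitudes are
deliberately not shared across peaks — real peaks respond with visibly
different amplitudes depending on their distance from the binding
interface.  The optimizer is bounded Levenberg–Marquardt least squares
(minpack.lm).  Two features guard against the isotherm's known
pathologies:

* for fixed $K_d$ the model is linear in the amplitudes, so a cheap
  profiled-RSS scan over a log-spaced $K_d$ grid ($10^{-4}$–$10^{3}$
  times the largest titrant concentration, 71 points) locates the global
  basin first.  Without it, Levenberg–Marquardt started above the truth
  reliably falls into a local minimum at $K_d \to 0$ in strong-depletion
  designs (tight binder, $[U_0] \gg K_d$), where the stoichiometric-limit
  curve is a locally attracting but much worse solution;
* the grid start is supplemented by multistarts at
  $\{0.1, 1, 10\} \times \max[L_0]$, because the likelihood is nearly
  flat in $K_d$ once binding stops approaching saturation.

Standard errors come from the Jacobian-based covariance at the optimum
(residual variance times the inverse Gauss–Newton Hessian).  No
bootstrap is run by default; the SE is an asymptotic quantity and the
recovery tests verify that the ±1 SE interval covers the generating
value in at least half of the noisy replicates.

## Saturation diagnostics and lower bounds

A titration that never approaches saturation cannot pin down $K_d$; only
a lower limit is defensible.  `assessSaturation()` downgrades a fit to a
lower bound when the bound fraction at the highest titrant concentration
is strictly below 0.5 (a fit sitting exactly at the threshold stays
quantified — the documented tie-break), or when the upper edge of the
approximate 95% confidence interval exceeds 3× the highest titrant
concentration.  The reported bound defaults to $\max[L_0]$ itself — the
most conservative value the design can support — and is configurable,
because published lower limits are often derived from
instrument-specific sensitivity arguments that no refitting can
reconstruct.

## Outlier exclusion

Individual traces sometimes report on a second concentration-dependent
process (non-specific association, weak secondary sites) superimposed on
the binding isotherm.  `refitExcluding()` repeats the identical global
fit on a reduced peak set and records the exclusions; the tests
construct a drift-contaminated trace and verify that its removal moves
$K_d$ by less than 25% while reducing the residual variance.

# Anisotropy fits

Steady-state fluorescence anisotropy titrations of a labeled subunit by
an unlabeled partner are fit with
$r(L_0) = r_{free} + (r_{bound} - r_{free})\,f_b(K_d, U_0, L_0)$, where
$U_0$ is the labeled-species concentration in mol%.  $r_{free}$ and
$r_{bound}$ are linear given $K_d$, so the same profiled-grid +
multistart strategy applies.  Adding a constant to all anisotropy values
shifts $r_{free}$ and $r_{bound}$ equally and leaves $K_d$ unchanged
(affine invariance, tested).  A titration whose anisotropy only
decreases is rejected outright: either there is no binding signal or the
labeling scheme is inverted.

# Paramagnetic-probe topology profiling

Proximity to an unpaired electron broadens NMR resonances, so the ratio
$I/I_0$ between matched probe-containing and probe-free spectra reports
probe access per residue (low ratio = high access).  Two complementary
probes read out membrane topology: a water-soluble chelate broadens
solvent-exposed residues, leaving a *plateau* of protected ratios across
the membrane-embedded span, while a lipid-partitioning nitroxide
broadens membrane-core residues, producing a matching *trough*.  Peaks
broadened beyond detection are encoded as ratio 0, not missing, so they
count as maximally accessible.  Per-residue errors follow the rule
max(noise-derived error, 5% of the value).

The plateau/trough reading is qualitative in the literature; the caller
makes it operational with explicit defaults: after a moving-median
smoothing (window 3), the TM span is the longest contiguous run where
the hydrophilic ratio is ≥ 0.7 **and** the lipophilic ratio is ≤ 0.5,
with a minimum run length of 12 residues (shorter than any plausible
single-pass TM helix, long enough to reject noise runs).  All four
numbers are configurable; the defaults were chosen once so that
noise-free profiles generated from the packaged fixtures reproduce the
fixtures' annotated boundaries exactly, and they are a modeling choice,
not a measured quantity.

`compareProfiles()` asks whether two profiles of the same probe class
differ: per-residue deltas with errors combined in quadrature, a residue
being significant when $|\delta| > k\sigma$ (default $k = 2$).  The
"unchanged" verdict allows as many significant residues as chance alone
produces: the larger of 5% of the shared residues and the 95th
percentile of the binomial null count $\mathrm{Bin}(n, 2\Phi(-k))$.  The
binomial term matters: with ~80 residues and $k = 2$ the expected null
count is ~3.6, so a fixed 5% cap alone would call a third of identical
replicate pairs "changed".

# Dynamics and secondary structure

* **CPMG R2**: per-residue monoexponential fits
  $I(t) = I_0 e^{-R_2 t}$ with $R_2 \ge 0$, log-linear initialization and
  Levenberg–Marquardt refinement.  The delay list is data — the standard
  eight-delay schedule (17–173 ms) is a default, never an assumption.
* **CLEANEX**: raw per-residue $I/I_0$ after a fixed water-exchange
  mixing period; low values mark exchange-resistant amides.  No
  thresholding — fraying gradients along a helix are the interesting
  signal, and binarizing them would discard it.
* **CSI**: per-atom indices from deviations of CA/CB/CO shifts beyond
  ±0.7/±0.7/±0.5 ppm of shipped random-coil reference values, combined
  by majority vote (helix needs CA and CO downfield, CB upfield), helix
  segments being runs of ≥ 4 helix-consistent residues with ≥ 70% CA
  coverage.  This is a deliberately simple rule-based caller — an
  approximation of the dual chemical-shift-index/dihedral-database
  analysis practitioners run on deposited shifts, adequate for calling
  helix boundaries in strongly helical TM/CT data.  Calls are invariant
  to a common referencing offset applied to both shifts and reference.

# The synthetic-data generator

Raw spectrometer peak lists for the motivating study are not published,
so the package carries a first-class simulator that generates every
input type with known ground truth.  Its defaults *are* the documented
study conditions, fixed once:

* slow-exchange titrations: six points at mole ratios 0, 0.5, 1, 2, 3, 4
  with the observed subunit at 0.17 mol%; fast exchange: ratios 0, 1.25,
  2.5, 3.75, 5, 7.5 at 0.23 mol%; talin-style titrations reuse the slow
  design at 100 µM in µM units;
* 5% multiplicative Gaussian noise on NMR observables (typical
  peak-height reproducibility of TROSY spectra of detergent/bicelle
  samples), 3% on relaxation decays, 0.003 additive on anisotropy
  (replicate-mean scatter);
* per-peak amplitudes log-uniform: starting intensities 0.5–2 (arbitrary
  units), saturation shifts 0.02–0.2 ppm (the range of well-resolved
  chemical-shift perturbations);
* anisotropy design: 12 points, zero plus 11 log-spaced to 3.2 mol%,
  $r_{free} = 0.12$, $r_{bound} = 0.22$, labeled species 0.2 µM in 2%
  w/v q = 0.3 bicelles (≈ 0.0023 mol%);
* topology fixtures: the β1 TM/CT construct (residues 719–798, TM
  732–757, helix to 765) and the β3 TM/CT construct (685–762, TM
  693–721, helix to 737).  Fixtures store numbering and annotations
  only; amino-acid sequences are not needed by any simulated observable.

Accessibility profiles are built from logistic shapes: the hydrophilic
ratio rises from 0.2 outside to 0.9 inside the TM and the lipophilic
ratio falls from 0.9 to 0.1, both with flank steepness 1.5 residues.
The logistic midpoints are offset from the span edges (−2 and −0.5
residues respectively) so that the noise-free curves cross the caller's
default thresholds exactly between the last exposed and first protected
residue — the generator and caller are calibrated to each other by
construction, which is what lets zero-noise round trips recover the
annotated spans exactly.  An optional chelate-artifact mode multiplies
the hydrophilic ratios by a Gaussian well (depth 0.6, width 3 residues)
centered on a designated carboxylate site, emulating transient
association of an open chelate coordination site with Glu/Asp side
chains — the failure mode that historically produced spurious
topology differences between charge mutants.

Every generator takes a mandatory seed, draws all randomness from one
seeded stream, restores the caller's RNG state, and is bit-reproducible
given (truth, design, seed).  Zero-noise output lies exactly on the
generating model.

## What the simulator does not emulate

Peak overlap, spectral artifacts, exchange-broadening contributions to
slow-exchange intensity loss beyond population transfer,
intermediate-exchange lineshapes, field-dependent relaxation, and
correlated noise between residues.  Passing recovery tests therefore
demonstrate estimator correctness under the stated noise model, not
robustness to every pathology of real spectra; the outlier-exclusion
machinery exists precisely because real traces deviate in ways the
generator does not.

# Numerical choices and degenerate inputs

* Kd lower bound in optimization: $10^{-10} \times \max[L_0]$ (a free
  scale guard, far below any resolvable affinity).
* Slow-exchange amplitudes are constrained non-negative; fast-exchange
  amplitudes are free in sign (a peak can move upfield or downfield, and
  the hybrid statistic is computed before fitting).
* All-zero intensity matrices, all-flat shift matrices, probe-class
  mismatches, duplicate (assignment, condition) rows, and excluding
  every peak are hard errors with named offenders.
* Ties at the saturation threshold stay quantified (strict inequality).
* Undetectable paramagnetic peaks are ratio 0 with a noise-floor error,
  so they participate in smoothing and thresholding like any other
  residue.

# Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data at the sizes the estimators are designed for: 50-seed recovery
ensembles for each binding scenario (four to five peaks, six titration
points), 100-seed boundary-recovery ensembles over 80-residue profiles,
and 100-residue relaxation sets at eight delays.  These sizes give
medians and coverage proportions stable to well within the tolerances
they are tested against.

# Known limitations

Only 1:1 stoichiometry is modeled — no cooperative or 2:1 schemes, and
no membrane-assisted multi-domain binding models.  Lower-bound values
are reported as policy, not inference.  The CSI caller does not use HA
or N shifts and is not a substitute for dihedral-database analysis when
loop/turn detail matters.  Topology calling assumes a single contiguous
membrane-embedded span; multi-pass topologies would need the threshold
logic applied per span.
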