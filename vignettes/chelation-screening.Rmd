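---
title: "Competitive screening of calcium and magnesium chelation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive screening of calcium and magnesium chelation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chelascreen)
```

## The assay and its model

The screen measures how strongly a test compound chelates Ca²⁺ or Mg²⁺ by
letting it compete with the metallochromic indicator
*o*-cresolphthalein complexone (*o*-CC). At pH 7.5 the indicator forms an
intensely purple complex with either metal; a competing chelator strips
metal from the indicator and bleaches the well. Each plate carries
negative controls (indicator only), positive controls (metal + indicator)
and sample wells (metal + chelator + indicator), and the readout is

$$\mathrm{chelation}\,[\%] = \left(1 - \frac{A_x - \bar A_N}{\bar A_P -
\bar A_N}\right)\times 100,$$

where $A_x$ is a sample absorbance and $\bar A_N$, $\bar A_P$ are the
control means. The statistic is affine-invariant in absorbance, is
reported unclipped (values outside $[-10, 110]$ are flagged, not
truncated, because clipping biases curve fits near the extremes), and is
undefined when the assay window $|\bar A_P - \bar A_N|$ falls below
0.05 AU.

Everything upstream of that statistic is driven by a mass-action
equilibrium model with three species balances,

$$M_t = [M] + [MD] + [ML_s],\qquad D_t = [D] + [MD],\qquad
L_t = [L] + s\,[ML_s],$$

with $[MD] = \beta'_{MD}[M][D]$ and $[ML_s] = \beta'_{ML_s}[M][L]^s$.
Primed constants are conditional constants at the well pH: each
protonatable donor group contributes a side-reaction factor
$(1 + 10^{pK_a - \mathrm{pH}})^{-1}$. This single mechanism produces both
the pH collapse of the assay below pH ≈ 7 (through the indicator's
phenolic groups) and the structure–activity trend across quinolines
(through the chelating hydroxyl's $pK_a$).

Model assumptions worth keeping in mind:

* one dominant chelate species $ML_s$ per system with $s \in \{1,2,3\}$ —
  stepwise ladders are not identifiable from a single titration readout;
* the metal–indicator complex is fixed at 1:1; the indicator's true
  binding stoichiometry and constant are not published, so both are
  simulator parameters rather than measured facts;
* no activity-coefficient or ionic-strength corrections, no binding
  kinetics — the immediate and 5-minute plate reads are treated as two
  independent equilibrium snapshots.

## The equilibrium solver

`solve_speciation()` runs a damped Newton iteration on log-transformed
free concentrations (positivity is automatic, and convergence is fast
even when $\beta' L_t$ spans fifteen orders of magnitude), with an
analytic Jacobian, a log-step cap of 4, residual-reducing backtracking,
and a convergence tolerance of 1e-10 on the log concentrations within
200 iterations. If Newton fails, the solver falls back to bisection on
free metal — the metal balance is strictly increasing in free metal once
the indicator balance is substituted in closed form and the chelator
balance is solved by inner bisection — so a valid system cannot fail to
converge. Every result is checked against all three balances; relative
residuals above 1e-9 raise an error instead of returning a bad solution.
The test suite additionally compares the solver against an independent
nested-bisection oracle on randomized systems.

## What the generator emulates — and what it does not

The synthetic-data module reproduces the statistical structure the
analysis assumes:

* **Spectra.** Molar absorptivities are sums of Gaussian bands. Free
  indicator: 574 nm (major) and 388 nm (minor, 5 % of the major
  amplitude). Complexes: 573/388 nm (Ca) and 568/386 nm (Mg) with ~3×
  intensification — a small hypsochromic shift plus intensification.
  Band amplitudes (major 1200 vs 3600 M⁻¹cm⁻¹) and widths (σ = 40/22 nm)
  are stated assumptions: the real extinction coefficients under these
  buffer conditions are unpublished, so only the qualitative pattern, not
  the absolute absorbances, should be read as meaningful.
* **Protocol.** 50 µL ion + 150 µL buffer + 50 µL agent + 50 µL
  indicator = 300 µL per well; 3 mM ion stock → 500 µM final, 4 mM
  indicator stock → 667 µM final; 0.9 cm path; triplicates.
  `validate_protocol()` recomputes finals from stocks and flags >1 %
  mismatch.
* **Noise.** Additive Gaussian photometric noise, SD 0.005 AU,
  independent per well and wavelength — typical plate-reader noise.
* **pH.** The indicator's conditional binding uses two effective
  protonation constants of 7.2. This yields a strong window at pH 7.5,
  a visibly reduced slope at pH 6.8, and essentially no calibration slope
  (< 5 % of the pH 7.5 slope) at pH 5.5 and 4.5.
* **Aggregometry.** Impedance rises logistically (midpoint 90 s, time
  constant 30 s, 6-min window) with a plateau scaled by a Hill function
  of free calcium, $K_{Ca} = 0.2$ mM, $h = 4$. The steep Hill coefficient
  makes aggregation collapse when free calcium is sequestered
  stoichiometrically, while leaving it nearly intact above ~0.4 mM.

Not emulated: instrument drift, well-edge and evaporation effects,
compound solubility limits, absorbing chelators or chelate complexes
(all test agents are modelled as transparent over 350–650 nm), and
binding kinetics. Passing tests therefore demonstrate that the analysis
recovers the generator's ground truth under realistic noise — not that
any particular real compound will behave identically.

## Chelation curves and the 1:1 expectation

Curves are fit on $x = \log_{10}(\text{chelator:metal ratio})$ — the
screen reports activity by ratio, not by absolute concentration — as

$$Y(x) = \frac{100}{1 + 10^{(\mathrm{LogEC50} - x)k}},$$

by Levenberg–Marquardt with the analytic Jacobian (`minpack.lm::nls.lm`;
`nls()`-style numeric derivatives degenerate when LogEC50 sits near zero
or the residuals vanish). Ratio-zero wells are solvent controls and carry
no information on the log scale, so they are excluded from fits. The
expected chelation at the 1:1 ratio is the curve at $x = 0$,

$$Y_{1:1} = \frac{100}{1 + 10^{\mathrm{LogEC50}\cdot k}},$$

so LogEC50 = 0 forces $Y_{1:1} = 50\%$ exactly, and a more negative
LogEC50 means a higher 1:1 expectation. That sign convention is the
default; since the printed form of the expectation does not fix the sign
itself, `fit_chelation_curve(..., y_sign = -1)` evaluates the opposite
convention. Confidence bands for curve comparison come from the delta
method on the parameter covariance; two compounds are distinguished only
when one band clears the other over a contiguous majority (> 50 %) of the
shared log-ratio range.

## Stoichiometry inference and the potency tiers

A very strong chelator titrates the metal almost quantitatively, so its
curve approaches the complete-binding template
$Y_s(r) = 100\min(r/s, 1)$: linear rise, saturation at the equivalence
ratio $s$. `infer_stoichiometry()` compares per-ratio means against the
templates $s \in \{1,2,3\}$ by SSE and accepts the best candidate when
its SSE is within twice a replicate-variance benchmark. The benchmark
adds, per ratio, the variance of the replicate mean and a fixed 5
percentage-point template tolerance. The tolerance is not cosmetic: a
finite formation constant rounds the template's sharp corner near
equivalence (with $\beta_{ML_3} = 10^{15}\,\mathrm{M^{-3}}$ and 0.5 mM
metal, equilibrium reaches only ~93 % at ratio 3 even without noise), and
the idealized template should not be rejected for physics the template
itself idealizes away. The same equilibrium analysis sets the
very-strong classification window: completeness (mean ≥ 95 %) must be
reached at a ratio no larger than $\max(3, 2s)$ — the titration has to
saturate essentially at its own equivalence point, with one tested step
of slack for that soft shoulder.

The four tiers are then: **very strong** (template accepted and complete
near equivalence — only here is a stoichiometry reported), **moderate**
(complete at 10:1 — mean ≥ 95 % or its 95 % CI containing 100 — the 95 %
threshold and CI rule operationalize "complete", for which no number is
inherited), **weak** (significantly above zero at 10:1 by a one-sided
one-sample t test at α = 0.05; the sidedness is a stated choice), and
**inactive** otherwise. When solubility caps the ladder below ratio 10
the largest tested ratio substitutes and the result is flagged. The
suite checks that the category is monotone in the generator's formation
constant.

## Wavelength selection, LOD and QC

* `optimize_wavelength()` regresses per-concentration replicate means
  (matching the per-concentration summary convention; a flag switches to
  pooled replicates) of absorbance on concentration at every wavelength;
  wavelengths with $R^2 > 0.9$ are admissible and the largest absolute
  slope wins, with ties broken toward the global slope maximum and then
  the lower wavelength. On noiseless data the winner is the argmax of
  $|\varepsilon_{MD} - \varepsilon_D|$ — slightly below the complex peak,
  because the free-indicator band overlaps it.
* `limit_of_detection()` runs two-sided, equal-variance two-sample
  t tests of each ladder level against the blank (Welch via a flag;
  two-sided because the sidedness of the original comparison is
  unstated) and defines the LOD by a monotone rule: the smallest
  concentration that is significant along with every larger tested
  concentration. The monotone rule is this package's addition; it
  prevents an isolated false positive from defining the limit. No
  multiple-testing correction is applied across the ladder — a caveat
  carried in the documentation rather than corrected away.
* `stability_check()` pairs stored against fresh reagents (paired t
  test), flags mean stored/fresh ratios departing from 1 by more than
  10 %, and reports the absorbance–temperature Pearson correlation so a
  seasonal temperature confounder can be excluded; constant series are
  reported as not assessable rather than erroring.

## Degenerate inputs and numerical edges

Zero totals drop out of the Newton system instead of hitting the log
transform; `beta = 0` reduces to the two-species quadratic closed form;
identical blank and ladder draws give p = 1, not an exception; flat
chelation data and singular parameter covariances raise "not
identifiable" errors that the classifier catches by falling through to
its threshold rules; and a perfectly linear calibration (zero residual)
reports $R^2 = 1$ without the unreliable-summary warning leaking to the
user.

## Problem sizes

The shipped simulations are sized for a desk-scale run: 8-point
calibration ladders in triplicate over a 2 nm grid, 6–8-ratio titrations
in triplicate read at one wavelength and two timepoints, 100 randomized
solver-versus-oracle systems, 50-seed parameter-recovery sweeps, and
20-seed stoichiometry-recovery sweeps. The full workflow
(`run_end_to_end()`) runs in about a second; the complete test suite in
well under a minute.

## Known limitations

The screen compares chelators through a shared competitive readout; it
does not determine thermodynamic stability constants, cannot rank two
very strong chelators of equal denticity (both saturate the template),
and reports stoichiometry only when binding is nearly quantitative.
Simulated pKa–activity relationships inherit the generator's own
conditional-binding mechanism, so the SAR stages validate the analysis
machinery, not any particular chemical series.
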