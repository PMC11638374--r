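# chelascreen

Simulation and analysis toolkit for a competitive spectrophotometric
screen of **calcium and magnesium chelation** on 96-well microplates.

Clinically used chelators are rarely selective: compounds given for iron
or copper overload can also deplete Ca²⁺ and Mg²⁺, with real clinical
consequences. A cheap way to rank that risk is an indicator-displacement
assay: the metallochromic indicator *o*-cresolphthalein complexone
(*o*-CC) forms a purple 1:1 complex with either metal at pH 7.5, and a
test chelator competing for the metal bleaches the well. This package
implements the full data pipeline for that screen — and, because the
wet-lab signal is governed by straightforward mass-action chemistry, a
physics-based synthetic-data generator that stands in for the plate
reader, so every analysis stage is testable against known ground truth.

## The model and the statistics

**Equilibrium engine.** Each well is a competitive speciation system
solved from the mass balances

```
M_t = [M] + [MD] + [ML_s]    D_t = [D] + [MD]    L_t = [L] + s [ML_s]
```

with `[MD] = β'_MD [M][D]`, `[ML_s] = β'_MLs [M][L]^s`, and conditional
(pH-corrected) constants `β' = β · Π(1 + 10^(pKa−pH))⁻¹` (damped Newton
on log concentrations, bisection fallback, mass balance verified to
1e-9).

**Chelation percentage.** With negative (indicator-only) and positive
(metal + indicator) control means,

```
chelation [%] = (1 − (A_x − Ā_N) / (Ā_P − Ā_N)) × 100
```

**Chelation curve.** Logistic in the log chelator:metal ratio
`x = log10(r)`:

```
Y(x) = 100 / (1 + 10^((LogEC50 − x) · k)),   Y(1:1) = 100 / (1 + 10^(LogEC50 · k))
```

Very strong chelators approach the complete-binding template
`Y_s(r) = 100·min(r/s, 1)`, from which the complex stoichiometry
`s ∈ {1,2,3}` is inferred; compounds are classified into four potency
tiers (very strong / moderate / weak / inactive). Downstream stages add
optimal-wavelength selection (R² > 0.9, then maximal slope),
t-test-based limit of detection, pKa structure–activity regression, and
platelet-aggregation quantification,
`aggregation [%] = 100 · AUC(test)/AUC(blank)`, with the stoichiometric
prediction of the fully inhibiting chelator dose
`s × [metal]_blood × dilution`.

## Worked example

```r
library(chelascreen)

# one sample well of the competitive assay: 0.5 mM Ca, 670 uM o-CC,
# 0.5 mM of a strong 1:1 chelator (conditional beta 1e12)
sys <- speciation_system(M_total = 5e-4, D_total = 6.7e-4, L_total = 5e-4,
                         beta_MD = 2e5, beta_MLs = 1e12, s = 1, pH = 7.5,
                         pKa_indicator = c(7.2, 7.2))
solve_speciation(sys)
#> Speciation result (newton, 24 iterations)
#>   free  M 2.876e-09  D 0.0006698  L 1.738e-07 (M)
#>   bound MD 1.709e-07  MLs 0.0004998 (M)
#>   max |relative residual| 1.7e-15
```

The chelator captures 99.96 % of the metal (`MLs` ≈ `M_total`), leaving
almost no colored `MD` complex — this well would read like a negative
control, i.e. ~100 % chelation.

The whole workflow, simulation through report:

```r
run_end_to_end(seed = 1)
#> Simulated chelation screen (seed 1, metal Ca)
#>   indicator peak 574 nm; complex peaks Ca 572.5 nm, Mg 567.5 nm
#>   optimal wavelengths: Ca 576 nm (R2 1.000), Mg 562 nm (R2 1.000)
#>   limit of detection: 2.5e-06 M
#>   classification:
#>              compound    category  s mean_at_top
#>  aminopolycarboxylate very_strong  1   99.835504
#>        quinoline_3to1 very_strong  3  100.495788
#>              moderate    moderate NA   97.635098
#>                  weak        weak NA   52.474233
#>              inactive    inactive NA    0.152262
#>   SAR slope -18.19 %/pKa unit (R2 0.910, p 0.00314)
#>   aggregation: predicted full-inhibition 0.001 M, observed threshold 0.001 M
```

Reading the report: the detected spectral peaks sit at the generator's
band positions (574 nm free indicator; complex bands a few nm blue of
it); the optimal detection wavelengths land near the complex bands with
calibration R² ≥ 0.99; a 2.5 µM metal spike is the smallest
distinguishable from blank under the default noise; the five demo
compounds fall into the four potency tiers with the correct 1:1 and 3:1
stoichiometries for the two very strong chelators; chelation falls with
rising hydroxyl pKa (negative SAR slope); and the simulated
whole-blood experiment confirms the stoichiometric prediction that 1 mM
of a 1:1 calcium chelator abolishes platelet aggregation (2 mM blood
calcium halved by saline dilution).

A thin command-line wrapper is included at `inst/cli/chelascreen.R`
(`report` and `simulate` subcommands).

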