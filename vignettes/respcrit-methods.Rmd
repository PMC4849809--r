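---
title: "Methods: respirometry, Pcrit estimation and closed-chamber carbonate chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respirometry, Pcrit estimation and closed-chamber carbonate chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respcrit)
```

This vignette is the package's account of the models it implements, the
defaults it chose where the field's conventions are loose, and the things
its synthetic-data tests do and do not demonstrate.

## Oxygen solubility and unit conversion

All conversions run through a single physical chain. The partial pressure
of oxygen in water-vapour-saturated air is

$$P_{O_2}^{sat} = 0.20946\,(P_{baro} - p_{H_2O}(T)),$$

with the dry-air O~2~ mole fraction fixed at 0.20946 and the vapour
pressure from the Benson–Krause empirical fit (the salinity correction to
vapour pressure is below 0.1% and is ignored, as is standard respirometry
practice). Air-saturated concentration comes from the Garcia–Gordon (1992)
fit to the Benson–Krause data, evaluated in µmol/kg and converted to
per-litre units with the Millero–Poisson surface-density approximation;
the solubility coefficient is $\beta = C_{sat}/P_{O_2}^{sat}$
(mg L^-1^ kPa^-1^). The choice matters in the third digit at most against
the classical solubility tables used across the respirometry literature;
at 15 °C / 0 PSU the package gives 10.08 mg/L. Pressure-family
conversions (kPa, mmHg, torr; µatm and atm in `pressure_unit()`) use the
exact definitions 1 atm = 760 mmHg = 101.325 kPa = 10^6^ µatm, with torr
treated as identical to mmHg (the true difference is below 2×10^-7^).
Round trips through any unit pair reproduce the input to 10^-9^ relative;
this is asserted property-style over random conditions.

## Oxygen uptake from respirometry traces

Closed chambers obey the mass balance
$\mathrm{MO_2} = (V_r - V_f)\,\Delta O_2 / (\Delta t \cdot bw)$. Rather
than differencing endpoints, `mo2_closed()` uses the least-squares slope
of concentration against time inside each window, which equals the
endpoint difference for two-point windows and is far more robust to
optode noise otherwise. The averaging window is deliberately a required
user choice — source studies never agree on one — and the worked examples
show how strongly short windows amplify multiplicative probe noise. MO~2~
is positive for declining oxygen; windows where oxygen rises produce
non-positive MO~2~ and are flagged `suspect` but retained, so nothing is
silently dropped. An optional constant blank (background respiration) can
be subtracted; the default is zero.

Flow-through chambers use the steady-state balance
$\mathrm{MO_2} = F_w (C_{in} - C_{out})/bw$. No deconvolution of chamber
dynamics is attempted: samples within a configurable wash-out window
(default three mean residence times $V_r/F_w$) of the trace start or of
any step in inflow oxygen are flagged `equilibrating`, because the
steady-state balance is biased until the chamber has turned over.
Intermittent-flow traces are handled as a sequence of closed measurement
phases: one slope (with its r^2^) per phase, flush samples excluded, and
phases with fewer than three samples skipped with a warning rather than
an error.

## SMR and the critical oxygen level

`estimate_smr()` implements the conventions found across the literature:
single lowest normoxic value, mean of the N lowest, an empirical quantile
(linear interpolation), and extrapolation of ln(MO~2~) against swimming
speed back to zero activity. The method and its parameter are carried in
the result because P~crit~ values referenced to different metabolic
baselines are not directly comparable.

`pcrit_broken_stick()` fits the continuous two-segment model: for a knot
$c$, MO~2~ is linear below and above $c$ with the segments constrained to
meet at $c$ (three free parameters). The knot is found by exhaustive
search over every interior observed PO~2~ and the midpoints between
adjacent values, then polished by a one-dimensional optimizer inside each
inter-point interval, where the RSS is a smooth function of the knot.
This makes the search exact on noiseless piecewise-linear data and
equivalent to a brute-force fine-grid scan (the test suite asserts
equality against an independently coded grid oracle). RSS ties break
toward lower PO~2~. The continuity constraint matches the "inflection
point" reading of P~crit~ and prevents pathological disjoint fits.

Whether a fish is an oxyconformer is a model-selection question the
source literature leaves open; the package compares the one-line and
two-segment fits by BIC, which penalises the two extra parameters
conservatively. When the single line wins, the classification is
`oxyconformer` and no P~crit~ is reported. Confidence intervals come from
a seeded nonparametric residual bootstrap (default 1000 resamples);
bootstrap distributions of breakpoints are wide whenever the MO~2~ series
is short or noisy, and the interval honestly reflects that.

`pcrit_intersection()` reproduces the older graphical convention: a
least-squares line through the conforming points (chosen by the same
breakpoint search) intersected with a horizontal SMR/RMR level. A
conforming slope that is not positive has no meaningful intersection and
errors; an SMR of zero gives the degenerate answer zero and is flagged.
The conforming line is not forced through the origin (set
`smr = 0` aside, the literature does not require it).

`pcrit_nonlinear()` fits the saturating curve
$\mathrm{MO_2} = \mathrm{MO_{2,max}}\,P/(K + P)$ by multi-start
Levenberg–Marquardt. A saturating curve has no breakpoint, so "P~crit~"
needs a definition: the package reports the PO~2~ at which the fitted
curve reaches a stated fraction of its asymptote
($P = \tfrac{f}{1-f}K$; default $f = 0.90$, always recorded in the
result). This is the least arbitrary operationalization, but it is *not*
interchangeable with the breakpoint: on sharply biphasic data the
90%-of-asymptote reading sits well above the broken-stick estimate,
because a Michaelis–Menten curve approaches its plateau slowly. The test
suite asserts this bias direction rather than pretending the two methods
agree.

## The closed-respirometer CO~2~ model

A fish driving itself into hypoxia in a sealed chamber excretes CO~2~
into the water. The model quantifies the resulting pCO~2~: the water
starts in equilibrium with the atmosphere (395 µatm) at a given NBS pH,
temperature (15 °C) and salinity; respiration adds Δ DIC (default
140 µmol/kg — the amount implied by an air-saturation → ~6 kPa drawdown
at RQ 0.85, see `delta_dic_from_o2()`) while total alkalinity stays
constant, because dissolved CO~2~ is a neutral gas; the final state is
recovered by solving the alkalinity balance for pH.

The carbonate constants are pinned to the set the classic CO2SYS program
pairs with the NBS pH scale: Weiss (1974) K~0~, the original Mehrbach
et al. (1973) K~1~/K~2~ (reported directly on NBS; the package reproduces
pK~1~ ≈ 6.00 and pK~2~ ≈ 9.11 at 25 °C / 35 PSU), Dickson (1990) boric
acid and Millero (1995) water constants converted through the Takahashi
activity factor f~H~, and Uppström total borate. Pinning matters: the
final pCO~2~ is sensitive to the constant choice, and this is the pairing
that reproduces the published envelope. Nutrient alkalinity terms are
zero (the TA-from-pH construction implies none), and the "µM" CO~2~
addition is treated as µmol/kg — the ≤2% density difference is far below
the model's stated precision. Note that NBS pH runs ≈0.13 units higher
than total-scale pH for the same water, so the DIC attached to "pH 8.0"
here (≈1380 µmol/kg at 15 °C / 35 PSU) is lower than the value the same
number would imply on the total scale; this is a property of the scale,
not a solver discrepancy.

The inverse solve uses Brent root-finding on pH over [2, 12] with an
alkalinity residual tolerance of 10^-4^ µmol/kg; it is deterministic and
is verified in the tests against an independent polynomial-root solution
of the same equilibrium (agreement far inside 0.5%) and by exact
round-tripping against the forward (pH, pCO~2~) construction. TA
conservation is asserted on every model run. On the default grid
(pH 7.5–8.5 × 20–40 PSU) the final pCO~2~ in the least-buffered
(S = 20) water spans ≈637 µatm at pH 8.5 to ≈3558 µatm at pH 7.5 — the
published "five-fold, ~650 to ~3500 µatm" envelope; across the full grid
the spread is wider still (≈514 µatm at pH 8.5 / S 40), which is why the
package reports the whole surface and leaves endpoint selection explicit.

## The trait-database pipeline

`load_pcrit_database()` reads delimited text with an optional
header→schema map, types the recognised columns, rejects rows missing the
mandatory fields (species, P~crit~ value and unit, trial temperature)
with logged reasons, and passes unknown columns through.
`harmonize_units()` attaches both representations used in comparative
work — kPa always (pressure units need no conditions), mg/L when trial
temperature and salinity are available — and flags what it cannot
convert; it is idempotent. `control_subset()` applies the three
comparability rules (unfed/post-absorptive; no additional abiotic
stressor; temperature acclimation strictly longer than 2 days) and logs
every exclusion, so included + excluded always partitions the input.

Climate zones use the astronomical tropic (23.44°) and polar (66.56°)
circles with a conventional 35° subtropical bound; the source analyses
name the zones without defining boundaries, so all three cutoffs are
arguments. The zone ANOVA is one-way fixed-effects on kPa values with
polar excluded (always too few records), followed by all pairwise
comparisons using the ANOVA mean square error and Šidák adjustment
($p_{adj} = 1-(1-p)^m$). Method contrasts within species use Student's
unpaired equal-variance t-tests, only where a species has more than two
records under each of at least two respirometry types. The
freshwater/seawater contrast is a Mann–Whitney U with the tie-corrected
normal approximation (group sizes in the hundreds make exact enumeration
pointless; the statistic is cross-checked against `wilcox.test` in the
tests), run separately on kPa and mg/L because the two representations
answer different questions: identical concentration thresholds translate
into ~20–25% lower partial-pressure thresholds in cold fresh water purely
through solubility.

`pcrit_regression()` is OLS of P~crit~ (kPa) on salinity, temperature,
body mass and RMR over complete cases (no imputation anywhere; exclusion
counts are reported). "Stepwise" in the source literature is
directionless, so the package implements forward selection with an
F-to-enter threshold (default p < 0.05), records every entry decision,
and reports raw b, standardized β, squared semipartials sr², adjusted r²
and the overall F. Designs with condition number above 10^10^ error
rather than returning garbage.

## Synthetic data: what it emulates and what it does not

The generators exist so every estimator can be exercised against known
truth. The metabolic profile is the standard piecewise abstraction:
regulators hold RMR above P~crit~ and decline linearly through the origin
below it (the simplest form consistent with MO~2~(0) = 0); obligate
conformers are proportional throughout. Facultative metabolic depression
below P~crit~ is deliberately not simulated. Probe noise is
multiplicative (optode error scales with signal). The closed-chamber
trace integrates d[O~2~]/dt = −MO~2~(PO~2~)·bw/(V~r~−V~f~) with
fixed-step RK4 at one tenth of the sampling interval, stops at 0.5 kPa,
and conserves oxygen mass to well under 0.5% at the default step; the
depletion rate scales as expected with the metabolic-rate-to-volume
ratio (doubling RMR halves the 20→1 kPa depletion time within 5%).

`generate_pcrit_database()` draws (salinity, temperature, body mass,
RMR) from a correlated model with the covariate means and SDs of the
published regression table. Body mass and RMR get lognormal margins —
their printed SDs exceed their means, which no positive normal variate
can do — with latent correlations analytically inflated so the observed
Pearson correlations hit their targets after the transform; salinity and
temperature are censored to physical bounds with pre-censoring moments
calibrated so the post-censoring mean/SD still match. Two published
features cannot be reproduced exactly and are handled openly: the printed
zero-order correlations are not jointly feasible once the margins must
respect positivity (the latent matrix has a −0.15 eigenvalue), so the
generator projects to the nearest positive-semidefinite structure, and
the realized correlations land within about 0.05–0.07 of the printed
values with all signs correct; and the printed body-mass correlation with
P~crit~ (−0.166) has the opposite sign to the regression coefficient
(+1.931) — the generator imposes only the predictor structure and the
regression, so the marginal correlation is whatever those jointly imply.
P~crit~ is generated from the printed prediction equation
(5.689 + 0.047·S − 0.083·T + 1.931·M + 0.001·RMR) with Gaussian noise
calibrated so the population r² equals the published adjusted r² of
0.195. Control-filter fields are allocated deterministically at the
published 297/331 rate, so the subset size scales exactly with n.

`simulate_fw_sw_pcrit()` encodes the solubility-artefact hypothesis
directly: freshwater and seawater groups share one P~crit~ distribution
in mg/L, and each record converts to kPa at its own temperature and
salinity, producing an emergent ≈23% lower freshwater P~crit~ in kPa
with no concentration difference — exactly the pattern a kPa-based
comparison detects and a mg/L-based one does not. Passing those tests
shows the pipeline's statistics behave correctly under that mechanism; it
does not show that real freshwater and seawater faunas differ only
through solubility.

## Problem sizes and numerical defaults used by the tests

The suite runs at desk scale by design: 30-point MO~2~ series with 5%
noise and 200 replicates for breakpoint recovery (median absolute error
≈0.12 kPa, comfortably inside 0.5 kPa, with no replicate misclassified
as a conformer), 50 random instances for the brute-force equivalence, a
1159-row synthetic database for the regression fit quality
(adjusted r² within ±0.05 of 0.195), 116/150 freshwater/seawater groups,
and a 10^5^-row draw for generator moment convergence (means and SDs
within 2%). Bootstrap intervals default to 1000 resamples but tests use
200–500. All stochastic steps are seeded, and seeds are recorded in the
objects they produce.

## Known limitations

* The carbonate solver is valid only for the Mehrbach salinity range
  (19–43 PSU) and 0–40 °C; freshwater carbonate systems are out of scope.
* The nonlinear P~crit~ depends on the asymptote fraction; cross-study
  comparisons must match fractions, which is why the fraction is embedded
  in the result.
* The rate at which hypoxia develops can bias measured P~crit~; the
  simulator exposes the depletion rate so the effect can be studied, but
  no correction is implemented.
* Phylogenetic non-independence across species is not modelled anywhere
  in the database pipeline.
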