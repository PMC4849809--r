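# respcrit

Tools for quantifying hypoxia tolerance in fishes from respirometry data,
and for analysing critical-oxygen-level (P<sub>crit</sub>) trait databases.

Aquatic hypoxia is increasingly common, and the oxygen level below which a
fish can no longer hold its oxygen uptake steady — the critical oxygen
level, P<sub>crit</sub> — is the most widely used quantitative trait of
hypoxia tolerance. Comparing P<sub>crit</sub> values across the literature
is harder than it looks: studies report dissolved oxygen in five different
units, use three different respirometer designs, quantify "resting"
metabolism in at least four ways, locate the regulation/conformity
breakpoint with different regressions, and (in closed respirometers) let
CO<sub>2</sub> accumulate to levels that depend strongly on the starting
water chemistry. This package implements each of those steps explicitly so
they can be applied, compared and audited:

* **Oxygen units and solubility** — `convert_o2()` moves values among
  kPa, mmHg/torr, % air saturation, mg/L and µmol/L using Garcia–Gordon
  oxygen solubility (`o2_solubility()`), with exact factors inside the
  pressure family (760 mmHg = 101.325 kPa) and `pressure_unit()` for
  µatm/atm/mmHg/kPa.
* **Oxygen uptake (MO₂)** — `mo2_closed()` implements
  MO₂ = (V<sub>r</sub> − V<sub>f</sub>) ΔO₂ / (Δt · bw) with windowed
  least-squares slopes; `mo2_flow_through()` implements
  MO₂ = F<sub>w</sub>(O₂,in − O₂,out)/bw with wash-out flagging;
  `mo2_intermittent()` extracts one slope per closed measurement phase.
* **SMR and P<sub>crit</sub>** — `estimate_smr()` (lowest value, mean of N
  lowest, quantile, zero-speed extrapolation);
  `pcrit_broken_stick()` (continuous two-segment least squares with an
  exhaustive-plus-polished breakpoint search, BIC-based oxyconformer
  classification, residual-bootstrap CI); `pcrit_intersection()`
  (conforming line × SMR level); `pcrit_nonlinear()` (Michaelis–Menten
  fit, P<sub>crit</sub> read at a stated fraction of the asymptote).
* **Closed-respirometer CO₂** — a from-scratch seawater carbonate-system
  solver on the NBS pH scale (`carb_constants()`,
  `carb_state_from_ph_pco2()`, `carb_state_from_ta_dic()`) drives
  `respirometer_co2_model()`: equilibrate water with the atmosphere at a
  given starting pH and salinity, add respiratory CO₂ to DIC at constant
  total alkalinity, and solve for the final pCO₂.
* **Trait-database pipeline** — `load_pcrit_database()`,
  `harmonize_units()`, `control_subset()`, `assign_climate_zone()`,
  `zone_anova()` (Šidák post hoc), `method_comparisons()`,
  `salinity_comparison()` (Mann–Whitney in both kPa and mg/L) and
  `pcrit_regression()` (OLS / forward stepwise with β and sr²).
* **Synthetic data** — seeded generators for every input:
  `simulate_closed_trace()` (RK4 depletion ODE), `simulate_mo2_series()`,
  `generate_pcrit_database()` (correlated covariates + the published
  regression structure) and `simulate_fw_sw_pcrit()`.

## Worked example

Simulate a 120 g oxyregulator (RMR 180 mg O₂ kg⁻¹ h⁻¹, true
P<sub>crit</sub> 5.2 kPa) depleting a 3 L closed chamber at 15 °C / 35 PSU
with 2% probe noise, then recover its P<sub>crit</sub>:

```r
library(respcrit)

prof <- fish_profile("regulator", rmr = 180, pcrit = 5.2, body_mass = 0.12)
ch   <- respirometer_config(3, 0.12, 0.12, "closed",
                            conditions = water_conditions(15, 35))
tr   <- simulate_closed_trace(prof, sim_config(ch, sampling_interval = 0.01,
                                               noise_sd = 0.02, seed = 42))
tr
#> Respirometry trace: 145 samples over 1.44 h (closed mode, unit mg_per_L)

series <- mo2_closed(tr, window = 12)
pcrit_broken_stick(series, n_boot = 500, seed = 42)
#> Pcrit (broken_stick): 6.322 kPa (oxyregulator)
#>   bootstrap 95% CI: [4.771, 7.457] kPa

smr <- estimate_smr(series$mo2[series$po2 > 10], "quantile", parameter = 0.2)
pcrit_intersection(series, smr)
#> Pcrit (regulation_intersection): 4.713 kPa (oxyregulator)
```

The two estimators bracket the true 5.2 kPa: the broken stick reads the
bend of the full two-segment fit, while the intersection method crosses
the conforming line with a routine-metabolism level (here the 0.2
quantile of normoxic MO₂, 147 mg O₂ kg⁻¹ h⁻¹).

How much CO₂ builds up while such a fish drives itself to hypoxia in a
sealed chamber? Adding the 140 µmol/kg of respiratory CO₂ implied by an
air-saturation → 6 kPa drawdown at RQ 0.85 (`delta_dic_from_o2()`), at
constant alkalinity:

```r
m <- respirometer_co2_model()   # pH 7.5-8.5 x 20-40 PSU, 15 degC, 395 uatm
round(attr(m, "pco2_matrix"))
#>         salinity
#> start_ph   20   25   30   35   40
#>     7.5  3558 3553 3537 3511 3475
#>     7.75 3260 3150 3023 2882 2731
#>     8    2558 2253 1962 1701 1484
#>     8.25 1299 1030  875  782  722
#>     8.5   637  581  548  528  514
```

Final pCO₂ (µatm) spans roughly 650–3500 µatm in the least-buffered
(S = 20) water as starting pH falls from 8.5 to 7.5 — a five-fold range
driven almost entirely by the starting water chemistry, and at pH 8.0 a
~1000 µatm swing from salinity alone.

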