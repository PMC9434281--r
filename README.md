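# pyroalga

Pyrolysis kinetics, activation thermodynamics and bioenergy indicators for
microalgal biomass, from multi-heating-rate thermogravimetric (TGA)
records.

Slow pyrolysis of algal biomass is routinely characterized by
non-isothermal TGA: the sample mass `w(T)` is recorded while the
temperature ramps at several heating rates `β = dT/dt`. The package turns
such records into the quantities a bioenergy study reports:

* **Conversion / DTG processing** — degree of conversion
  `α = (w0 − w)/(w0 − wf)`, its rates `dα/dT` and `dα/dt = β·dα/dT`,
  Savitzky–Golay-type derivative smoothing, pyrolysis-zone annotation
  (drying ≤ 400 K, active 400–740 K, passive ≥ 760 K) and DTG peak
  characterization.
* **Isoconversional ("model-free") activation energy** — at each fixed
  conversion, `Ea(α)` from regressions across heating rates:
  Friedman (`ln(dα/dt)` vs `1/T`), Flynn–Wall–Ozawa (`ln β` vs `1/T_α`,
  Doyle linearization, `Ea = −slope·R/1.052`), Kissinger–Akahira–Sunose
  (`ln(β/T_α²)` vs `1/T_α`) and Popescu
  (`ln(β/(T_α − T_{α−Δα}))` vs `1/(T_α + T_{α−Δα})`), with per-level
  regression diagnostics and pre-exponential factors.
* **Combined kinetic analysis** — the truncated Šesták–Berggren fit
  `ln(dα/dt) − ln[(1−α)^n α^m] = ln(cA) − Ea/(R·T)`, plus master-plot
  ranking of eleven ideal solid-state mechanisms by the reduced model
  function `f(α)/f(0.5)` (which the Friedman intercepts give up to a
  constant that cancels).
* **Activation thermodynamics** — `ΔH = Ea − R·T_ref`,
  `ΔG = Ea + R·T_p·ln(k_B·T_p/(h·A))`, `ΔS = (ΔH − ΔG)/T_p`.
* **Bioenergy indicators** — dry weight from optical density
  (`DW = 0.263·OD688 + 0.0104` g/L), CO₂ biofixation rate
  `R = P·C_C·MW_CO2/MW_C`, and higher heating value from the ultimate
  analysis (C, H, N, S, O wt%).
* **Neural surrogate** — a 4-10-1 feed-forward network (exponential
  hidden / sine output, BFGS-trained) mapping
  (T, β, α, dα/dt) → Ea(α).
* **Synthetic data** — a pseudo-component devolatilization simulator
  (carbohydrate / protein / lipid + moisture + ash, each with its own
  kinetic triplet integrated through `deSolve`) whose default spec is
  calibrated to a *Gonium pectorale*-like biomass; it provides exact
  ground truth for every estimator above.

## Worked example

```r
library(pyroalga)

tgs      <- simulate_biomass(default_biomass_spec(noise_sd = 0), c(5, 10, 20))
profiles <- lapply(tgs, compute_conversion, window = c(400, 740))

peaks <- do.call(rbind, lapply(profiles, detect_peaks))
peaks[peaks$is_main, c("heating_rate", "T_p", "rate_at_peak")]
#>   heating_rate   T_p rate_at_peak
#> 1            5 589.5   0.08476444
#> 4           10 596.5   0.16531948
#> 7           20 604.0   0.32235553

iso <- temperatures_at_conversion(profiles)      # alpha grid 0.1..0.8 by 0.05
summary(isoconv_fit(iso, "friedman"))
#> friedman: Ea 101.5-306.8 kJ/mol over 15 levels (mean 184.5 +- 80.1), min R2 0.999
summary(isoconv_fit(iso, "fwo"))
#> fwo: Ea 104.5-267.9 kJ/mol over 15 levels (mean 176.5 +- 75.4), min R2 0.999
```

The main DTG peak shifts from 589.5 K to 604.0 K as the heating rate
doubles twice, and `Ea(α)` rises from ~100 kJ/mol (carbohydrate-dominated
conversions) to ~300 kJ/mol (lipid tail) — the multi-step signature of a
multi-component feedstock. On single-step data the mechanism tools recover
the generating model exactly:

```r
ua <- ultimate_analysis(C = 49.34, H = 7.04, N = 8.64, S = 0.69, O = 34.98)
hhv_from_ultimate(ua)                    # 20.41882 MJ/kg
round(co2_fixation_rate(74.2, 49.34), 3) # 0.134 g/L/day
```

`run_pipeline(pipeline_config(...), "out/")` chains every stage and writes
the result tables, a config snapshot and a MANIFEST into `out/`;
`reference_table()` exposes the bundled reference tables (ultimate
analysis, DTG peaks, FWO kinetics, combined fits) used by the worked
examples.

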