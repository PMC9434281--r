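---
title: "Pyrolysis kinetics of microalgal biomass: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pyrolysis kinetics of microalgal biomass: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pyroalga)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind them, the parameters that matter, and
the places where a design choice had to be made. Nothing stated here as a
number is asserted beyond what the test suite and `scripts/acceptance.R`
actually compute.

## The kinetic model

Non-isothermal solid-state kinetics start from the rate law

$$\frac{d\alpha}{dt} = A\,e^{-E_a/RT} f(\alpha), \qquad
  \alpha = \frac{w_0 - w}{w_0 - w_f},$$

where $\alpha$ is the degree of conversion computed from the initial,
instantaneous and final sample masses over an analysis window, $A$ (1/min)
and $E_a$ (kJ/mol) are the Arrhenius parameters, and $f(\alpha)$ is the
reaction model. Under a constant heating rate $\beta = dT/dt$ this becomes
$d\alpha/dT = (A/\beta)\,e^{-E_a/RT} f(\alpha)$, the equation the
synthetic generator integrates and every estimator inverts in some form.

**Assumptions.** A single (apparent) reaction per component; Arrhenius
temperature dependence; no heat- or mass-transfer limitation inside the
sample (a few mg of powder in an alumina crucible approximates this); a
baseline-corrected mass signal. None of the estimators assume a constant
$E_a$ across conversion — detecting its variation is the point of the
isoconversional analysis.

## Isoconversional estimators

At each grid conversion the package regresses, across heating rates:

| method   | ordinate | abscissa | $E_a$ from slope |
|----------|----------|----------|------------------|
| friedman | $\ln(d\alpha/dt)$ | $1/T$ | $-sR$ |
| fwo      | $\ln\beta$ | $1/T_\alpha$ | $-sR/1.052$ |
| kas      | $\ln(\beta/T_\alpha^2)$ | $1/T_\alpha$ | $-sR$ |
| popescu  | $\ln\!\big(\beta/(T_\alpha - T_{\alpha-\Delta\alpha})\big)$ | $1/(T_\alpha + T_{\alpha-\Delta\alpha})$ | $-sR/2$ |

Plain OLS is used (the classical presentations show simple linear fits;
weighting would change little with three heating rates and invites
over-interpretation). The FWO method inherits a systematic 2–3% bias from
the Doyle linearization of the temperature integral; the tests therefore
hold Friedman to 0.5%, KAS to 1%, Popescu to 2% and FWO to 3% on exact
single-step data, and these tolerances are met with large margin.

Grid points with non-positive rates are dropped and recorded; a
conversion level with fewer than two usable points, or a degenerate
abscissa (identical temperatures), yields no row rather than a garbage
estimate.

**Defaults.** Conversion grid 0.1–0.8 in steps of 0.05, extendable to 0.9
(both ranges appear in practice); Popescu $\Delta\alpha$ = one grid step
(0.05) — nothing in the method fixes it, so the smallest resolvable
interval is used.

**Pre-exponential factors.** Two conventions are implemented and the
choice is always recorded in the output, because published tables rarely
say which was used and the two differ by orders of magnitude on
multi-step data: `friedman_intercept_first_order`
($A = e^{\mathrm{intercept}}/f(\alpha)$, exponential error amplification
documented) and `kissinger_per_alpha`
($A = \beta E_a e^{E_a/RT_p}/(R T_p^2)$). The intercept route is the
default.

## Combined kinetic analysis and master plots

The truncated Šesták–Berggren model $f(\alpha) = c(1-\alpha)^n \alpha^m$
linearizes to

$$\ln\frac{d\alpha}{dt} - \ln\big[(1-\alpha)^n\alpha^m\big]
  = \ln(cA) - \frac{E_a}{R\,T}.$$

For each candidate $(n, m)$ the left side is regressed on $1/T$; a coarse
grid ($n \in [0,4]$, $m \in [-1,1]$, step 0.05 — brackets every exponent
pair a biomass fit plausibly needs) is refined by bounded
quasi-Newton maximization of $R^2$. Standard errors come from the
covariance of the equivalent joint linear model at the optimum. A best
$R^2$ below 0.5 is flagged `adequate = FALSE` instead of being returned
silently. All points with $\alpha \in [0.05, 0.95]$ and positive rate
enter the fit.

Master-plot ranking uses the fact that the Friedman intercepts estimate
$\ln[A f(\alpha)]$: normalizing at $\alpha = 0.5$ cancels $A$, so
$e^{\mathrm{ic}(\alpha) - \mathrm{ic}(0.5)} = f(\alpha)/f(0.5)$ can be
compared against the reduced curves of eleven ideal mechanisms
(F1–F3, A2, A3, R2, R3, D1–D3, P2) by RMSE over the grid — RMSE rather
than maximum deviation, as a single noisy level should not decide the
mechanism.

Two behaviors discovered while validating deserve a warning label:

* **Incomplete-conversion renormalization.** A third-order tail converts
  so slowly that a 303–1073 K ramp leaves $1-\alpha \approx 4\times10^{-4}$
  unreacted. Renormalizing conversion over the ramp then distorts
  $\ln(1-\alpha)$ near $\alpha \to 1$ and biases the recovered $n$ upward
  by about 0.1 (the estimator itself is exact on unrenormalized curves).
  This is a property of the data definition, not of the fit, and it
  affects real records the same way.
* **Master plots presume single-step kinetics.** On strongly multi-step
  data (the default synthetic biomass) the Friedman intercepts swing by
  tens of log-units across the mechanism crossover and the reduced curve
  explodes; the ranking is then meaningless for all models at once. Rank
  mechanisms on data that the $E_a(\alpha)$ profile shows to be
  single-step, as the flat-profile convention recommends.

## Activation thermodynamics

$$\Delta H = E_a - R\,T_{\mathrm{ref}}, \quad
  \Delta G = E_a + R\,T_p \ln\frac{k_B T_p}{h\,A}, \quad
  \Delta S = \frac{\Delta H - \Delta G}{T_p}.$$

$T_{\mathrm{ref}}$ and $T_p$ are deliberately *separate explicit
arguments*. Published tabulations of these quantities are frequently
internally consistent only with a $T_{\mathrm{ref}}$ that matches none of
the reported peak temperatures — the bundled reference kinetics table
implies $T_{\mathrm{ref}} \approx 619.6$ K against peak temperatures of
592.7–607.0 K — so silently picking one temperature would make the
results unreproducible. Likewise, $k_B T/h$ is a frequency in 1/s, so a
pre-exponential factor in 1/min must be divided by 60 inside $\Delta G$;
`convert_A = TRUE` is the default and the flag is recorded, with
`convert_A = FALSE` available to reproduce tabulations that skipped the
conversion (the difference is exactly $R\,T_p \ln 60$, about 20 kJ/mol).

## Bioenergy calculators

Dry weight from optical density is the affine calibration
$DW = 0.263\,\mathrm{OD}_{688} + 0.0104$ g/L. The CO₂ biofixation rate is
$R_{\mathrm{CO_2}} = P \cdot C_C \cdot MW_{\mathrm{CO_2}}/MW_C$ with
$MW_C = 12.011$, $MW_{\mathrm{CO_2}} = 44.01$ g/mol (standard atomic
weights); rounding happens only at presentation (3 decimals).

**The HHV correlation required disambiguation.** As typeset in the
sources that circulate it, the correlation's exponent groupings are not
uniquely parseable (e.g. whether `−1.3101` is an exponent of H or an
additive constant, and whether `HO` means $H\cdot O$ or $H/O$). All 432
algebraically admissible groupings were evaluated against the eleven
bundled (composition, HHV) reference pairs; exactly one variant,

$$\mathrm{HHV} = -0.8738\,N H^{-1.3101} - 0.1583\,C O^{0.3497}
 + 0.3856\,C (HO)^{0.1462} + 2.1436\,(H/O)^{-0.3846}
 + 0.1076\,C H^{-0.3846} + 0.1098\,N S - 11.2794\,(H/C),$$

reproduces seven of the eleven rows to within 0.005 MJ/kg. The remaining
four rows are inconsistent with *every* variant (and the mismatch does not
track sulfur: an S = 0.69 row reproduces exactly while an S = 0.48 row is
2.5 MJ/kg off), so the reference table itself is internally inconsistent
for them. Per-row residuals of the frozen variant, in MJ/kg:

| condition | residual | condition | residual |
|---|---|---|---|
| TAP + air | −2.511 | 3NBBM control | −0.005 |
| TAP + nitrate | −2.480 | 3NBBM + air | +0.005 |
| TAP without acetic acid | −0.740 | 3NBBM + 1% CO₂ | −0.004 |
| TAP + 0.1% glucose | +0.002 | 3NBBM + 2% CO₂ | −0.001 |
| TAP + 0.2% glucose | +0.004 | 3NBBM + 5% CO₂ | +0.003 |
| TAP control | +0.170 | | |

A literal variant raising S to its negative power is kept in the registry
(`"s_power"`) purely so that requesting it on an S = 0 composition fails
with a clear diagnostic rather than an arithmetic surprise.

## The synthetic generator

`default_biomass_spec()` emulates a microalgal feedstock as three
first-order pseudo-components plus a moisture stage and inert ash:

| component | mass fraction | volatile fraction | A (1/min) | Ea (kJ/mol) |
|---|---|---|---|---|
| carbohydrate | 0.26 | 0.75 | 3.984e10 | 100 |
| protein | 0.16 | 0.75 | 2.694e12 | 130 |
| lipid | 0.30 | 0.95 | 4.024e23 | 270 |
| moisture | 0.06 | 1 | 3.86e8 | 60 |
| ash | 0.22 | 0 | — | — |

Each $A$ was fixed once from the first-order peak-stationarity condition
$E_a \beta / (R T_p^2) = A e^{-E_a/R T_p}$ at a target peak temperature
for $\beta = 10$ K/min (480, 535, 596.5 and ~355 K respectively), chosen
so the component peaks sit inside the conventional decomposition windows
(carbohydrates 410–540 K, proteins 470–550 K, lipids 560–630 K), the
global DTG peak lands near 590–605 K and shifts upward with heating rate,
and secondary peaks above 20% of the main height appear — the qualitative
fingerprint of a multi-component algal biomass. The very large lipid $A$
is the kinetic-compensation counterpart of its high $E_a$; a slowly
shifting dominant peak (a fraction of a kelvin per doubling of $\beta$ at
the low end) is only achievable with a high-$E_a$ component. The ramp is
303–1073 K sampled every 0.5 K of ramp (a finer step is a spec
parameter), and gaussian mass noise (default sd 0.002 mg, a realistic
microbalance floor; 0 for oracle data) is added with a fixed seed —
identical seeds give bit-identical records.

Component curves are integrated with `deSolve::lsoda` at `rtol = 1e-9`,
`atol = 1e-12`, with dense output on the fixed grid; the rate law is
non-stiff at these parameters. Conversion is clipped against floating
overshoot only within $10^{-9}$.

**What the generator does not emulate** — and hence what passing tests do
*not* demonstrate about real data: heat- and mass-transfer limitation,
baseline drift and buoyancy effects, secondary char-forming reactions
that couple components, and instrument temperature-control error. The
generator is a stand-in for unavailable raw traces, not a measurement;
its composition fractions are calibrated choices, not determinations.

## Preprocessing choices

The kinetic analysis window defaults to the active pyrolysis zone
(400–740 K) so that moisture and chlorophyll loss below 400 K do not
contaminate the devolatilization kinetics; conversion for a full-record
TG plot can be computed over the whole ramp by passing `window = NULL`.
The window conversion is renormalized within the window by definition.

Derivatives are central finite differences on the (possibly non-uniform)
temperature grid; `smooth_derivative()` replaces them with the derivative
of a local cubic fitted in a 21-point moving window — the conventional
Savitzky–Golay setting at these sampling densities — with window
shrinkage (and automatic order reduction) at the record ends instead of
extrapolation. $d\alpha/dt$ is always recomputed as
$\beta \cdot d\alpha/dT$, so the rate-consistency identity survives
smoothing exactly. Peak detection reports the global in-zone maximum as
the main peak and any strict local maxima above 20% of it — the
multiple-peak threshold is a package choice, stated rather than hidden,
since the field's descriptions of "multiple peaks" name no criterion.

## The neural surrogate

A single-hidden-layer 4-10-1 perceptron maps standardized
(T, β, α, dα/dt) to $E_a$, with exponential hidden and sine output
activations (the combination reported to perform best in the
architecture family this mirrors); sine outputs require bounded targets,
so $E_a$ is min–max scaled to $[-0.9, 0.9]$ and the scaler stored.
Training minimizes the sum of squared errors plus an L2 weight penalty by
full-batch BFGS to convergence; a small penalty grid
($\lambda \in \{10^{-4}, 3\times10^{-4}, 10^{-3}\}$) × 8 random restarts
is searched, and the single network with the smallest validation error is
retained — mirroring the practice of training several candidate networks
and choosing one by external validation. The 70/15/15
train/test/validation split and the initialization both derive from one
seed; identical seeds reproduce the fit exactly.

**Known limitation.** On the default synthetic biomass the
activation-energy surface has a sharp two-plateau transition
(~100 → ~300 kJ/mol over a narrow conversion interval) where three of the
four inputs are mutually redundant. A network this small, trained on
~32 rows, reliably reaches held-out R² ≈ 0.95–0.99 but not better: it
cannot be forced to ignore the redundant inputs between training points,
and its held-out error concentrates at the transition. An α-only
interpolator would be exact here, so this is a genuine capacity/training
limitation of the mirrored architecture, not of the data. Weight-decay
annealing, Bayesian regularization, restart ensembling and jitter
augmentation were all evaluated and none robustly improves on the frozen
protocol; the surrogate is an optional stage and no kinetic result
depends on it.

## Problem sizes

The test suite and acceptance script run, end to end: three-rate
simulations of the four-component default biomass (1541 samples per
record), single-component oracles at three rates, 50-replicate
noise-stability loops, and one surrogate training (24 BFGS fits on 32
training rows). The full suite completes in well under a minute on one
core; these sizes were chosen as the smallest at which every estimator's
tolerance is meaningful.
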