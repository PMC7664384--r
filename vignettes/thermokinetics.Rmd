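---
title: "Thermokinetics of reversible enzyme reactions from single-injection calorimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermokinetics of reversible enzyme reactions from single-injection calorimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermokin)
```

## The problem

Many enzyme-catalysed reactions in central metabolism are reversible: they
do not consume their substrate completely but run into a thermodynamic
equilibrium, and much of their in-vivo operation happens close to that
equilibrium. Irreversible Michaelis-Menten kinetics cannot describe this
approach to equilibrium, and the fully reversible Michaelis-Menten
mechanism needs more parameters than a small set of progress curves can
identify. This package implements an alternative analysis built on
irreversible thermodynamics, worked out for two glycolytic reactions
measured by isothermal titration calorimetry (ITC): the phosphoglucose
isomerase (PGI) reaction, measured in the direction F6P to G6P, and the
enolase reaction, measured as PEP to 2PG.

ITC records the heat production rate $P(t)$ (W) of the reaction mixture
after a single injection. Because every mole converted releases the molar
reaction enthalpy $\Delta_R H$, a single thermogram contains the complete
progress curve: the substrate consumption rate is

$$ r(t) = \frac{P(t)}{\Delta_R H \cdot m}, \qquad
   c_S(t) = c_{S0} - \frac{\int_0^t P\,dt'}{\Delta_R H \cdot m}, $$

with $m$ the mass of solution in the cell. `to_concentration_trace()`
implements exactly this transform (composite trapezoid for the running
integral; the grid is dense and uniform, so a higher-order rule would buy
nothing).

## Driving force and the two rate laws

The distance from equilibrium is expressed by the dimensionless driving
force

$$ \iota \;=\; 1 - e^{\Delta_R G / RT}
   \;=\; 1 - \frac{c_S^{eq}\, c_P}{c_S\, c_P^{eq}}, $$

with activities approximated by molalities throughout (the reacting
species sit at millimolar levels in a dilute aqueous buffer; activity
corrections enter only through the equilibrium ratio $K_c$, which is an
input). $\iota = 1$ with no product present, $0$ at equilibrium.
`driving_force()` and `gibbs_energy()` satisfy
$\iota = 1 - \exp(\Delta_R G/RT)$ to machine precision, which the test
suite asserts on random compositions.

Two equilibrium-aware rate laws are fitted:

* **Flux-force relation** (one parameter):
  $r = L \cdot c_E \cdot \dfrac{\iota}{2-\iota}$.
  $L$ (s$^{-1}$) is the phenomenological coefficient. The law is exact in
  the near-equilibrium limit; far from equilibrium it underestimates the
  curvature of real saturation kinetics, which is why its fitting window
  is restricted (below).
* **Separable (Noor) rate law** (two parameters): capacity times enzyme
  saturation times driving force. Two single-saturation reductions are
  used: substrate saturation
  $r = r_{max}\frac{c_S/K_S}{1+c_S/K_S}\,d(c_S)$ for the concave PGI
  curve, and product saturation
  $r = \Lambda \frac{c_S}{1+(c_{S0}-c_S)/K_P}\,d(c_S)$ for the convex
  enolase curve, where
  $d(c_S) = 1 - \frac{c_S^{eq}(c_{S0}-c_S)}{(c_{S0}-c_S^{eq})c_S}$ is the
  driving factor under the mass balance $c_P = c_{S0} - c_S$. In the
  product-saturated regime the capacity and the substrate Michaelis
  constant only appear as the ratio $\Lambda = c_E k^+_{cat}/K_S$, so
  $\Lambda$ is the identifiable parameter. The full double-saturation
  form is provided (`noor_rate_double()`) but not fitted by default: for
  both worked reactions a single saturation term describes the data, and
  adding the second denominator term only degrades identifiability.

All three laws are exactly zero at the equilibrium composition — the
property that makes them suitable for progress curves that end in
equilibrium — and the tests assert this pointwise.

## Equilibrium and thermodynamic outputs

`equilibrium_concentrations()` solves the end point of the measured
direction from $K_c$ and the mass balance. Conventions matter here and
are easy to get backwards, so the solver is written against explicit
species roles: for the isomerization $K_c = c_S^{eq}/c_P^{eq}$ with F6P
the substrate of the measured direction (hence $K_c < 1$ even though the
reaction proceeds far toward product), and for the dehydration
$K_c = c_S^{eq} c_{H_2O}/c_P^{eq}$ in mol kg$^{-1}$, with the water
molality held at the pure-water value 55.51 mol kg$^{-1}$ — water is in
$\sim$700-fold excess over the converted amount, so its depletion is far
below every other error source.

From the integrated heat, `reaction_enthalpy()` computes
$\Delta_R H = Q/((c_{S0}-c_S^{eq})\,m)$; `vant_hoff_enthalpy()` regresses
$\ln K_c$ on $1/T$; `fit_arrhenius()` regresses $\ln L$ on $1/T$ to give
the activation energy; and `q10_activation_energy()` provides the
closed-form plausibility check from a rate-doubling rule of thumb
($R\,\ln q \cdot T_1 T_2/(T_2-T_1)$, about 52.9 kJ mol$^{-1}$ for a
doubling between 298.15 and 308.15 K).

The cell solution mass deserves a note: it is not printed with the
reference data. The cell volume is stated as roughly 250 µL, while
back-calculating from the tabulated heats and enthalpies implies closer
to 200 µL. The package takes $m$ as an explicit input everywhere and the
worked systems default to $2.0\times10^{-4}$ kg; with that choice the
integrated-heat enthalpy of the PGI reaction at 310.15 K comes out at
11.0 kJ mol$^{-1}$ against the tabulated 11.1 ± 0.5. The tabulated
enolase enthalpy (2.4 kJ mol$^{-1}$) cannot be reproduced from its $Q$
and $K_c$ with any single cell mass consistent with the PGI rows; those
rows are therefore carried as reference values, not derivations.

## Trim rules: which points enter a fit

The head of a thermogram does not reflect reaction kinetics: the
instrument responds with first-order inertia, and the injection carries a
heat-of-dilution pulse. Rather than deconvolving the instrument response
(numerically ill-conditioned on noisy data), the analysis drops the
distorted points:

1. everything at or before the time of maximum $|r|$ is excluded — until
   the measured heat flow has peaked, the signal is rising because of
   instrument inertia, not chemistry;
2. in flux-force mode, additionally every point with
   $\iota/(2-\iota) > 0.6$ (i.e. $\iota > 0.75$) is excluded, because the
   linear flux-force relation only holds near equilibrium. The threshold
   is applied inclusively (points exactly at 0.6 are kept).

`apply_trim_rules()` implements both, never re-admits a point, and
errors if fewer than five points survive. Rule 1 is an operationalisation
of "before the heat flow reaches its maximum"; the exact trimmed duration
is not specified more precisely by the source analysis, and on simulated
data the choice is inconsequential because the maximum is sharp.

## Fitting choices

The flux-force fit is a zero-intercept regression of $r$ on
$x = \iota/(2-\iota)$: the law forces $r = 0$ at $x = 0$, so estimating
an intercept would spend a degree of freedom on a parameter known to be
zero (a free-intercept variant exists behind `intercept = TRUE` for
sensitivity checks). $R^2$ is computed against the zero-intercept model
and the slope t-test uses $n-1$ degrees of freedom. $L$ follows as
slope$/c_E$, so it is only as accurate as the enzyme molality.

The separable-law fits are bounded nonlinear least squares
(Levenberg-Marquardt) of $r$ against $c_S$ with $c_{S0}$ and $c_S^{eq}$
held fixed. Start values come from the data ($r_{max,0} = 1.5\max r$,
$K_{S,0} = \mathrm{median}\,c_S$; $\Lambda_0 = \max r/c_{S0}$,
$K_{P,0} = 0.2\,c_{S0}$) and the optimiser is restarted from five
deterministically jittered starts, keeping the lowest residual sum of
squares — the surfaces are benign, but the jitter guards against a bad
basin at no stochastic cost. Replicates are fitted per trace and
summarised as mean ± sd; the Arrhenius regression runs on replicate
means, unweighted (a $1/\sigma^2$-weighted option would be a natural
extension but three temperature points give it little leverage).

## The synthetic-data generator

No raw thermograms are distributed with the reference results, so the
generator stands in for the instrument. It emulates the single-injection
design: `simulate_progress()` integrates $dc_S/dt = -r(c_S)$ for the
chosen ground-truth law (lsoda on a uniform output grid, rtol $10^{-9}$,
atol $10^{-12}$ — the right-hand sides are smooth and non-stiff at these
parameter scales), and `simulate_thermogram()` maps the rate to ideal
power $P = r\,\Delta_R H\,m$ and applies the instrument model:

* a first-order response of time constant $\tau$, implemented as the
  exact closed-form response to piecewise-linear input rather than a
  discrete convolution kernel, so the filter has unit DC gain and the
  integrated heat is conserved identically in continuous time (the tests
  verify conservation to well below 0.1% after discretisation);
* a Gaussian dilution pulse of prescribed total heat at the injection
  time (the pulse shape of real dilution peaks is not parameterised by
  the reference analysis; a Gaussian of adjustable width is the simplest
  shape with a controlled area);
* i.i.d. Gaussian baseline noise with a fixed seed for bit-identical
  reproducibility.

Defaults $\tau = 10$ s and noise sd $= 0.02$ µW are engineering choices
on the scale of modern titration microcalorimeters; the actual instrument
constants are not reported with the reference data, which is why both are
configuration fields rather than constants.

What the generator does *not* emulate: baseline drift, enzyme
deactivation (observed only above the analysed temperature range),
multi-injection protocols, and activity-coefficient dynamics along the
progress curve. Passing recovery tests therefore show that the
*processing and fitting chain* is correct and robust at realistic noise,
not that the rate laws are true of any particular enzyme.

## Study conditions and problem sizes

The worked designs mirror the reference experiments: 4.8 mmol kg$^{-1}$
F6P with 14.3 nmol kg$^{-1}$ PGI, and 74.8 mmol kg$^{-1}$ PEP with
2 µmol kg$^{-1}$ enolase, at 298.15–310.15 K. Simulated records are
3600 s at 1 Hz for the PGI designs and 6000 s at 0.5 Hz for enolase —
about ten relaxation times in both cases (analytically ~250 s and ~580 s
near equilibrium), so the signal genuinely returns to baseline. The
recovery study uses one ideal-instrument run per law plus three noisy
runs at seeds fixed in advance (101, 202, 303); recovered parameters sit
within 0.01% (ideal) and 5% (noisy) of truth, with the product Michaelis
constant of the enolase design the least well determined (~4%), as
expected for a parameter that only shapes the early, partially trimmed
part of the curve.

## Numerical edge cases

* `gibbs_energy()` at $c_P = 0$ returns $-\infty$ as a sentinel (the
  driving force is exactly 1 there; an exception would make the first
  sample of every fresh injection an error).
* Integrator round-off at the equilibrium plateau is clipped: $c_S$ is
  made non-increasing and the simulated $r$ and $\iota$ are clipped at 0
  and $[0,1]$ — all at the $10^{-13}$ level, far below any fitted
  quantity.
* `to_concentration_trace()` refuses traces whose implied $c_S$ goes
  negative, naming the first offending time; this is the symptom of a
  wrong $\Delta_R H$, wrong mass, or un-subtracted dilution heat.
* Reference subtraction interpolates linearly; spline interpolation was
  rejected because it rings at the injection spike.

## Limitations

The flux-force coefficient $L$ absorbs everything the two-parameter laws
resolve (capacity and saturation), so it transfers across conditions only
to the extent that the near-equilibrium window dominates. The package
fits each law independently and reports $R^2$ side by side; it provides
no formal model-selection machinery. Activity-coefficient prediction is
out of scope — $K_c$ (or $K_a$ with a user-supplied $K_\gamma$ via
`kc_from_ka()`) is an input.
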