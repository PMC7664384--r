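# thermokin

Thermokinetic analysis of reversible enzyme reactions from
single-injection isothermal titration calorimetry (ITC).

Reversible reactions — most of glycolysis among them — run into a
thermodynamic equilibrium rather than to completion, and classical
irreversible Michaelis-Menten kinetics cannot describe that approach to
equilibrium. `thermokin` is for enzymologists and systems-biology
modellers who want equilibrium-aware kinetic parameters out of
calorimetric progress curves. It implements the full chain for two
worked glycolytic systems, the phosphoglucose isomerase (PGI) reaction
(measured as F6P → G6P) and the enolase reaction (PEP → 2PG):

1. **Thermogram processing.** Reference (heat-of-dilution) subtraction,
   heat integration, and the progress-curve transform
   `r(t) = P(t)/(Δ_R H · m)`,
   `c_S(t) = c_S0 − ∫P dt/(Δ_R H · m)`,
   turning one single-injection thermogram into a complete rate vs
   concentration curve.
2. **Equilibrium-aware rate laws.** The thermodynamic driving force
   `ι = 1 − exp(Δ_R G/RT) = 1 − (c_S^eq c_P)/(c_S c_P^eq)` and three
   laws that vanish exactly at equilibrium: the one-parameter flux-force
   relation `r = L·c_E·ι/(2−ι)`, and the separable (Noor) rate laws with
   substrate saturation (`r_max`, `K_S`) or product saturation
   (`Λ`, `K_P`).
3. **Fitting and derived thermodynamics.** Zero-intercept flux-force
   regression with near-equilibrium trimming (`ι/(2−ι) ≤ 0.6`), bounded
   multi-start nonlinear fits of the separable laws, reaction enthalpy
   from integrated heat (`Δ_R H = Q/((c_S0 − c_S^eq)·m)`), van 't Hoff
   enthalpy from `K_c(T)`, and Arrhenius activation energy from `L(T)`.
4. **Synthetic data.** A thermogram generator (ODE progress curve +
   first-order instrument response + dilution pulse + Gaussian noise)
   with the tabulated parameters of both reactions as ground truth, so
   the whole chain is testable without access to an instrument.

## Worked example

Simulate the PGI experiment at 310.15 K (4.8 mmol/kg F6P, 14.3 nmol/kg
enzyme, tabulated `Kc = 0.343`, ground-truth `L = 518.44 1/s`) with a
realistic instrument, then recover `L` from the thermogram alone:

```r
library(thermokin)

rs  <- pgi_system(310.15)                 # cell composition + Kc lookup
eq  <- equilibrium_concentrations(rs)
cfg <- simulation_config("flux_force",
                         flux_force_params(L = 518.44, cE = rs$cE),
                         rs, duration = 3600, dt = 1,
                         tau_instrument = 10, noise_sd = 2e-8, seed = 101)
tg    <- simulate_thermogram(simulate_progress(cfg), rs, 11.1e3, cfg)
trace <- to_concentration_trace(tg, delta_h = 11.1e3, m = rs$m,
                                cS0 = rs$cS0)
fit   <- fit_flux_force(apply_trim_rules(trace, eq, flux_force_mode = TRUE),
                        cE = rs$cE)
fit
#> <flux_force_fit> L = 518 +/- 0.075 1/s (R2 = 0.99993, n = 3251)
```

The fitted coefficient lands within 0.1% of the ground truth, at the
fit quality (R² > 0.99) seen on real traces of this reaction. Deriving
the thermodynamics from the packaged reference tables:

```r
th  <- load_fixture_tables()$thermo
pgi <- th[th$reaction == "pgi", ]
vant_hoff_enthalpy(pgi$Kc, pgi$temperature_K)$dH / 1e3
#> [1] 11.86579            # kJ/mol, van 't Hoff from Kc(T)

L <- load_fixture_tables()$flux_force
fit_arrhenius(L$L_per_s[L$reaction == "pgi"],
              L$temperature_K[L$reaction == "pgi"])
#> <arrhenius_fit> Ea = 55.64 kJ/mol (se 1), A = 1.21e+12 1/s, R2 = 0.99967
```

The activation energy of ~55.6 kJ/mol for PGI (and ~44.4 kJ/mol for
enolase) is consistent with the ~52.9 kJ/mol implied by the classical
rule that a 10 K rise doubles a reaction rate
(`q10_activation_energy(298.15, 308.15, 2)`).

## Analysis workflow

The `analysis/` scripts are thin numbered drivers over the package and
write their tables under `results/`:

| script | what it does |
|---|---|
| `01_reference_thermodynamics.R` | equilibrium compositions, integrated-heat enthalpies, van 't Hoff, Q10 |
| `02_arrhenius.R` | Arrhenius fits of the flux-force coefficients for both reactions |
| `03_recovery_study.R` | full-chain parameter recovery for all three rate laws, ideal + noisy instrument |
| `04_pipeline_triplicates.R` | `run_pipeline()` emulation of the triplicate, three-temperature PGI campaign |

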