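# cardioloop

Closed-loop lumped-parameter (0D) modelling of the human circulation and
a decomposed inverse-analysis framework that identifies patient-specific
parameters from clinical pressure, flow and chamber-volume time series —
with an in-silico pulmonary-valve-replacement workflow for repaired
tetralogy-of-Fallot (ToF) physiology.

The package is aimed at cardiovascular modellers and methods researchers
who want a desk-scale, fully testable implementation of:

* a **closed-loop 0D forward model**: systemic and pulmonary 3-element
  arterial / 2-element venous windkessels
  (`C (dp/dt − Z dq/dt) − q_valve + q_distal = 0`,
  `(p_ven − p_ar + Z q)/R + q_distal = 0`), four dynamic Bernoulli valves
  (`Δp = ρ/(2A_eff²) q|q| + (ρ l_eff/A_eff) dq/dt`, effective orifice
  area `A_eff = (A_max − A_min)ζ + A_min`, state rate
  `dζ/dt = (1−ζ)K_vo Δp` / `ζ K_vc Δp`), and active-stress-driven
  pressure–volume chamber surrogates
  (`dτ_a/dt = −|u|τ_a + σ₀|u|₊` under a trapezoidal activation),
  integrated monolithically with a One-Step-θ scheme, analytic-Jacobian
  Newton iteration and cycle-to-cycle iteration to a periodic state;
* a **decomposed inverse analysis**: arterial windkessel fits on a
  flow-eliminated pressure ODE, venous dependency rules, semilunar-valve
  effective-orifice-area fits from transvalvular pressure and flow, and
  an adjoint-gradient L-BFGS calibration of the 12 per-chamber
  active-stress parameters `(σ₀, α_max, α_min)` gated by a periodicity
  criterion;
* a **synthetic twin bench**: a ToF-like scenario generator, measurement
  synthesis at clinical sampling rates (cine-MRI volumes 25/cycle,
  phase-contrast flows 30/cycle, catheter pressures), end-to-end
  parameter-recovery experiments, and pre/post valve-replacement outcome
  tables.

The hot loops (residual assembly, Newton stepping, forward cycles, the
discrete adjoint) are compiled (RcppArmadillo); a pure-R reference
assembly is kept and tested against the compiled one.

## Worked example

Simulate the regurgitant ToF-like scenario to its periodic state, then
predict the effect of sealing the pulmonary valve:

```r
library(cardioloop)
scen <- make_tof_scenario(seed = 1)
sim  <- run_cycles(NULL, scen$params, dt = 1e-3)
summary(sim)
#> Final-cycle clinical metrics
#>   right: EDV 210.0  ESV 113.4  SV 96.7 ml   EF 46.0 %   FV 39.0  RV 57.7 ml   RF 59.7 %
#>   left:  EDV 104.6  ESV 62.2  SV 42.4 ml   EF 40.6 %   FV 42.0  RV 0.4 ml   RF 1.0 %
#>   p_v_l -0.10..12.62 kPa, p_v_r -0.03..4.34 kPa
#>   p_ar_sys 7.59..11.84 kPa, p_ar_pul -0.04..4.10 kPa

out <- predict_replacement_outcome(scen$params, pre_sim = sim)
print(out$delta, digits = 3)
#>    ventricle metric     pre     post     delta
#> 1      right    EDV 210.048 1.36e+02 -73.65089
#> 3      right     SV  96.689 5.08e+01 -45.85522
#> 6      right     RV  57.710 7.13e-05 -57.70946
#> 7      right     RF  59.685 1.40e-04 -59.68532
#> 10      left     SV  42.421 4.60e+01   3.60698
#> ...
```

The right ventricle is dilated (EDV 210 ml vs 105 ml on the left) with a
pulmonary regurgitation fraction near 60 % — the hallmark of the
post-repair ToF state. Sealing the valve (`A_eff_min → 0`, nothing else
changed) abolishes the backward volume (RV 57.7 → ~0 ml), unloads the
right ventricle (EDV −74 ml) and raises left-sided output (SV +3.6 ml).

End-to-end identification on synthetic measurements:

```r
tw <- run_twin_experiment(seed = 1, noise = "none")
print(tw)          # truth vs estimate for every identified parameter
```

A thin command-line front end wraps the same functions
(`inst/cli/cardioloop simulate|metrics|fit-windkessel|fit-valve|
fit-active-stress|twin|predict-replacement`).

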