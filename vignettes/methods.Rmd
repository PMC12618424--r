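---
title: "Closed-loop 0D cardiovascular modelling and decomposed inverse analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop 0D cardiovascular modelling and decomposed inverse analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`cardioloop` simulates the human circulation as a closed loop of lumped
(0D) compartments and identifies patient-specific parameters of that loop
from clinical pressure, flow and chamber-volume time series. The forward
model has three building blocks.

**Vascular compartments.** Each arterial bed (systemic, pulmonary) is a
3-element windkessel: compliance $C_{ar}$, peripheral resistance
$R_{ar}$, and characteristic impedance $Z_{ar}$ that represents wave
transmission. Its two balance equations are a mass balance
$C_{ar}(\dot p_{ar} - Z_{ar}\dot q_{v,out}) - q_{v,out} + q_{ar} = 0$ and
an algebraic momentum balance
$(p_{ven} - p_{ar} + Z_{ar} q_{v,out})/R_{ar} + q_{ar} = 0$. Each venous
bed is a 2-element windkessel ($C_{ven}$, $R_{ven}$) draining into an
atrium. Internal units are mm^3 / kPa / s; millilitres appear only at the
I/O boundary (1 ml = 1000 mm^3).

**Valves.** Each of the four valves follows a dynamic Bernoulli law
$\Delta p = \tfrac{\rho}{2A_{eff}^2} q\lvert q\rvert +
\tfrac{\rho l_{eff}}{A_{eff}}\dot q$, with the effective orifice area
interpolated between a minimum and maximum,
$A_{eff} = (A_{eff,max}-A_{eff,min})\,\zeta + A_{eff,min}$, and the valve
state $\zeta\in[0,1]$ driven by
$\dot\zeta = (1-\zeta)K_{vo}\Delta p$ for $\Delta p > 0$ and
$\zeta K_{vc}\Delta p$ otherwise. A positive minimum area is an
incompetent (regurgitant) valve; the $q\lvert q\rvert$ form carries
backward flow with the correct sign. Inside $1/A_{eff}$ terms the area is
floored at $10^{-4}$ mm^2 so a fully sealing prosthesis
($A_{eff,min}=0$) keeps the Jacobian finite.

**Chambers.** Active fiber stress per chamber obeys
$\dot\tau_a = -\lvert u\rvert \tau_a + \sigma_0 \lvert u\rvert_+$, where
the transmembrane potential $u$ blends an upstroke rate $\alpha_{max}>0$
and a relaxation rate $\alpha_{min}<0$ through a trapezoidal activation
$\hat f(t)\in[0,1]$ with regularization $K = 10$: zero until $c_1 - 1/K$,
a linear ramp to 1 at $c_1$, a plateau to $c_2$, and a ramp back to zero
at $c_2 + 1/K$, with $c_1 = t_{contr} + \alpha_{max}/(K(\alpha_{max} -
\alpha_{min}))$ and $c_2 = t_{relax} - \alpha_{max}/(K(\alpha_{max} -
\alpha_{min}))$. Activation is spatially homogeneous per chamber and
periodic with the cycle length $T_{cycl}$.

The reference formulation resolves the myocardium as a 3D finite-element
continuum; that component is out of scope here and replaced by a 0D
pressure–volume surrogate per chamber,

$$p(V, \tau_a) = E_{pass,a}\left(e^{E_{pass,b}(V - V_{ref})} - 1\right)
 + w\,\tau_a\,(V/V_{ref})^{1/3},$$

an exponential passive end-diastolic relation vanishing at the reference
volume $V_{ref}$ plus an active term that maps fiber stress to cavity
pressure through a dimensionless wall factor $w$ (so
$p_{act}(V_{ref}) = w\,\tau_a$) with a mild volume dependence. The
$(V/V_{ref})^{1/3}$ exponent was chosen over a Laplace-type
$(V_{ref}/V)^{1/3}$ because it keeps $p$ strictly increasing in both $V$
and $\tau_a$ (a C^1, monotone closure is what the Newton solver and the
adjoint need) while preserving the roles of $\sigma_0$, $\alpha_{max}$,
$\alpha_{min}$, which remain the identifiable quantities. The surrogate
is an artifact of this package, not part of the reference model; its
constants ($V_{ref}$, $E_{pass,a}$, $E_{pass,b}$, $w$) are configuration,
not fitted.

## Discretization and solution

The 28 unknowns per time level (20 circulation variables, 4 chamber
volumes, 4 active stresses) are advanced with the One-Step-$\theta$
scheme, $\theta = 0.5$ (trapezoidal) by default. Rows with time
derivatives are $\theta$-blended; derivative-free rows (the windkessel
momentum balances and the chamber pressure closures) are enforced fully
at the new time level. With that split the scheme is exactly trapezoidal
on the reduced ODE — the analytic RC test shows second order for
$\theta = 0.5$ and first order for $\theta = 1$ — whereas $\theta$-blending
algebraic rows would ring against inconsistent initial conditions. Valve
events ($q\lvert q\rvert$, branch switching, area floor) are non-smooth,
so global convergence on full heartbeats degrades toward first order at
event-crossing steps; the refinement test asserts at least first order.

Each step solves the coupled system with a damped Newton iteration:
analytic Jacobian, $q\lvert q\rvert$ linearized as
$2\lvert q\rvert\,\delta q$, valve branches frozen at the current iterate
(semismooth treatment), step-halving line search, convergence at
$10^{-8}$ on a diagonally scaled residual infinity norm, at most 25
iterations, and a fallback that halves the time step (up to four levels)
when a step refuses to converge. The default step is $dt = 10^{-3}$ s
(750 steps per 0.75 s cycle). The assembly, Newton loop, cycle marches
and the adjoint sweep are implemented in compiled code (RcppArmadillo);
an R reference implementation of the assembly is kept and tied to the
compiled one by a unit test.

Because the dynamics are driven by periodic activation, the cardiac cycle
is repeated with initial conditions carried over until the periodicity
error — the maximum relative change of the four compartment pressures and
the ventricular and atrial volumes between cycle start and end — falls
below $\epsilon_{cycl} = 0.04$. The printed form of this criterion lists
the right atrial volume twice and omits the left; we include both atria
(presumed typo) and expose `literal_printed_set` to reproduce the printed
set. Total blood volume (chamber volumes plus compartment stored volumes
$C(p - Zq)$) is conserved exactly by the discrete flux telescoping, which
the tests verify to $10^{-9}$ relative.

# Measurement handling

Measurements live in a `measurement_set`: named series of $(t,
\text{value})$ samples with a cycle duration and the convention that
$t_0 = 0$ is the onset of atrial contraction. CSV I/O uses a `t` column
plus any subset of the recognized series names, with units declared in a
sidecar JSON. Sparse clinical series — flows at 30 samples/cycle
(phase-contrast MRI), volumes at 25 (cine MRI) — are interpolated with
periodic cubic splines, whose analytic derivative feeds the
flow-eliminated windkessel ODE. Dense catheter pressure traces are
smoothed with a cross-validated smoothing spline (on a three-period
replication, so values and slopes wrap across the seam) before extrema
and rate features are extracted — but only when a third-difference MAD
noise estimate flags actual noise: maxima and derivatives of an
*interpolating* spline through noisy dense samples would be order
statistics of the noise, while cross-validated smoothing of a *clean*
trace blunts the systolic upstroke and biases the rate feature. Heart-rate differences
between acquisitions are removed by uniform time scaling per series and a
circular shift to the atrial-contraction origin. A mass-consistency check
compares the ejection-phase volume drop against the integrated semilunar
flow and can rescale the volume excursion (flows are trusted, volumes
adjusted).

Clinical metrics per ventricle: EDV and ESV are the volume extrema,
SV = EDV − ESV, EF = 100·SV/EDV; the retrograde volume RV integrates the
negative part of the semilunar flow; the forward volume is reported as
FV = SV − RV so that FV + RV = SV, and RF = 100·RV/(FV + RV). The FV
convention follows the arithmetic of the published preoperative table
(32.9 + 43.1 = 76.0), where "forward volume" is otherwise ambiguous.

# The decomposed inverse analysis

Because the coupling quantities between submodels are measured, the large
coupled identification problem splits into independent, well-posed
subproblems, each using only its own submodel as the forward problem.

**Arterial windkessels** (one fit per circulation). Eliminating the
distal flow turns the two windkessel balances into one scalar ODE for
$p_{ar}$ driven by the measured valve flow (and its spline derivative)
and venous pressure, started at the measured pressure. The objective is
four normalized squared mismatches: pressure maximum, minimum,
end-of-cycle value (periodicity), and maximum systolic pressure rate.
L-BFGS-B runs on $\log(R, C, Z)$ (positivity without constraints) from
Ohmic initial guesses; venous parameters then follow dependency rules
($R_{ven}^{sys} = R_{ar}^{sys}/10$, $C_{ven}^{sys} = 30\,C_{ar}^{sys}$,
$R_{ven}^{pul} = R_{ar}^{pul}$, $C_{ven}^{pul} = 2.5\,C_{ar}^{pul}$),
since the venous pressures and flows needed for a direct fit are not
measurable in routine practice. Systemic venous pressure is rarely
catheterized; when absent the right atrial trace is used as the venous
proxy.

**Semilunar valve areas** (one fit per valve). With the transvalvular
gradient prescribed from the two measured pressure series (splined onto a
common grid; the catheter runs are not simultaneous), the valve ODE pair
is marched over one cycle and the cycle-integrated forward and backward
volumes are matched to the measured flow integrals — two parameters, two
targets. The measured volumes integrate the *spline* of the sparse flow
(trapezoid over 30 raw samples would bias the targets). When the valve is
closed at $t_0$ the initial conditions are $q = 0$, $\zeta = 0$; a
regurgitant valve starts from the measured leak flow, clamped to the
trial valve's steady-Bernoulli capacity so that exploring small minimum
areas cannot force an unphysical initial flow through a sealed orifice
(the trapezoidal scheme would ring). Atrioventricular valves are not
fitted: their maximum areas come from imaging-based geometric orifice
areas and their minimum areas are zero (internally floored) absent
regurgitation.

**Active-stress parameters** (one fit, 12 parameters). The full closed
loop is the forward problem; the objective sums squared mismatches
between computed and measured chamber volumes (ml^2) at selected time
steps — by default every volume sample inside the chamber's active window
from contraction onset to relaxation onset plus a 0.25 s tail during
which the decaying stress still shapes the volumes (18 ventricular
samples at clinical rates; the cycle-start sample is excluded because the
initial state is pinned there). The gradient is a discrete adjoint
(discretize-then-differentiate) of the One-Step-$\theta$ system: one
backward sweep of the transposed linearized dynamics, cost comparable to
a forward solve, exact for the implemented forward model. The rate
parameters enter through the activation ramps, whose centers they shift;
the ramp kinks are handled by one-sided derivatives (measure-zero events
on the grid). L-BFGS runs in log-magnitude coordinates (signs fixed),
restarting with refreshed initial conditions every $N_f = 15$ forward
evaluations by default, and terminates only when both the objective falls
below $\epsilon_{sc}$ — computed as (error budget)^2 × (number of points),
e.g. $0.5^2\times 18 = 4.5$ ml^2 for a clinical 0.5 ml budget — and the
current solution is periodic ($E_{cycl}\le\epsilon_{cycl}$).

Three refinements proved necessary beyond the reference algorithm, all
exploiting that a 0D forward cycle costs milliseconds rather than a 3D
finite-element solve:

1. *Burn-in cycles* (`burn_in`): each evaluation may prepend a few cycles
   so the objective is evaluated near the parameter vector's periodic
   orbit. Without this, objectives from different restart rounds are not
   comparable and the optimizer chases the initial-condition transient.
   `burn_in = 0` reproduces the literal single-cycle forward problem.
2. *Orbit-converged initial-condition updates*: at each periodicity
   check the cycle map is iterated (tolerance `ic_eps`, default
   $10^{-4}$) instead of taking a single cycle, so the next round sees a
   stationary forward problem.
3. *Measured initial stored volumes*: the closed loop conserves total
   blood volume, so the limit cycle — and therefore the best attainable
   volume fit — depends on the initial compartment pressures. With a
   systemic venous compliance near 339 ml/kPa, guessing those pressures
   mis-sets total volume by tens of millilitres, an offset no
   active-stress parameter can repair. The initial state is therefore
   pinned to the measured pressures and semilunar flows at cycle start.

Per-round trust bounds (a factor 2.5 in log-magnitude space around the
incumbent) and a finite penalty sloping back toward the round start on
solver failure keep the line search out of unphysiological corners.

# The synthetic scenario and what it does (not) show

`make_tof_scenario()` is the study condition generator: a repaired
tetralogy-of-Fallot-like state with severe pulmonary regurgitation. The
circulation, valve, activation-timing and active-stress parameters use
the published patient-level values (e.g. pulmonary
$A_{eff,min} = 164$ mm^2, $A_{eff,max} = 308$ mm^2, $T_{cycl} = 0.75$ s,
ventricular contraction from $t_0 + 0.1425$ s to $t_0 + 0.4275$ s). The
chamber surrogate constants were sized once so that the converged loop
shows a dilated, volume-overloaded right heart — right EDV about twice
the left, pulmonary regurgitation fraction near 60 %, left-ventricular
systolic pressure ~13 kPa — and were then frozen. Right-ventricular
systolic pressure sits near 5 kPa, below the catheter traces of the
clinical case: with the published pulmonary windkessel, an 8 kPa right
ventricle would eject an implausibly large stroke volume through the
low-impedance pulmonary bed; the volume targets were given priority.

`synthesize_measurements()` samples a converged cycle at the clinical
rates (volumes 25/cycle, flows 30/cycle, pressures every solver step) and
adds independent Gaussian noise: 2 % multiplicative on pressures, additive
with sd = 3 % of peak |q| on flows (multiplicative noise would vanish at
flow reversals), 2 ml on volumes. Optional heart-rate jitter and time
shifts exercise the normalization step. The ground-truth run uses a much
tighter periodicity tolerance ($10^{-4}$) than the forward default: a
twin's reference orbit must be converged well below the calibration gate,
or its own residual transient masquerades as measurement error.

Twin experiments (`run_twin_experiment()`) exercise the full pipeline and
compare every identified parameter with its generating value. Two
findings from the noiseless twin are worth stating because they bound
what passing tests show about real data:

* At 30 flow samples per cycle, a cubic spline under-estimates the peak
  flow derivative at the aortic valve-opening kink by roughly 10 %.
  Through the maximum-pressure-rate term of the windkessel objective this
  biases the systemic $C_{ar}$ (≈ −9 %) and $Z_{ar}$ (≈ +7 %) even with
  noise-free data — an irreducible property of the clinical sampling, not
  of the optimizer. The pulmonary side, whose regurgitant flow is smooth,
  recovers to 0.2 %.
* That propagated bias floors the closed-loop volume objective near
  0.5 ml^2, below which the weakly identifiable atrial rate parameters
  cannot be pinned down; ventricular active-stress parameters still
  recover to ~1 %, and with the generating circulation parameters all 12
  active-stress parameters recover within 5 %.

The valve-replacement workflow (`predict_replacement_outcome()`) seals
the pulmonary valve ($A_{eff,min}\to 0$, everything else unaltered), runs
from the preoperative state to a new periodic state, and reports pre/post
clinical metric tables and the cycle-by-cycle transient. On the default
scenario the prediction shows the expected response: pulmonary
regurgitation abolished, right-ventricular volumes reduced, left-sided
volumes and cardiac output increased.

# Numerical choices at a glance

| Quantity | Default | Why |
|---|---|---|
| $\theta$ | 0.5 | second order on smooth segments |
| $dt$ | $10^{-3}$ s | 750 steps per cycle resolve valve events |
| Newton tolerance | $10^{-8}$ (scaled) | residual contract used by the adjoint |
| $\epsilon_{cycl}$ | 0.04 | published periodicity gate |
| $K$ | 10 | published activation regularization |
| $N_f$ | 15 | published evaluations between periodicity checks |
| area floor | $10^{-4}$ mm^2 | finite Jacobian for sealed valves |
| $\Delta p = 0$ | closing branch | as printed in the valve law |

Problem sizes used in the shipped tests: single cycles at $dt = 10^{-3}$,
twin experiments with one scenario and a few hundred optimizer
evaluations, and oracle checks on sub-second scalar integrations.

# Known limitations

* The chamber surrogate has no regional mechanics, fiber fields, or
  pericardial boundary identification; stress/strain output is out of
  scope, as is growth and remodelling (predictions are short-term).
* The effective lengths printed for the clinical case are inconsistent
  with the stated "three times the orifice diameter" rule for all valves
  except the tricuspid; `l_eff` is therefore an explicit parameter and
  the rule is not hard-coded.
* Identification quality is bounded by the clinical sampling rates, as
  quantified above; parameters whose signatures are blurred by the flow
  spline (systemic $C_{ar}$, $Z_{ar}$) or barely expressed in 25-point
  volume curves (atrial rates) carry correspondingly larger errors.
* The printed pulmonary parameter labels of the clinical case carry
  "sys" superscripts; they are treated as typos for pulmonary values.
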