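---
title: "A Doppler-driven lumped-parameter model of the left heart: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Doppler-driven lumped-parameter model of the left heart: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiolpm)
```

## The model

`cardiolpm` simulates the left heart and its loading circulation as a 0-D
(lumped-parameter) electrical-analogue circuit, driven entirely by
quantities measurable with Doppler echocardiography and an arm cuff.  The
state comprises two chamber volumes (LV, LA), four capacitor pressures
(aortic, systemic-arterial, pulmonary-arterial, pulmonary-venous), and six
inductor flows (four valve branches and two pulmonary lines) — twelve ODEs
in all.

**Chambers.** LV and LA couple pressure to volume through a time-varying
elastance `P(t) = E(t) (V(t) - V0)`.  `E(t)` is a double-Hill product: an
ascending Hill term models contraction, a descending one relaxation,

$$E(t) = N\,\frac{(t/\tau_1)^{m_1}}{1+(t/\tau_1)^{m_1}}\cdot
         \frac{1}{1+(t/\tau_2)^{m_2}} + E_{\min},
  \qquad N = \tfrac12 (E_{\max}-E_{\min}),$$

with $\tau_i$ fixed fractions of the cycle length `T` so one parameter set
serves any heart rate.  Defaults: LV `E_max` 2.1, `E_min` 0.06 mmHg/mL,
`m1` 1.32, `m2` 27.4, `tau1` 0.269 T, `tau2` 0.452 T; LA `E_max` 0.17,
`m2` 13.1, `tau1` 0.110 T, `tau2` 0.18 T.

*Atrial phase.* The parameter tables place both activations at `t = 0`,
which cannot be literally right: atrial contraction must precede LV
isovolumic contraction.  We evaluate the LA elastance on a time axis
shifted by `la_phase_frac * T` (default 0.85), placing the atrial kick in
late diastole, just before the cycle wraps.  The default produces a
distinct A wave after the E wave in the transmitral flow; it is a
configurable convention, not a measured quantity.

**Valves.** Each valve is a nonlinear branch with the net-pressure-gradient
formulation: `PG = L dQ/dt + B Q|Q|`, where for the aortic-side branches
`L = 2*pi*rho/sqrt(E_L_Co)` and `B = rho/(2 E_L_Co^2)` with the energy loss
coefficient `E_L_Co = EOA*A/(A - EOA)` (pressure-recovery-corrected
effective area), and for the mitral-side branches `L = M_MV/EOA`,
`B = rho/(2 EOA^2)` with the constant mitral inertance `M_MV = 0.53`
g/cm^2^.  These coefficients are evaluated in CGS and converted with
1 mmHg = 1333.22 dyn/cm^2^; the package otherwise works throughout in
clinical units (mmHg, mL, s, cm).  Regurgitant branches (AR, MR) are
present only when a regurgitant orifice area is recorded.

*Gating.* Each branch is an ideal diode in orientation: it integrates its
momentum equation while `Q > 0` or its forward pressure difference is
positive, and otherwise relaxes its flow to zero with a 1 ms time
constant.  This keeps the right-hand side Lipschitz (no event location
needed); residual reverse flow is below 10^-3^ mL/s for one step and is
clamped to zero in the reported waveforms.

**Circulation.** The pulmonary source is a rectified sine of duration
`t_ee` (taken as the measured systolic ejection time) and amplitude
`Q_MPV`, delivering `2 Q_MPV t_ee / pi` mL per beat; it abstracts the
right heart, and `Q_MPV` is the first fitted parameter.  The venous return
node is clamped at `P_CV0 = 4` mmHg.  The full netlist (each named element
used exactly once) is printed by `netlist()`:

```{r netlist}
rec <- healthy_patient_record()
model <- lpm_model(circulation_params(), build_patient_valves(rec), rec)
writeLines(netlist(model))
```

Two placements were genuinely open.  (1) `R_PA` and `R_PVC` are paired
with their compliances as series (viscoelastic) resistances, which uses
each element once in its named position.  (2) The systemic compliance
`C_SAC` is placed *between* `R_pda` and `R_SA` — the standard windkessel
reading, compliance proximal to the arteriolar resistance — rather than at
the `R_SA`/`R_SV` junction.  The junction variant hides `C_SAC` behind the
full arteriolar resistance, making it (and hence the total arterial
compliance) essentially invisible to the brachial pressures the estimation
stage fits; the windkessel placement is both the physiological convention
and measurably better identified.  See "Known limitations" — even with
this placement the compliance *split* remains weakly identified.

## Numerics

The production integrator is classical fixed-step RK4 in C++ with step
`dt = 1e-4` s (the model's reference initial step).  The assembled system
is only mildly stiff — the fastest time constant is `L_PC/R_PC` ≈ 1.4 ms,
an order of magnitude above the step — and the dominant non-smoothness is
valve switching, which a small fixed step resolves robustly and, equally
important, bit-reproducibly: repeated runs and refits are exactly
deterministic.  An identical right-hand side is exposed in R
(`assemble_rhs()`, deSolve-compatible); the test suite checks the two
implementations against each other at random states (agreement to
machine precision) and checks whole-cycle trajectories against
`deSolve::ode(method = "rk4")`.

Integration starts from zeroed capacitor pressures and inductor flows and
proceeds cycle by cycle until the relative L-infinity change of the
cycle-start state falls below `steady_tol` (default 1e-6; the healthy
baseline converges in ~150 cycles, so `max_cycles` defaults to 200 with
headroom).  Non-convergence is a flagged state carried through the
results, not an exception.  Optimizer loops warm-start each steady solve
from the previous end state, which preserves the periodicity criterion
while cutting fit times by an order of magnitude.

## Patient-specific estimation

Inputs per patient: forward LVOT stroke volume, `T`, `T_EJ`, valve
effective orifice areas (mitral optionally as an ellipse from two apical
diameters), LVOT and ascending-aorta diameters with their VTIs, EDV/ESV,
and cuff SBP/DBP.  The estimation runs in two sequential response
optimizations with tolerance 1e-6:

1. **Flow.** `Q_MPV` is fitted so the model's forward aortic-valve volume
   matches the measured forward LVOT stroke volume.  The map is monotone;
   the solve is a bracketed scalar root find seeded at the analytic value
   `pi*SV/(2 t_ee)`, which for non-regurgitant circuits is already within
   0.1% (mass conservation makes the delivered volume nearly
   parameter-independent).
2. **Pressures.** `(R_SA, C_SAC, C_ao)` are fitted by bounded
   Levenberg-Marquardt so the steady aortic pressure extrema equal
   SBP/DBP.  `R_SA` is seeded from the measured total systemic resistance
   `TSR = MAP/CO` (MAP as `DBP + PP/3`, venous pressure neglected) minus
   the fixed series resistances; the compliances start at their reference
   initial values (0.5 and 2 mL/mmHg).  The finite-difference step is set
   to `epsfcn = 1e-6` so parameter perturbations stay well above the
   steady-solver's ~1e-4 mmHg reproducibility floor.  Success means both
   pressure residuals within 1 mmHg.

When a regurgitant branch is present the two stages couple — the
recirculating volume depends on the diastolic pressures — so `fit_patient()`
repeats the stage pair once if the verification solve misses either target.
Patients without regurgitation complete in a single pass.  Before the fits,
`R_ub` is tuned once (and then held) so the upper body carries 15% of
systemic flow in the healthy baseline.  After the fits, the unloaded LV
volume is shifted by the end-diastolic mismatch
(`V0' = V0 + EDV_meas - EDV_sim`) and the model re-solved once; because the
dynamics depend on `V - V0` only, this anchors the P-V loop to the measured
EDV without disturbing pressures or flows.

## Metrics

Ejection fraction `(EDV-ESV)/EDV` (reduced below 0.41); LV stroke work as
the shoelace area of the P-V loop (1 mmHg·mL = 1.33322e-4 J; a second
trapezoidal contour oracle agrees to 1e-9); systemic arterial compliance
as `SV/(SBP-DBP)` — the formula is a documented package convention (the
standard stroke-volume-to-pulse-pressure estimator), reported unindexed in
mL/mmHg with body-surface-area indexing left to the caller, and flagged low
at or below 1 mL/mmHg.  E/A ratio from transmitral velocity `Q_MV/EOA_MV`:
the two largest diastolic local maxima separated by at least `0.05 T`,
earlier peak = E; a fused A wave yields an explicit undefined-ratio flag.
Transvalvular gradients are phase-restricted (transmitral `P_LA - P_LV`
maximum over diastole, aortic `P_LV - P_ao` maximum over systole), the mean
aortic gradient is the ejection-phase time average (severe stenosis above
40 mmHg), and a Doppler-style `4 v^2` transmitral estimate is reported
alongside.  TAWSS is the trapezoidal cycle average of a supplied wall-shear
series (normal LV band 0.2-1.2 Pa), and the vortex sphericity index is the
supplied length/width ratio (normal above 2): both operate on supplied
series/dimensions — this package contains no 3-D flow solver.

## Tissue kernels and the modulus surrogate

The solid-mechanics module provides pointwise St. Venant-Kirchhoff kernels:
Lame constants from `(E, nu)`; Green-Lagrange strain
`E = (F^T F - I)/2` under the convention `F = I + (grad u)^T` (note many
texts transpose this; the `F`-form is convention-invariant); the second
Piola-Kirchhoff stress `Sigma = lambda tr(E) I + 2 mu E`; the Cauchy
push-forward `sigma = F Sigma F^T / det F`; and the Robin pressure-boundary
coefficients `h_s = dt sqrt((lambda+2mu)/rho_s)`,
`alpha = rho_s h_s / rho_fluid` used by added-mass interface schemes.

Young's-modulus calibration against the LV diastolic P-V limb is performed
on a declared surrogate: a thin-walled spherical SVK shell (equibiaxial
membrane, plane stress, Laplace relation), for which
`P(V) = (h C_ps / R_0)(lambda^2-1)/lambda` with `lambda = (V/V_0)^{1/3}`
and `C_ps` the plane-stress biaxial modulus.  Pressure is linear in the
modulus, so the least-squares interpolation is closed-form; the bracket is
still checked and a sign-homogeneous bracket is an error.  The surrogate
exists so the calibration *procedure* is testable at desk scale; it is not
a replacement for a 3-D solid model, and the interface accepts any
pressure-volume functional a finer model might supply.  `nu` (default 0.4)
and `rho_s` (default 1050 kg/m^3^) are exposed configuration — no values
are fixed by measurement here.

## The synthetic cohort

`generate_cohort()` emulates the measurement process: it samples a
ground-truth circuit — heart rate 50-90/min, ejection fraction of the
cycle 0.28-0.38, target stroke volume 40-100 mL, `EOA_AV` 0.6-2.5 cm^2^,
mitral orifice 2.5-5 cm^2^, free parameters log-uniform within ±50% of
their reference initial values, `Q_MPV` set analytically to the sampled
stroke volume, regurgitant orifices present with probability 0.15 per
valve on 0.05-0.4 cm^2^ — forward-simulates it to periodic steady state,
and reads the record back out as a sonographer would: stroke volume from
the simulated forward aortic volume, SBP/DBP from the simulated pressure
extrema, EDV/ESV from the simulated loop, VTIs consistent with the
continuity relations.  Optional multiplicative noise on volumes and
additive noise on pressures models measurement error.  Draws that fail
steady convergence or produce degenerate records (pulse pressure below
15 mmHg, SBP above 260 mmHg) are resampled with a bounded retry budget;
the wide pressure guard is deliberate, because truth draws centred on the
*optimizer-seed* values produce lower diastolic pressures than a treated
clinical population.

What the cohort does *not* emulate: real measurement error structure
(correlated, operator-dependent), pathophysiological co-variation between
valve areas and chamber function, heart-rate variability within a
recording, and any attempt to match a specific patient population.
Passing recovery tests therefore demonstrates that the estimation
pipeline inverts the model's own measurement map — a necessary
correctness property — not that it is accurate on clinical data.

## Problem sizes

Default runs use 0.1 ms integration steps (10,000 per cycle at 60/min),
500 output samples per cycle, up to 200 cycles to steady state, and
20-patient recovery cohorts; these sizes are the package's reference
experiment and complete in minutes on one core.

## Known limitations

* **Compliance split is weakly identified.**  The pressure-fit data are
  two numbers (SBP, DBP).  At the fitted point the measured Jacobian gives
  `dPP/dC_ao ≈ -21` and `dPP/dC_SAC ≈ -4.4` mmHg per mL/mmHg: distal
  compliance is ~5x less effective because the fixed resistances
  `R_ao = R_pda = 0.05` separate the two nodes.  Consequently a
  one-dimensional family of `(R_SA, C_SAC, C_ao)` triples reproduces any
  target pair exactly, and along it the *total* `C_ao + C_SAC` varies
  (about 0.78 mL/mmHg per mL/mmHg of split shift).  The optimizer
  therefore leaves `C_SAC` at its initial value and recovers the total
  only to ~13% (median, noise-free n=20) — a property of the estimation
  problem itself, not of the optimizer; recovering totals to a few percent
  would require fitting waveform shape, which the estimation procedure
  deliberately does not use.  `Q_MPV`, `R_SA` and the reproduced pulse
  pressure are recovered essentially exactly.
* The right heart is a prescribed source; venous return is a fixed
  pressure; there is no baroreflex and no respiratory modulation.
* Chambers are single-compartment; no regional wall mechanics.
* The solid module is pointwise kernels plus a spherical surrogate; no
  mesh-based solid or FSI solve.
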