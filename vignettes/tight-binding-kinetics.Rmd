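---
title: "Models and methods: tight-binding kinetics of PP2A-B55 sequestration"
author: "b55kin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: tight-binding kinetics of PP2A-B55 sequestration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b55kin)
```

## The biological model

At M-phase exit the phosphatase PP2A-B55 must dephosphorylate the CDK1
substrates that define the mitotic state, but during M phase it is held
inactive by Greatwall-phosphorylated Endosulfine (pEndos). The
mechanism modelled here — *inhibition by unfair competition* — rests on
two numbers: pEndos binds the PP2A-B55 active site with a Michaelis
constant around 1 nM (five orders of magnitude below the Km of the
mitotic reporter substrates), and is turned over with a kcat of only a
few hundredths per second. A slow, tight substrate of this kind
sequesters essentially the whole enzyme pool whenever it is present in
stoichiometric excess, and is consumed — automatically relieving the
inhibition — as soon as its kinase switches off.

All internal computation is in nM and seconds; `uM_to_nM()` and
`per_min_to_per_s()` convert at the interface.

## Tight-binding algebra

Because the assays are run with enzyme concentrations comparable to the
pEndos Km, the classic assumption that free and total substrate
coincide fails. Mass conservation plus the quasi-steady state of the
complex give the quadratic

$$[NP]^2 - (N_T + P_T + K_m)\,[NP] + N_T P_T = 0,$$

whose smaller root is the physical complex concentration
(`bound_complex()`); multiplying by kcat yields the Morrison velocity.
The root is evaluated in conjugate form
$2 N_T P_T / (s + \sqrt{s^2 - 4 N_T P_T})$ with $s = N_T + P_T + K_m$,
which avoids catastrophic cancellation when $4 N_T P_T \ll s^2$; zero
concentrations return exact zeros instead of solving a degenerate
quadratic. Ignoring tight binding on such data biases Km upward, which
is why the classic Michaelis–Menten fit is offered only as a comparison
model in `fit_velocity_curve()`.

The total-QSSA pair (`tqssa_free_pair()`) solves
$[N] = N_T/(1+[P]/K_m)$ and $[P] = P_T/(1+[N]/K_m)$ simultaneously —
both relations imply the same complex, so the solution reuses the same
quadratic and remains valid when enzyme and substrate totals are
comparable, the regime of deep sequestration.

For the okadaic-acid competition system,
`free_concentrations_competitive()` solves the three coupled relations
for free substrate, competitor and enzyme under the substrate-excess
approximation $[N] \approx N_T$, which collapses them to

$$a[P]^2 + (a K_{dO} + O_T - P_T)[P] - P_T K_{dO} = 0,
\qquad a = 1 + N_T/K_m .$$

The function enforces $N_T \ge 100\,P_T$. The approximation's relative
error in $[P]$ is of order $P_T/N_T$ — up to about 1% at that boundary,
and 0.1% only when the excess reaches a thousandfold — which is why the
tests assert the scaling rather than a single flat tolerance. The
positive root is again evaluated in a cancellation-safe form; the
printed closed form circulating for this system suffers from flattened
typography, so the implementation was derived from the coupled
relations and verified against fixed-point iteration.

## Fitting

All fitters assume *identically distributed fractional errors*:
residuals are $(y_{obs} - y_{mod})/\max(y_{mod}, 10^{-12})$, with the
model value re-evaluated at every iterate. This is a continuous form of
iteratively reweighted least squares with weights $\propto 1/y^2$, and
matches a multiplicative error model. Whether the original analyses
weighted by observed or modelled values is not documentable; weighting
by the model is the default here because it does not reward downweighted
outliers, and the observed-weight variant would differ only at second
order in the noise. Parameters are optimised on the log scale
(positivity without hard bounds) with Levenberg–Marquardt
(`minpack.lm::nls.lm`, ftol = ptol = 1e-12, max 500 iterations);
standard errors come from a central-difference Jacobian of the residual
vector at the optimum, scaled to the natural scale by the delta method.
Starting values: kcat from $\max(v)/P_T$, Km from the interpolated
half-saturation point (velocity fits); the zero-dose release (competition
fits). All-zero observations raise a degenerate-data error rather than
returning a spurious fit.

The okadaic-acid competition method exists because direct velocity
titrations at sub-nanomolar Km require enzyme and substrate
concentrations at the edge of detectability. Competing a fixed, easily
measured amount of pEndos dephosphorylation against a competitor of
known affinity (KdO = 30 nM, fixed and never co-fitted) moves the
information into the dose axis. `predict_release()` integrates
$dN_T/dt = -k_{cat} N_T [P]/K_m$ with `deSolve::lsoda`
(rtol 1e-8, atol 1e-12 nM), stacking all doses into one vector ODE; the
released fraction is $1 - N_T(t_{end})/N_T(0)$, so mass balance is
exact by construction. The synthetic design uses doses of 0 and
30–30000 nM (log-spaced): the half-competition dose sits near
$K_{dO} N_T/K_m$, a few μM for sub-nanomolar Km, and the doses must
bracket it for the fit to be well conditioned.

The automatic-reset fit is two-stage, mirroring the structure of the
experiment: the no-pEndos control identifies the reporter efficiency
`eff_C` (kcat/Km, μM⁻¹s⁻¹ — the reporter sits far below its own Km, so
only the second-order efficiency is identifiable) and the enzyme decay
rate `kdeg` from the closed form
$[^{32}P](t) = \mathrm{eff}_C\, pC_T P_T(0)(1-e^{-k_{deg}t})/k_{deg}$;
the inhibited course is then fit for (Km, kcat) with those fixed.
Decay onset is 0 in controls and 1500 s in inhibited samples by
default (configurable): the data behind the model show enzyme emerging
from sequestration more active than the decayed control, as if binding
were protective, and the asymmetry has little effect on the estimates.
`deg_onset` is not fitted by default. The lag statistic is defined on
model trajectories — the first time the inhibited sample's
instantaneous reporter rate reaches 50% of the control's at the same
time, by linear interpolation — rather than on finite differences of
noisy data.

Dose-response curves for tight-binding inhibitors use the Morrison
free-enzyme fraction with an apparent Kd as shape parameter (a logistic
with fitted Hill slope serves for weak inhibitors); the IC50 is read
off the fitted curve, never the nearest measured dose, and converted to
a true dissociation constant by the standard tight-binding competitive
correction $K_d = (IC_{50} - P_T/2)/(1 + S/K_m^S)$. With the measured
inputs (IC50 197 pM, 0.125 nM enzyme, 5 μM substrate, Km 85 μM) this
yields 0.127 nM, conventionally rounded to 0.12 nM; the package reports
the unrounded value. Inverse-variance pooling
(`pool_experiments()`) combines independent experiments:
$\hat\theta = \sum w_i\theta_i/\sum w_i$, $w_i = 1/SE_i^2$, pooled SE
$(\sum w_i)^{-1/2}$.

## M-phase-exit simulations

`simulate_tqssa()` integrates the one- or two-enzyme total-QSSA system;
with a second phosphatase PPX the free-substrate concentration is the
root of a cubic, found by `uniroot` at tolerance 1e-13 on the bracket
$[0, N_T]$ (the function is monotone, so the root is unique). The 50%
free-enzyme crossing is located by the integrator's root detection
(lsodar) rather than post-hoc grid interpolation. Default horizons are
600 s for substrate scenarios and 20000 s for the dead-end scenario,
with 6000 output points — dense enough that even the fallback
interpolation would resolve the crossing to well under a second.

The explicit mass-action cross-check (`simulate_mass_action()`)
integrates free substrate, free enzyme and complex from fully unbound
initial conditions. The dissociation rate follows the Briggs–Haldane
convention $k_{off} = k_{on}K_m - k_{cat}$ in substrate mode (with
$k_{on} = 0.057$ nM⁻¹s⁻¹ this gives 0.007 s⁻¹, matching the measured
pair) and $k_{off} = k_{on}K_d$ in dead-end mode; a nonpositive
Briggs–Haldane koff raises an error rather than silently switching
conventions. PPX, whose Km (85 μM) dwarfs every concentration in the
system, enters as the equivalent Michaelis flux in both simulators.

Two diagnostics qualify the tQSSA (`tqssa_validity()`). The
perturbation parameter is reported in two readings — with the enzyme
total in the numerator (dimensionless, $1.4\times10^{-4}$ for the
canonical scenario) and without it (per-nM, $5.6\times10^{-7}$) —
because its printed form is ambiguous about the factor; both are far
below the 1e-2 threshold, so the conclusion is insensitive to the
reading. The initial transient lasts
$t_c = 1/\{k_{on}(N_T(0)+K_m)\} \approx 0.02$ s, during which the two
simulators necessarily disagree (the tQSSA has the complex pre-formed
at $t=0$).

On the question of *how well* the two simulators agree afterwards: the
appropriate metric is the sup-norm of the difference between the
fraction curves, which is what "visually indistinguishable" means and
what the tests assert (< 1%). A *relative* comparison of the
phospho-fraction is not meaningful over a full horizon, because the
tQSSA decay rate carries a relative error equal to the validity
parameter (≈ 0.35% late in the single-enzyme scenario) that compounds
over the ~13 e-folds by which the substrate decays — producing large
relative deviations at concentrations around $10^{-13}$ of input, far
below anything an assay resolves. The tests therefore additionally
assert relative agreement only while the phospho-fraction is above 1%
of input.

`fractional_velocities()` splits the instantaneous dephosphorylation
flux between the two enzymes; the fractions sum to one by construction,
and collapse onto PP2A-B55 once total pEndos falls below the enzyme
pool — the algebraic form of the claim that a secondary anti-Endos
phosphatase cannot touch the sequestered reserve.

## Synthetic data: what it does and does not emulate

The generators reproduce the three assay *designs*: a velocity
titration at 0.5 nM enzyme over a 1–1100 nM substrate grid; a
competition curve at 50 nM substrate, 0.25 nM enzyme and a 600 s
incubation (kept below 20% conversion — the generator refuses designs
that violate this, and the velocity generator warns); and paired
two-hour reset time courses at ten-minute spacing. Noise is
multiplicative Gaussian truncated at zero (cv 0.10, 3 replicates by
default), the simplest model consistent with identically distributed
fractional errors; a lognormal option exists. Generators are pure
functions of (truth, design, seed) and restore the global RNG state.

They do *not* simulate scintillation-counting statistics, background
subtraction, TCA-extraction efficiency, pipetting drift or any
systematic error. Passing recovery tests therefore demonstrates that
the estimation machinery is correct and well conditioned under the
stated error model — not that real assays are free of systematic bias.

Simulation sizes used by the test suite were chosen to characterise the
estimators while keeping the default run fast: 50 seeded draws for the
Monte-Carlo recovery and method-comparison properties, 30 per noise
level for the consistency sweep, and 6000-point output grids for the
ODE comparisons.

## Known limitations

* The competition model treats okadaic acid as a rapidly equilibrating
  dead-end ligand; slow-onset (two-step) inhibitor binding is out of
  scope.
* The exit scenarios hold total phosphatase constant and exclude
  Greatwall kinase dynamics, cyclin degradation and the rest of the
  mitotic oscillator; they describe desequestration only.
* Error models with additive components, global fits across
  substrates, and stochastic (Gillespie) simulation are not provided.
* In dead-end mode the reset and exit models force kcat to zero
  exactly; a residual slow turnover of thiophosphorylated Endosulfine,
  if any, is not represented.
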