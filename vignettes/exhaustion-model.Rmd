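---
title: "An exhaustion-enhanced Hill-type muscle model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An exhaustion-enhanced Hill-type muscle model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hillphos)
```

## The model

`hillphos` simulates an isometric muscle–tendon unit (MTU) whose classical
Hill-type excitation–contraction dynamics are coupled to a minimal model of
ATP phosphate kinetics. The macroscopic structure is the usual four-element
arrangement: a contractile element (CE) in parallel with a passive elastic
element (PEE), in series with a tendon spring (SEE) in parallel with a
serial damper (SDE). With the MTU length $\ell_{MTU}$ held fixed, the state
of the coupled system is

* $\gamma \in [0,1]$ — normalized free-calcium concentration, driven by the
  neural stimulation $u(t)$ through first-order Hatze-type dynamics
  $\dot\gamma = m\,(u - \gamma)$;
* $\ell_{CE}$ — CE length, advanced by the contraction dynamics (the CE
  velocity that balances the four element forces);
* $[\mathrm{P_i}]$ — free inorganic phosphate, advanced by the
  hydrolysis/condensation ODE described below.

Calcium sets the troponin activity through a length-modulated sigmoid

$$\tilde q(\gamma, \tilde\ell_{CE}) =
  \frac{q_{\min} + (\rho(\tilde\ell_{CE})\,\gamma)^{\nu}}
       {1 + (\rho(\tilde\ell_{CE})\,\gamma)^{\nu}},
  \qquad \rho(\tilde\ell) = \varpi_{opt}\,\tilde\ell^{\,3},$$

bounded in $[q_{\min}, 1)$: $\tilde q$ is the fraction of cleared active
sites on actin. What actually scales the force-generating cross-bridge
population is the *muscle activity*

$$\tilde a = \tilde q \cdot \tilde\mu_{ATP},$$

where $\tilde\mu_{ATP}$ is the relative chemical potential of ATP. This
single discount factor is the exhaustion mechanism: as phosphate
accumulates, $\tilde\mu_{ATP}$ falls and the same troponin activity
produces less force.

### Phosphate kinetics

The cross-bridge cycle consumes ATP; its hydrolysis/condensation balance is
collapsed into one pseudo-first-order reaction with equilibrium constant
$K_{ATP} = k_{con}/k_{hyd}$. The free phosphate evolves as

$$\frac{d[\mathrm{P_i}]}{dt} =
  k_{hyd}\,[\mathrm{ATP}] - k_{con}\,[\mathrm{ADP}]\,[\mathrm{P_i}]/c_0,$$

with concentrations in mM and the standard concentration $c_0$ = 1 M
normalizing the second-order term so that both rate constants carry units
of 1/s. The hydrolysis rate constant scales with activity and inversely
with fiber length,

$$k_{hyd} = \hat k_{hyd}\,\tilde q / \tilde\ell_{CE},$$

so a resting fiber ($\tilde q = q_{\min}$) still turns over ATP at about
1% of the maximal rate, and a stretched fiber hydrolyses more slowly per
myosin head. $\hat k_{hyd}$ is the only free kinetic parameter; the other
metabolic constants (pools, equilibrium constants, $k_{con}$) are fixed
literature values exposed through `metabolic_constants()`.

The remaining metabolites are *algebraic* functions of $[\mathrm{P_i}]$:
creatine kinase (CK) and adenylate kinase (AdK) are fast relative to the
contraction time scale, so after every integrator step the state is
projected onto the manifold defined by

* $K_{CK} = [\mathrm{ATP}][\mathrm{Cr}] /
  ([\mathrm{ADP}][\mathrm{PCr}]) = 200$,
* $K_{AdK} = [\mathrm{ATP}][\mathrm{AMP}]/[\mathrm{ADP}]^2 = 1$,
* adenine conservation $[\mathrm{ATP}]+[\mathrm{ADP}]+[\mathrm{AMP}] =
  c_{ad} = 7$ mM,
* creatine conservation $[\mathrm{PCr}]+[\mathrm{Cr}] = c_{cr} = 25$ mM,
* phosphate conservation (see below) with $c_{ph} = 46$ mM.

In practice the projection is a one-dimensional root-find in
$[\mathrm{ADP}]$ (`equilibrate_pools()`), solved by a safeguarded Newton
iteration with analytic derivatives; the residual is strictly monotone so
the root is unique. Because the pools are enforced exactly at every
evaluation, conservation holds to $10^{-9}$ mM along entire trajectories —
this is a differential-algebraic formulation by construction rather than by
drift correction.

**Phosphate accounting.** The default counts the phosphate bound in
nucleotides, $c_{ph} = [\mathrm{P_i}] + [\mathrm{PCr}] + 3[\mathrm{ATP}] +
2[\mathrm{ADP}] + [\mathrm{AMP}]$, which puts the resting free phosphate at
a physiologically plausible 5.6 mM; a "free-only" accounting
($c_{ph} = [\mathrm{P_i}] + [\mathrm{PCr}]$) is available as a
configuration alternative (it moves resting $[\mathrm{P_i}]$ to 26.6 mM
and weakens the simulated decay).

### The chemical potential

$$\tilde\mu_{ATP} = \frac{-\Delta G^0_{ATP} +
   R\,T\,\ln\!\big([\mathrm{ATP}]\,c_0/([\mathrm{ADP}][\mathrm{P_i}])\big)}
  {\mu_{ATP,\max}}, \qquad \mu_{ATP,\max} \approx 60\ \mathrm{kJ/mol}.$$

By default $\Delta G^0_{ATP}$ is *calibrated at construction time* so that
$\tilde\mu_{ATP} = 1$ exactly in the resting equilibrated state; this keeps
$F_{\max}$ interpretable as the force of a fresh fiber at optimal length.
The calibrated value, $-29.5$ kJ/mol at 39 °C, lands close to the textbook
standard free energy of ATP hydrolysis ($\approx -30.5$ kJ/mol), which we
take as a consistency check of the accounting; a fixed-value mode is
available. Because the potential depends only on the concentration *ratio*,
the calibration makes the choice of $c_0$ immaterial for the dynamics.

### The ATP floor

A hard floor $[\mathrm{ATP}]_{\min} = 1.2$ mM is part of the metabolic
constant set. A subtlety discovered during implementation: on the physical
branch of the AdK equilibrium (the root with
$[\mathrm{ATP}] \ge [\mathrm{AMP}]$), ATP cannot drop below
$c_{ad}\sqrt{K_{AdK}}/(1+2\sqrt{K_{AdK}}) = 2.33$ mM — the adenine
quadratic pinches before the nominal floor is reached. The clamp therefore
binds at whichever is larger: the nominal floor or the branch minimum
(inset by $10^{-3}$ relatively, for conditioning of the projection
Jacobian). While the clamp binds, the hydrolysis flux is zeroed and a flag
is raised; condensation then pulls the state back off the boundary.

### Contraction dynamics

CE force is Hill's hyperbola on the concentric branch, with
activity-scaled constants $A_{rel} = A_{rel,0}\,L_A(\tilde\ell)\,Q_A(a)$,
$B_{rel} = B_{rel,0}\,Q_B(a)$, where $Q_A = (1+3a)/4$ and $Q_B = (3+4a)/7$
(the van Soest convention used throughout this model family; both can be
switched off), and $L_A$ is 1 on the ascending limb and the force–length
value on the descending limb. The eccentric branch is the mirrored
hyperbola constructed so that force is continuous at $v_{CE} = 0$, the
slope ratio there is $S_e$, and the force saturates at
$F_e\,a\,\tilde F_{isom}\,F_{\max}$.

At each instant the CE velocity solves
$F_{SEE} + d_{SE}(\dot\ell_{MTU} - v_{CE}) = F_{CE}(v_{CE}) + F_{PEE}$.
The damper coefficient $d_{SE}$ is evaluated at the *isometric* CE + PEE
force, which keeps the damping force linear in $v_{CE}$ and the balance a
quadratic per branch; the analytic root is validated against the balance
residual ($< 10^{-9} F_{\max}$) with a bracketed bisection fallback.
Branch choice is by the sign of the residual at $v_{CE} = 0$, preferring
the concentric branch at exact ties.

## Parameters

The 24 MTU parameters (units and meaning in `?mtu_params`) ship as four
fitted presets for rabbit gastrocnemius (GAS) and plantaris (PLA)
preparations: `GAS_plus`/`PLA_plus` include phosphate kinetics
($\hat k_{hyd}$ = 1.45 and 2.27 1/s), `GAS_minus`/`PLA_minus` are the
classical variants without it. `mtu_bounds()` returns the per-muscle
estimation hyperrectangle used by `mtu_fit()`. Three defaults deserve
comment:

* `gamma_rho = 3` — the exponent of the length dependence of the calcium
  sensitivity, $\rho \propto \tilde\ell^{\,3}$. This is Hatze's classical
  cubic scaling; it affects only the length coupling of activation, not the
  sigmoid shape, and is exposed as a constructor argument.
* `temperature = 312.15` K (39 °C), matching the heated preparation the
  presets were fitted to; the rate constants themselves carry no
  temperature dependence.
* Serial damping follows
  $d_{SE} = D_{SDE}\,\frac{F_{\max} A_{rel,0}}{\ell_{CE,opt} B_{rel,0}}
  \big((1-R_{SDE})\,F/F_{\max} + R_{SDE}\big)$ — force-independent when
  $R_{SDE} = 1$.

## Simulation and numerics

`mtu_simulate()` integrates the three-state system with `deSolve::lsoda`
(stiff-capable; the SEE/SDE subsystem has millisecond time constants),
relative tolerance $10^{-8}$ and per-state absolute tolerances
($10^{-10}$ for $\gamma$, $10^{-12}$ m for $\ell_{CE}$, $10^{-8}$ mM for
$[\mathrm{P_i}]$). Stimulation protocols are piecewise constant; the
integration is restarted at every protocol breakpoint so discontinuities in
$u$ never cross a solver step, and output is produced on the protocol's
sampling grid (1 kHz for the standard isometric protocol: 0.1 s rest,
0.7 s full stimulation, 0.4 s relaxation). Runs start from the passive
equilibrium ($\gamma = 0$, troponin activity $q_{\min}$) with metabolites
at rest. Halving the solver tolerance moves the peak force by well under
0.1%.

The integrator's right-hand side is a specialized closure
(`hillphos:::.make_model_fns`) with hoisted constants, an
analytic-derivative Newton for the pool projection (warm-started between
calls) and the per-branch quadratic for the CE velocity. It is
cross-checked against the public element-wise functions in the test suite;
the two routes agree to solver precision.

Degenerate inputs are handled deterministically: a passive equilibrium in
which both elastic elements can be slack returns the infimum of the slack
interval ($\ell_{MTU} - \ell_{SEE,0}$, the SEE just taut); integrator
trial states with non-positive phosphate are projected back to the domain
boundary; the activity is capped at 1 (the potential may exceed 1 when
hydrolysis is switched off and condensation raises the ratio above its
resting value — the model variant with $\hat k_{hyd} = 0$ shows exactly
this force overshoot).

## Estimation

`mtu_fit()` estimates any subset of the 24 parameters by bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) on the stacked force residuals
of all experiments of one muscle simultaneously. Two numerical choices
matter:

* the Jacobian finite-difference step is set through `epsfcn = 1e-6`
  (relative steps around $10^{-3}$), far above the ODE-solver noise floor —
  with the library default the Jacobian is dominated by integration noise
  and the optimizer stalls;
* optional multi-start uses a small seeded Latin hypercube inside the bound
  box of the free parameters; the reported optimum is the best final
  objective over starts, so it is never worse than the single-start answer,
  and it is reproducible per seed.

Residues are reported in the two conventions used for isometric-fit
comparisons: the least-squares residue scaled to 1000 data points,
$\sqrt{(1000/N)\sum r^2}$, and the mean absolute deviation per point.
`sensitivity_timecourse()` computes relative local sensitivities
$S_\theta(t) = \partial F(t)/\partial\theta \cdot \theta/F(t)$ by central
differences (default relative step $10^{-4}$, per-parameter override, zero
step freezing a row); exported matrices are clipped at magnitude 1 for
comparability, internal values are not.

## Exhaustion analyses

Under constant stimulation the force settles and then decays; the
*exhaustion time* is the first instant the force has fallen more than 5%
below its reference. Two reference conventions are provided, because runs
started from the passive equilibrium rise before they decay: the default
reference is the running maximum of the trace; the literal alternative
(force at $t = 0$) is meaningful when runs are started at their activated
steady state (`simulate_constant(..., init = "active")`, which solves the
active force balance at $\gamma = u$ with fresh metabolites). Both
initializations are implemented; the map and boundary functions default to
the passive start with the running-maximum reference. Long runs stop
integrating as soon as the criterion triggers (chunked integration with
state carry-over), which keeps 60 s horizons cheap.

`exhaustion_map()` scans an (MTU length × stimulation) grid;
`endurance_boundary()` bisects for the largest stimulation that never
exhausts within the horizon and reports that run's quasi-steady force.
The quasi-steady force is measured as the mean over the 0.58–0.68 s
window, the interval late in the standard stimulation phase where
near-steady conditions hold; `steady_decay_rate()` reports the
$F_{\max}$-normalized regression slope over the same window, and
`fit_kappa()` fits the scalar decay-rate scale $\kappa$ of the theoretical
relation $\dot F \propto -\tilde F_{isom}(\ell_{CE})\,
\ell_{CE,opt}/\ell_{CE}$ by its closed-form least-squares ratio.

### What the coupled model does and does not reproduce

The qualitative exhaustion phenomenology is robust in this implementation:
phosphate accumulates and the potential decays monotonically during
sustained stimulation; switching hydrolysis off removes the decay pathwise;
higher stimulation always shortens the exhaustion time; recovery follows
when stimulation ends. Two quantitative behaviors depend strongly on how
the potential's *rate* couples to fiber length, and this implementation —
which routes everything through the CK/AdK pool algebra above — is
conservative there: the sustained decay rate at full stimulation comes out
at roughly half of the $\kappa \approx 0.16$ 1/s scale that the fitted
presets suggest for the real preparations, and at MTU lengths beyond the
optimum the descending-limb force–length feedback outweighs the
$1/\tilde\ell_{CE}$ hydrolysis protection, so simulated exhaustion time
*decreases* with length there instead of increasing. Both behaviors are
measured honestly by the acceptance checks rather than patched; a stronger
direct length coupling in the potential's decay rate would be the natural
model extension.

## The synthetic-trace generator

The measured rabbit traces behind the presets are not available in
machine-readable form, so `generate_fixtures()` produces synthetic
stand-ins with the experimental layout: the GAS length series 114–120 and
128–132 mm (7 lengths), the PLA series 114–124 mm (6 lengths), 2 mm
increments, the standard 1.2 s / 1 kHz protocol, and i.i.d. Gaussian force
noise with $\sigma = 0.5$ N by default — the order of the per-point
absolute residues of isometric fits of this kind. The generator is
deterministic per seed. What it does *not* emulate: correlated measurement
noise, stimulation artifacts, trial-to-trial drift, or any model
misspecification — parameter-recovery results on these fixtures therefore
demonstrate the estimator's correctness and identifiability under the
model, not robustness to real-data pathologies.

## Problem sizes used in the checks

The shipped tests and the acceptance script run forward simulations of
1.2–1.9 s at 1 kHz output, constant-stimulation runs up to 60 s at 50–100
Hz output, a 5 × 5 length–stimulation map with a 60 s horizon, and a
single-parameter refit against seven noiseless 1.2 s traces; these sizes
exercise every code path while keeping a full run in the minutes range.

## Known limitations

* No pH, lactate, magnesium, reactive-oxygen or glycolytic-supply effects;
  no temperature or fiber-type dependence of the rate constants.
* No calcium-sensitivity modulation by accumulated phosphate (its absence
  is one reason the simulated early decay is conservative).
* Isometric focus: a prescribed MTU-length-rate hook exists internally but
  dynamic (shortening) protocols are untested territory, and parameters
  fitted from isometric data should be treated cautiously there.
* Pennation/gearing and history-dependent force enhancement are out of
  scope.
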