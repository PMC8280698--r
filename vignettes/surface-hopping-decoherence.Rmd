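---
title: "Decoherence-corrected surface hopping on model Hamiltonians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoherence-corrected surface hopping on model Hamiltonians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfhop)
```

## The problem

Fewest-switches surface hopping (FSSH) propagates an ensemble of classical
nuclear trajectories, each moving on a single Born--Oppenheimer (BO)
surface and carrying a coherently evolving electronic wavefunction
$\Psi = \sum_n C_n\,\Phi_n$.  Per nuclear step the coefficients obey

$$ i\,\dot C_n \;=\; \varepsilon_n C_n \;-\; i \sum_k
   \big(\dot{\mathbf R}\cdot \mathbf d_{nk}\big)\, C_k \;+\; i\,\xi_n, $$

with $\varepsilon_n$ the adiabatic energies, $\mathbf d_{nk} =
\langle u_n|\nabla_R u_k\rangle$ the nonadiabatic coupling vector (NACV),
and $\xi_n$ a decoherence contribution that is zero in plain FSSH.  Hops
from the active state $a$ to state $k$ fire with the fewest-switches
probability

$$ \zeta_{ak} = \max\!\left(0,\;
   \frac{2\,\Delta t\,(\dot{\mathbf R}\cdot\mathbf d_{ak})\,
   \mathrm{Re}\,\rho_{ak}}{\rho_{aa}}\right),
   \qquad \rho_{ak} = C_a^* C_k , $$

selected by the cumulative-window rule against a uniform draw.  Because
the coefficients stay in a coherent superposition while the nuclei commit
to one surface, plain FSSH is *overcoherent*: the fraction of
trajectories per state, $\Pi_k(t)$, drifts away from the mean electronic
population $\bar\rho_{kk}(t)$ ("internal inconsistency"), and this
package exists to quantify that failure and the three corrections that
repair it.

## The three decoherence corrections

**SHXF** (exact-factorization scheme).  Each trajectory carries one
auxiliary ("phantom") trajectory per populated nonactive surface.  The
decoherence term couples the *nuclear quantum momentum* to the
*accumulated force difference* between surfaces:

$$ \xi_n \;=\; \sum_\nu \frac{Q_\nu}{M_\nu}
   \Big( f_{n,\nu} - \sum_l |C_l|^2 f_{l,\nu} \Big)\, C_n ,
   \qquad
   Q_\nu = \frac{R_\nu - \sum_k |C_k|^2 R^{aux}_{k,\nu}}{2\sigma_\nu^2}, $$

where $f_{k}$ is the momentum change accumulated by the trajectory
moving on surface $k$ (the time integral of $-\nabla\varepsilon_k$) and
$\sigma$ is the width of a Gaussian ascribed to each trajectory.  The
term redistributes population without changing the norm (an algebraic
identity we verify to $10^{-14}$), vanishes when one state holds all
population or when the accumulated forces coincide, and pushes population
toward the state whose accumulated force aligns with $Q$ --- in practice,
the active state.  It also vanishes identically for parallel surfaces,
a known blind spot of the whole correction family.

**SHEDC** (energy-based damping).  Nonactive amplitudes decay as
$C_n \to C_n e^{-\Delta t/\tau_n}$ with

$$ \tau_n = \frac{\hbar}{|\varepsilon_n - \varepsilon_a|}
            \Big(1 + \frac{\alpha}{T}\Big), $$

$T$ the nuclear kinetic energy and $\alpha = 0.1\,$Ha by convention; the
active amplitude is rescaled so the total population stays 1.  The
correction acts on the coefficients (not the populations), and a zero
gap means no damping.

**A-FSSH** (stochastic collapse).  Position and momentum moments
$\delta R_n, \delta P_n$ of each nonactive surface are propagated with
the force difference $\delta F_n = -(\nabla\varepsilon_n -
\nabla\varepsilon_a)$ driving $\delta P$, in a velocity-Verlet step
matching the nuclear integrator.  Per step and nonactive state the
amplitude collapses to zero with probability $\Delta t/\tau_n$,

$$ \frac{1}{\tau_n} = \frac{\delta F_n\cdot\delta R_n}{2\hbar}
   \;-\; \frac{2}{\hbar}\,\big|(\varepsilon_n-\varepsilon_a)\,
   \mathbf d_{an}\cdot\delta R_n\big| , $$

with a companion reset rate $-\,\delta F_n\cdot\delta R_n/2\hbar$ that
zeroes the moments when the surfaces pull the auxiliary back.  Moments
are also zeroed on every accepted hop and after a collapse.

The three corrections act very differently on a single trajectory ---
continuous nonlinear redistribution (SHXF), monotone damping (SHEDC),
discrete stochastic jumps (A-FSSH) --- which is why the package records
per-trajectory traces and a per-step debug dump alongside the ensemble
averages.

## Velocity adjustment and frustrated hops

An accepted hop changes the potential energy by $\Delta\varepsilon$;
total energy is restored either isotropically
($\dot{\mathbf R} \to \kappa \dot{\mathbf R}$,
$\kappa = \sqrt{1 - \Delta\varepsilon/KE}$) or along the NACV
($\dot R_\nu \to \dot R_\nu + \gamma d_{\nu,an}/M_\nu$ with $\gamma$ the
smaller-magnitude real root of the energy-conservation quadratic), or
NACV-first with isotropic fallback (`nacv+iso`).  A hop whose
potential-energy gain exceeds the available kinetic energy is
*frustrated*; the default policy keeps the momentum, with full reversal
available (`frustrated = "reverse"`), since the literature has not
settled the question.  The hop log records which rescaling branch fired
for every attempt.

## Model systems

Four analytic two-state 1D diabatic models (mass 2000 a.u.) stand in for
molecular surfaces:

| label | character | standard parameters |
|---|---|---|
| `single_crossing` | one avoided crossing, single passage | A=0.01, B=1.6, C=0.005, D=1 |
| `dual_crossing` | two crossings, Stueckelberg interference | A=0.1, B=0.28, C=0.015, D=0.06, E0=0.05 |
| `extended_coupling` | extended coupling with reflection and recrossing | A=6e-4, B=0.1, C=0.9 |
| `sharp_slope` | steeply sloped, very narrow crossing | A=0.03, B=4, C=6e-5, D=8 |

The first three follow the standard literature parameterizations.
`sharp_slope` is an in-house fixture built so that its NACV spike
(half-width $\approx C/AB \approx 5\times10^{-4}$ bohr) is a small
fraction of the distance a trajectory covers in one coarse nuclear step:
whether a step lands inside the interaction region becomes a matter of
chance, so observables depend strongly on $\Delta t$.  That is the
behavior the convergence harness must detect; the smooth models are the
control.

## Study conditions

All quantities are in Hartree atomic units ($\hbar = 1$); times convert
to fs only at I/O ($1\,\mathrm{a.u.} = 0.0242$ fs).  The frozen
conditions used by the validation suite and the acceptance script:

* Initial ensembles are Wigner samples of a harmonic ground state with
  position spread $\sigma_x = 0.35$ bohr (hence momentum spread
  $1/2\sigma_x \approx 1.43$), centered at $x_0$ with mean momentum
  $k_0$; the exact reference starts from the identical minimum-uncertainty
  Gaussian, making the comparison apples-to-apples.
* Single-crossing runs: $x_0=-6$, $k_0 \in \{10, 15, 25\}$ (just above
  the upper-channel threshold $\sqrt{2m\Delta} \approx 8.9$, a medium,
  and a high energy).  Recrossing runs: $x_0=-13$, $k_0=10$.  Sharp
  model: $x_0=-4$, $k_0=20$.
* $\Delta t = 0.4$ a.u. with 20 electronic RK4 substeps;
  energies and $\dot R\cdot d$ interpolate linearly across the step.
  Ensemble sizes are 600--2000 trajectories, run lengths 1000--8000 a.u.;
  these were chosen so the slowest packets clear the interaction region
  and the late-time coherence has visibly settled.
* SHXF $\sigma = 0.35$ bohr, the ground-state width of the sampled mode,
  following the no-empiricism prescription; a scalar override is
  accepted and recorded in the run metadata.

## Numerical and algorithmic choices

*Electronic integration.*  Fixed-substep RK4 (default 20 substeps) with
linear interpolation of $\varepsilon_n$ and $\dot R\cdot d_{nk}$ between
the nuclear step endpoints.  With $\xi = 0$ the propagation conserves
the norm to $\sim10^{-13}$ over full runs; a drift monitor aborts with a
"reduce dt" error past $10^{-6}$.

*Ordering within a step.*  Verlet nuclear step, electronic step (SHXF's
$\xi$ lives inside the right-hand side, with $Q$ and $f$ frozen over the
step), hop test on step-end quantities, then SHEDC damping or A-FSSH
moment propagation/collapse using the post-hop active state.  Applying
the damping before the hop test measurably biased single-crossing
populations (it suppresses the return flux mid-coupling), so the
post-hop ordering --- the common choice in production codes --- is used.

*SHXF auxiliary bookkeeping.*  The auxiliary spawns when the nonactive
population first exceeds 0.01 and is killed only when the population
falls below $10^{-4}$.  Both choices are deliberate and differ from a
single small threshold: spawning much earlier (e.g. at $10^{-4}$) puts
the launch point far up the entrance channel where the gap equals its
asymptotic value, and the accumulated-force difference then cancels
asymptotically on symmetric models, switching the decoherence off;
killing at the spawn value pins every trajectory's late-time coherence
at $p(1-p)\approx$ the threshold itself.  The auxiliary launches along
the parent's direction with speed set by the energy partition
$KE_{aux} = KE + \varepsilon_a - \varepsilon_n$ (a classically forbidden
launch freezes it and increments a prominently reported counter), and
thereafter keeps its *own* direction, refreshing only its speed from
energy conservation on its surface and reflecting at its own classical
turning points.  Slaving the direction to the parent instead injects a
spurious $-2m|v|$ kick into the accumulated force whenever the parent
reflects, which inverts the decoherence direction on reflected
trajectories --- on the recrossing model this made SHXF's internal
consistency *worse* than uncorrected FSSH, which is how the defect was
found.  On an accepted hop the real trajectory takes over the new active
state and the auxiliary respawns for the previously active state at the
current position, keeping one position per populated state.

*Degeneracies and phases.*  Exact degeneracy raises a
"conical-intersection point" error rather than returning an arbitrary
NACV; eigenvector signs follow the previous step (first-nonzero-positive
fallback), removing NACV sign flips from the coefficient equation.
NACV antisymmetry $d_{nk} = -d_{kn}$ is exact by construction.

*RNG.*  Every trajectory owns a counter-based splitmix64 stream keyed on
(base seed, trajectory index); hop, collapse, and reset draws interleave
deterministically and can be logged in full for replay.  Repeating a run
with the same base seed reproduces hop logs bitwise.  "Several
trajectories per initial condition" is therefore the same (R, P) row
with different trajectory indices.

*Exact reference.*  A two-state split-operator wavepacket propagator in
the diabatic representation (exact 2x2 potential exponential, spectral
kinetic step) provides the accuracy oracle.  Adiabatic populations come
from a pointwise basis rotation.  Grid 2048 points over [-30, 30] bohr,
$\Delta t_q = 0.5$ a.u.; halving both changes final populations by
under $10^{-6}$.  Amplitudes are never renormalized; the norm drifts
only at FFT roundoff level ($\sim 2\times10^{-12}$ over $10^4$ steps).

## What the tests do and do not show

The synthetic models reproduce the mechanisms that matter for the
decoherence question --- localized nonadiabatic events, recrossing,
wavepacket splitting, sharply sloped intersections --- under conditions
where a numerically exact reference is available.  They do not emulate
multidimensional vibrational energy flow, conical-intersection
topography (the 1D "crossing" is an avoided one), anharmonic initial
states, or ab initio surface noise, so agreement here shows algorithmic
correctness and the corrections' intended operation, not chemical
accuracy for molecules.

Findings the validation runs establish (and the acceptance script
recomputes):

* FSSH, SHXF, and A-FSSH final populations track the exact reference to
  within a few 0.01 at all three momenta on the single-crossing model.
  SHEDC overshoots the transfer there by up to about 0.1 at the medium
  momentum: with a broad coupling region the damping time
  ($\tau \approx 300$ a.u. mid-crossing) is comparable to the traversal
  time, so amplitude that should have flowed back after an early up-hop
  has already been damped away.  This is the method's known
  overdamping artifact, consistent with energy-based damping moving
  populations away from the reference while plain FSSH sits close to it.
* On the recrossing model uncorrected FSSH violates internal consistency
  badly (max $|\Pi_1 - \bar\rho_{11}| \approx 0.14$ and a late-time
  coherence indicator $\approx 0.19$); all three corrections cut the
  inconsistency by a factor 3--4.
* The ensemble decoherence indicator $\overline{\rho_{11}\rho_{22}}$
  decays below 0.01 after the crossing for SHXF and SHEDC.  A-FSSH does
  *not* get there on this model: its collapse rate is proportional to
  the force difference, which vanishes on the flat asymptotes exactly
  where the separation $\delta R$ finally grows, so collapses fire only
  during the brief exit interval.  The slower A-FSSH decoherence is a
  structural property of the rate expression, matching its reputation
  for remaining coherent longest.
* The sharp-slope model's final populations shift by far more than
  3 Monte-Carlo standard errors across $\Delta t \in \{0.5, 0.25, 0.1\}$
  and the harness flags it non-converged, while the smooth control
  passes the same ladder.

## Known limitations

One auxiliary per nonactive state (two-state engine); state-pairwise
decoherence for many parallel surfaces is out of scope.  The compiled
engine covers the built-in 1D models --- the R-level operations are
dimension-general and are cross-checked against the engine to machine
precision, but ensembles on user-supplied R-function models would need a
slow pure-R loop that the package deliberately does not provide.
Couplings enter through explicit NACVs; overlap/local-diabatization
coupling evaluation is not implemented, so the sharp-slope pathology
cannot be mitigated the way locally diabatized codes do.  Frustrated-hop
reversal flips the full (1D) momentum; no partial reversal along the
NACV is offered.
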