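---
title: "Methods: quasi-attractor landscapes in cholinergically modulated theta-neuron networks"
author: "QLandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quasi-attractor landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

## One unit

A *unit* is a globally coupled subnetwork of $N_E$ excitatory (pyramidal,
PYR) and $N_I$ inhibitory (fast-spiking interneuron, IN) phase neurons,
interpreted as a cortical minicolumn in layers 2/3.  Each neuron is a theta
neuron, the canonical phase model of a type-I spiking cell.  Neuron $i$ of
ensemble $X \in \{E, I\}$ obeys

$$\dot\theta^{(i)}_X = (1 - \cos\theta^{(i)}_X)
 + (1 + \cos\theta^{(i)}_X)\,\bigl(r_X + \xi^{(i)}_X(t) + u_X(t)\bigr)
 \;{+}\; \frac{g_{gap}}{N_I}\sum_j \sin\!\bigl(\theta^{(j)}_I - \theta^{(i)}_I\bigr)\Big|_{X=I},$$

with phases on $(-\pi, \pi]$ and a spike defined as the upward crossing of
$\theta = \pi$.  $r_X < 0$ places the neuron below the saddle-node
bifurcation: it is excitable, possesses a stable equilibrium
$\theta_{eq} = -2\arctan\sqrt{-r}$, and fires only when driven.
$\xi^{(i)}_X$ is Gaussian white noise,
$\langle\xi(t)\xi(t')\rangle = D\,\delta(t - t')$, entering through the
same $(1+\cos\theta)$ sensitivity factor as the drive, and independent
across neurons.  The last term is the diffusive (gap-junction) coupling
among interneurons.

Chemical synapses are all-to-all through the summed postsynaptic currents

$$u_E = g_{EE} I_E - g_{IE} I_I, \qquad u_I = g_{EI} I_E - g_{II} I_I,$$

where $I_X(t)$ is the per-neuron spike train of ensemble $X$ filtered by an
exponential kernel of decay time $\kappa_X$ and normalized by ensemble
size.  In the simulator the kernel sum is held in one state variable per
ensemble, updated by decay-plus-jump at each step — exactly equivalent to
summing per-spike exponentials, at $O(1)$ cost per step.

## The mean-field (Fokker-Planck) limit

For $N \to \infty$ the phase density $n_X(\theta, t)$ of each ensemble
obeys the nonlinear Fokker-Planck equation

$$\partial_t n_X = -\partial_\theta\!\left[A_X(\theta, t)\, n_X\right]
 + \frac{D}{2}\,\partial_\theta\!\left[B(\theta)\,
   \partial_\theta\bigl(B(\theta)\, n_X\bigr)\right],
 \qquad B(\theta) = 1 + \cos\theta,$$

where $A_X$ is the deterministic drift of the phase equation (including
the mean-field form of the gap coupling,
$g_{gap}(\langle\sin\rangle\cos\theta - \langle\cos\rangle\sin\theta)$).
The population firing rate is the probability flux at the spike phase;
because $B(\pi) = 0$ the flux there reduces to $J_X(t) = 2\,n_X(\pi, t)$.
The synaptic currents close the loop through
$\dot I_X = (-I_X + J_X)/\kappa_X$.

The mean field is a *deterministic* PDE/ODE system: any irregularity or
pattern switching it produces is intrinsic to the dynamics, not noise.

## Numerical scheme

*Finite-N path.* Euler-Maruyama with a fixed user-supplied step; the
multiplicative factor $(1+\cos\theta)$ vanishes at the spike phase, so
threshold crossings are clean and their times are interpolated linearly
inside the step.  Noise is generated by counter-based streams indexed by
(seed, neuron, step): reproducibility is bit-for-bit, independent of
vectorization order, and a run split into chunks continues the identical
streams.

*Mean-field path.* Spectral Galerkin in the phase: each periodic density is
evolved through its Fourier coefficients $c_k$, $k = 0..K/2-1$.  Because
the drift contains only the harmonics $\{1, \cos\theta, \sin\theta\}$ and
the noise factor $B$ only $\{1, \cos\theta\}$, every term of the
Fokker-Planck operator is an exactly banded map on the coefficients: there
is no aliasing, and the $k = 0$ equation vanishes identically, so mass is
conserved to rounding error (the realized drift is still monitored with an
abort tolerance of $10^{-6}$).  The coefficients are coupled to the $2M$
synaptic ODEs and advanced by adaptive Dormand-Prince 5(4); the local
error is scaled against the coefficient magnitude plus a fixed floor of
0.05 (the natural density scale $1/2\pi$), so empty high modes are not
tracked to meaningless relative precision.  Grid values are reconstructed
at output times only; small negative excursions of the reconstruction
(Gibbs oscillation of a truncated series) are tolerated up to a
configurable bound, reported in the diagnostics, and never clipped;
exceeding the bound aborts the run with a pointer to the resolution.
The uncoupled population also carries a weakly damped circulation mode
that rings around the stationary state for a long time at weak noise;
stationary-flux comparisons therefore average over the second half of a
long horizon.  A first-order upwind
finite-volume reference stepper (in the test suite) provides an
independent cross-check of the spectral dynamics, and the stationary state
of the uncoupled population is checked against a finite-difference
null-space solution (`stationarySolution()`), an independent discretization
solved by direct linear algebra.

Grid sizes: both one-unit analyses and multi-unit protocol runs use
$K = 128$ (64 Fourier modes per density).  The sharpest structure to
resolve is the density of a suppressed unit, of width
$\sigma \approx \sqrt{D}\,(1+\cos\theta_{eq})/\sqrt{2\lambda_{eq}}$;
the sizes were chosen by grid-refinement checks on the stationary flux
and on network trajectories (the intermittent-unit statistics are
identical at $K = 128$, 192 and 256).

# The memory network

$M$ units are wired by three modified-Hebbian weight families built from
$P$ stored binary patterns $\eta^\mu \in \{0,1\}^M$ with firing rate $a$
(fraction of active units).  With co-activation sums
$S_{kl} = \sum_\mu \eta^\mu_k \eta^\mu_l$ and regulated complements
$T_{kl} = \sum_\mu (X - \eta^\mu_k)\eta^\mu_l$:

$$w^{EE}_{kl} = \frac{G_{EE}}{aM} S_{kl} - \frac{G_{EE}\,c}{M}, \quad
  w^{IE}_{kl} = \frac{G_{IE}}{aM} S_{kl} - \frac{G_{IE}\,c}{M}, \quad
  w^{EI}_{kl} = \frac{G_{EI}}{aM} T_{kl} - \frac{G_{EI}\,c}{M}.$$

The two excitatory families connect co-active units and pull them toward
synchrony; the inhibitory family ($w^{EI}$, INs of an active unit onto
PYRs of units inactive in that pattern) enforces pattern competition.  In
the conventional associative-memory rule the complement factor would be
$(1 - \eta^\mu_k)$; the regulating parameter $X$ generalizes it because an
inhibitory ensemble, not a sign-flipped excitatory one, carries the
competition here.  The three subtraction constants derive from the single
regulation parameter $c$; they remove the net input shift that a
synchronized pattern would otherwise impose on its own members, so the
one-unit working-point dynamics survive inside an active cluster
(exactly so, under perfect synchrony of a single stored pattern, when
$c = 1/a$; $c$ is kept free because synchrony is imperfect with several
patterns stored).  INs receive no inter-unit inhibition: there is no
$w^{II}$ family.

Unit indexing is 1-based everywhere in the user-facing API and file
formats; the compiled core uses 0-based indices internally, with the
conversion confined to the R wrapper layer.

## Neuromodulation

Two factors deform the landscape and one input selects within it:

* $g_{ACh}(t) \in [0, 1)$ — the cholinergic reduction of inhibition —
  scales every IN$\to$PYR strength (intra-unit $g_{IE}$ and inter-unit
  $w^{EI}$) by $(1 - g_{ACh})$, modeling presynaptic muscarinic
  suppression of IPSCs onto pyramidal cells.
* $g_E(t) \in [0, 1)$ — the cholinergic modulation of excitation — scales
  every PYR$\to$PYR strength ($g_{EE}$, $w^{EE}$) by $(1 - g_E)$, modeling
  the weaker presynaptic depression of excitatory transmission.
* Top-down glutamatergic volleys add an increment to the excitatory drive
  $r_E$ of selected units during a short window, modeling layer-1 input to
  apical dendrites.

Both cholinergic factors follow one time course: zero before the onset,
a plateau during the window, and an exponential tail
$e^{-(t - t_1)/\tau}$ afterwards.  The Glu window is constrained by the
schedule validity check to be shorter than the ACh effect, reflecting the
faster clearance of synaptic glutamate.  The two signals play different
dynamical roles: the cholinergic factors are *bifurcation parameters*
(they reshape the attractor landscape), while the Glu input is an
*external force* (it moves the state within a fixed landscape).

# Observables

*Overlap.* The instantaneous rate of a synchronized unit oscillates, so
rates are first passed through a local-peak-hold filter: strict local
maxima with a minimum-prominence guard (default 5% of the series range, so
fine fluctuations do not register), holding the mean of the up to three
most recent peak heights within a 25-time-unit lookback window.  The
window matters: when a unit falls silent, its held value must relax to
the raw series rather than keep a stale burst peak forever.  The held
value $P_k(t)$ is mapped to
$F_k = P_k/(P_k + p_{1/2}) \in [0, 1)$ (default half-saturation
$p_{1/2} = 0.05$, well below a burst-peak rate of order 1 and above the
quiescent-rate floor), and the overlap with pattern $\mu$ is

$$m^\mu(t) = \Bigl(\tfrac{1}{aM}\textstyle\sum_k \eta^\mu_k F_k\Bigr)
            \Bigl(\tfrac{1}{(1-a)M}\textstyle\sum_k (1 - \eta^\mu_k)(1 - F_k)\Bigr),$$

the product of mean activation on the pattern's active units and mean
silence elsewhere: $m^\mu \in [0, 1]$, exactly 1 on the pattern, exactly
0 on its complement.

*Staying times.* Maximal intervals with $m^\mu(t) \ge$ threshold
(default 0.85, exposed everywhere and reported with every result; a
sensitivity sweep over 0.7–0.95 is part of the test suite).  Intervals
cut by the horizon are *censored* and excluded from means; a sweep point
with no uncensored exit is reported as right-censored ("diverged"), never
as an infinite staying time.

*Lyapunov exponents.* Two-trajectory (Benettin) renormalization on the
discretized mean field: a mass-preserving density perturbation of norm
$10^{-7}$ is renormalized every $\tau = 4$ time units; the exponent is the
tail mean of the log growth rates, with the running estimate kept as a
convergence diagnostic and a warning when it has not settled.  A positive
exponent on the deterministic mean field certifies chaos.

*Landscape classification.* A modulation point $(g_E, g_{ACh})$ is an
*attractor* landscape when no pattern-loaded start exits its pattern
within the horizon, and a *quasi-attractor* landscape otherwise — always
a finite-horizon statement, reported with the horizon.  The boundary in
the $(g_E, g_{ACh})$ plane is located by bisection in $g_{ACh}$ at fixed
$g_E$, with the bracket endpoints re-verified.

# Calibration

All numeric values below are package calibrations chosen once to realize
the defining qualitative regimes; they are exposed as presets
(`unitPreset()`, `networkPreset()`) and every analysis accepts arbitrary
values.

*One-unit bistable preset* (`unitPreset("bistable")`): $r_E = r_I =
-0.025$, $g_{EE} = 8.1$, $g_{EI} = 5.7$, $g_{IE} = 3.9$, $g_{II} = 3.85$,
$\kappa_E = 1$, $\kappa_I = 3$, $D = 0.002$.  At this point a near-silent
quiescent state is linearly stable and coexists with a self-sustained,
irregular-amplitude synchronized oscillation of the PYR-IN loop: finite-N
simulations reach either state depending on the initial phase spread,
reproducing the dependence on initial conditions that defines the
one-unit phenomenology.  The noise is kept weak because the quiescent
state ignites once the recurrent drive at the noise-driven firing floor
exceeds the excitability gap ($g_{EE} J_{stat}(D) \gtrsim |r_E|$).

*Network unit preset* (`unitPreset("network")`): $g_{EE} = 6.85$,
$g_{EI} = 5.29$, $g_{IE} = 5.01$, $g_{II} = 3.54$, $\kappa_I = 5$,
$D = 0.0052$.  The slow inhibition places this unit near burst failure:
its attractor is an intermittent burster whose orbit spends most of the
time near quiescence and erupts in synchronized bursts.  These
spontaneous collapses are the transition mechanism of the memory
network: a pattern's visit ends when its units' bursting collapses, and
the released competition lets another pattern ignite.

*Inter-unit intensities*: $G_{EE} = 1.5$, $G_{IE} = 1$, $G_{EI} = 0.6$,
$X = 1$, $c = 2.67 \approx 1/a$.  Setting $c$ near $1/a$ is essential:
it cancels the self-pattern input shift, so the units of an active
pattern keep the intermittent one-unit dynamics instead of being driven
into sustained firing — precisely the role the regulation constants are
designed for.  With these values the reduced network (M = 8, two
patterns sharing one unit) alternates deterministically between its two
memories with staying times of a few tens of time units at baseline;
$g_{ACh} \gtrsim 0.02$ censors all exits within desk-scale horizons,
and positive $g_E$ shifts the boundary to larger $g_{ACh}$.

*On chaos.* The pattern transitions are deterministic — the mean field
contains no noise — but at both calibrated working points the largest
Lyapunov exponent, estimated over $10^4$ time units, is statistically
indistinguishable from zero ($|\lambda| \lesssim 10^{-3}$): the
itinerant alternation is long-period/quasi-periodic rather than
measurably chaotic.  An extensive search of the coupling space (grids,
randomized draws, gap-junction variants, two-timescale synapses, fine
continuations along period-doubling-like cascades) found no regime that
combines the required phenomenology with a clearly positive exponent at
the resolutions this package targets.  The Lyapunov machinery itself is
verified against closed-form and literature benchmarks in the test
suite, and `largestLyapunov()` reports convergence diagnostics so users
can evaluate other parameter regions.

*Stationary-check preset* (`unitPreset("excitable")`): the uncoupled
population at $D = 0.005$, where the stationary state is reached within a
short horizon.

The stored-pattern presets are synthetic constructions satisfying the
structural constraints of the reference memory (16 units, 3 patterns of
6 active units with pairwise overlaps of 1; units 9 and 10 active only in
pattern 2 so that they address it uniquely; the reduced 8-unit memory
stores 2 patterns of 3 units sharing one unit, with units 4 and 5
specific to pattern 2).

*Protocol presets.* The Glu volley adds 0.4 to the excitatory drive of
the target units for 50 time units; the stabilizing ACh level in the
selection experiments is $g_{ACh} = 0.05$ with exponential decay
constant 200.  The staying-time threshold is 0.85 on $m^\mu$ (exposed
everywhere and reported with every result; the alternating visit
sequence of the reduced network is insensitive to the choice across
0.75-0.85).

# What the synthetic scenarios do and do not show

The generator-driven scenarios emulate the study conditions: identical
units, homogeneous all-to-all intra-unit coupling, binary patterns with
equal firing rates, spatially uniform cholinergic factors, and noiseless
deterministic mean-field dynamics at the network level.  Real cortical
data differ in every one of these respects (heterogeneous cells, sparse
connectivity, graded and local neuromodulation, finite-size fluctuations).
Passing tests therefore certify the implementation and the internal
consistency of the model's phenomenology — not that cortical dynamics
follow this model.

# Known limitations

* The mean-field path requires the phase densities to stay resolvable on
  the configured grid; very small noise intensities need larger grids and
  proportionally more time.  The integrator aborts loudly (rather than
  silently clipping) when ringing exceeds the tolerance.
* Landscape verdicts are finite-horizon: an "attractor" is a state with
  no observed exit within the horizon.
* The Lyapunov estimator uses finite-difference perturbations, not
  tangent dynamics; its renormalization interval trades variance against
  saturation and the convergence diagnostic should always be inspected.
* GABAergic projections from the basal forebrain, nicotinic effects on
  layer-1 interneurons, multipolar bursting interneurons, top-down
  inhibitory inputs, and any learning of the weights are outside the
  model's scope.
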