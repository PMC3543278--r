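# QLandscape

Cortical memories can be modeled as attractors of a recurrent network —
but spontaneous cortical activity does not sit still in one attractor.
It wanders: the network visits one internal state for a few hundred
milliseconds, then moves on.  QLandscape implements a two-scale
computational model of how acetylcholine (ACh) can convert between these
two regimes.  Units of pulse-coupled excitatory (pyramidal, PYR) and
inhibitory (fast-spiking interneuron, IN) **theta neurons** are wired into
a multi-unit associative memory by a modified Hebbian rule.  At baseline
ACh the stored patterns are *quasi-attractors*: the deterministic
mean-field dynamics visit them transiently (a Q-landscape).  Because ACh
presynaptically suppresses IN→PYR synapses, a transient rise of ACh scales
every inhibitory strength by $(1-g_{ACh})$ and acts as a *bifurcation
parameter* that stabilizes the patterns into genuine attractors (an
A-landscape), while top-down glutamatergic volleys to selected units act
as an *external force* that chooses which memory is reactivated.

The package is for computational neuroscientists who want to simulate,
analyze, and extend this class of models.

## The model in brief

Each neuron obeys the theta-neuron equation

$$\dot\theta = (1-\cos\theta) + (1+\cos\theta)\,(r + \xi(t) + u(t)),$$

with excitable drive $r<0$, white noise $\xi$ of intensity $D$, synaptic
input $u$ through exponentially filtered population currents, and a spike
at each upward crossing of $\theta=\pi$.  Two integration paths are
provided and kept consistent with each other:

* **Finite N** — Euler–Maruyama with counter-based per-neuron noise
  streams (bit-for-bit reproducible, chunkable);
* **Mean field** — the nonlinear Fokker–Planck equation for the phase
  densities, $\partial_t n = -\partial_\theta(A n) + \tfrac{D}{2}
  \partial_\theta[B\,\partial_\theta(B n)]$ with $B = 1+\cos\theta$,
  evolved spectrally (Galerkin, on Fourier coefficients — the operator is
  exactly banded) with adaptive Dormand–Prince time stepping.  The
  population firing rate is the probability flux
  $2\,n(\pi,t)$ at the spike phase.

$M$ units store $P$ binary patterns $\eta^\mu$ through three weight
families (PYR→PYR and PYR→IN between co-active units; IN→PYR from active
units onto units inactive in the same pattern), with three regulation
constants that preserve the one-unit dynamics inside a synchronized
pattern.  Analysis tools compute local-peak-held firing rates, pattern
overlaps $m^\mu(t)\in[0,1]$, staying times at quasi-attractors, largest
Lyapunov exponents of the (deterministic) mean field, and the
quasi-attractor/attractor boundary in the $(g_E, g_{ACh})$ plane.

See the methods vignette (`vignettes/qlandscape-methods.Rmd`) for the full
model description, numerical choices, and calibration rationale.

## Worked example

Deform the landscape of the reduced 8-unit, 2-pattern network:

```r
library(QLandscape)

net <- networkPreset("reduced")

## ongoing state: baseline ACh, pattern 1 loaded
rep <- runOngoing(net, horizon = 600, gridSize = 128, negTol = 0.8)
head(subset(visits(rep), end - start > 10), 8)
```

```
  pattern  start    end censored
1       1   0.50  33.00    FALSE
2       2  46.00  76.75    FALSE
3       1  91.75 126.00    FALSE
4       2 137.50 168.75    FALSE
5       1 183.25 217.50    FALSE
6       2 229.00 263.25    FALSE
7       1 275.00 305.75    FALSE
8       2 320.50 354.75    FALSE
```

The network alternates deterministically between its two memories,
staying a few tens of time units in each: they are quasi-attractors.
Now reduce the inhibition (raise ACh):

```r
stayingTimeCurve(net, gAchGrid = c(0, 0.01, 0.03), horizon = 600,
                 gridSize = 128, negTol = 0.8)
```

```
  gAch meanStayingTime nExits diverged
1 0.00         33.6875     12    FALSE
2 0.01         34.2500      1    FALSE
3 0.03              NA      0     TRUE
```

Exits become rare and then stop entirely (right-censored at the horizon)
beyond a critical value: the quasi-attractors have been stabilized into
attractors.  A transient glutamatergic volley aimed at the units specific
to pattern 2 (units 4 and 5), delivered together with ACh, selects and
holds that memory; without ACh the same volley gives only a transient
visit:

```r
sel <- runSelection(net, gAch = 0.05, horizon = 600, negTol = 0.8)
reportConfig(sel)$retrieved     # 2
reportConfig(sel)$targetCensored  # TRUE: still in pattern 2 at the horizon
```

(All mean-field numbers above are deterministic and reproduce exactly on
any machine.)

## Command line

A thin wrapper over the exported functions lives in
`inst/scripts/qlandscape.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","qlandscape.R",package="QLandscape"))')" \
    ongoing --config cfg.yaml --out out/
```

Subcommands: `simulate-unit`, `simulate-fp`, `ongoing`, `selection`,
`decay`, `boundary`, `lyapunov`, `fixtures`.  `fixtures` writes complete
example configurations (schema `qlandscape/1`, fail-loud validation).
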