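---
title: "Efficient balanced spiking networks with population adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficient balanced spiking networks with population adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balspike)
```

## The model

`balspike` simulates populations of leaky integrate-and-fire (LIF) neurons
whose connectivity and intrinsic currents are *derived*, not hand-tuned:
they follow from asking that the population minimize, spike by spike, a
global cost–accuracy objective. A stimulus $\phi(t) \in \mathbb{R}^M$ is
read out from the population through fixed decoding weights $w_i \in
\mathbb{R}^M$ applied to the decoder-filtered spike trains $r_i(t)$
(leaky integration with time constant $\tau$):

$$\hat\phi(t) = \sum_i w_i\, r_i(t), \qquad
  \dot r_i = -r_i/\tau + o_i(t),$$

with $o_i(t)$ the spike train of neuron $i$. A second, much slower filter
of the same spike train, $f_i(t)$ with time constant $\tau_a \gg \tau$,
represents the neuron's firing history — the metabolic footprint of its
recent activity. The objective combines squared coding error and the
squared firing histories:

$$E(t) = \lVert \phi(t) - \hat\phi(t)\rVert^2 + \mu \sum_i f_i(t)^2 .$$

The greedy rule — a neuron fires if and only if its spike lowers $E$ at
that instant — reduces algebraically to a threshold condition on

$$V_i(t) = g_i\left(w_i^\top(\phi - \hat\phi) - \mu f_i\right),
  \qquad g_i = \frac{1}{\lVert w_i\rVert^2 + \mu},$$

with threshold $1/2$ and reset $-1/2$ in normalized units. Differentiating
$V_i$ yields a LIF voltage equation whose terms are interpretable currents:
a feedforward drive $g_i w_i^\top(\tau\dot\phi + \phi)$, recurrent
connections $\Omega_{ij} = w_i^\top w_j + \mu\,\delta_{ij}$ scaled by the
gain, and a spike-frequency adaptation current $-\kappa_i f_i$ with
$\kappa_i = \mu\, g_i (1 - \tau/\tau_a)$. Neurons with small decoding
weights have high gain: they are excitable and precise but costly; large
weights give cheap, imprecise, weakly excitable neurons. Because the
integrated excitation $g_i w_i^\top \phi$ is cancelled by the recurrent
inhibition $-g_i w_i^\top \hat\phi$ up to the cost penalty, the network
operates in a tight E/I balance, and the *population* adapts — activity is
redistributed from excitable to less excitable neurons as cost
accumulates — while the fixed linear decoder stays accurate.

All of this is assembled by `build_network(W, mu, tau, tau_a, eta)`. The
optional threshold offset `eta` raises each threshold to $1/2 + \eta g_i$;
the orientation networks use it to keep neurons from spiking on the
recurrent excitation they receive from neurons with opposing preferences.

## Parameters that matter

| parameter | meaning | units | typical values |
|---|---|---|---|
| `W` | decoding weights, one row per neuron | stimulus units/spike | 1–10 per row norm |
| `mu` | cost weight of the objective | – | 0.02–1 |
| `tau` | decoder = membrane time constant | ms | 5–25 |
| `tau_a` | adaptation (firing-history) time constant | ms | 1000–2000 |
| `eta` | threshold offset coefficient | – | 0 (generic), 1–10 (rings) |
| `dt` | integration step | ms | 0.1 |

$\mu = 0$ is the winner-take-all limit: cost is ignored and the most
excitable neuron silences all others. $\tau_a = \tau$ switches the
adaptation current off. The derivation assumes $\tau_a \gg \tau$;
`build_network()` warns otherwise.

## Numerical scheme

`run_simulation()` advances the network on a uniform grid (default
`dt = 0.1` ms):

1. the filters $r$, $f$ and the estimate $\hat\phi$ decay by their exact
   exponential factors $e^{-dt/\tau}$, $e^{-dt/\tau_a}$;
2. the membrane potential is updated by one forward-Euler step of the
   voltage equation; the stimulus derivative is a backward finite
   difference, so a step edge in a piecewise-constant stimulus delivers
   its whole fast-onset drive within a single step (matching the
   instantaneous jump of the closed-form voltage);
3. spike resolution: at most one spike per step. Among neurons whose
   greedy condition holds strictly, the one with the largest margin above
   threshold fires (ties break to the lowest index). The spike applies
   the instantaneous recurrent/self currents $-g_i\Omega_{ij}$, increments
   the spiker's $r$ and $f$, and adds $w_j$ to the estimate. The
   normalized self-coupling $g_j \Omega_{jj} = 1$ *is* the reset: a neuron
   spiking from exactly $1/2$ lands at $-1/2$.

Two voltage representations are carried deliberately. The spike decision
uses the closed-form voltage — the greedy condition itself, which is the
model's definition — while the Euler-integrated voltage of the ODE is
recorded as the membrane-potential trace. The two agree to $O(dt)$ and the
gap halves when `dt` is halved (a standing test). Forward Euler
systematically leads the exact solution by about half a per-step increment
on rising trajectories, so thresholding the integrated voltage would emit
occasional spikes that *increase* the objective at any step size;
thresholding the greedy condition keeps the descent property exact, which
is what the derivation promises. (`decision = "euler"` switches to
integrated-voltage thresholding for numerical experiments.) One spike per
step caps the population rate at $1/dt$; at the default step this bound is
far above the rates any of the shipped protocols produce, so coding error,
not discretization, limits firing. There is no intrinsic noise anywhere:
identical inputs give bit-identical spike rasters.

Simulations abort with a diagnostic on non-finite voltages. Initial
conditions default to $V = r = f = 0$.

## Synthetic stimuli

The generators produce every input used by the shipped protocols:
seven-segment digit patterns (`digit_pattern()`, segments A–G top to
bottom; amplitude default 2, the midpoint of the 0–4 training range) and
timed sequences of them (`digit_sequence()`: 200 ms per digit, 100 ms gap
between consecutive digits — a gap after every digit except the last);
constant pulses (`constant_pulse()`); random constant training patterns,
i.i.d. uniform on [0, 4] (`random_pattern_stimuli()`); and oriented
drives $[C\cos 2\theta,\; C\sin 2\theta]$ (`orientation_stimulus()`).

The angle doubling deserves a note: orientation has period $\pi$, so
mapping $\theta \mapsto 2\theta$ puts orientations onto the full circle.
With the same convention in the ring weights
($[\gamma_i \cos 2\Theta_i, \gamma_i \sin 2\Theta_i]$) and in the decoder
($\hat\theta = \tfrac12\,\mathrm{atan2}(\hat\phi_2, \hat\phi_1)$),
preferred and decoded orientations agree, opposing preferences
($90^\circ$ apart) have anti-parallel weight vectors and hence mutually
excitatory couplings, and the decode–generate round trip is the identity
on $(-\pi/2, \pi/2]$. These stimuli are deliberately minimal: constant
segments and pure orientation vectors, with none of the spatial structure,
contrast dynamics or noise of real visual input. Passing tests therefore
certify the coding dynamics, not robustness to natural stimuli.

## Readout

`train_optimal_decoder()` fits the least-squares linear decoder from
stacked time samples of response traces. Three choices are exposed, with
defaults documented here: the first 50 ms of every trace are discarded so
the decoder reflects steady responses; samples are thinned to one per ms
(neighbouring samples of a 5 ms filter are redundant, and the Gram
accumulation stays cheap); and a ridge term of $10^{-6}$ times the mean
Gram diagonal guards rank deficiency — silent neurons are common in the
random baseline. `ridge = 0` recovers the pure pseudoinverse.

## The three networks

*Random LIF baseline* (`build_random_baseline()`): feedforward weights
uniform on $[-1, 1]$, off-diagonal recurrent weights $\mathcal N(0,
0.87^2)$, and an autapse equal to minus the summed squared feedforward
weights of the neuron. Unstated details are fixed as follows and are
assumptions of this package: the membrane time constant equals the decoder
$\tau$; the base threshold is 1 (the adaptive variant uses $1 + \mu
f_i(t)$); volleys are allowed (every neuron above threshold spikes in a
step); and the reset acts *through the autapse* — a spike applies the
spiker's full recurrent column, so the spiker drops by its own negative
autapse. An earlier variant with a hard reset to 0 leaves the autapse with
no role and largely erases the history dependence of the
adaptive-threshold condition; the autapse-reset convention restores the
strong along-sequence degradation the digit experiment is meant to
exhibit.

*Dual ring* (`build_dual_ring()`): $N/2$ preferred orientations evenly
spaced over $(-\pi/2, \pi/2]$, each carrying one high-gain ($\gamma = 3$)
and one low-gain ($\gamma = 9$) neuron.

*Random-gain ring* (`build_random_gain_ring()`): identical geometry with
one neuron per orientation and $\gamma_i \sim U[3, 9]$; evenly spaced
preferences, only the gains are random.

## Protocols and the sizes they run at

`digit_experiment()` trains the baseline decoder on 100 random patterns of
300 ms (thinned to 1 sample/ms), then presents the same 8-digit sequence
(2300 ms) to the fixed-threshold baseline, the adaptive-threshold
baseline, and the balanced network built from the baseline's feedforward
weights as decoding weights ($\mu = 0.02$, $\tau_a = 2000$ ms); it
tabulates the per-presentation reconstruction MSE after a 20 ms onset
allowance. The balanced network for this comparison reuses the baseline's
feedforward weight matrix as its decoding weights — the comparison is
then between identically-selective populations differing only in their
recurrent structure.

`tuning_curve_protocol()` presents each test orientation for 250 ms from a
reinitialized network, and again immediately after a 1.5 s adaptor; a
response is the mean filtered rate over the test window. Population curves
center each neuron on its preferred orientation at the nearest grid point
and average within gain class. The shipped tests run a 5-point orientation
grid; the function takes any grid.

`tilt_bias_protocol()` / `bias_curve()` present a 2 s adaptor ($C = 25$)
then a 250 ms test ($C = 5$), decode the *mean* network output over the
test window, and report the signed bias with positive = repulsion away
from the adaptor. The bias curve sweeps a 5° grid of adaptor–test
differences and finds the repulsion-to-attraction crossover by linear
interpolation between the flanking grid points.

The acceptance script (`scripts/acceptance.R`) recomputes the bias-curve
sweep at exactly these settings.

## Degenerate inputs and tie-breaks

Zero weight rows require $\mu > 0$ (the gain would diverge). A zero
estimate makes the decoded orientation undefined and is reported as
missing rather than guessed. Equal spike margins break to the lowest
neuron index; with distinct gains this occurs only on measure-zero
configurations. `bias_curve()` reports the crossover as `NA` when the
bias never changes sign on the grid.

## Known limitations

* Under the default conditions the attractive lobe of the tilt-bias curve
  is shallow (a fraction of a degree) and the sign change sits near 59°,
  later than the midpoint of the sweep. The mechanism is instructive: with
  the exact greedy rule, neurons whose preferences oppose the adaptor are
  never permitted to spike during adaptation — their spikes would raise
  the objective — so they accumulate no firing history, and the only
  attraction pathway is the weak far-flank fatigue of the test response.
  In integrated-voltage variants those opposite-preference neurons sit
  marginally below threshold during adaptation (each adaptor spike kicks
  them by $\approx g_i \lVert w_i \rVert^2$, i.e. order 1), and schemes
  that allow simultaneous volleys can push them over — at the price of
  losing the guaranteed objective descent, and, at the extreme, of a
  runaway ping-pong between opposite poles that we verified and rejected.
  The threshold offset $\eta g_i$ exists precisely to suppress this
  marginal activation; the tilt protocol runs with $\eta = 0$.
* The random LIF baseline is a deliberately generic comparison network;
  its firing rates are unconstrained and biologically implausible, and
  results that depend on it are qualitative by design.
* Exact event-driven integration, conductance synapses, delays and
  stochastic spiking are out of scope; the integrator is first-order and
  the voltage traces inherit its $O(dt)$ bias.
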