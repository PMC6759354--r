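# balspike

Simulation toolkit for **efficient balanced spiking networks with
population-level adaptation**: networks of leaky integrate-and-fire
neurons derived from a greedy, spike-by-spike minimization of a
cost–accuracy objective. It is aimed at computational neuroscientists who
want to study how spike-frequency adaptation and tightly balanced
recurrent inhibition jointly keep a *fixed* linear decoder accurate while
single-neuron responses change dramatically — and at the perceptual
consequences (orientation tuning-curve adaptation, the tilt aftereffect)
when they don't quite.

## The model

A stimulus $\phi(t)\in\mathbb{R}^M$ is decoded from filtered spike trains
through fixed weights, $\hat\phi(t)=\sum_i w_i r_i(t)$ with
$\dot r_i=-r_i/\tau+o_i$. A slower filter of the same spikes,
$\dot f_i=-f_i/\tau_a+o_i$, tracks each neuron's firing history. The
population greedily minimizes

$$E(t)=\lVert\phi-\hat\phi\rVert^2+\mu\sum_i f_i^2 ,$$

firing a spike only when it lowers $E$. That rule is equivalent to a LIF
threshold condition on $V_i=g_i\,(w_i^\top(\phi-\hat\phi)-\mu f_i)$ with
gain $g_i=1/(\lVert w_i\rVert^2+\mu)$, normalized threshold $1/2$ and
reset $-1/2$, recurrent weights $\Omega_{ij}=w_i^\top w_j+\mu\delta_{ij}$
and an adaptation current $-\kappa_i f_i$,
$\kappa_i=\mu g_i(1-\tau/\tau_a)$. Feedforward excitation and recurrent
inhibition cancel up to the cost penalty (E/I balance), so adaptation
redistributes activity across neurons without moving the population
read-out.

The package provides the network builders (`build_network`,
`build_random_baseline`, `build_dual_ring`, `build_random_gain_ring`),
the simulator (`run_simulation`), stimulus generators (seven-segment
digit sequences, pulses, oriented drives), decoder training and
orientation decoding, and scripted experiment protocols
(`digit_experiment`, `population_trace_experiment`,
`tuning_curve_protocol`, `tilt_bias_protocol`, `bias_curve`). See the
vignette `vignettes/balanced-adaptation.Rmd` for the numerical scheme and
all modelling choices.

## Worked example: population adaptation under a constant pulse

Ten neurons with graded decoding weights $w = 1,\dots,10$ receive a
constant pulse $\phi = 10$ for 2 s ($\mu=0.2$, $\tau=5$ ms,
$\tau_a=1000$ ms):

```r
library(balspike)
spec <- build_network(W = matrix(1:10, ncol = 1), mu = 0.2,
                      tau = 5, tau_a = 1000)
stim <- constant_pulse(10, duration_ms = 2000, dt = 0.1)
print(run_simulation(spec, stim))
#> Simulation result: 10 neurons, 20000 steps (dt = 0.1 ms), 758 spikes
#>   final objective E = 2552 (error 6.05 + cost 2546)

pe <- population_trace_experiment()
pe$recruitment
#> [1] 1 2 3 4 5 6 7 8 9
round(pe$first_spike_ms[pe$recruitment], 1)
#> [1]    0.0    0.8    6.6   24.9   69.2  157.3  327.1  694.2 1876.0
```

The most excitable neuron ($w=1$) fires first; as its firing history (and
hence its adaptation current) accumulates, progressively less excitable
neurons are disinhibited and recruited — neuron 9 only after 1.9 s, and
neuron 10 not at all within the pulse. The decoded estimate stays near
the stimulus while its dispersion grows as cheaper, less precise neurons
take over:

```r
sm <- smooth_estimate(pe$result$estimate_trace[1, ], window_ms = 100, dt = 0.1)
#> estimate mean (sd) at 0.2 s: 8.97 (1.38);  at 1.8 s: 7.84 (1.76)
```

Every spike in these runs strictly lowers the objective
(`all(pe$result$raster$delta_E < 0)` is `TRUE`).

## Command line

A thin CLI over the same functions is installed with the package
(`system.file("cli/balspike", package = "balspike")`); subcommands
`simulate`, `digits`, `population`, `tuning`, `tilt` and `bias-curve`
take a YAML run configuration, with `--seed`, `--dt` and `--out`
overrides, and write raster/trace/summary CSVs plus a `run_log.yaml`.

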