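# sinet: swim interneuron dynamics and two-cell rhythm-generating networks

Swim central pattern generators of the sea slugs *Melibe leonina* and
*Dendronotus iris* are built from interneurons that never burst on their
own, yet the assembled circuits produce robust slow bursting. `sinet` is a
simulation and analysis toolkit for the building blocks of such circuits:

* a conductance-based **swim-interneuron model** — an adapted Plant R15
  burster whose endogenous bursting is removed by two slow-subsystem
  shifts, Δ<sub>x</sub> (half-activation of the slow TTX-resistant gate)
  and Δ<sub>Ca</sub> (calcium reversal), plus a depolarizing h-current:

      Cm V' = −I_I − I_K − I_h − I_leak − I_T − I_KCa − I_syn + I_app
      x'    = [x∞(V; Δx) − x]/τx,   x∞(V) = 1/(1 + exp(−0.15 (V + 50 − Δx)))
      [Ca]' = ρ [Kc x (ECa − V + ΔCa) − Ca]

* five **synapse models** (fast threshold modulation, first-order
  alpha kinetics, higher-order cascades, a slow-modulated dynamic
  synapse, and the logistic synapse
  S' = α S (1 − S) f∞(V_pre) − β (S − S0), a high-pass filter with
  latency and sigmoidal summation);
* **slow-fast dissection** of the ([Ca], x) phase plane: fast-subsystem
  equilibria and spiking orbits at frozen slow variables, the four
  organizing curves (x-nullcline, orbit-averaged ⟨x⟩ nullcline, calcium
  nullcline, SNIC boundary), their deformation under applied or synaptic
  currents, and activity prediction from the plane;
* **activity classification** (tonic / bursting / quiescent /
  subthreshold) and two-parameter regime scans over (Δ<sub>Ca</sub>,
  Δ<sub>x</sub>), including the three transition routes;
* a **two-cell network simulator** with a registry of published
  experiment presets — half-center oscillators (HCO), winner-takes-all,
  and excitatory/inhibitory (E/I) modules — plus burst metrics,
  normalized phase lags, and bistability probes.

Time is measured in the millisecond-scale Plant model unit (published
"seconds" are 1000 units; spike frequencies in Hz are 1000/ISI);
voltages are in mV, conductances in nS.

## A worked example: emergent antiphase bursting

Two identical cells at Δ<sub>Ca</sub> = −30 mV, Δ<sub>x</sub> = −4 mV are
quiescent in isolation:

```r
library(sinet)
p  <- sin_params(delta_Ca = -30, delta_x = -4)
tr <- simulate_cell(p, opts = solver_options(duration = 400e3,
                                             rtol = 1e-7, atol = 1e-9))
classify_trace(tr, classifier_options(transient = 250e3, window = 140e3))
#> activity: quiescent (0 spikes, amplitude 0.00 mV)
```

Coupling them reciprocally with inhibitory logistic synapses at the
published strength (g = 0.047 nS, α = 0.05, β = 0.0051) and igniting
from the standard anti-phase initial condition turns the pair into a
self-sustained half-center oscillator:

```r
cfg <- preset("hco_quiescent")
net <- simulate_network(cfg)
network_label(net)$network
#> [1] "bursting"
burst_metrics(net)
#> network bursting: period 19305 units (19.3 s), phase lag 0.500
#>   cell1: 11 bursts, duty 0.48 | cell2: 10 bursts, duty 0.52
```

The two quiescent cells burst in exact alternation (normalized phase lag
0.500, i.e. half a period) with a 19 s network period — a rhythm neither
cell possesses alone. The same machinery exposes the underlying
mechanism: a release from inhibition triggers a fast post-inhibitory
rebound whose spike rate transiently exceeds the logistic synapse's
corner frequency,

```r
inhibitory_pulse_protocol(p, g_syn = 1)$peak_frequency
#> [1] 4.58        # Hz, versus a quiescent cell's 0 Hz baseline
```

and the asymmetric E/I module (`preset("ei_diverse")`) bursts with a
quarter-period lag instead. `slow_nullclines()` /
`predict_activity_from_plane()` reproduce the slow-plane reading of all
of these regimes, and `scan_diagram()` maps the full
(Δ<sub>Ca</sub>, Δ<sub>x</sub>) plane.

See the methods vignette
(`vignettes/swim-interneuron-networks.Rmd`) for the model equations,
parameter provenance and calibration rationale, the dissection
machinery, and known limitations.

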