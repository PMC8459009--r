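# CortexColumn

Spiking-network simulation of a neocortical column and an image-based
persistent-activity (working-memory) assay, built to compare how neuron
membrane parameters — for example human versus rodent cortical parameter
sets — shape a column's ability to hold and transfer a stimulus.

## The model

**Neurons.** Each of the 2,000 neurons is an adaptive exponential
integrate-and-fire (aEIF) unit with membrane potential *V* and adaptation
current *w*:

```
C dV/dt = -g_L (V - E_L) + g_L exp((V - V_th)/ΔT) + I - w
τ_w dw/dt = a (V - E_L) - w
if V > V_th:  V → V_r,  w → w + b
```

integrated by forward Euler at dt = 0.05 ms (units package-wide: pF, nS, mV,
ms, pA). Neurons start at `V = E_L`, `w = 0`.

**Synapses.** Conductance-based AMPA, GABA-A and NMDA channels with
difference-of-exponentials kernels, a transmission delay τ_D, and the NMDA
magnesium-block gate `s(V) = 1.08 / (1 + 0.19 e^(-0.064 V))`:

```
I_X = g_X^max s(V) Σ_sp a(t_sp) (e^(-(t - t_sp - τ_D)/τ_off) - e^(-(t - t_sp - τ_D)/τ_on)) (V - E_rev)
```

Every connection carries Tsodyks–Markram short-term plasticity: utilization
*u* (facilitation, τ_facil = 500 ms) and resources *R* (depression recovery
τ_rec = 300 ms), baseline utilization U = 0.25, per-spike efficiency
`a = u·R`, first spike at `(u, R) = (U, 1 - U)`.

**Column.** Three layers (2/3, 5, 6) and five cell classes — pyramidal cells
(PC, excitatory), local-layer interneurons (LL-IN), bipolar cells (BPC,
cross-layer), large basket cells (LBC) and Martinotti cells (MC, both
long-range); LBCs share the PC membrane parameters of their layer. Wiring is
random with per-population-pair probabilities; excitatory sources project
AMPA+NMDA, interneurons GABA-A. Background currents: 250 pA (excitatory),
200 pA (interneurons).

**Assay.** A 30×30 binary image maps row-major onto the 900 layer-2/3 PCs.
ON pixels receive 50 Hz Poisson trains of suprathreshold 1-ms current pulses
over 200–300 ms; the decoded output sets pixel *k* to 1 iff neuron *k*
spiked during 202–300 ms. Three statistics summarize a run: whole-network
spike density (spikes/ms per 100-ms window), the excited-neuron ratio
(fraction of stimulated cells whose firing rose ≥ 50% after stimulation),
and the signal-transfer accuracy (pixelwise agreement of input and output,
percent). Experiments repeat nine times with fresh connectivity and
stimulus randomness and are summarized as mean ± SEM with one-way ANOVA.

The bundled rodent and human parameter tables are editable defaults that
encode the qualitative species contrasts (human deep-layer pyramidal
capacitance about half the rodent value, human LL-IN capacitance about
twice, human reset and threshold potentials higher); see the vignette for
exactly what they do and do not represent.

## Worked example

```r
library(CortexColumn)
cfg <- defaultColumnConfig()
net <- assignParameters(buildColumn(cfg, seed = 1),
                        speciesTable(cfg, "human"), cfg$background_currents)
net
#> ColumnNetwork: 2000 neurons, 364215 synapses (seed 1)
#>   populations: L2/3 BPC=20, L2/3 LBC=20, L2/3 LL-IN=40, L2/3 MC=20,
#>   L2/3 PC=900, L5 BPC=24, L5 LBC=24, L5 LL-IN=48, L5 MC=24, L5 PC=480,
#>   L6 BPC=16, L6 LBC=16, L6 LL-IN=32, L6 MC=16, L6 PC=320

runAssay(cfg, speciesTable(cfg, "human"), loadPattern("square"), seed = 1)
#>  seed pattern noise spike_density_baseline spike_density_pa excited_ratio accuracy
#>     1  square     0                      0            196.5          99.5    83.11

runAssay(cfg, speciesTable(cfg, "rodent"), loadPattern("square"), seed = 1)
#>  seed pattern noise spike_density_baseline spike_density_pa excited_ratio accuracy
#>     1  square     0                  119.7            88.64            67    44.44
```

The human column is silent at baseline (0 vs 119.7 spikes/ms) but, once the
square is presented, fires more during the retention window (196.5 vs 88.6
spikes/ms), keeps a larger fraction of the stimulated cells excited (99.5%
vs 67%) and reconstructs the image far more faithfully (83.1% vs 44.4%
pixel agreement — the rodent column's tonically active layer recruits
broadly, so its output saturates near the ON-pixel fraction).

Higher-level drivers: `runSpeciesComparison()`, `morphSingleParam()`,
`sweepBackground()`, `sweepStdRecovery()`, `noiseRobustness()`,
`responseSurface()` / `fitQuadraticResponse()`. A command-line front end
ships at `inst/scripts/column-experiment.R`:

```sh
Rscript inst/scripts/column-experiment.R compare --seed 1 --out-dir results/
```

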