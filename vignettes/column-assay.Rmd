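---
title: "The column model and its persistent-activity assay: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The column model and its persistent-activity assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

CortexColumn simulates a single neocortical column of 2,000 adaptive
exponential integrate-and-fire (aEIF) neurons and scores how well the
column holds a briefly presented binary image in its spiking activity.
This vignette explains the model equation by equation, documents every
numerical and design decision that the equations alone do not fix, and
states plainly what the bundled defaults do and do not represent.

## 1. Neuron model

Each neuron follows the two-variable aEIF dynamics

$$C\,\dot V = -g_L (V - E_L) + g_L e^{(V - V_{th})/\Delta_T} + I - w,
\qquad \tau_w\,\dot w = a (V - E_L) - w,$$

with the reset rule: if $V > V_{th}$ then $V \to V_r$, $w \to w + b$.
Units are fixed package-wide as pF, nS, mV, ms and pA, which are mutually
consistent (pA/pF = mV/ms). Parameters per cell class: capacitance $C$,
leak conductance $g_L$ and reversal $E_L$, reset $V_r$, threshold $V_{th}$,
slope factor $\Delta_T$, adaptation time constant $\tau_w$, subthreshold
adaptation $a$ and spike-triggered increment $b$.

Three deliberate choices:

* **Exponential prefactor.** The spike-initiation term is implemented with
  a bare $g_L$ prefactor, as written above. The canonical aEIF multiplies
  the exponential by $g_L \Delta_T$; because the model is used with the
  bare form throughout, that form is the package default and the canonical
  variant is available behind `simulationProtocol(canonical_exp_term =
  TRUE)` for sensitivity checks. With the bundled $\Delta_T \le 3$ mV the
  term only matters within a few millivolts of threshold either way.
* **Spike criterion.** A spike is a threshold crossing: the reset fires
  when the Euler-stepped $V$ exceeds $V_{th}$; there is no separate upswing
  cutoff ($V_{peak}$) and no refractory period. Spikes are therefore
  recorded at the end of the step in which the crossing occurred.
* **Overflow guard.** The exponent $(V - V_{th})/\Delta_T$ is clamped at
  +10 before exponentiation (configurable via `exp_clamp`), preventing
  numeric overflow in the same step in which the reset fires. The clamp is
  unreachable for subthreshold dynamics.

Integration is forward Euler at the reference step `dt = 0.05` ms. The test
suite verifies first-order convergence, and that spike times of driven
neurons stay within 0.2 ms of an adaptive high-order integration with
exact event location over 200-ms protocols.

## 2. Synapses

Transmission is conductance-based through AMPA, GABA-A and NMDA channels.
A presynaptic spike at $t_{sp}$ contributes, after a transmission delay
$\tau_D$, a difference-of-exponentials conductance with onset and offset
time constants $\tau_{on} < \tau_{off}$; the channel current is

$$I_X = g_X^{max}\, s(V) \sum_{sp} a(t_{sp})
 \left(e^{-(t - t_{sp} - \tau_D)/\tau_{off}} -
       e^{-(t - t_{sp} - \tau_D)/\tau_{on}}\right)(V - E_{rev}),$$

subtracted from the membrane drive, so a channel with $E_{rev}$ above the
membrane potential depolarizes and one below hyperpolarizes. The NMDA gate
$s(V) = 1.08\,(1 + 0.19\,e^{-0.064 V})^{-1}$ (magnesium-block
phenomenology) applies to NMDA only; its three constants are frozen, not
configuration keys. The kernel is *not* peak-normalized; $g^{max}$ scales
the raw difference of exponentials.

**Short-term plasticity.** Every connection carries Tsodyks–Markram
dynamics with utilization $u$ (facilitation) and resources $R$
(depression):

$$u_{n+1} = u_n e^{-\Delta t/\tau_{facil}} + U(1 - u_n e^{-\Delta t/\tau_{facil}}),
\qquad
R_{n+1} = R_n (1 - u_{n+1}) e^{-\Delta t/\tau_{rec}} + 1 - e^{-\Delta t/\tau_{rec}},$$

with per-spike efficiency $a_n = u_n R_n$ using the post-update values, and
first-spike state $(u_1, R_1) = (U,\, 1 - U)$. Defaults: $U = 0.25$,
$\tau_{facil} = 500$ ms, $\tau_{rec} = 300$ ms. Three readings had to be
fixed where the recursion is written ambiguously in the literature this
model family comes from:

* the recovery term is the standard $1 - e^{-\Delta t/\tau_{rec}}$ (a stray
  factor sometimes printed inside that term is read as a typo);
* $u$ updates first and $R$ uses the updated $u_{n+1}$, as the subscripts
  indicate;
* the first-spike state follows the explicit initial-condition equation
  $R_1 = 1 - U$ rather than the surrounding prose ($R_1 = 1$); with
  $U = 0.25$ the first-spike efficiency is $a_1 = 0.1875$.

STP is evaluated per connection at the *emission* time of the presynaptic
spike (not at delivery; the two differ when $\tau_D > 0$), and one
efficiency scales AMPA and NMDA of an excitatory projection jointly — both
receptors are driven by the same release event. Since all outgoing synapses
of a neuron share its spike train and the constants are global, the engine
keeps one STP state per presynaptic neuron.

**Engine bookkeeping.** Rather than summing over past events, the engine
maintains two auxiliary accumulators per receptor per neuron, decayed by
$e^{-dt/\tau_{on}}$ and $e^{-dt/\tau_{off}}$ each step, with each delivery
adding its efficiency to both. This is algebraically identical to the
direct sum when events land on grid points; the equivalence is asserted to
1e-9 in the tests. Delays shorter than one step round up to one step. The
per-step order is: (1) deliver due events, (2) evaluate currents at the
current $V$, (3) Euler step, (4) threshold/reset and STP update,
(5) enqueue new spikes, (6) decay accumulators. Alternative orders shift
spikes by one step; this one makes the kernel exactly zero at the delivery
instant.

## 3. The column

Three layers (2/3, 5, 6; layer 4 is deliberately absent from this model
family) and five classes per layer: pyramidal cells (PC, the only
excitatory class), local-layer interneurons (LL-IN), bipolar cells (BPC,
cross-layer), and the long-range large basket (LBC) and Martinotti (MC)
cells. LBCs are electrophysiologically pyramidal-like: a parameter table
may omit LBC rows, which then default to the PC row of their layer
(likewise BPC/MC default to LL-IN). The default architecture fixes what the
source constraints fix — 2,000 neurons total, 900 L2/3 PCs at ids 1–900 in
row-major pixel order — and distributes the rest as L2/3 = 1,000, L5 = 600,
L6 = 400 with an 80/20 excitatory/inhibitory split within the deep layers.
Every count is a configuration key.

Wiring draws each ordered (pre, post) pair once, independently, with a
probability depending on the two populations; autapses are excluded (a
configuration flag restores them; recurrent "self-connection" of a
population means its within-population wiring, not literal autapses). The
bundled probabilities are rule-generated: dense local excitation
(PC→PC 0.12, PC→IN 0.20 within a layer), strong local inhibition
(LL-IN→PC 0.30), feedforward L2/3→deep 0.10, weak deep→L2/3 feedback 0.02,
L5↔L6 0.08 with layer 6 mirroring layer 5, and sparse cross-layer
inhibition (BPC, LBC, MC ~0.05–0.10). The feedback value is the one
genuinely dynamical choice: stronger feedback lets deep-layer activity
re-ignite layer 2/3 wholesale, erasing the image (section 6).

Background currents stand in for out-of-column input: 250 pA to excitatory
cells, 200 pA to interneurons, constant in time.

## 4. The stimulus, and why its default is a Poisson train

A 30×30 binary image maps pixel $(r, c)$ to L2/3 PC id $30(r-1)+c$; ON
pixels define the stimulated set. The scoring output sets pixel $k$ to 1
iff neuron $k$ spikes in the closed window 202–300 ms. Accuracy is
pixelwise agreement with the clean input (both agreement cases count: ON
and spiking, OFF and silent).

The stimulation description this assay derives from — 50 Hz Poisson
current pulses applied at 201 ms, spiking recorded over the following
99 ms — leaves the waveform underdetermined, and the choice matters more
than any other parameter in the package. Two readings were implemented:

* `pulse`: one rectangular current per target, default 1 ms, covering
  millisecond 201 only;
* `poisson50` (**default**): per target, an independent 50 Hz Poisson
  train of 1-ms rectangles over the whole 100-ms retention window
  (~5 pulses expected per target).

The single-pulse reading was tried first and abandoned as the default on
dynamical grounds: a synchronized one-millisecond volley into an
*unstructured* random column either dissipates or ignites the entire
layer — across wide grids of NMDA/GABA-A conductances and connection
probabilities the decoded output was all-zero or all-one, never graded —
and the volley's direct spikes land at ~201 ms, before the scoring window
opens. The Poisson-train reading distributes the drive through the window
the description itself says is being scored, produces graded, per-pixel
outcomes, and is consistent with the stated 50 Hz rate actually mattering
(at 50 Hz a 1-ms window would contain 0.05 pulses). Each Poisson pulse is
a 1-ms rectangle at the protocol amplitude; a one-time-step (0.05 ms)
rectangle was rejected because at any plausible amplitude it transfers
under 2 mV of charge to a 150-pF cell.

The default amplitude is 4000 pA: a 1-ms rectangle of that size
depolarizes every bundled cell class from rest across its threshold
(ΔV = amplitude × 1 ms / C ≈ 13–27 mV), making "suprathreshold pulse"
literally true. Amplitude, rate, width, onset and window are all protocol
fields.

Salt-and-pepper noise flips `round(p·900)` *distinct* pixels chosen
uniformly (guaranteeing the stated corruption level as a Hamming
distance); the classic set-to-0-or-1 variant is available via
`mode = "extreme"`. Noise corrupts only the encoded input; accuracy is
always scored against the clean pattern.

## 5. Metrics and statistics

* **Spike density**: whole-network spikes per ms in a half-open 100-ms
  window; baseline 100–200 ms, persistent activity (PA) 200–300 ms.
* **Excited-neuron ratio**: the percentage of *stimulated* neurons whose
  post-window count is at least 1.5× the pre-window count and strictly
  larger. The zero-baseline edge case is fixed as: silent→silent is not
  excited, silent→any spike is (any increase from zero exceeds 50%).
* **Transfer accuracy**: 100 × (agreeing pixels)/900.

Each experiment runs nine independent repeats; a repeat's seed derives
three child streams (connectivity, stimulus, noise) so any one source can
be frozen while others vary. Summaries report mean ± SEM (sd/√n) and
one-way ANOVA across groups with significance marks at 0.05, 0.01 and
0.0001. When every value is identical the ANOVA is reported as F = 0,
p = 1 rather than 0/0.

## 6. The bundled species tables: what they are and are not

The exact membrane tables, synapse constants and connection probabilities
behind the original human–rodent comparison are not published in the main
text this package works from. The bundled `rodent` and `human` tables are
therefore **synthetic defaults**, constructed once to satisfy the stated
qualitative constraints — human L5/L6 PC capacitance about half the rodent
value, human LL-IN capacitance about double, human $V_r$ and $V_{th}$
higher everywhere, backgrounds 250/200 pA — with otherwise generic
cortical aEIF magnitudes. Within those constraints the remaining freedom
was spent to place the two columns in dynamically distinct, interpretable
regimes:

* the **rodent** column rests tonically active (its PCs' resting drive
  exceeds rheobase) with strong spike-triggered adaptation
  ($b = 120$ pA), so stimulation adds little on top of an already-busy
  layer and broad NMDA recruitment saturates its decoded output near the
  ON-pixel fraction;
* the **human** column rests silent (higher thresholds, hyperpolarized
  rest) with weak adaptation ($b = 30$ pA) and resets close to threshold,
  so it responds strongly and selectively to the stimulated set.

Under these defaults the assay reproduces the directional contrasts —
human baseline density lower, human PA density and excited ratio higher,
human accuracy higher, accuracy falling with input noise — which is what
the acceptance suite asserts. The *absolute* densities and accuracies of
the original study are not reproduced and are not claimed: they depend on
the unpublished tables. Anyone holding the real tables can drop them into
the YAML configuration or a CSV (`importAeifTable()`) unchanged. One
interaction worth knowing: because the bundled human L2/3 reset (−48 mV)
sits above the bundled rodent L2/3 threshold (−50 mV), morphing *only*
$V_r$ between species is rejected by table validation (the reset would
exceed the threshold); morph $V_{th}$ first, or scope the morph to deep
layers.

In the noise experiment the rodent column's saturation means its accuracy
is pinned at the ON fraction for every noise level; the monotone-decline
property is therefore assessed on the assay's mean accuracy averaged over
the two species, where the human column's ~10-points-per-10%-noise decline
dominates.

## 7. Response surface

`responseSurface()` regresses assay accuracy on five normalized membrane
parameters — $C$ of L5 and L6 PCs and $V_{th}$ of the three LL-IN
populations — each mapped linearly from its rodent value (0) to its human
value (1). Sample points come from a Latin hypercube over $[0,1]^5$
(default 30 points, 3 repeats averaged per point) rather than a full
factorial; the model has no cross terms,

$$P = \beta_0 + \textstyle\sum_i \beta_i x_i + \sum_i \gamma_i x_i^2,$$

so the fit is ordinary least squares in the monomial basis. An iterative
(Gauss–Newton) solver started from all-ones coefficients is retained as an
option for procedural parity; for a model linear in its coefficients it
lands on the same solution. `vertexForm()` completes the square per
predictor, returning each parabola's curvature and vertex and the shifted
constant. A rank-deficient design (a predictor constant across samples) is
an error, not a silent drop.

## 8. Numerical and reproducibility notes

* Determinism: the compiled engine draws no random numbers; connectivity,
  Poisson pulse times and noise pixels are drawn in R under seeds derived
  from the experiment seed. Identical seeds give byte-identical rasters,
  metrics and reports.
* Raster events are recorded at step resolution (multiples of dt); voltage
  traces are recorded at 1 ms for inspection.
* dt-refinement: halving dt changes the default column's 300-ms spike
  count by well under 5% (regression-tested).
* Degenerate inputs: an empty stimulated set yields an undefined (NA)
  excited ratio; a zero-length metric window, negative probabilities,
  inconsistent architecture totals and unknown configuration keys are
  errors.
* Problem sizes in the shipped tests: the full 2,000-neuron column at
  dt = 0.05 ms for 300 ms per run; nine repeats × four patterns per
  species for the comparison, nine repeats × four noise levels × two
  species for the noise sweep; miniature (≤ 1,000-neuron) columns for
  plumbing tests. These sizes are the package's reference conditions; the
  engine itself is O(neurons + deliveries) per step.

## 9. Known limitations

* Point neurons only: no dendrites, no conductance-based ion channels, no
  refractory period, no spike upswing.
* One column: no layer 4, no horizontal interactions between columns, no
  distance-dependent connectivity.
* A single global synapse parameter block per receptor type; projections
  do not have private kernel constants (the experiments never vary them).
* The stimulus waveform is a modeling decision (section 4), and absolute
  assay numbers depend on it; only directional comparisons between
  parameter sets should be read off the bundled defaults.
* Long-term plasticity and stochastic vesicle release are out of scope.
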