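---
title: "Methods: an orientation-selective spiking network with tempotron read-out"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an orientation-selective spiking network with tempotron read-out}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spikevision classifies 28×28 grayscale images with a hierarchical spiking
network modeled on the early visual cortex: oriented-energy V1 responses,
a spiking V2 orientation layer, single-spike latency coding and a multiclass
tempotron decision layer. This vignette explains each stage, the parameters
that matter, the numerical choices, and what the synthetic benchmarks do and
do not demonstrate.

## The V1 front end

Simple cells are modeled as oriented linear filters: a quadrature pair of
second- (even) and third- (odd) derivative-of-Gaussian kernels across the
preferred orientation, at 28 orientations uniform over [0°, 180°) and three
spatial scales (σ = 1, 2, 4 px, support truncated at 3σ), giving 84 channels
per pixel. Complex cells pool each quadrature pair into phase-invariant
energy, `sqrt(even² + odd²)`, and the energy is mapped linearly to firing
rates on a 0–400 Hz scale by dividing by each channel's theoretical response
ceiling (the positive-part sum of the kernel, the largest response any
image valued in [0, 1] can evoke).

A static image is first replicated into a 20-frame movie of 50 ms frames
(1 s of stimulation), because the energy front end is defined over movies.
For a static stimulus the temporal dimension carries no information, so the
temporal kernel is all-pass and identical frames are computed once; the
84-channels-per-pixel structure is preserved exactly. Direction (motion)
selectivity is deliberately out of scope.

Filtering is same-size zero-padded cross-correlation, evaluated by FFT with
kernel transforms cached per bank and image size. Rates are converted to
homogeneous Poisson spike trains by Bernoulli thinning in 1 ms bins
(`rate·dt` must stay below 1 per bin; 400 Hz at 1 ms gives p = 0.4).

## The V2 orientation layer

V2 holds one 28×28 pool of regular-spiking (RS) Izhikevich neurons per
preferred orientation (4 pools = 3136 neurons by default; 2- and 8-pool
variants are supported). The membrane model is

    dV/dt = 0.04 V² + 5V + 140 − U + I_syn,   dU/dt = a(bV − U),

with reset `V ← c`, `U ← U + d` when V reaches 30 mV (RS: a = 0.02, b = 0.2,
c = −65, d = 8; FS: a = 0.1, b = 0.2, c = −65, d = 2). Synapses are
conductance-based with four receptors (τ in ms): AMPA 5, NMDA 150 with the
magnesium-block gate ((V+80)/60)²/(1+((V+80)/60)²), GABAa 6, GABAb 150.
Reversal potentials are not part of the published constants; we use the
standard simulator values 0 mV (AMPA/NMDA), −70 (GABAa), −90 (GABAb),
configurable. The synaptic drive enters as `I_syn = −Σ g·gate·(V − v_rev)`,
the sign convention under which excitatory conductance depolarizes.

Integration uses dt = 1 ms with two 0.5 ms half-steps for V (clamped at 30
mV) and one Euler step for U — the update ordering of the original published
implementation of the model, with the threshold test at step entry so that
the reset step performs no integration. Conductances decay by the exact
exponential factor rather than an Euler approximation.

Each V2 neuron at pixel p with preferred angle θ receives the 84 V1 channels
at p with Gaussian weight `w(φ) = w₀·exp(−d(θ,φ)²/2σ²)` in the circular
orientation distance d (period 180°), σ = one angular step (45° at four
pools): broad tuning, as the architecture requires. The anti-preferred pool
(θ + 90°) sends a direct GABAergic synapse of weight 0.5·w₀ — inhibitory
interneurons are not modeled explicitly, a declared simplification. The peak
weight w₀ = 0.06 was calibrated once so that a full-contrast oriented bar
drives its preferred pool to ≈400 Hz, the top of the rate scale; it is not
re-tuned per experiment.

A deterministic **rate-based shortcut** computes the same Gaussian-pooled,
inhibition-corrected orientation response directly from V1 rates, skipping
Poisson sampling and spiking integration. It is the default preprocessing
path (the two paths agree on pool rankings; the test suite checks rank
correlation > 0.9 on synthetic digits) and makes preprocessing roughly two
orders of magnitude faster. The spiking path remains first-class and fully
tested.

## Latency coding

V2 rates are normalized to [0, 1] and each neuron emits a single spike at

    t = (1 − f) · T,

so stronger responses fire earlier. Normalization is per image by default
(the strongest neuron of every image fires at t = 0, making the code
contrast-invariant); a global 400 Hz denominator is available, since the
original account does not say which was used. A neuron with f = 0 lands
exactly on the window edge t = T and is flagged inactive: edge spikes are
excluded from membrane integration and learning. Times are kept at floating
precision; the kernel below is evaluated analytically, so no binning is
needed. The default window T = 400 ms is the model's stated operating point.

## The tempotron decision layer

Each of the output neurons (one per class) integrates

    V_j(t) = Σ_i w_ij Σ_{t_i} K(t − t_i) + V_rest,
    K(s) = V₀ (e^{−s/τ} − e^{−s/τ_s}),  s > 0,

with τ = 16 ms, τ_s = 4 ms, V_rest = 0, threshold 1. V₀ normalizes the
kernel peak to 1; the closed form V₀ = 1/[e^{−t*/τ} − e^{−t*/τ_s}] with
t* = ττ_s ln(τ/τ_s)/(τ−τ_s) gives 2.12 at the defaults. If V crosses
threshold, the output spikes and all later input spikes are shunted: the
post-spike trace carries only the PSPs of earlier inputs and decays back to
rest.

Training is the error-correcting rule. For each sample the labeled output
must fire (P+) and the other outputs must stay silent (P−); on an error the
weights change by ±λ·K(t_max − t_i) for all afferent spikes before t_max,
the time of maximal voltage. λ = 0.001 for both error types (the update rule
permits asymmetric rates; equality is our default, not an established fact),
weights start at 0.001, and each sample's corrections repeat — re-evaluating
all outputs each round — until its ten conditions hold or 100 rounds pass
(the cap is non-binding in practice; typical counts are ~5 P+ and ~1 P−
corrections). Samples are visited in a seed-controlled shuffled order, for
at most 5 epochs by default, stopping early after an error-free epoch.

Numerical choices: voltages are evaluated on a 1 ms grid over [0, T] with
the kernel computed exactly at grid points (the sum is closed-form; no ODE
integration); t_max is grid-resolved with ties broken earliest, and
`find_tmax(refine = TRUE)` optionally sharpens it by golden-section search
between grid points. t_max for a P− error is taken from the unshunted trace
(the maximal postsynaptic potential). Classification is argmax of the
unshunted peak voltage — shunting only shapes spike generation during
training — with ties resolved to the lowest class index.

## Synthetic data

The generator renders anti-aliased oriented strokes with positional jitter
(σ = 1.5 px), angular jitter (σ = 5°) and additive uniform background noise
on [0, 20] of 255. The default four classes carry one dominant stroke each
at 0°, 45°, 90°, 135°, so each class's orientation signature lands in a
distinct V2 pool — the separability property that makes a handwritten "1"
light up the vertical pool. `synthetic_digit_templates()` adds ten
seven-segment-style digit classes that share most of their orientation
content and differ mainly in spatial arrangement; they are markedly harder
and closer to handwritten digits.

What the synthetic benchmarks show: that the full chain — energy model,
spiking orientation layer, latency code, tempotron — extracts and classifies
orientation signatures end to end, deterministically and from a cold start.
What they do not show: performance on real handwritten digits, whose
within-class variability (stroke curvature, thickness, style) far exceeds
the generator's jitter. MNIST IDX files are never bundled or downloaded; the
reader/writer is bit-exact and the command-line interface will run the same
pipeline on user-supplied IDX files.

## Experiment sizes and known limitations

The packaged experiments are scaled to run quickly on one CPU: the
end-to-end four-class benchmark uses 100 training and 50 test samples per
class over three seeds; the encoding-window sweep uses the ten digit-like
classes at 15 training and 10 test samples per class with T ∈ {50, 400,
2000} ms. At that operating point accuracy peaks at the moderate window
(0.73 vs 0.72 at T = 50 and 0.51 at T = 2000 in our runs): compressing the
code into 50 ms smears the PSPs of τ = 16 ms together, and stretching it to
2000 ms pushes all but the latest spikes beyond the reach of the voltage
maximum.

Limitations worth knowing:

* The large-T degradation is robust; the small-T degradation is weak in this
  synthetic emulation and can invert with more training data (single-stroke
  classes remain separable from late-firing afferents alone). Expect the
  clean interior optimum mainly on tasks with overlapping orientation
  content.
* Rotation covariance of the filter bank is exact at the coarsest scale
  (σ = 4 px; verified for all 28 orientation steps). At σ = 1–2 px a 28×28
  grid cannot render a 6.4° rotation faithfully and the maximally responding
  channel snaps to the axis orientations — a stimulus-resolution limit, not
  a filter property.
* The simple→complex pooling is quadrature energy; the original
  motion-energy formulation leaves the pooling weights to its sources, and
  energy pooling is the declared variant here.
* V2 inhibition is direct cross-pool GABA, not an explicit interneuron
  population.
* No synaptic delays, short-term plasticity, STDP, or current-based (CUBA)
  synapse mode; V1→V2 weights are fixed (only the tempotron layer learns).
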