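---
title: "Feature-specific inhibition-stabilized networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-specific inhibition-stabilized networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Cortical networks are widely thought to operate as inhibition-stabilized
networks (ISNs): the recurrent excitatory subnetwork alone would be
unstable, and is held in check by recurrent inhibition. The classical
experimental signature is the *paradoxical effect* — reducing the external
input to inhibitory neurons *increases* their average activity. This
package studies the feature-specific extension of that idea: when both
excitatory and inhibitory connectivity are organized by functional
similarity (preferred orientation, or full receptive-field correlation),
the network carries *specific* unstable eigenmodes stabilized by matching
specific inhibition. Such "specific ISNs" exhibit a *specific paradoxical
effect*: across inhibitory neurons, the change in rate is anti-correlated
with the per-neuron input perturbation — but only when the perturbation
pattern is aligned with the network's specific eigenmode. Nonspecific or
shuffled perturbations, nonspecifically connected networks, and weakly
coupled (non-ISN) networks all produce a positive relation, even though
most of them still show the classical mean-level paradoxical effect.

The package implements the full simulation-and-analysis pipeline: synthetic
receptive fields and stimulus ensembles, similarity-modulated weight
matrices, rate and spiking dynamics, perturbation protocols, the slope and
transition metrics, and the closed-form linear-response theory used as an
analytic oracle. The `analysis/` scripts at the repository root run each
figure-level experiment and write summary tables under `results/`.

## Models

### Rate dynamics

Rates follow `tau dr/dt = -r + ([W r + s]+)^n` with time constant
`tau = 10` (simulation time units), half-wave rectification, and
nonlinearity exponent `n = 1` (threshold-linear) by default; `n > 1` gives
the expansive power-law variant. Integration is forward Euler with
`dt = 0.1` (`dt/tau = 0.01`). A perturbation experiment simulates a
baseline window `[0, 300)` followed by a perturbation window `[300, 700)`
and averages rates in each window after discarding the first third as
transient. A configurable ceiling (default `1e6`) converts runaway
trajectories into an instability error; strongly expansive networks
(`n = 5`) can trip it.

With `n = 1` and no rectified unit, the steady state solves
`r = W r + s` exactly, and an inhibitory-input perturbation changes
inhibitory rates by `dr_I = M ds_I` with
`M = [I - W_IE (I - W_EE)^{-1} W_EI - W_II]^{-1}`. When the perturbation is
aligned with a specific eigenvector of eigenvalue `lambda` whose inhibitory
counterpart is `-g` times the excitatory profile, the per-neuron response
slope is `(1 - lambda) / (1 - (1 - g) lambda)` — negative exactly when
`lambda > 1` *and* `g > 1`, the specific-ISN condition. These closed forms
are implemented in the theory module and cross-checked against brute-force
linear solves and against simulation.

### Spiking dynamics

Leaky integrate-and-fire neurons with exact integration of the leak:
`V <- V exp(-dt/tau_m)` per step (`tau_m = 20` ms, `dt = 0.1` ms), spike
threshold 20 mV, reset 0 mV, no refractory period, delays or conductances.
Each presynaptic spike adds its weight (mV) to every postsynaptic membrane
in the *next* simulation step, which makes the update independent of
neuron ordering within a step. External drive is an independent Poisson
stream per neuron with jump +2 mV. The baseline stream rate (800 events/s)
is a calibration choice placing baseline excitatory rates near 2–3
spikes/s, in the sparse-firing range of sensory cortex; the external rate
and jump size are free parameters of the model family, fixed once here. Spiking perturbations scale each inhibitory
neuron's external rate by `(1 + delta_s)` (relative units, floored at 0).

### Connectivity

All-to-all weights without autapses (self-connections are zeroed, the
standard convention; at these sizes the diagonal is negligible *except* when inhibitory weights are
rescaled far upward — see the broad-inhibition calibration below). Two
rules:

* **Ring (1D)**: `w_ij = J_b (1 + m_b cos 2(theta_i - theta_j))` per block
  `b` in {EE, IE, EI, II}, with preferred orientations uniform on
  `[0, pi)`.
* **RF correlation**: `w_ij = J_b (0.1 + m_b exp(eta psi_ij))` with
  `psi_ij` the Pearson correlation of the neurons' rasterized Gabor
  receptive fields and `eta = 2`.

Standard rate parameters: `N_E = N_I = 400`, `J_EE = J_IE = 0.05`,
`J_EI = J_II = -0.075` (the weak non-ISN control uses `0.001 / -0.0015`);
`m = 1` for the ring network, `m = 0.5` for the RF network. Spiking:
`N_E = N_I = 500`, `J = 2 / -4` mV. Optional modifiers: per-synapse
multiplicative noise `zeta ~ U[0, 2]` (mean- and sign-preserving) and
heterogeneous per-synapse specificity `m_ij ~ U[0, 1]`.

**Why the rate networks default to deterministic kernels.** At the standard
weights, i.i.d. `zeta` noise on every synapse of an 800-neuron matrix
contributes a random-bulk spectral radius above 1 on its own. The interior
fixed point then becomes linearly unstable, rectification silences roughly
half the population, and the specific paradoxical slope degrades to a weak,
barely significant value — at odds with the strong, magnitude-robust
negative slopes and fully active baseline profiles this model family is
supposed to produce. With the deterministic kernel the ring network is
stable (leading eigenvalue 0.15), inhibition-stabilized (E-block eigenvalue
about 20), and the patterned slope is strongly negative at any perturbation
size. `zeta` therefore defaults to off for the rate configurations (the
flag, and tests of its mean/sign-preservation, remain), and to on for the
spiking networks, whose results are robust to it.

## Synthetic data

Receptive fields are 2D Gabor functions on a 200 x 200 pixel grid spanning
50 degrees at 4 pixels/degree: orientation and phase uniform on `[0, pi)`,
envelope SD 2.5 degrees, aspect ratio 0.5 (squared in the envelope, the
standard Gabor parameterization; a flag selects the unsquared variant),
spatial frequency gamma-distributed (shape 2, scale 0.04; mean 0.08
cycles/degree), centres jittered within ±1.25 degrees. Stimulus ensembles
are (a) fields drawn from the *same* generative model ("RF-statistics"
stimuli), (b) full-field gratings with fixed spatial frequency 0.04, or
(c) gratings with the RF frequency distribution. A stimulus modulates each
neuron's input by `1 + beta * cor(RF, stimulus)` (`beta = 0.5` for
RF-statistics stimuli, 1 for gratings).

This generator emulates the *statistics* of visual receptive fields and
their pairwise similarity, which is all the connectivity rule consumes. It
does not emulate natural-image content, retinotopy beyond centre jitter,
colour, or measurement noise — so passing tests show that the perturbation
protocols work when similarity is estimated from responses to structured
stimuli, not that they survive the estimation noise of calcium imaging.

## Perturbation protocols and metrics

Patterns over the inhibitory population: nonspecific
(`U[-2 gamma, 0]`, support matched to the 1D pattern so slope comparisons
are like-for-like), orientation-patterned (`gamma (sin 2 theta* - 1)`,
always nonpositive; the sign convention follows the negative-perturbation
axis of the experiments, with the opposite printed form behind a flag),
similarity-patterned (`-gamma exp(kappa psi_k)` toward a reference cell k,
`gamma = 0.25`, `kappa = 2`), plus shuffled, partial (random subset, or the
most similar units), rescaled and sign-flipped transforms.

The *slope metric* is the OLS slope of per-neuron inhibitory rate change
against the per-neuron perturbation, with its two-sided t-test; a
significant negative slope flags the specific paradoxical effect, while
opposite signs of the mean change and mean perturbation flag the
nonspecific one. For *partial* perturbations the fit runs over the
perturbed cells: the zeroed complement has no protocol-driven abscissa, and
a linear-response decomposition shows that including it adds a positive
mask-noise term that swamps the specific component at any fraction below
about 90% — with the perturbed-cell fit, the slope progresses from clearly
positive (10% perturbed) through near zero (50%) to significantly negative
(70%).

Population selectivity uses the doubled-angle circular mean
`R = sum r_j exp(2 i theta_j) / sum r_j` per 10-ms window over active
excitatory neurons (at least 5 active required); the population PO is
`arg(R)/2` mapped to `[0, pi)` and the OSI is `|R|`. (A printed variant
with period-1 phases exists behind the `doubled` flag, but it cannot
return an orientation; the doubling is forced by the pi-periodicity.) The
spontaneous-transition index builds the histogram of selective-window POs
(OSI > 0.5, 24 bins over `[0, pi)`), takes `H_osi` as the histogram's own
doubled-angle selectivity, and reports
`STI = (1 - H_osi) * <pop OSI over selective windows>`; zero selective
windows give STI 0 with a degenerate flag rather than an error, so sweeps
never crash. The bootstrap shuffles every neuron's activity independently
across time windows, 100 times, and reports the observed STI minus the
null mean.

## Design choices made where the design was open

* **Tuned input.** The evoked drive is
  `base [(1 - f) + f (1 + cos 2(theta* - theta_stim))]`: the tuned
  component is normalized to unit mean, so the "specific input" fraction
  `f` changes tuning without changing total drive. The halved-mean variant
  (peak capped at `base`) conflates input specificity with overall drive
  reduction and distorts the spontaneous/evoked comparison.
* **Broad-inhibition recalibration.** Broadening the IE/EI/II specificity
  to `m_broad` leaves a residual specific excitatory eigenvalue of about
  `N_E J_EE (m_EE - m_broad)/2`, so a stable recalibration only exists for
  `m_broad > 1 - 2/(N_E J_EE m_EE)` (0.9 at the standard weights); the
  default is 0.95. The common factor on `|J_EI|, |J_II|` is found by
  scanning a geometric grid for the smallest stabilizing value, because
  stability is not monotone in the factor: without autapses, scaling
  inhibition also removes ever larger self-inhibition from the diagonal.
* **Theory-oracle conditions.** The 1%-level comparison between simulated
  response changes and `M ds_I` is run with the deterministic kernel and
  near-uniform baseline input (jitter 1%), because the identity only holds
  at an interior fixed point; the check verifies interiority and the
  measured relative error is about `1e-5`.
* **Reference-cell sweeps.** Response correlations are computed for all
  inhibitory neurons from their per-stimulus mean responses (each 200-unit
  presentation integrated from the shared baseline state; window means
  discard the first third). Batching the stimuli and the reference cells
  as columns of one matrix integration is exact — columns are independent —
  and keeps the 400-reference sweep within minutes. The responsiveness
  filter keeps units above the 20th percentile of mean activity; only
  responsive units serve as references.
* **Eigenmode orderings.** Eigenvector-versus-similarity profiles report
  Spearman alongside Pearson correlations; similarity enters the weights
  through a monotone exponential, so rank correlation is the faithful
  measure of "ordered by similarity".

## Numerical conventions and degenerate inputs

Seeds control every random draw; seeded runs are bit-reproducible
(including the spiking simulator, whose external Poisson counts come from
R's RNG in a fixed neuron-major order, verified spike-for-spike against a
straight-line reference implementation). Eigenvectors are normalized to
unit norm with the largest-magnitude excitatory component made real and
positive. Zero-variance fields make correlations error; constant
perturbation vectors make the slope fit error; windows shorter than the
transient discard error; fewer than 3 responsive units error. The
perturbation-window instability guard propagates as an error rather than
returning garbage.

## Problem sizes

The test-suite and acceptance runs use the standard sizes: 400 + 400 rate
networks with 200-stimulus ensembles and all-responsive-reference sweeps,
500 + 500 spiking networks with 10-second spontaneous rasters (10-ms
windows, 100-shuffle bootstraps) and a 6-point specificity grid, chosen to
keep a full run on one CPU within tens of minutes. Unit tests use reduced
instances (up to ~120 neurons) with closed-form or brute-force oracles.

## Known limitations

One inhibitory class only (no SOM/VIP disinhibitory motifs), no synaptic
delays or short-term plasticity, no conductance-based synapses, no
plasticity mechanism for how specific EI connectivity emerges, and no
claim about real cortical data: the package characterizes the model
family's dynamics and the perturbation protocols that reveal them. The
bootstrapped transition index compares against a time-shuffle null whose
standard deviation shrinks with the number of windows; for strongly
specific networks under tuned input the genuine residual wobble of the
selective state therefore remains statistically above that null even
though its magnitude is strongly quenched — judge evoked conditions by the
STI magnitude, not the shuffle z-score.
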