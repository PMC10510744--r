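---
title: "Modeling neural adaptation to changing background noise with dynamic STRFs"
author: "dstrfadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling neural adaptation to changing background noise with dynamic STRFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Auditory cortex maintains a usable representation of speech while the
acoustic background changes abruptly — a street, a restaurant, an
aircraft cabin. Intracranial recordings show that high-gamma responses
adapt within a few hundred milliseconds of a background switch. The
classical encoding model for such data, the spectro-temporal receptive
field (STRF), is a single linear filter and cannot express this
adaptation; a convolutional network (CNN) can, but is opaque unless its
computation is re-expressed in filter form. This package implements that
full analysis chain on simulated data with known ground truth:

1. **Stimulus/response simulation** (`buildSession()`,
   `simulateResponses()`): 23-band, 100-Hz spectrograms of speech-like
   foregrounds mixed at 6 dB SNR with backgrounds that switch every 3 or
   6 s between clean and three noise classes, plus electrode responses
   generated by encoders with known adaptive structure.
2. **Encoding models** (`fitStrf()`, `trainCnn()`, `fitStp()`) fit under
   a leave-one-block-out jackknife (`jackknifeFit()`).
3. **Dynamic STRF extraction** (`dstrfTimecourse()`): the exact local
   linearization of the CNN at every time point, averaged over jackknife
   members under a sign-consistency mask.
4. **Adaptation metrics** (`gainChangeIndex()`, `noiseFilteringIndex()`,
   `adaptationIndex()`) and **population statistics**
   (`fitImprovementModel()`, `clusterNoiseFiltering()`,
   `compareGroups()`).

## The dSTRF: exact linearization of a ReLU CNN

The CNN is a stack of causal dilated 1-D convolutions with ReLU
activations and *no hidden biases*; only the final per-electrode linear
projection carries a bias. For any fixed input window, each ReLU is
either open or closed, so the network output is an exactly linear
function of the input within the region where no ReLU flips:
\(\hat y_t = \langle \mathrm{dSTRF}(x_t),\, x_t\rangle + b\).
Because hidden layers are bias-free, the dSTRF equals the gradient
\(\partial \hat y_t / \partial x_t\), which `computeDstrf()` obtains by
reverse-mode accumulation through the frozen activation pattern rather
than by materializing per-layer masked weight products; the two are
algebraically identical, and `dstrfLinearityCheck()` enforces the
identity (observed relative error is at machine precision, bounded in
tests at 1e-4).

Two conventions matter:

* Gradients at a ReLU kink (pre-activation exactly 0) use subgradient 0,
  the standard autodiff convention; the set has measure zero.
* The network consumes per-band z-scored input (normalization constants
  are estimated on each member's training blocks and stored in the
  model). The exact linearity identity holds in those normalized units;
  for the scientific analyses the frames are converted to raw
  spectrogram units (dividing by the per-band scale) so that members
  with slightly different normalizations average coherently and the
  lag-averaged profiles are comparable with noise spectra. The constant
  offset introduced by input centering is absorbed in the effective
  bias and does not affect gains, correlations, or indices, all of
  which ignore the intercept.

The jackknife average applies the reference sign-consistency rule: a
lag-frequency bin is kept only if at least 15 of 17 members agree on a
strict sign (zeros count toward neither sign); reduced ensembles with M
members use `ceiling(M * 15/17)` (`defaultMaskThreshold()`). Masked
averaging is idempotent, monotone in the threshold, and tested as such.

## The jackknife

With B blocks, each held-out test block gets an ensemble of B − 1
members, member m excluding the test block and one further block; test
predictions and dSTRFs are member averages (17 members when B = 18).
Member seeds are distinct, derived deterministically from the top-level
seed. Predictions (and dSTRF frames) may use stimulus context from
before a block boundary: the stimulus is always observable, only the
responses are partitioned, so no response leakage occurs and every
block sample is predicted exactly once.

## Ground-truth encoders

Every simulated electrode is one of four generative mechanisms applied
to a smooth random Gabor-like base filter (excitatory lobe plus delayed
inhibitory sideband, calibrated to unit-order drive variance):

* `static_linear`: r(t) = softplus(drive + driveBias).
* `gain_adaptive`: the same response premultiplied by
  g = k (c + 0.3)^(−α), where c is the population SD of all
  spectrogram bins in a trailing 1-s window and the gain state relaxes
  toward its target with time constant τ (default 0.25 s). The 0.3
  floor bounds the gain during the silent lead-in (where c → 0 and the
  bare power law diverges); k defaults to 0.85 so g ≈ 1 at typical
  clean-speech contrast.
* `noise_filtering`: the filter acquires an inhibitory component
  matched to the current noise class's unit-norm spectrum (exponential
  approach with τ after each transition, lag footprint e^(−lag/0.1 s)).
  `suppressionMode = "inhibitory_only"` restricts the component to bins
  where the base filter is ≤ 0, giving a population that suppresses
  noise only through its inhibitory field; because that restricted
  footprint carries less mass, an inhibitory-only population is planted
  with a correspondingly deeper suppression so the mechanism remains
  expressible.
* `ln_stp`: the rectified drive is depressed by the two-parameter
  Tsodyks–Markram resource (release fraction u, recovery τ_rec;
  x' = (1−x)/τ_rec − u·x·drive, clipped to [0,1]) and passed through a
  Gompertz ("double exponential") nonlinearity
  y = base + a·exp(−exp(−k(v − v₀))).

Observation noise is additive Gaussian at the response stage; responses
are z-scored to the 2-min silent lead-in (skipped, and recorded, for
noiseless electrodes whose baseline variance is zero, so the
convolution-oracle identity can hold exactly). `driveBias` (default 3)
sets a spontaneous-activity-like operating point; it keeps the softplus
rectifier mostly in its linear range, which is what makes the "static"
encoder genuinely static in its linearization. An optional
`transientAmp` adds an exponentially decaying response transient (τ =
0.3 s) at every transition, the controllable ground truth for the
adaptation index.

Design choices the simulator deliberately makes, and their limits:
spectrograms are generated directly in the 23-band domain (no audio);
"speech" is formant-like drifting peaks with a 2–8 Hz envelope and
< 300 ms gaps, not intelligible speech; the condition sequence is a
balanced random walk with no immediate repeats, not the original
stimulus order. Passing tests therefore demonstrate that the analysis
pipeline recovers planted adaptive structure under realistic geometry
and SNR — not that it would behave identically on real iEEG.

A second empirical property: the contrast-gain mechanism, at 6 dB SNR
and with gain excursions of 10-20% between conditions, is almost
entirely capturable by a single linear filter (the gain is a smooth,
slowly varying multiplier, and a ridge STRF absorbs most of its
variance); the clearly nonlinear population at this scale is the
noise-filtering one, whose receptive-field shape changes give the CNN a
large held-out advantage concentrated in the post-transition window.

A property of the mixtures worth noting: steady, spectrally concentrated
(jet-like) noise *lowers* segment contrast relative to clean speech
because it fills the silent gaps, while strongly modulated (bar-like)
noise raises it. Gain-index signs around transitions therefore follow
the measured contrast change of each transition type, not a blanket
"noise = more contrast" rule; this matches the contrast-gain-control
literature, where additive noise typically reduces spectro-temporal
contrast.

## Indices

All indices are paired t statistics over the 50 (or 70) within-window
positions of the transition-averaged time course: gain-change compares
dSTRF gain (SD of all filter bins; excitatory/inhibitory variants zero
the other sign and keep the zeros in the population) in [−0.5, 0) s
versus [0.65, 1.15) s; noise-filtering does the same for the
correlation between the lag-averaged (region-zeroed) dSTRF profile and
the incoming background spectrum, sign-flipped so positive = steering
away from the new noise; the adaptation index compares the response in
[0, 0.7) s versus [2, 2.7) s (3-s segments lack the late window and are
excluded with a count). Windows are half-open at 10-ms resolution and
the transition sample belongs to the post-transition condition.
Positional pairing (rather than (transition, timepoint) pairs) follows
from the windowed definition and gives a fixed df; it is the package
default and the alternative would simply widen the t distributions.
Zero-variance differences are capped at ±1e6 and flagged; windows with
under 50% frame coverage yield missing indices rather than silent
zeros. For transitions to clean, the correlation target is the
time-averaged foreground-only spectrogram over the whole stimulus
(silent gaps included — they are part of what "speech" looks like to
the models).

Only clean→noise and noise→clean transitions enter the aligned gain and
correlation time courses (noise→noise transitions have no common
baseline); the contrast/gain coupling across transitions uses every
transition, grouped by (from, to) type.

## Statistical layer

Subject-controlled t-tests regress electrode values on an intercept
plus sum-coded subject indicators and report the intercept's t — with
one subject this is exactly the one-sample t-test, and per-subject
offsets are absorbed by the subject terms. The improvement model is
`improvement ~ gain_change + noise_filtering + (1 | subject)` per
condition (random intercept only, as only a subject random effect is
specified; a fixed intercept is included as standard practice), fit
with lme4 and falling back to OLS with a warning when the random-effect
variance is singular. Electrode groups come from Ward (minimum
variance) clustering on Euclidean distance over the eight
noise-filtering indices (excitatory and inhibitory × four
to-conditions), cut at k = 2, group 1 being the group with the higher
mean excitatory to-noise index. The timepoint-wise group comparison
uses uncorrected rank-sum p < 0.05, flagged as such in the output.

## Problem sizes and numerical choices

The package's own reduced-scale configuration (used by the test suite
and `defaultConfig("demo")`) runs 4 blocks of 36–45 s, a 24-kernel CNN,
3-member ensembles with mask threshold 3, and dSTRF frames restricted
to the ±transition windows the indices consume; at this scale one full
session analysis takes a few minutes on one CPU. The reference-scale
configuration (18 × 60 s blocks, 128 kernels, 17 members, mask 15) is
`defaultConfig("paper")`. Training hyperparameters at reduced scale
deviate from the reference defaults where the data volume demands it:
with ~90 s of training data per member we use weight decay 0.07 and
learning-rate decay 0.98-0.985/epoch (defaults 0.03 and 0.996), because
at this scale the weaker regularization leaves visibly noisier
instantaneous gradients (unstable dSTRF frames) while prediction
accuracy is unchanged. The base learning rate (2e-3) is not specified
by the reference description and is exposed as a parameter. Training
is minibatch (250-500-sample windows with receptive-field context,
reshuffled per epoch), full MSE across electrodes, RAdam updates, early
stopping on one held-out block with patience; the output bias starts at
the training-mean response. The model that is validated and returned is
a bias-corrected exponential moving average of the weights (decay 0.9
per epoch): the last SGD iterate carries minibatch jitter that leaves
predictions untouched but visibly destabilizes the instantaneous
gradient, and weight averaging removes it at no extra cost (set
`emaDecay = 0` for the raw iterate). All randomness derives from one
integer seed through named substreams (`deriveSeed()`), and identical
seeds give bit-identical sessions, fits, and dSTRFs.

Known limitations and one load-bearing observation: the simulator's
four mechanisms are caricatures (one mechanism per electrode; real
sites mix them). The shared CNN trunk couples electrodes fit together:
when heterogeneous populations share all convolution layers, one
population's adaptation dynamics bleed into the dSTRFs of the others
(static electrodes co-fit with many gain-adaptive ones acquire spurious
gain dynamics; gain electrodes co-fit with many noise-filtering ones
lose their index signs). The package therefore fits each synthetic
population with its own jackknifed model — structurally the same thing
the per-subject models of a multi-subject recording do — and any
shared-backbone encoding analysis should expect the same effect.
Finally, with 3-member ensembles the sign-consistency mask (3 of 3)
zeroes roughly half of all bins, which is stricter in proportion than
15 of 17; mask density varies a few percent with the background
condition, which puts a floor on how small a condition-dependent gain
effect can be read off masked frames.
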