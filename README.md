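# dstrfadapt

Dynamic spectro-temporal receptive fields (dSTRFs) and neural adaptation
to changing background noise — a simulation and analysis package for
computational auditory neuroscience.

## The problem

Human auditory cortex adapts within a few hundred milliseconds when the
acoustic background changes (street noise → restaurant → quiet),
keeping speech representations stable. A linear spectro-temporal
receptive field (STRF) cannot express such adaptation, and nonlinear
models that can — convolutional networks in particular — are opaque.
The analysis implemented here resolves that tension: a causal dilated
ReLU CNN without hidden biases is *piecewise linear*, so at every time
point it applies one exact linear filter to its input window, and that
filter — the **dSTRF** — equals the input gradient
`dSTRF(x_t) = ∂ŷ_t/∂x_t`. Watching the dSTRF move around background
transitions reveals the model's adaptive computation in STRF-like,
interpretable form:

* **Adaptive gain control** — dSTRF gain (the SD of its lag-frequency
  bins) moves opposite to stimulus contrast (the SD of all
  spectrogram bins in a segment);
* **Noise filtering** — the filter's inhibitory region steers away
  from the spectrum of a newly appearing background noise.

Because the original intracranial recordings cannot be public, the
package ships a first-class synthetic-session generator with known
ground truth: 23-band, 100-Hz spectrograms of speech-like foregrounds
mixed at 6 dB SNR with backgrounds switching every 3/6 s between clean
and three spectrally distinct noise classes, and electrode responses
produced by static-linear, contrast-gain-adaptive,
noise-band-suppressing, and LN + Tsodyks-Markram short-term-plasticity
encoders, z-scored to a 2-min silent lead-in. Every stage of the
pipeline is therefore testable against a recoverable ground truth.

Quantities computed per electrode: held-out prediction correlations
under a leave-one-block-out jackknife (B−1 member models per test
block, member mean as the prediction, sign-consistency-masked member
average for the dSTRF); gain-change, noise-filtering, and adaptation
indices (paired-t statistics over fixed windows around transitions);
mixed-effects prediction of CNN-over-STRF improvement from the indices;
and Ward clustering of electrodes into noise-filtering groups.

## Worked example

```r
library(dstrfadapt)

## a small session: 4 blocks x 30 s, 6 dB SNR, 2-min silent lead-in
session <- buildSession(nBlocks = 4, blockDuration = 30, snrDb = 6,
                        seed = 1)
enc <- c(makeEncoderPopulation("gain_adaptive", 3, seed = 2,
                               outputNoiseSd = 0.5),
         makeEncoderPopulation("static_linear", 2, seed = 3,
                               outputNoiseSd = 0.5))
session <- simulateResponses(session, enc, seed = 4)
session
#> SessionData
#>   stimulus: Spectrogram: 24000 samples x 23 bands @ 100 Hz (240.0 s)
#>   schedule: NoiseSchedule: 27 segments over [120.0, 240.0] s, 4 blocks, 120 s silent lead-in
#>   exposure (s): bar=30, city=33, clean=27, jet=30
#>   responses: ResponseMatrix: 5 electrodes x 24000 samples @ 100 Hz, 4 subjects
#>   encoders: gain_adaptive=3, static_linear=2

blocks <- blockIndices(schedule(session))
jkStrf <- jackknifeFit(stimulus(session), session@responses, blocks,
                       "strf", seed = 5)
jkCnn  <- jackknifeFit(stimulus(session), session@responses, blocks,
                       "cnn", seed = 6,
                       config = cnnConfig(nKernels = 24),
                       epochs = 100, weightDecay = 0.1, lrDecay = 0.98)

ana <- analyzeAdaptation(session, jkCnn, jkStrf)
head(subset(ana$indexTable, index_kind == "gain_change" &
                            condition == "bar"))
#>    electrode subject condition region index_kind value n_transitions
#> 1          1      S1       bar   full gain_change -4.31             3
#> ...
ana$coupling$correlation   # contrast-change vs gain-change coupling
#> [1] -0.41
```

A negative `gain_change` index means the model's dSTRF gain dropped
after a clean-to-bar transition (bar noise raises local
spectro-temporal contrast, so an adaptive-gain electrode turns its gain
down); the coupling correlation summarizes this across all transition
types, and the `improvement` columns of `ana$splitCorrelation` show how
much the CNN outperforms the STRF, overall and within the 650-ms
adaptation window. (Numbers shown are from one seed at this small
scale; exact values vary with the session configuration.)

`runExperiment(defaultConfig("demo"))` runs the whole chain — session,
jackknife fits, dSTRFs, indices, population statistics — with stage
caching and plain-text outputs (schedule TSV, index CSV, report JSON).
The methods vignette (`vignettes/dstrf-adaptation-methods.Rmd`)
documents the model, the estimators, every tunable parameter, and the
package's numerical choices.

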