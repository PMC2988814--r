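---
title: "Classifying fish species from single biosonar echoes: models and methods"
author: "echofish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying fish species from single biosonar echoes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echofish)
```

## The scientific problem

Dolphins and porpoises forage selectively, and field observations strongly
suggest they recognize prey species by biosonar alone. A fish's echo is shaped
by its swim bladder, internal surfaces and propagation paths, varies strongly
with the angle of ensonification, and differs substantially even between
individuals of one species. The question this package addresses is whether a
*single* echo, at an arbitrary and unknown aspect angle, carries enough
species-specific structure for statistical classification — and if so, which
spectro-temporal features carry it.

`echofish` implements a complete, reproducible desk-scale version of that
analysis: it simulates the emission signals and the fish echoes, extracts two
alternative representations (six Hilbert-envelope statistics; band-limited dB
spectrograms), classifies species with a quadratic discriminant analysis and
with linear maximum-margin classifiers, renders the learned weight vectors as
interpretable "decision echoes", and runs three validation procedures:
decision-echo smoothing, noise injection, and eigen-fish (PCA) resampling.

## Emission signals

Two emission styles are modeled after the signals used in tank backscatter
measurements with real fish:

* **dolphin-like** — 130 kHz spectral peak, 70 microsecond duration, broadband;
* **porpoise-like** — 138 kHz spectral peak, 270 microsecond duration,
  narrowband.

`makeClick()` builds each click as a tone burst at the peak frequency with
short Hann-shaped cosine ramps (7 samples per edge by default) at a 1 MHz
sampling rate. Two constraints drove this choice and they interact: the burst
support must equal the nominal duration to within a sample, and the duration
measured by `measureDuration()` — the inclusive span of Hilbert-envelope
samples above 1% of the peak (a −40 dB floor, our convention; field practice
varies and no single convention is canonical) — must also equal the nominal
duration. A full-length Hann envelope fails the second constraint: it crosses
the 1% level about 3% of the window in from each edge, so a 70 µs Hann burst
measures only ~65.5 µs. The short edge taper keeps every in-support sample
above the floor, so both constraints hold exactly, and the duration ordering
(and hence the bandwidth ordering: the 70 µs dolphin click is several times
broader-band than the 270 µs porpoise click) is preserved.

One compromise is worth stating plainly: a 70 µs burst at 130 kHz completes
about 9 carrier cycles, while real recorded dolphin-like signals of that
duration concentrate their energy in roughly 5 cycles; no near-rectangular
envelope can satisfy the duration, the peak frequency and the cycle count
simultaneously. We privilege duration and peak frequency — the two quantities
with quantitative anchors — and store the carrier cycle count
(`peakFrequency * duration`) as metadata.

`measurePeakFrequency()` zero-pads to 8192 points before the FFT, keeping the
frequency-grid error near 60 Hz, well below the 250 Hz we budget for.

## The echo simulator

No deposited recordings of the original tank measurements exist, so the
synthetic-data generator is a first-class component: it defines the study
conditions every downstream result refers to. Each species is a
`SpeciesModel`: a small set of internal point reflectors, each delaying,
second-order band-pass filtering and scaling the incident click:

$$ e(t) \;=\; \sum_k g_k(\theta)\, (h_k * s)(t - \tau_k(\theta)) \;+\;
   \varepsilon(t), $$

truncated to the 1024-sample (1.024 ms) acquisition window. Delays are
modulated sinusoidally with aspect angle $\theta$ (period 180°, as geometry
dictates for a roughly fore-aft symmetric body) and gains carry a broadside
lobe peaking at 90°/270°, so echoes vary smoothly but strongly around the
rotation. The three built-in presets contrast in reflector count and
frequency response:

| preset | reflectors | filter centers | interpretation |
|---|---|---|---|
| cod | 1 strong | 95 kHz, broad | large single swim bladder |
| mullet | 2 close | 118/132 kHz, narrow | two nearby reflectors, high-frequency response |
| bass | 3 weak | 78/104/142 kHz | weak reflectors spread across the band |

Individuals within a species share the preset but differ by anatomical jitter
(fractional SDs: 4% on delays, 15% on gains, 4% on filter centers), drawn
once per individual from a deterministic seed. Within-ping white noise has an
RMS of 5% of the echo peak. Neither the jitter scale nor the SNR is published
for the original measurements; these values were chosen once as a realistic
middle ground — strong enough that individuals are clearly distinct and
echoes visibly noisy, weak enough that a species' reflector geometry remains
recognizable — and are exposed as parameters, not revisited per result.

A full dataset is 3 species × 3 individuals × 144 angles (2.5° spacing; the
original rotation produced "approximately 145" pings, and we use the exact
144-step grid) = 1296 echoes per emission style, reproducible bit-for-bit
from one master seed. The aspect convention assigns angles within 45° of the
head–tail axis (boundary inclusive) to the *tail* sector and the rest to
*broadside*; on the default grid the inclusive boundary gives the tail sector
two extra angles per half-rotation, which we accept in exchange for a
deterministic rule.

What the generator does *not* emulate: physically calibrated target
strengths, frequency-dependent absorption, near-field effects, schooling
fish, or the detailed multipath structure of real swim bladders. Passing
classification tests on these data therefore shows that the *pipeline*
recovers species structure of the kind the physical argument predicts
(aspect-dependent multi-highlight echoes with species-specific spectral
coloring) — it does not certify performance on ocean recordings.

## Envelope statistics and discriminant classification

For the parametric branch, each echo is reduced to six statistics of its
Hilbert envelope $s_i$ (magnitude of the FFT-based analytic signal):

1. centralized second moment $m_2 = \frac{1}{N}\sum_i (s_i-\bar s)^2$;
2. normalized third moment $m_3/m_2^{3/2}$ (skewness);
3. normalized fourth moment $m_4/m_2^{2}$ (kurtosis);
4. crest factor $\max_i s_i / \sqrt{\tfrac1N\sum_i s_i^2}$;
5–6. amplitude $A$ and width $b$ of an exponential fit
   $P_i = A e^{-b x_i}$ to the 50-bin histogram of envelope amplitudes.

All moments use population (1/N) normalization; at $N = 1024$ the distinction
from 1/(N−1) is negligible but must be fixed, and 1/N makes the fitted model
an exact function of the per-class moments. The exponential fit uses
positivity-constrained nonlinear least squares (`minpack.lm`), initialized
from a log-linear fit on occupied bins; empty bins stay in the objective at
zero. Degenerate inputs (constant envelopes, single-bin histograms) return
flagged results rather than silent NaNs.

Classification uses a quadratic discriminant analysis: class-conditional
Gaussians with per-class covariances ridge-stabilized by adding
$10^{-6}\times\overline{\mathrm{diag}(S)}$ to the diagonal. Priors are class
frequencies (the default design is balanced, so this matches uniform priors).
Per-species accuracy is the per-class recall — the only per-species reading
consistent with reporting one number per species in a three-class task.

**Cross-validation protocol.** Ten repeats; each draws a random 10% test set;
every echo of the same individual within two angular positions (on the
circular rotation grid) of a test echo is excluded from training, so a
classifier is never trained on the immediate neighbours of an echo it is
tested on. Excluded echoes are not used as test items either. Significance is
a one-sided one-sample t-test of the repeat accuracies against the chance
level (33.3% for three balanced species); zero-variance repeat sets are
reported as exact comparisons with a degenerate flag.

## Spectrograms and the linear maximum-margin classifier

The machine-learning branch deliberately uses a representation available to
the odontocete auditory system: short-time magnitude spectra (100-point Hann
window, 90% overlap — 10 kHz × 0.1 ms resolution), a step band-pass keeping
only 60–150 kHz (10 frequency rows), dB scaling with a floor 80 dB below the
maximum (the floor is our choice; some floor is needed before taking logs),
and per-echo affine rescaling of the dB matrix to [0, 1] with maximum exactly
1. "Normalized to a maximum of 1" is ambiguous for signed dB values; we chose
min–max rescaling because it yields a bounded, sign-free input and apply it
identically at training and test time. Frames are left-aligned and the final
partial window is dropped, giving exactly (1024 − 100)/10 + 1 = 93 frames;
flattening is row-major (93 frames of the 60 kHz row first), 930 features.

`trainLinearSvm()` fits the soft-margin linear separator (decision rule
exactly $\mathrm{sign}(\langle w, x\rangle + b)$, ties to the positive class)
through libsvm (`e1071`), with the weight vector recovered from the
support-vector expansion; the default penalty is C = 1 (the original analysis
used an off-the-shelf SVM toolbox and never reported its penalty) and the
tests verify the trained separator against direct minimization of the primal
objective. Tasks are the three pairwise problems (chance 50%) and the three
one-vs-all problems. For one-vs-all, accuracy $1 - (FP+FN)/N$ is compared
against the majority-class baseline of 66.7% — a deliberate, conservative
choice, since class proportions are 1/3 vs 2/3 and no chance level is printed
for such tables. The cross-validation machinery (splits, exclusion, t-test)
is shared verbatim with the discriminant branch; whether the original SVM
protocol also used adjacent-echo exclusion is unstated, and we apply it
uniformly for consistency.

## Decision echoes and the three validation procedures

The weight vector reshaped to the 10 × 93 spectrogram grid is the **decision
echo**; regions of high absolute weight drive the species decision.

**Smoothing.** The decision echo is convolved with a 10 × 10 pixel 2-D
Gaussian kernel, width sigma = 7 pixels, normalized to sum 1 — exactly this
strongly truncated kernel, renormalized after truncation. Borders are handled
by index reflection, which preserves constant weight maps exactly; because
the weight matrix has only 10 rows while the kernel spans 10, some mass of
row-central structure reflects out of the matrix (an impulse keeps ~92% of
its mass), which we accept as inherent to smoothing a matrix no wider than
the kernel. The anchor of the even-sized kernel sits at pixel (5, 5): a
half-pixel shift, accepted and documented. Re-scoring uses the smoothed
weights with the *original* offset. High accuracy after smoothing indicates
the rule rests on broad spectro-temporal structure, not on pixel-level
artifacts of a small sample.

**Noise injection.** Gaussian noise with mean 10–50% of the spectrogram
maximum is added per pixel to *test* spectrograms only, while the classifiers
remain trained on clean data. Only the noise mean is specified by the
procedure we reproduce; we set the SD to half the mean so the perturbation is
predominantly positive, like added acoustic intensity, and expose it as a
parameter. Noisy spectrograms are deliberately not re-normalized: the trained
rule is tested exactly as learned. Because the noise mean is positive, it
shifts every decision value by roughly `level * sum(w)`; rules whose weights
have large positive sums are therefore biased at high noise — visible as
asymmetric degradation across species, which is informative rather than a
defect.

**Eigen-fish resampling.** For each species, the first k = 6 principal
components of its mean-centered spectrograms (6 because the design has three
individuals × two aspect sectors) form a basis; synthetic spectrograms are
the species mean plus Gaussian component weights with SD 3× the training
projection SDs ("much wider" is operationalized as widthFactor = 3,
configurable; the distribution family is our Gaussian assumption). The
default 1550 samples per species make the three-species total (4650) about
five times the 930-dimensional feature space, removing the n ≪ d regime in
which any labeling is linearly separable. Clean-trained one-vs-all models are
then scored on ten independently generated synthetic sets.

## Numerical choices and degenerate inputs

* FFT-based analytic signal; envelopes are exact for periodic signals and
  dominated by edge leakage otherwise (tests use integer-cycle tones where
  exactness matters).
* Angle-smoothness of the simulator is assessed on envelopes, not raw
  waveforms: a few microseconds of aspect-dependent delay shift decorrelates
  the 130 kHz carrier completely while leaving the envelope nearly unchanged,
  so the envelope is the quantity that is smooth in angle.
* Constant envelopes, single-bin histograms, all-zero waveforms, silent
  echoes, single-class training sets, double smoothing, out-of-window
  reflector delays: all raise errors or flagged degenerate results, never
  silent NaNs.
* All randomness flows from explicit seeds (master seed → individual anatomy
  seeds → per-ping noise seeds; CV seed → split draws; validation seeds →
  noise and resampling draws), so every table is bit-reproducible.

## Problem sizes

The default experiment — 1296 echoes per emission style, 10 CV repeats per
task, 10 resampling seeds — was chosen to mirror the original design while
remaining comfortable on a single CPU: the complete dolphin-style analysis
(generation, both feature branches, six classification tasks raw and
smoothed, noise and resampling validation) runs in about two minutes. The
test suite uses a 144-echo dataset (2 individuals, 15° spacing) for
structural checks and the full 1296-echo dataset for the end-to-end
acceptance checks.

## Known limitations

* The simulator is statistical, not physical: reflector presets were tuned to
  qualitative properties (aspect dependence, intra-species variability,
  species separability that degrades to chance as anatomical jitter grows),
  not to measured target strengths.
* Cross-validation mixes angles of the same individuals between training and
  test (as in the original protocol); the adjacent-echo exclusion reduces but
  does not remove the resulting optimism. Cross-individual generalization is
  exercised separately in the tests.
* The envelope-statistics branch discards all timing information by design;
  the spectrogram branch discards phase. Matched filtering / impulse-response
  estimation is intentionally out of scope.
* Real-data input is supported through the WAV + manifest interface but the
  shipped presets make no claim of matching any particular species'
  scattering physics.

## A worked example

```{r example, eval = FALSE}
library(echofish)

es <- generateEchoSet(masterSeed = 7)        # 1296 dolphin-style echoes
feats <- featureTable(es)
dfa <- crossvalidateDfa(feats, seed = 1)
dfa$cod

spectra <- computeSpectrograms(es)
runSvmTask(spectra, list(type = "pairwise", classes = c("cod", "mullet")),
           seed = 1)

model <- trainFullModel(spectra, list(type = "one_vs_all", species = "cod"))
de <- smoothDecisionEcho(decisionEcho(model))
image(de@timeAxis * 1e3, de@freqAxis / 1e3, t(de@weights))

runExperiment(experimentConfig(), "echofish-results")
```
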