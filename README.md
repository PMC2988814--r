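# echofish

Species classification of fish echoes from simulated biosonar signals.

## The problem

Echolocating dolphins and porpoises forage selectively, which implies they
can recognize prey species from the echoes of their own clicks. Fish echoes
are hard material for classification: they depend strongly on the aspect
angle of ensonification and vary widely between individuals of one species.
`echofish` is an R package for studying whether a **single echo at an
arbitrary angle** carries enough species-specific structure to classify the
species, and for interpreting *which* spectro-temporal features carry it. It
is aimed at bioacousticians and quantitative biologists who want a fully
reproducible, desk-scale version of this analysis — no tank, transducer or
fish required.

## What it does

Because no recordings from the original tank measurements were ever
deposited, the package ships a seeded synthetic-data generator as a
first-class component: echoes are sums of a few aspect-dependent internal
reflectors (swim-bladder-like) that delay, band-pass filter and scale a
simulated emission click (dolphin-like: 130 kHz peak, 70 µs; porpoise-like:
138 kHz peak, 270 µs), plus noise — 3 species × 3 individuals × 144 angles
(2.5° spacing) = 1296 echoes of 1024 samples at 1 MHz per emission style.

Two classification branches operate on these echoes:

1. **Envelope statistics + quadratic discriminant analysis.** Six statistics
   of the Hilbert envelope s_i: the centralized second moment
   m2 = (1/N) Σ (s_i − s̄)², the normalized third and fourth moments
   m3/m2^(3/2) and m4/m2², the crest factor max(s)/rms(s), and the amplitude
   A and width b of an exponential fit P_i = A·exp(−b·x_i) to the envelope
   amplitude histogram. Cross-validated QDA (10 × random 10% test sets, with
   echoes of the same individual within 2 angular positions of any test echo
   excluded from training) gives per-species recall vs. the 33% chance level.

2. **Spectrograms + linear maximum-margin classification.** Band-limited
   (60–150 kHz), dB-scaled, max-normalized magnitude spectrograms (100-point
   Hann window, 90% overlap → 10 kHz × 0.1 ms resolution, 10 × 93 pixels)
   are classified by a linear soft-margin separator,
   class = sign(⟨w, x⟩ + b). The weight vector reshaped to spectrogram
   geometry is the **decision echo** — the interpretable map of which
   time-frequency regions drive the decision.

Three validation procedures probe whether the learned rules are real
structure rather than small-sample artifacts: Gaussian smoothing of the
decision echoes (10 × 10 kernel, σ = 7, unit sum) followed by re-scoring;
noise injection at 10–50% of the spectrogram maximum into test data under
clean-trained classifiers; and "eigen-fish" resampling — per-species PCA
bases used to synthesize ~4650 spectrograms with component weights 3× wider
than the originals, scored by clean-trained models.

## A worked example

```r
library(echofish)

es <- generateEchoSet(masterSeed = 7)   # the default dolphin-style dataset
es
#> EchoSet: 1296 echoes of 1024 samples (dolphin-style emission)
#>   species: cod, mullet, bass
#>   9 individuals, 144 angles

feats <- featureTable(es)               # six envelope statistics per echo
crossvalidateDfa(feats, seed = 1)$cod
#> ClassificationResult: dfa:cod
#>   100+-0%* over 10 repeats (chance 33.3%, one-sided p = 0)

spectra <- computeSpectrograms(es)
runSvmTask(spectra, list(type = "pairwise", classes = c("cod", "mullet")),
           seed = 1)
#> ClassificationResult: pairwise:cod|mullet
#>   100+-0%* over 10 repeats (chance 50.0%, one-sided p = 0)

runSvmTask(spectra, list(type = "pairwise", classes = c("cod", "mullet")),
           smoothed = TRUE, seed = 1)
#> ClassificationResult: pairwise:cod|mullet (smoothed)
#>   92+-3%* over 10 repeats (chance 50.0%, one-sided p = 1.04e-11)
```

The first result reads: across 10 cross-validation repeats, the quadratic
discriminant recalled cod echoes perfectly (mean ± SD = 100 ± 0%), far above
the 33.3% three-class chance level (the `*` marks p < 0.05). The last two
show the pairwise spectrogram classifier at ceiling on raw decision echoes
and still at 92 ± 3% after Gaussian smoothing — the learned rule survives
removal of its high-frequency structure.

`runExperiment(experimentConfig(), "results-dir")` reproduces the complete
analysis for both emission styles: per-aspect DFA tables, raw/smoothed
pairwise classification tables, noise-sensitivity + eigen-fish validation
tables, a decision-echo figure, and a JSON log of every seed and parameter.

## Documentation

The methods vignette (`vignettes/echofish-methods.Rmd`) documents the
emission and echo models, every convention and tunable parameter (with
defaults and rationale), the cross-validation protocol, the three validation
procedures, numerical choices, and known limitations.
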