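---
title: "Decoding whisker motion from peripheral nerve recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding whisker motion from peripheral nerve recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(whiskdecode)
```

## The problem

Extraneural electrodes on the facial nerve of an awake animal record
low-amplitude multi-unit activity (tens of microvolts) whose envelope tracks
the animal's whisker movements. `whiskdecode` implements the full analysis
chain for such data: quantifying recording quality, and regressing the
whisker trajectory from the nerve signal with a model that transfers across
animals. Because no public recordings of this kind exist, the package also
ships a calibrated generator of synthetic multi-subject cohorts, which both
makes every stage testable and defines the conditions under which the
package's own claims are verified.

## The synthetic cohort

`subject_profile()` describes one synthetic animal. A subject's trajectory
(`synthesize_trajectory()`, 125 Hz, normalized to 0–1 with rest baseline
0.5, full scale 0–28 mm) alternates rest with whisking bouts: protraction to
an offset with a superimposed oscillation at the subject's whisking
frequency (default 7 Hz, ~0.25 bouts/s of ~1.5 s — rabbit whisking
statistics are not published for this preparation, so these are the
package's own choices of a realistic regime, not claims about any animal).
The nerve channel (`synthesize_neural()`, 16 kHz) is band-limited Gaussian
noise (default 100–1500 Hz, where movement-related energy concentrates)
amplitude-modulated by the movement envelope — the low-passed (10 Hz)
deviation `|trajectory − 0.5|` — advanced by the subject's signal-to-motor
latency (neural leads movement; default 20 ms), on top of a white-plus-pink
noise floor. The modulation gain is calibrated so the movement-period RMS
hits 13.31 µV over a 5.58 µV rest floor, the amplitudes characteristic of
high-quality awake extraneural recordings. A carrier of filtered noise
rather than spike trains is deliberate: every downstream statistic operates
on multi-unit envelopes, not sorted units.

`make_cohort()` draws per-subject profiles around these defaults.
`heterogeneity` is the coefficient of variation of a log-normal spread on
the subject-specific physiology: modulation gain, noise floor, latency,
excursion amplitude and carrier-band shape (half that spread on bout/whisk
statistics). One subject trait is categorical: the **movement direction**
along the measurement axis. A laser micrometer measures position along one
axis, and whether protraction moves the reading above or below the rest
baseline depends on whisker/sensor geometry; the nerve envelope is unsigned,
so this orientation cannot be inferred from the input signal. This trait is
what makes cross-subject transfer a genuine problem in synthesis: any purely
scalar heterogeneity (gain, noise, latency, amplitude, or even plant-filter
and recruitment nonlinearity mismatches) leaves a subject decodable by a
shared readout, because the concordance metric is nearly insensitive to such
mismatches — a 30% amplitude error costs ~3% CCC, and extreme smoothing or
exponent mismatches cost under 10%. A direction mismatch, by contrast,
inverts the prediction and collapses concordance, which is the failure mode
reported for non-personalized controls on real animals ("delays and
inconsistencies in amplitude"). Off-nerve controls
(`synthesize_offnerve()`) are uncoupled broadband noise.

What the generator does **not** emulate: EMG cross-talk into the nerve
channel, motion artifacts, electrode impedance drift, non-stationary noise,
and spike-level structure. Tests passing on this cohort therefore establish
the correctness and the qualitative transfer behaviour of the pipeline, not
animal-level performance numbers.

## Signal conditioning and quality metrics

All filters are 4th-order Butterworth applied forward–backward
(`signal::filtfilt`), i.e. zero-phase, so envelope timing — on which the
alignment step depends — is never biased: neural band-pass 1–1500 Hz, EMG
high-pass 10 Hz, mains band-stop 45–55 Hz. Envelopes are the magnitude of
the FFT-computed analytic signal, low-pass smoothed at 10 Hz (trajectories
use the rest-baseline deviation `|x − 0.5|` directly).
`align_by_envelope_xcorr()` decimates both envelopes to the lower sampling
rate (a choice, there being no canonical rate for envelope
cross-correlation) and reports the lag maximizing the normalized
cross-correlation; block-mean decimation contributes a bias of at most half
a decimated sample (~4 ms), within the one-trajectory-sample tolerance the
round-trip tests assert. Movement segments are excursions of the smoothed
deviation above median + 3·MAD (a robust rest-floor estimate), with gaps
under 100 ms merged and bouts under 80 ms dropped; all intervals are
half-open `[start, end)` with `sample = floor(t·fs)`.

The quality metrics follow the conventions of awake electrophysiology:
sliding RMS and peak-to-peak voltage (200 ms windows, 100 ms overlap);
trial SNR as `10·log10(RMS_signal/RMS_noise)` — the printed amplitude-ratio
convention of this literature, kept as the default with a `power = TRUE`
toggle for `20·log10` — against a rest floor that must comprise at least
10 s of rest; a persistence spectrum (256 Hamming-windowed segments, 50%
overlap, per-segment FFT power discretized into 256 levels spanning the
observed dB range, since no absolute range is canonical); and the in-band
power ratio, energy in 10–1500 Hz over all energy above 10 Hz after the
50 Hz notch, in 2 s/1 s windows. Pearson correlations of zero-variance
windows are reported as missing, not zero. Lin's concordance correlation
coefficient uses population (1/N) variances by default (`population =
FALSE` for sample variances).

## The decoding model

The model consumes sliding windows of 2000 neural samples advancing by
`fs_data/fs_laser = 128` samples, emitting one normalized position per
stride (so a 2000-sample input yields exactly one output). Two encoder
pathways process each window:

* **Handcrafted pathway** — the window is split into 16 sub-windows of 125
  samples; each yields ten classical amplitude/complexity features (MAV,
  SSI, AAC, STD, RMS, waveform length, zero crossings, slope-sign changes,
  Willison amplitude at a 10 µV threshold, variance; the canonical
  surface-EMG set, standing in for an unpublished feature table), z-scored
  by per-subject statistics. The 16-step sequence of 10-dim vectors runs
  through an LSTM with hidden size 30 (the "160 × 30" sizing: 16 windows ×
  10 features in, 30 hidden), whose final state passes a 30 × 30 dense map.
* **CNN pathway** — the z-scored raw window passes a 1-D convolution
  (kernel 7, 16 channels), is arranged as a 16 × 1994 single-channel image,
  then alternates average pooling and single-channel 3 × 3 convolutions
  (pools are 2 along channels × 4 along time, chosen so the post-CNN
  sequence has 122 steps — a ~1 ms-per-step temporal grain that keeps the
  recurrent pass proportionate; all kernel/pool sizes are package choices,
  none being published). The resulting sequence feeds a second LSTM
  (hidden 30).

The decoder fuses the two 30-dim latents through a linear 60 × 60 dense
layer into a feature vector `F_t`, kept in a 16-slot buffer with the
preceding 15 steps (zero-initialized; the first 15 outputs are flagged as
warm-up). Shared ReLU key/query/value transforms (60 → 30) map each slot;
per-slot saliences `kᵀq/4` (the divisor kept at exactly 4) are softmaxed
into 16 scores and the score-weighted value sum is squashed by a
many-to-one dense layer and sigmoid into (0, 1). Multiplying by 28 converts
to millimetres. Key/query/value transforms are shared across slots
(standard self-attention), not per-lag.

Normalization statistics (raw mean/sd and per-feature means/sds) are always
computed from the subject's own training or adaptation split — up to 1000 s
for training subjects, at most 500 s of adaptation data for test subjects —
and each statistic records its source time span so that predictions on
overlapping spans are refused outright.

## Training, adaptation, evaluation

Training minimizes `1 − ρ_c` (concordance loss) over contiguous sequences
of 125 output steps (1 s), with a `1e-12`-guarded denominator so the loss
stays defined for near-constant early output. Optimization is Adam at
`1e-3` with global gradient-norm clipping at 5 — standard choices, fully
logged and seeded. In the shared phase, one encoder is updated on every
subject's sequences (round-robin within each epoch, avoiding subject-order
bias) while each subject's private decoder sees only that subject's data;
per-epoch validation CCC on a held-out tail of each subject's split drives
early stopping (patience 3, best epoch retained). Adaptation freezes the
encoder — its latents for the adaptation split are computed once and cached,
making decoder-only training cheap — and trains a freshly initialized
decoder. Backpropagation through the attention buffer is truncated: lagged
feature vectors are treated as constants (their key/query/value *parameter*
gradients still accumulate), so each step's gradient reaches the encoder
only through the current `F_t`. This one-step truncation is exact for the
dominant lag-0 path, keeps memory flat, and is validated against central
finite differences in configurations where it is exact.

Evaluation mirrors the cross-subject protocol: leave-one-subject-out folds,
each repeated under seeds 1..n; two controls — a fully-shared model with a
single decoder and no adaptation, and a fully-individualized model trained
from scratch on the test subject's adaptation data alone; and
adaptation-data learning curves over increasing data lengths with
contiguous-block cross-validation folds, summarized by the smallest length
reaching 90% of the curve's maximum. Per-seed values are always retained;
cross-seed aggregation is by mean.

## Problem sizes and numerical choices

The packaged verification study uses 4 training + 1 test synthetic subject,
120 s per subject at heterogeneity 0.3, ten epochs of ten 1-s sequences per
subject per epoch, 60 s of adaptation data, and learning-curve grids of
{12, 24, 48} s over five folds — sizes chosen so the full suite runs on a
single CPU while leaving the trends far from threshold. Degenerate inputs
fail loudly rather than silently: zero-variance sequences make the
concordance undefined, flat envelopes make alignment undefined, rest floors
under 10 s refuse an SNR, and adaptation splits shorter than one training
sequence are rejected.

## Known limitations

Decoding quality on this generator is bounded by what the envelope encodes:
within-bout oscillation phase is not recoverable from an unsigned envelope
at 125 ms windows, so concordance saturates below 1 by construction.
Scalar subject heterogeneity alone does not make transfer hard (see above);
the direction trait carries most of the cross-subject difficulty, and for
cohorts in which every training subject happens to share the test subject's
direction the no-adaptation control is not handicapped. Real tissue
artifacts, non-stationarity and chronic drift are out of scope.
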