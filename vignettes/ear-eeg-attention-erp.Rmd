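---
title: "Methods: simulating and analysing an attention-modulated auditory ERP in scalp and ear EEG"
author: "earerp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing an attention-modulated auditory ERP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

When a listener attends to one of several concurrent speech streams,
semantically defined target words in the *attended* stream evoke a late
positive event-related potential (ERP) over centro-parietal scalp sites — a
P3b-like component, peaking around 625 ms for spoken-word stimuli, whose
amplitude shrinks as the listening situation becomes more realistic
(single word stream, competing word streams, competing continuous
speech). The same component is present, heavily attenuated, in EEG
recorded from electrodes inside the ear, which matters for unobtrusive
auditory-attention decoding in hearing devices.

`earerp` implements the full analysis chain for this problem as tested,
reusable code: a synthetic data generator that emulates the paradigm
structure, a preprocessing pipeline, ERP estimation, a max-SNR spatial
filter for the ear channels solved as a generalized eigenvalue problem
with cross-task validation, and nonparametric permutation statistics.
Because no real dataset ships with the package, the generator is
first-class, tested code: every downstream stage is validated against
data with known ground truth.

## The synthetic data model

### Event structure

A trial of the word-category oddball paradigm contains 20 word onsets:
the first two are always non-targets, between 2 and 5 are semantic
targets, and consecutive onsets are separated by gaps uniform on
[0.8, 1.2] s while the trial occupies exactly 20 s. These two
constraints — a fixed uniform gap distribution *and* an exact total
length — cannot both hold for raw uniform draws, so the generator draws
19 gaps from U(0.8, 1.2) and applies the centred affine map

    g' = 1 + c (g - mean(g)),   c = min(1, 0.2 / max|g - mean(g)|),

which forces the gap sum to exactly 19 s while keeping every gap inside
[0.8, 1.2] s. The price is a slight shrinkage of the gap distribution's
spread in trials whose raw draws are extreme; event-count and ordering
statistics are untouched. Competing-stream paradigms generate two
independent streams (left/right); the attended side alternates
deterministically with the trial index so the design stays balanced. For
the continuous-speech paradigm, non-target word onsets form a dense
stream with gaps uniform on [0.25, 0.6] s — a configurable placeholder,
since word rates of natural stories are not a fixed quantity — with
sparse targets (at least two intervening words).

### The component and the forward model

The evoked component is a windowed Gaussian: peak latency 625 ms, FWHM
300 ms, peak amplitude set by the event's condition. Defaults emulate
the studied effect sizes: 4.15 uV for attended targets in the
single-stream paradigm, 3.3 uV and 1.61 uV for attended targets under
competing words and competing speech, and 0 for non-targets and all
unattended events. The linear ramp through the Gaussian's edge values is
subtracted (clamped at zero) so the template is exactly zero at its
window edges.

Channel data are `leadfield x source + noise`. The cognitive leadfield
is a parietal-maximal bump (centred near Pz) minus a weaker frontal bump
— the two ends of one dipolar source, so scalp topographies show the
characteristic opposite-polarity frontal cluster. Scalp weights are
zero-mean across the 32 scalp channels (average re-referencing then
leaves them unchanged) and scaled so the Pz weight is exactly 1: the
configured amplitude is the amplitude recovered at Pz. Ear channels
receive the parietal weight times an attenuation of 0.15, with a
zero-mean sign gradient across the six in-ear electrode positions.

Ocular activity is a Poisson train of blinks (default 0.25/s, ~120 uV)
projected frontally; a dedicated EOG channel carries the blink source
plus low-level noise. Background noise is 1/f pink noise, 10 uV per
scalp channel.

### Ear noise: mostly shared within an earpiece

Ear-channel noise is three times the scalp level, reflecting the lower
SNR of dry in-ear electrodes. Crucially, it is modelled as

    sqrt(0.9) * common-per-ear + sqrt(0.1) * independent-per-channel,

i.e. 90% of the noise variance is shared across the six electrodes of an
earpiece. In-ear electrodes sit millimetres apart, so volume-conducted
background EEG is nearly identical across them; what differs between
electrodes is sensor-level noise. This structure is what per-ear average
referencing (and, more generally, spatial filtering) exploits: the
shared part cancels under the within-ear reference, leaving the much
smaller independent residual. With spatially independent ear noise of
the same magnitude, no spatial method — not even one using the true
leadfield — could beat a single channel on energy-ratio criteria, which
would misrepresent why max-SNR filtering exists.

### What the generator does not emulate

No realistic head-model leadfields (a fixed weight map), no trial-to-
trial or subject-to-subject latency/amplitude variability of the
component, no spatially correlated *scalp* background (scalp channels
are far enough apart that the iid simplification is conventional), no
muscle or line-noise artifacts, no reverberation or acoustics. Passing
tests therefore demonstrate that the chain recovers what it assumes —
correctness of the machinery, calibration of the statistics — not that
real ear-EEG of any particular hardware will show the component.

## Preprocessing

The chain is: (1) scalp-average reference for scalp channels and
per-ear-average reference for each ear (computed independently, so scalp
and ear signals do not share a reference); (2) zero-phase FIR bandpass
0.1–40 Hz; (3) ICA-based ocular artifact removal on the scalp channels
only; (4) epoching on [-200, 1000) ms around word onsets; (5) baseline
correction using the 200 ms pre-stimulus mean; (6) peak-to-peak
rejection of epochs exceeding 200 uV on any channel (the EOG channel is
exempt — it legitimately spans blink amplitudes).

Numerical choices:

* **FIR design.** Windowed-sinc (Hamming), transition width 0.1 Hz at
  the low corner and 10 Hz at the high corner. At 1000 Hz the high-pass
  kernel alone has 33,001 taps, so the filter is applied by FFT
  convolution with reflection padding; applying the symmetric kernel
  forward-backward makes the net transfer the squared (real, zero-phase)
  kernel response — no group delay, verified by impulse symmetry and
  zero-lag cross-correlation tests.
* **ICA.** FastICA (fixed-point, logcosh contrast, symmetric
  decorrelation, deterministic identity initialization), with PCA
  whitening to `channels - 1` components — the rank of scalp data after
  average referencing. Components whose activation correlates with the
  (bandpassed) EOG channel at |r| > 0.8 are removed and the scalp data
  reconstructed from the rest. The unmixing is *fitted* on temporally
  decimated samples (every 25th; ocular activity lives far below the
  implied Nyquist) and the removal projection applied at full
  resolution. Residual rotation among the near-Gaussian background
  components at the iteration cap is expected and harmless; a warning is
  raised only if the update is still large. Note that ICA removal
  inevitably absorbs a small share of the evoked component (~0.6 uV at
  Pz in the default simulation) — real pipelines pay the same price.
* **Epoching.** Onsets snap to the nearest sample; the window is
  half-open `[tmin, tmax)`, so an epoch has exactly
  `round(1.2 * sfreq)` samples. Events whose window would be clipped are
  dropped and logged. Epochs overlap by construction (gaps are 0.8–1.2 s
  against a 1.2 s window); overlap of the component into the next
  epoch's baseline is part of what the paradigm accepts.
* **Rejection.** "Above 200 uV across all channels" is read as
  reject-if-any-channel-exceeds; the alternative (all channels must
  exceed) would essentially never reject.

## ERP estimation

Condition ERPs are sample-wise means over the condition's surviving
epochs; difference waves subtract non-target from target ERPs; grand
averages weight subjects equally regardless of their epoch counts. Peak
quantification takes the maximum (the component is positive-going) of a
wave inside a window — by convention the extent of the most significant
cluster — with ties broken towards the earlier latency and maxima on the
window edge flagged as non-local.

## The max-SNR ear filter

For epochs `X_i` (C channels x N samples) with target index set and
non-target index set, let `X_T` be the average target epoch and `X_N`
the concatenation of non-target epochs along time. With

    R_T = X_T X_T',    R_N = X_N X_N',

the filter `w` maximizes `w' R_T w` subject to `w' R_N w = 1` — the
ratio of the averaged target ERP's output energy to the output energy of
non-target activity. Any positive multiple of an unconstrained maximizer
has the same objective; the constraint pins the scale. The solution is
the top generalized eigenvector of the pencil `(R_T, R_N)`, computed by
Cholesky whitening of `R_N` followed by a symmetric
eigendecomposition, which satisfies the constraint exactly.

Choices the formulation leaves open:

* **Shrinkage.** Per-ear average referencing makes the 6-channel ear
  covariance rank 5, so `R_N` is regularized as
  `(1 - g) R_N + g (tr(R_N)/C) I` with `g = 0.05` before factorization.
* **Sign.** The eigenvector's sign is arbitrary; it is chosen so the
  filtered average-target waveform has a non-negative mean over
  400–800 ms, making the virtual channel positive-going like the scalp
  component.
* **Degenerate target.** If `R_T` is numerically zero the objective is
  flat; the solver warns and returns the direction of largest variance
  under the `R_N` normalization rather than failing silently.
* **Training pool.** Cross-task validation trains, for each paradigm and
  ear, on the *pooled epochs* of the other paradigms (not per-paradigm
  averaged covariances) — maximal sample size — and applies the filter
  to the held-out paradigm only; the filter object records its training
  provenance. Pooling epochs across subjects for filter training is a
  deliberate simplification of the package's pipeline driver.
* **Covariance window.** `R_T`/`R_N` use the full epoch by default. The
  held-out SNR-gain experiment computes its energy-ratio covariances on
  the 300–950 ms component window, where the target energy lives.

## Statistics

All tests are label-permutation tests with the add-one rule
`p = (1 + #{perm >= obs}) / (1 + n_perm)`, so the smallest attainable p
at 1,000 permutations is ~0.001 and p = 0 is impossible. The statistic
is the difference of condition means; the permutation unit is the epoch
(pooled across subjects where the driver pools).

The temporal cluster test thresholds the condition-mean difference
waveform (two-sided by default: positive and negative supra-threshold
runs form separate clusters), sums the difference within each run, and
compares each observed cluster against the permutation null of the
largest absolute cluster sum (permutations with no supra-threshold
cluster contribute 0). The cluster-forming threshold trades sensitivity
only — the false-alarm rate stays at the nominal level for any
threshold, which the type-I experiment verifies at 0.5 and 1.0 uV.
Defaults: 1.0 uV for scalp difference waves, 0.5 uV for filtered ear
waves (whose amplitudes are an order of magnitude smaller). The spatial
variant averages the difference over a time window per channel and
replaces temporal adjacency with a montage-derived channel adjacency
(neighbours within 1.5x the median nearest-neighbour distance in the 2D
layout); clusters are same-sign connected components.

The cosine-similarity test scores the angle between the ear difference
ERP and a scalp difference wave over the full epoch; its null shuffles
the ear epochs' target/non-target labels and rescores, and its p-value
is one-sided (similarity, not dissimilarity). Bonferroni correction
(`alpha / n` for `n` contrasts) is applied by the pipeline driver: four
contrasts per competing-stream paradigm (alpha 0.0125 at base 0.05), two
ears for similarity tests (alpha 0.025).

## Validation experiments and their problem sizes

The package validates itself with five simulation studies
(`validate_*`, also driven by `scripts/acceptance.R`). The problem
sizes below are the package's chosen operating points.

1. **Solver vs. brute force** — 20 random 4x4 SPD pencils; the GEVD
   objective must match (and never fall below) the best of 100,000
   random directions within 1%, with the unit-power constraint satisfied
   to 1e-8.
2. **Parameter recovery** — one cohort of 20 subjects, 16 trials each,
   full 1000 Hz pipeline with all defaults. The grand-average
   target-minus-non-target wave at Pz must peak at 625 +/- 15 ms with
   amplitude within 25% of 4.15 uV, and the pooled-epoch cluster test
   must find a significant (p <= 0.01) cluster overlapping 450–920 ms.
   Detection *power* is then estimated over 20 freshly simulated
   cohorts; these use 3 subjects each, a strictly harder setting than
   the recovery cohort (power is monotone in cohort size), chosen to
   keep twenty full-pipeline repetitions affordable. Every repetition
   must detect the cluster in at least 95% of cases.
3. **Type-I calibration** — 200 null datasets (two groups of pink-noise
   epochs, 40 vs 160, no component) per cluster-forming threshold (0.5
   and 1.0 uV); rejection rates at alpha = 0.05 must fall inside the
   exact binomial 95% interval [0.024, 0.086].
4. **Held-out ear SNR gain** — 50 independent ear datasets at
   cross-task pooled-cohort scale (8000/6000 training and 4000/4000
   held-out target/non-target epochs; roughly 24 subjects x 2 training
   paradigms at the paradigm's event rates), sampled at 250 Hz since
   energy ratios are sampling-rate invariant. The trained filter's
   held-out target/non-target energy ratio must beat the single channel
   selected on the training split in at least 95% of datasets. The
   baseline is train-selected deliberately: picking the best channel on
   the held-out data itself would hand the baseline a max-of-six
   selection-noise advantage that no fixed method (including the true
   leadfield direction) can match at realistic SNR.
5. **Similarity-test behaviour** — exact scores (1 for proportional,
   0 for orthogonal waveforms) and, over 500 null datasets, p-values
   whose distribution a Kolmogorov-Smirnov test cannot distinguish from
   uniform at the 1% level.

## Known limitations

* The generator's fixed leadfields and stationary Gaussian component
  make recovery easier than real data; the validation demonstrates
  correctness and calibration, not field performance.
* Per-subject spatial-filter training at single-paper data volumes is
  noise-dominated — consistent with held-out ear effects being
  hard-won in practice; the SNR-gain experiment therefore operates at
  pooled-cohort scale.
* FastICA on mostly-Gaussian background EEG does not fully converge (the
  non-Gaussian subspace does); component selection is robust to this but
  marginal |r| ~ 0.8 decisions can flip under tiny input perturbations.
* The events dialect and array container are this package's own
  documented formats, not a full BIDS implementation.
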