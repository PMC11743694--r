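# earerp

Simulation and analysis of an attention-modulated auditory ERP component
in scalp and ear EEG.

When a listener attends to one of several concurrent speech streams,
semantically defined target words in the attended stream evoke a late
positive ERP over centro-parietal scalp sites — a P3b-like component
peaking around 625 ms for spoken-word stimuli — whose amplitude shrinks
as the listening situation becomes more realistic, and which survives,
strongly attenuated, in EEG recorded from electrodes inside the ear.
This matters for unobtrusive auditory-attention decoding (e.g. in future
cognitively controlled hearing devices). `earerp` packages the full
analysis chain for this problem as tested, reusable R code, together
with a paradigm-faithful synthetic data generator so that every stage is
verifiable without access to any recording hardware.

## What is inside

* **Synthetic data** (`sim_config()`, `simulate_recording()`,
  `simulate_dataset()`): word-category oddball event sequences (20
  events per 20 s trial, 2–5 semantic targets, first two events
  non-targets, gaps uniform on [0.8, 1.2] s), competing-stream and
  continuous-speech variants, a parietal-maximal component with
  opposite-polarity frontal projection, frontal blink artifacts, 1/f
  background noise, and 32 scalp + 2x6 in-ear channels at 1000 Hz.
* **Preprocessing** (`preprocess_recording()` and per-stage functions):
  scalp-average and per-ear-average re-referencing, zero-phase FIR
  bandpass 0.1–40 Hz, FastICA-based ocular artifact removal (components
  with |r| > 0.8 against the EOG channel), epoching on [-200, 1000) ms,
  baseline correction, 200 uV peak-to-peak rejection.
* **ERP estimation** (`average_epochs()`, `difference_wave()`,
  `grand_average()`, `quantify_peak()`).
* **Max-SNR ear filter** (`train_spatial_filter()`, `apply_filter()`,
  `cross_task_validate()`): with `X_T` the average target epoch and
  `X_N` the concatenated non-target epochs, the filter solves

      maximize  w' R_T w   subject to  w' R_N w = 1,
      R_T = X_T X_T',      R_N = X_N X_N',

  i.e. the top generalized eigenvector of `(R_T, R_N)`, computed via
  Cholesky whitening with shrinkage regularization of `R_N`; the
  leave-one-paradigm-out scheme trains per ear on the pooled epochs of
  the other paradigms and evaluates on the held-out one.
* **Statistics** (`permutation_test()`, `temporal_cluster_test()`,
  `spatial_cluster_test()`, `cosine_similarity_test()`,
  `bonferroni_alpha()`): label-permutation tests with the add-one rule,
  cluster forming by thresholding the condition-mean difference
  (temporal runs, or montage-adjacency components for topographies),
  max-cluster permutation nulls, and a cosine-similarity permutation
  test between ear and scalp difference ERPs.
* **Pipeline driver** (`pipeline_config()`, `run_pipeline()`): simulate
  or read a BIDS-style dataset, preprocess, average, test all paradigm
  contrasts (AT-AN, AT-UT, AN-UT, UT-UN for competing streams), write
  result tables stamped with the configuration hash.

## Worked example

Simulate a small cohort of the single-stream word-oddball paradigm at
250 Hz, run the preprocessing chain, pool the parietal epochs, and test
the target vs. non-target difference:

```r
library(earerp)

cfg <- sim_config(paradigm = 1, sfreq = 250, seed = 2024)  # 16 trials
pool_t <- pool_n <- NULL; diffs <- list()
for (s in 1:3) {
  sim <- simulate_recording(cfg, subject = s)
  pp  <- preprocess_recording(sim$recording, sim$events)
  ti  <- which(pp$epochs$conditions == "TARGET")
  ni  <- which(pp$epochs$conditions == "NONTARGET")
  pool_t <- rbind(pool_t, t(pp$epochs$data["Pz", , ti]))
  pool_n <- rbind(pool_n, t(pp$epochs$data["Pz", , ni]))
  d <- difference_wave(average_epochs(pp$epochs, "TARGET"),
                       average_epochs(pp$epochs, "NONTARGET"))
  diffs[[s]] <- erp_wave(d$data["Pz", , drop = FALSE], d$times,
                         d$label, d$n, "Pz")
}
gd <- grand_average(diffs)
ct <- temporal_cluster_test(pool_t, pool_n, threshold = 1.0,
                            n_perm = 999, seed = 7, times = gd$times)
ct
best <- ct$clusters[which.min(ct$clusters$p), ]
quantify_peak(gd, "Pz", c(best$start_ms, best$end_ms))
```

Output (abridged):

```
<cluster_test> temporal, two-sided, threshold 1, 999 permutations
  ...
  cluster 7: [436, 796] ms, stat = 251, p = 0.002
  ...
peak: 3.88 uV at 588 ms
```

The pooled cluster test isolates one significant cluster (p = 0.002)
spanning 436–796 ms — the window where the simulated component lives —
and the grand-average difference wave peaks at 3.9 uV, close to the
configured 4.15 uV attended-target amplitude (the small deficit is the
share of the component absorbed by ICA cleanup, as in real pipelines).
All other supra-threshold runs are noise clusters with p near 1.

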