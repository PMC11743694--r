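# Shared fixtures: small, fast configurations and hand-built objects.

# A light configuration for unit tests: low sampling rate, few trials.
tiny_config <- function(paradigm = 1, sfreq = 250, n_trials = 2,
                        seed = 1, ...) {
  sim_config(paradigm = paradigm, sfreq = sfreq, n_trials = n_trials,
             seed = seed, ...)
}

# A small hand-built recording: n_chan x n_samples of given content.
toy_recording <- function(data, sfreq = 100, labels = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- labels
  eeg_recording(data, sfreq, labels,
                groups = stats::setNames(rep("scalp", nrow(data)), labels))
}

# Epochs built directly from an array (channels x samples x epochs).
toy_epochs <- function(arr, conditions, sfreq = 1000, tmin = -0.2) {
  times <- (round(tmin * sfreq) + seq_len(dim(arr)[2]) - 1) / sfreq * 1000
  eeg_epochs(arr, times, conditions, sfreq)
}

expect_same_numbers <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
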