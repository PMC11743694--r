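#' Re-reference a recording
#'
#' `scalp_average` subtracts the mean of all scalp channels from each
#' scalp channel; `per_ear_average` subtracts each ear's own mean from
#' that ear's channels. Other channel groups are untouched, so scalp and
#' ear signals remain independent of each other's reference.
#'
#' @param rec An [eeg_recording].
#' @param scheme `"scalp_average"` or `"per_ear_average"`.
#' @return The re-referenced recording.
#' @export
rereference <- function(rec, scheme = c("scalp_average", "per_ear_average")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(rec, "eeg_recording"))
  groups <- if (scheme == "scalp_average") "scalp" else
    c("ear_left", "ear_right")
  for (g in groups) {
    idx <- which(rec$groups == g)
    if (!length(idx)) stop("channel group '", g, "' is empty")
    m <- colMeans(rec$data[idx, , drop = FALSE])
    rec$data[idx, ] <- rec$data[idx, , drop = FALSE] -
      rep(m, each = length(idx))
  }
  rec
}

# Windowed-sinc (Hamming) lowpass kernel; odd length, -6 dB at `fc`.
fir_lowpass <- function(fc, sfreq, trans) {
  len <- ceiling(3.3 * sfreq / trans)
  if (len %% 2 == 0) len <- len + 1
  m <- (len - 1) / 2
  t <- (-m):m
  h <- 2 * fc / sfreq * sinc(2 * fc / sfreq * t)
  w <- 0.54 + 0.46 * cos(pi * t / m)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Real (zero-phase-arranged) frequency response of a symmetric kernel on
# an FFT grid of length n_fft.
kernel_response <- function(h, n_fft) {
  len <- length(h)
  m <- (len - 1) / 2
  hh <- numeric(n_fft)
  hh[1:(m + 1)] <- h[(m + 1):len]
  hh[(n_fft - m + 1):n_fft] <- h[1:m]
  Re(fft(hh))
}

#' Zero-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) design with transition widths of 0.1 Hz at the
#' low corner and 10 Hz at the high corner, applied forward-backward, so
#' the net transfer is the squared (real, zero-phase) kernel response and
#' the filter introduces no group delay. Implemented by FFT convolution
#' with reflection padding; for the default corners at 1000 Hz the
#' high-pass kernel alone has 33,001 taps, which rules out time-domain
#' filtering.
#'
#' @param rec An [eeg_recording].
#' @param low,high Passband corner frequencies, Hz (defaults 0.1 and 40).
#' @param trans_low,trans_high Transition widths at the two corners, Hz.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 40,
                            trans_low = 0.1, trans_high = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sfreq / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("corner frequencies must satisfy 0 < low < high < sfreq/2")
  }
  x <- rec$data
  n <- ncol(x)
  h_lp_low <- fir_lowpass(low, rec$sfreq, trans_low)    # to be subtracted
  h_lp_high <- fir_lowpass(high, rec$sfreq, trans_high)
  pad <- max(length(h_lp_low), length(h_lp_high))
  n_fft <- nextn(n + 2 * pad, c(2, 3, 5))
  # bandpass response = lowpass(high) - lowpass(low); forward-backward
  # application squares it
  resp <- kernel_response(h_lp_high, n_fft) - kernel_response(h_lp_low, n_fft)
  resp2 <- resp^2

  # reflection padding to avoid edge steps; work on the transposed
  # matrix so per-channel access is contiguous
  pl <- min(pad, n)
  lidx <- pl:1
  ridx <- n:max(1, n - pad + 1)
  n_chan <- nrow(x)
  xt <- t(x)
  out <- matrix(0, n, n_chan)
  keep <- (pl + 1):(pl + n)
  padded <- function(i) c(xt[lidx, i], xt[, i], xt[ridx, i],
                          numeric(n_fft - pl - n - length(ridx)))
  # filter channels in pairs: one complex FFT per pair (the response is
  # real, so real and imaginary parts stay independent)
  for (p in seq_len(ceiling(n_chan / 2))) {
    i1 <- 2 * p - 1
    i2 <- min(2 * p, n_chan)
    z <- complex(real = padded(i1), imaginary = padded(i2))
    y <- fft(fft(z) * resp2, inverse = TRUE) / n_fft
    out[, i1] <- Re(y)[keep]
    if (i2 > i1) out[, i2] <- Im(y)[keep]
  }
  out <- t(out)
  rownames(out) <- rec$labels
  rec$data <- out
  rec
}

# Fixed-point FastICA (symmetric decorrelation, logcosh contrast) with
# deterministic identity initialization. X: components-to-be x samples,
# already centred and whitened.
fastica_core <- function(Z, maxit = 40, tol = 1e-3) {
  nc <- nrow(Z)
  ns <- ncol(Z)
  sym_decor <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), nc) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decor(diag(nc))
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime_mean <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / ns - gprime_mean * W
    W1 <- sym_decor(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < tol) {
      return(list(W = W, converged = TRUE, iter = it, delta = delta))
    }
  }
  list(W = W, converged = FALSE, iter = maxit, delta = delta)
}

#' Remove ocular components with ICA
#'
#' FastICA (fixed-point, logcosh nonlinearity, symmetric decorrelation) is
#' run on the scalp channels only, with PCA whitening to `channels - 1`
#' components (the rank after scalp-average referencing). Components whose
#' activation has an absolute Pearson correlation with the EOG channel
#' above `r_threshold` are removed, and the scalp signals are
#' reconstructed from the remaining components via the mixing matrix. The
#' EOG channel itself is excluded from the decomposition and left intact.
#'
#' The unmixing is estimated on temporally decimated samples (every
#' `decim`-th) — ocular activity lives well below the implied Nyquist —
#' and the removal projection is applied at full resolution.
#'
#' @param rec An [eeg_recording] (scalp-average referenced, bandpassed).
#' @param eog_channel Label of the EOG channel.
#' @param r_threshold Absolute correlation threshold (default 0.8).
#' @param decim Decimation factor for the ICA fit (default 25).
#' @param maxit,tol FastICA iteration controls. The blink component
#'   stabilizes within a few dozen iterations; the default tolerance
#'   stops once the rotation update is below 1e-3.
#' @return List with `recording` (cleaned) and `report`, a data.frame
#'   with one row per component: `component`, `r_eog`, `removed`.
#' @export
remove_eog_ica <- function(rec, eog_channel = "EOG", r_threshold = 0.8,
                           decim = 25, maxit = 40, tol = 1e-3) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!eog_channel %in% rec$labels) {
    stop("EOG channel '", eog_channel, "' not found in the recording")
  }
  scalp_idx <- which(rec$groups == "scalp" & rec$labels != eog_channel)
  X <- rec$data[scalp_idx, , drop = FALSE]
  ns_full <- ncol(X)
  sub <- seq(1, ns_full, by = max(1, round(decim)))
  Xs <- X[, sub, drop = FALSE]
  ctr <- rowMeans(Xs)
  Xs <- Xs - ctr

  n_comp <- nrow(X) - 1L  # rank after average reference
  C <- tcrossprod(Xs) / ncol(Xs)
  e <- eigen(C, symmetric = TRUE)
  d <- e$values[seq_len(n_comp)]
  if (any(d <= 1e-12 * d[1])) {
    stop("ICA decomposition failure: scalp covariance is rank deficient ",
         "beyond the average-reference constraint (smallest retained ",
         "eigenvalue ", signif(min(d), 3), ")")
  }
  K <- diag(1 / sqrt(d), n_comp) %*% t(e$vectors[, seq_len(n_comp)])
  Z <- K %*% Xs
  fit <- fastica_core(Z, maxit = maxit, tol = tol)
  if (!fit$converged && fit$delta > 0.05) {
    # small residual rotations among near-Gaussian background components
    # are expected and harmless; only warn when the update is still large
    warning("FastICA still rotating after ", maxit,
            " iterations (update ", signif(fit$delta, 2), ")")
  }
  U <- fit$W %*% K                                   # unmixing, comp x chan
  A <- e$vectors[, seq_len(n_comp)] %*% diag(sqrt(d), n_comp) %*% t(fit$W)

  S_sub <- U %*% Xs
  eog_sub <- rec$data[eog_channel, sub]
  r <- as.numeric(cor(t(S_sub), eog_sub))
  removed <- which(abs(r) > r_threshold)
  report <- data.frame(component = seq_len(n_comp), r_eog = r,
                       removed = seq_len(n_comp) %in% removed)
  if (length(removed)) {
    ctr_full <- rowMeans(X)
    S_rm <- U[removed, , drop = FALSE] %*% (X - ctr_full)
    rec$data[scalp_idx, ] <- X - A[, removed, drop = FALSE] %*% S_rm
  }
  list(recording = rec, report = report)
}

#' Cut a recording into event-locked epochs
#'
#' One epoch per event whose full window fits inside the recording; events
#' with clipped windows are dropped and reported via the `"dropped"`
#' attribute. The window is half-open, `[tmin, tmax)`, so an epoch has
#' exactly `round((tmax - tmin) * sfreq)` samples; onsets are snapped to
#' the nearest sample. Overlapping epochs are permitted (inter-event gaps
#' are shorter than the window).
#'
#' @param rec An [eeg_recording].
#' @param events An event table (see [as_event_table()]).
#' @param tmin,tmax Window edges in seconds relative to onset (defaults
#'   -0.2 and 1.0).
#' @return An [eeg_epochs] object; epochs carry their event's
#'   `trial_type` as condition.
#' @export
epoch_recording <- function(rec, events, tmin = -0.2, tmax = 1.0) {
  stopifnot(inherits(rec, "eeg_recording"))
  events <- as_event_table(events)
  n <- ncol(rec$data)
  n_samp <- round((tmax - tmin) * rec$sfreq)
  rel0 <- round(tmin * rec$sfreq)
  onset_samp <- round(events$onset * rec$sfreq) + 1L   # sample at t = 0
  start <- onset_samp + rel0
  ok <- start >= 1L & (start + n_samp - 1L) <= n
  dropped <- events[!ok, , drop = FALSE]
  events <- events[ok, , drop = FALSE]
  start <- start[ok]
  idx <- outer(seq_len(n_samp) - 1L, start, "+")
  arr <- array(rec$data[, idx],
               dim = c(nrow(rec$data), n_samp, length(start)))
  times <- (rel0 + seq_len(n_samp) - 1) / rec$sfreq * 1000
  ep <- eeg_epochs(arr, times, events$trial_type, rec$sfreq,
                   rec$labels, rec$groups, rec$montage, events)
  attr(ep, "dropped") <- dropped
  ep
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' from the whole epoch.
#'
#' @param epochs An [eeg_epochs] object.
#' @param window Baseline window in seconds, half-open (default
#'   `c(-0.2, 0)` = the 200 ms pre-stimulus period).
#' @return Baseline-corrected epochs.
#' @export
baseline_correct <- function(epochs, window = c(-0.2, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  sel <- epochs$times >= window[1] * 1000 & epochs$times < window[2] * 1000
  if (!any(sel)) stop("baseline window contains no samples")
  d <- epochs$data
  bm <- apply(d[, sel, , drop = FALSE], c(1, 3), mean)   # chan x epoch
  epochs$data <- d - aperm(array(bm, dim = dim(d)[c(1, 3, 2)]), c(1, 3, 2))
  epochs
}

#' Peak-to-peak epoch rejection
#'
#' An epoch is rejected when any channel's max-minus-min amplitude over
#' the epoch exceeds `threshold`; survivors keep their order.
#'
#' @param epochs Baseline-corrected [eeg_epochs].
#' @param threshold Peak-to-peak rejection threshold, uV (default 200).
#' @param exclude Channel groups ignored by the criterion (default
#'   `"eog"`: the EOG channel legitimately spans blink amplitudes).
#' @return List with `epochs` (survivors) and `log`, a data.frame with
#'   one row per input epoch: `epoch`, `kept`, `channel` (worst channel),
#'   `p2p` (its peak-to-peak value, uV).
#' @export
reject_peak_to_peak <- function(epochs, threshold = 200, exclude = "eog") {
  stopifnot(inherits(epochs, "eeg_epochs"))
  ne <- n_epochs(epochs)
  chan_idx <- seq_along(epochs$channels)
  if (!is.null(epochs$groups)) {
    chan_idx <- which(!epochs$groups[epochs$channels] %in% exclude)
  }
  if (ne == 0) {
    return(list(epochs = epochs,
                log = data.frame(epoch = integer(0), kept = logical(0),
                                 channel = character(0), p2p = numeric(0))))
  }
  d <- epochs$data[chan_idx, , , drop = FALSE]
  p2p <- apply(d, c(1, 3), function(v) max(v) - min(v))  # chan x epoch
  p2p <- matrix(p2p, nrow = length(chan_idx))
  worst <- apply(p2p, 2, which.max)
  worst_val <- p2p[cbind(worst, seq_len(ne))]
  kept <- worst_val <= threshold
  log <- data.frame(epoch = seq_len(ne), kept = kept,
                    channel = epochs$channels[chan_idx][worst],
                    p2p = worst_val)
  list(epochs = subset_epochs(epochs, which(kept)), log = log)
}

#' Run preprocessing steps 1–6
#'
#' In order: scalp-average and per-ear-average re-referencing, zero-phase
#' FIR bandpass, ICA ocular-artifact removal (scalp only, optional),
#' epoching, baseline correction, peak-to-peak rejection.
#'
#' @param rec An [eeg_recording].
#' @param events Event table.
#' @param low,high Bandpass corners, Hz.
#' @param ica Logical: run ICA-based EOG removal (default TRUE when an
#'   EOG channel is present).
#' @param eog_channel EOG channel label.
#' @param r_threshold ICA component rejection correlation threshold.
#' @param tmin,tmax Epoch window, s.
#' @param p2p Peak-to-peak rejection threshold, uV.
#' @return List with `epochs`, `rejection_log`, `ica_report`.
#' @export
preprocess_recording <- function(rec, events, low = 0.1, high = 40,
                                 ica = NULL, eog_channel = "EOG",
                                 r_threshold = 0.8, tmin = -0.2,
                                 tmax = 1.0, p2p = 200) {
  rec <- rereference(rec, "scalp_average")
  if (any(rec$groups %in% c("ear_left", "ear_right"))) {
    rec <- rereference(rec, "per_ear_average")
  }
  rec <- bandpass_filter(rec, low, high)
  if (is.null(ica)) ica <- eog_channel %in% rec$labels
  ica_report <- NULL
  if (ica) {
    cleaned <- remove_eog_ica(rec, eog_channel, r_threshold)
    rec <- cleaned$recording
    ica_report <- cleaned$report
  }
  ep <- epoch_recording(rec, events, tmin, tmax)
  dropped <- attr(ep, "dropped")
  ep <- baseline_correct(ep, c(tmin, 0))
  rej <- reject_peak_to_peak(ep, p2p)
  attr(rej$epochs, "dropped") <- dropped
  list(epochs = rej$epochs, rejection_log = rej$log,
       ica_report = ica_report)
}
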