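#' Simulation configuration for paradigm-structured synthetic EEG
#'
#' Defines the study conditions the generator emulates: oddball word
#' sequences (20 events per 20-s trial, 2–5 semantic targets, the first
#' two events always non-targets, inter-onset gaps uniform on
#' \[0.8, 1.2\] s), a parietal-maximal positive ERP component whose
#' amplitude depends on the event's attention/target condition, frontal
#' ocular artifacts, and 1/f background noise over 32 scalp + 2x6 ear
#' channels sampled at 1000 Hz.
#'
#' Default component amplitudes follow the emulated findings: 4.15 uV at
#' 625 ms for attended targets in the single-stream paradigm; attended
#' targets in competing-word and continuous-speech paradigms default to
#' 3.3 uV and 1.61 uV respectively; non-targets and all unattended events
#' carry no component.
#'
#' @param paradigm 1 (single-stream word oddball), 2 (competing word
#'   streams) or 3 (competing continuous speech with targets).
#' @param n_trials Trials per subject (default 16 for paradigm 1, 20
#'   otherwise).
#' @param n_subjects Number of subjects the configuration describes.
#' @param sfreq Sampling rate, Hz.
#' @param erp_latency Component peak latency, ms.
#' @param erp_width Component width (Gaussian FWHM), ms.
#' @param erp_amplitude Named amplitudes in uV for conditions AT, AN, UT,
#'   UN. For paradigm 1 the TARGET/NONTARGET conditions use the AT/AN
#'   entries. NULL selects the paradigm-specific default.
#' @param noise_sigma Background 1/f noise standard deviation per scalp
#'   channel, uV.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha noise.
#' @param eog_rate Blink rate, events per second.
#' @param eog_amplitude Blink amplitude at the ocular source, uV.
#' @param ear_attenuation Ear leadfield weight relative to the Pz scalp
#'   weight.
#' @param ear_noise_factor Multiplier on `noise_sigma` for ear channels
#'   (ear EEG has lower SNR).
#' @param ear_noise_shared Fraction of ear-noise variance shared across
#'   the six channels of an earpiece (default 0.9): in-ear electrodes
#'   are millimetres apart, so volume-conducted background EEG is nearly
#'   identical across them; per-ear average referencing removes the
#'   shared part.
#' @param leadfield List with `cognitive` and `ocular` named weight
#'   vectors (default [default_leadfields()]).
#' @param n_events Events per stream and trial (word-category paradigms).
#' @param target_range Integer range of targets per stream and trial.
#' @param trial_dur Trial duration, seconds.
#' @param dense_gap Gap range (s) between word onsets in the continuous
#'   speech paradigm (paradigm 3); word rate for natural stories is not a
#'   measured quantity, these are configurable placeholders.
#' @param seed Root seed; per-subject child seeds are derived
#'   deterministically from it.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(paradigm = 1, n_trials = 2, sfreq = 250, seed = 1)
#' ev <- make_event_sequence(cfg, trial = 1)
#' table(ev$trial_type)
sim_config <- function(paradigm = 1, n_trials = NULL, n_subjects = 1,
                       sfreq = 1000, erp_latency = 625, erp_width = 300,
                       erp_amplitude = NULL, noise_sigma = 10,
                       noise_exponent = 1, eog_rate = 0.25,
                       eog_amplitude = 120, ear_attenuation = 0.15,
                       ear_noise_factor = 3, ear_noise_shared = 0.9,
                       leadfield = NULL,
                       n_events = 20, target_range = c(2, 5),
                       trial_dur = 20, dense_gap = c(0.25, 0.6),
                       seed = NULL) {
  paradigm <- as.integer(paradigm)
  if (!paradigm %in% 1:3) stop("`paradigm` must be 1, 2 or 3")
  if (is.null(n_trials)) n_trials <- if (paradigm == 1) 16L else 20L
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  if (sfreq <= 0) stop("`sfreq` must be positive")
  if (erp_width <= 0) stop("`erp_width` must be positive")
  if (is.null(erp_amplitude)) {
    at <- c(4.15, 3.3, 1.61)[paradigm]
    erp_amplitude <- c(AT = at, AN = 0, UT = 0, UN = 0)
  }
  if (!all(c("AT", "AN", "UT", "UN") %in% names(erp_amplitude))) {
    stop("`erp_amplitude` must name AT, AN, UT and UN")
  }
  target_range <- as.integer(round(target_range))
  max_targets <- floor(0.25 * n_events)  # rarity: at most 1 target in 4
  if (length(target_range) != 2L || target_range[1] > target_range[2] ||
      target_range[1] < 1L || target_range[2] > max_targets) {
    stop("invalid `target_range`: targets per trial must lie in [1, ",
         max_targets, "] for ", n_events, " events")
  }
  if (n_events < 4) stop("`n_events` must be at least 4")
  if (is.null(leadfield)) leadfield <- default_leadfields(ear_attenuation)
  groups <- default_channel_groups()
  for (nm in c("cognitive", "ocular")) {
    if (!setequal(names(leadfield[[nm]]), names(groups))) {
      stop("`leadfield$", nm, "` does not cover the channel set")
    }
  }
  structure(list(paradigm = paradigm, n_trials = as.integer(n_trials),
                 n_subjects = as.integer(n_subjects), sfreq = sfreq,
                 erp_latency = erp_latency, erp_width = erp_width,
                 erp_amplitude = erp_amplitude, noise_sigma = noise_sigma,
                 noise_exponent = noise_exponent, eog_rate = eog_rate,
                 eog_amplitude = eog_amplitude,
                 ear_attenuation = ear_attenuation,
                 ear_noise_factor = ear_noise_factor,
                 ear_noise_shared = ear_noise_shared,
                 leadfield = leadfield, n_events = as.integer(n_events),
                 target_range = target_range, trial_dur = trial_dur,
                 dense_gap = dense_gap, seed = seed),
            class = "sim_config")
}

# Deterministic per-subject child seed below 2^31.
child_seed <- function(seed, subject, salt = 0L) {
  (as.numeric(seed) + 104729 * subject + 15485863 * salt) %% 2147483647
}

# Gaps uniform on [0.8, 1.2] s, affinely rescaled around their mean so the
# gap sum is exactly (n-1) * 1.0 s while every gap stays in [0.8, 1.2]:
# the trial then has a fixed total length.
draw_gaps <- function(n_gaps, lo = 0.8, hi = 1.2) {
  g <- runif(n_gaps, lo, hi)
  mid <- (lo + hi) / 2
  half <- (hi - lo) / 2
  dev <- g - mean(g)
  cc <- if (max(abs(dev)) > 0) min(1, half / max(abs(dev))) else 1
  mid + cc * dev
}

# One oddball word sequence: onsets (relative to trial start), logical
# target flags. First two events are always non-targets.
oddball_sequence <- function(n_events, target_range, trial_dur) {
  gaps <- draw_gaps(n_events - 1)
  onsets <- 0.5 + c(0, cumsum(gaps))
  n_targets <- sample(seq(target_range[1], target_range[2]), 1)
  is_target <- rep(FALSE, n_events)
  is_target[sample(3:n_events, n_targets)] <- TRUE
  list(onset = onsets, is_target = is_target)
}

# Dense word stream for the continuous-speech paradigm: word onsets with
# short gaps, sparse targets as in the oddball sequences.
dense_sequence <- function(target_range, trial_dur, dense_gap) {
  onsets <- 0.5
  repeat {
    nxt <- onsets[length(onsets)] + runif(1, dense_gap[1], dense_gap[2])
    if (nxt > trial_dur - 0.5) break
    onsets <- c(onsets, nxt)
  }
  n <- length(onsets)
  n_targets <- sample(seq(target_range[1], target_range[2]), 1)
  is_target <- rep(FALSE, n)
  # keep targets sparse: at least two non-target words between targets
  cand <- 3:n
  chosen <- integer(0)
  while (length(chosen) < n_targets && length(cand)) {
    pick <- if (length(cand) == 1L) cand else sample(cand, 1)
    chosen <- c(chosen, pick)
    cand <- setdiff(cand, (pick - 2):(pick + 2))
  }
  is_target[chosen] <- TRUE
  list(onset = onsets, is_target = is_target)
}

#' Generate the event sequence for one trial
#'
#' Paradigm 1 produces a single stream of 20 word events; paradigms 2 and
#' 3 produce two interleaved streams (left/right), each obeying the
#' per-stream invariants. The attended side alternates deterministically
#' with the trial index (balanced over trials); events in the attended
#' stream are labelled AT/AN and in the unattended stream UT/UN.
#'
#' @param config A [sim_config()].
#' @param trial Trial index (1-based), used for the left/right balance.
#' @param offset Seconds added to all onsets (position of the trial in a
#'   longer recording).
#' @return An `event_table` (see [as_event_table()]).
#' @export
make_event_sequence <- function(config, trial = 1, offset = 0) {
  stopifnot(inherits(config, "sim_config"))
  one_stream <- function(stream, attended) {
    seqn <- if (config$paradigm == 3) {
      dense_sequence(config$target_range, config$trial_dur,
                     config$dense_gap)
    } else {
      oddball_sequence(config$n_events, config$target_range,
                       config$trial_dur)
    }
    tt <- if (config$paradigm == 1) {
      ifelse(seqn$is_target, "TARGET", "NONTARGET")
    } else if (attended) {
      ifelse(seqn$is_target, "AT", "AN")
    } else {
      ifelse(seqn$is_target, "UT", "UN")
    }
    data.frame(onset = offset + seqn$onset, duration = 0.5,
               trial_type = tt, stream = stream, trial = trial,
               stringsAsFactors = FALSE)
  }
  if (config$paradigm == 1) {
    df <- one_stream("single", TRUE)
  } else {
    attended_left <- trial %% 2 == 1
    df <- rbind(one_stream("left", attended_left),
                one_stream("right", !attended_left))
    df <- df[order(df$onset), ]
    rownames(df) <- NULL
  }
  as_event_table(df)
}

#' Parametric ERP component template
#'
#' A windowed-Gaussian stand-in for the observed late positive component:
#' smooth, unimodal, positive, exactly zero at the window edges, with its
#' maximum equal to `amplitude` at the sample nearest `latency`.
#'
#' @param latency Peak latency, ms.
#' @param fwhm Full width at half maximum, ms.
#' @param amplitude Peak amplitude, uV.
#' @param sfreq Sampling rate, Hz.
#' @param duration Template duration, ms.
#' @return Numeric vector of `round(duration/1000*sfreq)` samples.
#' @export
#' @examples
#' tpl <- make_erp_template(625, 300, 4.15, 1000, 1000)
#' max(tpl)  # 4.15 at sample 626 (625 ms)
make_erp_template <- function(latency, fwhm, amplitude, sfreq,
                              duration = 1000) {
  if (fwhm <= 0 || sfreq <= 0 || duration <= 0) {
    stop("`fwhm`, `sfreq` and `duration` must be positive")
  }
  if (latency < 0 || latency > duration) {
    stop("`latency` must lie within [0, duration]")
  }
  if (latency + fwhm > duration) {
    stop("`latency` + `fwhm` must not exceed `duration`")
  }
  n <- round(duration / 1000 * sfreq)
  t <- (seq_len(n) - 1) / sfreq * 1000
  if (amplitude == 0) return(numeric(n))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  g <- exp(-0.5 * ((t - latency) / sigma)^2)
  # window the Gaussian: subtract the linear ramp through its edge
  # values (clamping at zero keeps the waveform non-negative), so the
  # template is exactly zero at both window edges; rescale the peak
  ramp <- g[1] + (g[n] - g[1]) * (t - t[1]) / (t[n] - t[1])
  h <- pmax(g - ramp, 0)
  peak <- which.min(abs(t - latency))
  h / h[peak] * amplitude
}

#' 1/f^alpha noise
#'
#' Spectral-synthesis coloured noise: independent Gaussian Fourier
#' coefficients shaped by f^(-alpha/2), scaled deterministically so the
#' expected per-channel variance equals `sigma^2`. Channels are generated
#' in pairs from single complex FFTs.
#'
#' @param n Samples per channel.
#' @param n_channels Number of independent channels.
#' @param exponent Spectral slope alpha (0 = white, 1 = pink).
#' @param sigma Standard deviation per channel.
#' @return Matrix, n_channels x n.
#' @export
pink_noise <- function(n, n_channels = 1, exponent = 1, sigma = 1) {
  k <- seq_len(n - 1)
  f <- pmin(k, n - k)  # magnitude of the FFT-bin frequency (units cancel)
  s <- f^(-exponent / 2)
  # fft(, inverse = TRUE) does not normalize: Var(Re x_j) = sum(s^2)/2
  scale <- sigma / sqrt(sum(s^2) / 2)
  out <- matrix(0, n_channels, n)
  n_pairs <- ceiling(n_channels / 2)
  # two independent channels per complex transform; batch the transforms
  # in chunks to bound memory
  chunk <- max(1L, min(n_pairs, floor(2^25 / n)))
  p0 <- 0L
  while (p0 < n_pairs) {
    np <- min(chunk, n_pairs - p0)
    Z <- matrix(complex(real = rnorm((n - 1) * np),
                        imaginary = rnorm((n - 1) * np)) *
                  (s / sqrt(2)), n - 1, np)
    X <- mvfft(rbind(0i, Z), inverse = TRUE)
    odd <- 2 * (p0 + seq_len(np)) - 1
    out[odd, ] <- t(Re(X)) * scale
    even <- odd[odd + 1 <= n_channels] + 1
    if (length(even)) out[even, ] <- t(Im(X[, seq_along(even),
                                            drop = FALSE])) * scale
    p0 <- p0 + np
  }
  out
}

# Sum of per-event templates: one source time course for the whole
# recording, amplitudes chosen by each event's condition.
build_component_source <- function(config, events, n_samples) {
  amp <- config$erp_amplitude
  amp <- c(amp, TARGET = unname(amp["AT"]), NONTARGET = unname(amp["AN"]))
  sigma <- config$erp_width / (2 * sqrt(2 * log(2)))
  # template long enough to hold the full tail of the component
  dur <- config$erp_latency + max(4 * sigma, config$erp_width)
  tpl <- make_erp_template(config$erp_latency, config$erp_width, 1,
                           config$sfreq, dur)
  src <- numeric(n_samples)
  for (i in seq_len(nrow(events))) {
    a <- amp[[events$trial_type[i]]]
    if (a == 0) next
    start <- round(events$onset[i] * config$sfreq) + 1
    idx <- start:min(start + length(tpl) - 1, n_samples)
    src[idx] <- src[idx] + a * tpl[seq_along(idx)]
  }
  src
}

# Ocular source: blinks at Poisson times, Gaussian-shaped lobes.
build_ocular_source <- function(config, n_samples) {
  src <- numeric(n_samples)
  dur_s <- n_samples / config$sfreq
  n_blinks <- rpois(1, config$eog_rate * dur_s)
  if (n_blinks == 0 || config$eog_amplitude == 0) return(src)
  times <- sort(runif(n_blinks, 0, dur_s))
  amps <- config$eog_amplitude * runif(n_blinks, 0.8, 1.2)
  half <- round(0.25 * config$sfreq)
  t <- (-half):half
  lobe <- exp(-0.5 * (t / (0.08 * config$sfreq))^2)
  for (b in seq_len(n_blinks)) {
    cidx <- round(times[b] * config$sfreq) + 1
    idx <- (cidx - half):(cidx + half)
    keep <- idx >= 1 & idx <= n_samples
    src[idx[keep]] <- src[idx[keep]] + amps[b] * lobe[keep]
  }
  src
}

#' Simulate a continuous scalp+ear EEG recording with events
#'
#' Forward model: `samples = leadfield(cognitive) x component_source +
#' leadfield(ocular) x blink_source + 1/f^alpha noise`. The cognitive
#' source is the sum of per-event component templates with amplitudes set
#' by each event's condition; the EOG channel carries the ocular source
#' plus low-level noise; ear channels carry attenuated cognitive weights
#' and `ear_noise_factor` times the scalp noise level. Trials are
#' concatenated into one continuous recording.
#'
#' @param config A [sim_config()].
#' @param subject Subject index; combined with `config$seed` it selects a
#'   deterministic child seed, so identical config + seed give
#'   bit-identical output.
#' @return List with elements `recording` ([eeg_recording]) and `events`
#'   ([as_event_table()]).
#' @export
simulate_recording <- function(config, subject = 1) {
  stopifnot(inherits(config, "sim_config"))
  run <- function() {
    groups <- default_channel_groups()
    channels <- names(groups)
    n_chan <- length(channels)
    n_samples <- round(config$n_trials * config$trial_dur * config$sfreq)

    events <- do.call(rbind, lapply(seq_len(config$n_trials), function(tr) {
      make_event_sequence(config, tr, offset = (tr - 1) * config$trial_dur)
    }))
    events <- as_event_table(events)

    lf_cog <- config$leadfield$cognitive[channels]
    lf_ocu <- config$leadfield$ocular[channels]
    src_cog <- build_component_source(config, events, n_samples)
    src_ocu <- build_ocular_source(config, n_samples)

    sig <- c(scalp = config$noise_sigma,
             ear_left = config$noise_sigma * config$ear_noise_factor,
             ear_right = config$noise_sigma * config$ear_noise_factor,
             eog = config$noise_sigma * 0.2)
    data <- pink_noise(n_samples, n_chan, config$noise_exponent, 1)
    # within an earpiece, most background noise is common to all six
    # electrodes (shared variance fraction ear_noise_shared); mix each
    # ear's channels with a per-ear common pink series accordingly
    rho <- config$ear_noise_shared
    if (rho > 0) {
      common <- pink_noise(n_samples, 2, config$noise_exponent, 1)
      for (k in 1:2) {
        idx <- which(groups == c("ear_left", "ear_right")[k])
        data[idx, ] <- sqrt(1 - rho) * data[idx, , drop = FALSE] +
          rep(sqrt(rho) * common[k, ], each = length(idx))
      }
    }
    data <- data * sig[groups]          # per-channel noise level
    data <- data + outer(lf_cog, src_cog)
    if (any(src_ocu != 0)) data <- data + outer(lf_ocu, src_ocu)
    rownames(data) <- channels
    rec <- eeg_recording(data, config$sfreq, channels, groups,
                         standard_montage32())
    list(recording = rec, events = events)
  }
  if (!is.null(config$seed)) {
    withr::with_seed(child_seed(config$seed, subject), run())
  } else {
    run()
  }
}
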