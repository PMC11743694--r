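#' Construct a continuous multi-channel EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts. Row
#'   names, if present, must match `labels`.
#' @param sfreq Sampling rate in Hz.
#' @param labels Character vector of channel labels (default: row names).
#' @param groups Named character vector mapping each channel to one of
#'   `"scalp"`, `"ear_left"`, `"ear_right"`, `"eog"`; inferred from labels
#'   when omitted (see [infer_channel_groups()]).
#' @param montage data.frame with columns `channel`, `x`, `y` giving 2D
#'   positions; required for all scalp channels (used by the spatial
#'   cluster test and topography tables).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, labels = rownames(data),
                          groups = NULL, montage = NULL) {
  data <- as.matrix(data)
  if (is.null(labels)) {
    stop("channel labels are required (row names or `labels`)")
  }
  if (length(labels) != nrow(data)) {
    stop("number of labels (", length(labels),
         ") does not match number of channels (", nrow(data), ")")
  }
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0) {
    stop("`sfreq` must be a single positive number")
  }
  if (is.null(groups)) groups <- infer_channel_groups(labels)
  if (length(groups) != length(labels)) {
    stop("number of group assignments (", length(groups),
         ") does not match number of channels (", length(labels), ")")
  }
  groups <- groups[labels]
  if (anyNA(groups)) stop("groups missing for some channels")
  scalp <- labels[groups == "scalp"]
  if (length(scalp) && !is.null(montage) &&
      !all(scalp %in% montage$channel)) {
    stop("montage missing for scalp channels: ",
         paste(setdiff(scalp, montage$channel), collapse = ", "))
  }
  rownames(data) <- labels
  structure(list(data = data, sfreq = sfreq, labels = labels,
                 groups = groups, montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$sfreq, " Hz (",
      sprintf("%.1f", ncol(x$data) / x$sfreq), " s)\n", sep = "")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                                 table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Condition vocabulary for event tables
#'
#' `TARGET`/`NONTARGET` are used in the single-stream paradigm; the
#' four-way attended/unattended x target/non-target terminology
#' (`AT`, `AN`, `UT`, `UN`) in competing-stream paradigms.
#' @export
event_conditions <- function() c("AT", "AN", "UT", "UN", "TARGET", "NONTARGET")

#' Validate and type an event table
#'
#' @param df data.frame with columns `onset` (seconds from recording
#'   start), `duration`, `trial_type` (one of [event_conditions()]),
#'   `stream` (`"single"`, `"left"` or `"right"`) and `trial`.
#' @param recording_duration Optional recording length in seconds; onsets
#'   at or beyond it are an error.
#' @return The validated data.frame, additionally of class `event_table`.
#' @export
as_event_table <- function(df, recording_duration = NULL) {
  required <- c("onset", "duration", "trial_type", "stream", "trial")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("event table is missing columns: ", paste(missing, collapse = ", "))
  }
  df$onset <- as.numeric(df$onset)
  df$duration <- as.numeric(df$duration)
  df$trial <- as.integer(df$trial)
  bad <- which(!df$trial_type %in% event_conditions())
  if (length(bad)) {
    stop("unknown condition token '", df$trial_type[bad[1]],
         "' at row ", bad[1])
  }
  # onsets strictly increasing within each trial and stream
  for (key in split(seq_len(nrow(df)),
                    list(df$trial, df$stream), drop = TRUE)) {
    o <- df$onset[key]
    if (any(diff(o) <= 0)) {
      stop("onsets not strictly increasing within trial ",
           df$trial[key[1]], " (row ", key[which(diff(o) <= 0)[1] + 1], ")")
    }
  }
  if (!is.null(recording_duration)) {
    bad <- which(df$onset < 0 | df$onset >= recording_duration)
    if (length(bad)) {
      stop("onset ", df$onset[bad[1]], " s at row ", bad[1],
           " outside the recording (duration ",
           recording_duration, " s)")
    }
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' Construct an epoch set
#'
#' @param data 3D numeric array, channels x samples x epochs, microvolts.
#' @param times Numeric vector of sample times in ms relative to event
#'   onset (length = dim(data)[2]).
#' @param conditions Character vector of per-epoch condition labels.
#' @param sfreq Sampling rate in Hz.
#' @param channels Channel labels (default: dimnames).
#' @param groups,montage Channel metadata carried over from the recording.
#' @param events Optional data.frame of source events (back-references).
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, conditions, sfreq,
                       channels = dimnames(data)[[1]],
                       groups = NULL, montage = NULL, events = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (length(times) != dim(data)[2]) stop("`times` does not match samples")
  if (length(conditions) != dim(data)[3]) {
    stop("`conditions` does not match number of epochs")
  }
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[1]))
  dimnames(data) <- list(channels, NULL, NULL)
  structure(list(data = data, times = times,
                 conditions = as.character(conditions), sfreq = sfreq,
                 channels = channels, groups = groups, montage = montage,
                 events = events),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("<eeg_epochs> ", dim(x$data)[3], " epochs x ", dim(x$data)[1],
      " channels x ", dim(x$data)[2], " samples, [",
      x$times[1], ", ", x$times[length(x$times)] + 1000 / x$sfreq,
      ") ms\n", sep = "")
  tab <- table(x$conditions)
  cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param x An `eeg_epochs` object.
#' @return Integer count.
#' @export
n_epochs <- function(x) dim(x$data)[3]

# Subset epochs by index, keeping metadata in sync.
subset_epochs <- function(x, idx) {
  eeg_epochs(x$data[, , idx, drop = FALSE], x$times, x$conditions[idx],
             x$sfreq, x$channels, x$groups, x$montage,
             if (!is.null(x$events)) x$events[idx, , drop = FALSE])
}

#' Construct an ERP wave
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param times Sample times in ms.
#' @param label Condition or contrast label (e.g. `"AT-AN"`).
#' @param n Number of epochs (or subjects, for grand averages) averaged.
#' @param channels Channel labels.
#' @return An object of class `erp_wave`.
#' @export
erp_wave <- function(data, times, label, n, channels = rownames(data)) {
  data <- as.matrix(data)
  if (length(times) != ncol(data)) stop("`times` does not match samples")
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- channels
  structure(list(data = data, times = times, label = label, n = n,
                 channels = channels),
            class = "erp_wave")
}

#' @export
print.erp_wave <- function(x, ...) {
  cat("<erp_wave> '", x$label, "': ", nrow(x$data), " channels x ",
      ncol(x$data), " samples (n = ", x$n, ")\n", sep = "")
  invisible(x)
}
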