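#' Average epochs of one condition into an ERP
#'
#' @param epochs An [eeg_epochs] object.
#' @param condition Condition label to average (one of
#'   [event_conditions()]); `NULL` averages all epochs.
#' @return An [erp_wave] with `n` = number of epochs averaged.
#' @export
average_epochs <- function(epochs, condition = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- if (is.null(condition)) seq_len(n_epochs(epochs)) else
    which(epochs$conditions == condition)
  if (!length(idx)) {
    stop("no epochs with condition '", condition,
         "' (empty condition after rejection?)")
  }
  d <- epochs$data[, , idx, drop = FALSE]
  m <- matrix(rowMeans(matrix(d, nrow = prod(dim(d)[1:2]))),
              nrow = dim(d)[1])
  erp_wave(m, epochs$times,
           if (is.null(condition)) "all" else condition,
           length(idx), epochs$channels)
}

#' Difference wave between two ERPs
#'
#' @param a,b [erp_wave] objects on identical time axes and channels.
#' @return An [erp_wave] equal to `a - b`, labelled `"<a>-<b>"`.
#' @export
difference_wave <- function(a, b) {
  stopifnot(inherits(a, "erp_wave"), inherits(b, "erp_wave"))
  if (!isTRUE(all.equal(a$times, b$times)) ||
      !identical(a$channels, b$channels)) {
    stop("ERP waves have mismatching time axes or channels")
  }
  erp_wave(a$data - b$data, a$times, paste0(a$label, "-", b$label),
           min(a$n, b$n), a$channels)
}

#' Grand average across subjects
#'
#' Unweighted mean of individual ERPs: each subject contributes equally
#' regardless of how many epochs entered their average.
#'
#' @param waves List of [erp_wave] objects with identical axes.
#' @return An [erp_wave] with `n` = number of subjects.
#' @export
grand_average <- function(waves) {
  if (!length(waves)) stop("empty list of ERP waves")
  ref <- waves[[1]]
  for (w in waves[-1]) {
    if (!isTRUE(all.equal(ref$times, w$times)) ||
        !identical(ref$channels, w$channels)) {
      stop("ERP waves have mismatching time axes or channels")
    }
  }
  m <- Reduce(`+`, lapply(waves, `[[`, "data")) / length(waves)
  erp_wave(m, ref$times, ref$label, length(waves), ref$channels)
}

#' Quantify the peak of an ERP within a time window
#'
#' Returns the maximum of the waveform in the window (positive-going
#' component convention) and its latency; ties are broken by the earliest
#' latency. A maximum on a window edge is flagged as non-local.
#'
#' @param wave An [erp_wave].
#' @param channel Channel label (or index) to read.
#' @param window Two-element window in ms, typically the significant
#'   cluster extent.
#' @return List with `amplitude` (uV), `latency` (ms) and `edge`
#'   (logical: maximum lies on a window edge, i.e. not a local peak).
#' @export
#' @examples
#' tpl <- make_erp_template(625, 300, 4.15, 1000, 1000)
#' w <- erp_wave(matrix(tpl, 1), seq(0, 999), "AT", 1, "Pz")
#' quantify_peak(w, "Pz", c(450, 920))
quantify_peak <- function(wave, channel, window) {
  stopifnot(inherits(wave, "erp_wave"))
  if (is.character(channel)) {
    if (!channel %in% wave$channels) stop("unknown channel: ", channel)
    channel <- match(channel, wave$channels)
  }
  sel <- which(wave$times >= window[1] & wave$times <= window[2])
  if (!length(sel)) stop("window contains no samples")
  v <- wave$data[channel, sel]
  i <- which.max(v)
  list(amplitude = v[i], latency = wave$times[sel[i]],
       edge = i == 1L || i == length(v))
}

#' Write an ERP wave as a tab-separated table
#'
#' Channels x time table with a commented metadata header (label, n,
#' sampling information).
#'
#' @param wave An [erp_wave].
#' @param path Output file path.
#' @param extra Named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_erp <- function(wave, path, extra = NULL) {
  hdr <- c(label = wave$label, n = wave$n, extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(hdr), hdr), con)
  tab <- data.frame(channel = wave$channels, wave$data,
                    check.names = FALSE)
  names(tab) <- c("channel", sprintf("%g", wave$times))
  utils::write.table(format(tab, digits = 10, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
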