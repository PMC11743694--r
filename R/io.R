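#' Write a recording to a documented array container
#'
#' The container is a pair of files: `<stem>_eeg.tsv`, a tab-separated
#' table with one column per channel (header = channel labels, one row
#' per sample, values in microvolts), and `<stem>_eeg.json`, a sidecar
#' holding the sampling rate, channel groups, units and the 2D montage.
#' A plain-text format keeps synthetic datasets portable and diffable.
#'
#' @param rec An [eeg_recording].
#' @param stem Path stem (without the `_eeg.tsv` suffix).
#' @return The data file path, invisibly.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  data_path <- paste0(stem, "_eeg.tsv")
  json_path <- paste0(stem, "_eeg.json")
  dt <- data.table::as.data.table(t(rec$data))
  data.table::setnames(dt, rec$labels)
  data.table::fwrite(dt, data_path, sep = "\t")
  meta <- list(SamplingFrequency = rec$sfreq, Units = "uV",
               ChannelGroups = as.list(rec$groups))
  if (!is.null(rec$montage)) meta$Montage2D <- rec$montage
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(data_path)
}

#' Read a recording from the array container
#'
#' @param path Path to the `_eeg.tsv` data file (the `_eeg.json` sidecar
#'   must sit next to it).
#' @return An [eeg_recording].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  json_path <- sub("\\.tsv$", ".json", path)
  if (!file.exists(json_path)) {
    stop("parse error for ", path, ": sidecar ", json_path, " is missing")
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (is.null(meta$SamplingFrequency)) {
    stop("parse error for ", path, ": no sampling-rate metadata")
  }
  if (!is.null(meta$Units) && meta$Units != "uV") {
    stop("parse error for ", path, ": ambiguous units '", meta$Units, "'")
  }
  dt <- data.table::fread(path, sep = "\t")
  labels <- names(dt)
  groups <- if (!is.null(meta$ChannelGroups)) {
    unlist(meta$ChannelGroups)
  } else infer_channel_groups(labels)
  montage <- if (!is.null(meta$Montage2D)) {
    as.data.frame(meta$Montage2D)
  } else NULL
  eeg_recording(t(as.matrix(dt)), meta$SamplingFrequency, labels,
                groups, montage)
}

#' Write an events table (events.tsv dialect)
#'
#' UTF-8, header row, decimal point, tab-separated columns `onset`,
#' `duration`, `trial_type`, `stream`, `trial`.
#'
#' @param events An event table (see [as_event_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- as_event_table(events)
  data.table::fwrite(as.data.frame(events)[, c("onset", "duration",
                                               "trial_type", "stream",
                                               "trial")],
                     path, sep = "\t")
  invisible(path)
}

#' Read and validate an events table
#'
#' @param path Path to an events.tsv file.
#' @param recording_duration Optional recording length (s); onsets beyond
#'   it are a validation error.
#' @return An `event_table`.
#' @export
read_events <- function(path, recording_duration = NULL) {
  if (!file.exists(path)) stop("events file not found: ", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  as_event_table(df, recording_duration)
}

#' Write a simulated dataset in a BIDS-style layout
#'
#' One directory per subject (`sub-01`, ...) containing an `eeg/`
#' folder with `sub-XX_task-paradigmP_eeg.tsv` + `.json` and
#' `sub-XX_task-paradigmP_events.tsv`; a dataset-level
#' `simulation.json` sidecar records the configuration.
#'
#' @param config A [sim_config()] with `n_subjects` and `seed` set.
#' @param dir Output directory (created if needed).
#' @return A `dataset_layout` (see [read_dataset_layout()]), invisibly.
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  cfg$leadfield <- NULL  # numeric weights are reproducible from the seed
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                       file.path(dir, "simulation.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in seq_len(config$n_subjects)) {
    sub <- sprintf("sub-%02d", s)
    subdir <- file.path(dir, sub, "eeg")
    dir.create(subdir, recursive = TRUE, showWarnings = FALSE)
    sim <- simulate_recording(config, s)
    stem <- file.path(subdir, sprintf("%s_task-paradigm%d", sub,
                                      config$paradigm))
    write_recording(sim$recording, stem)
    write_events(sim$events, paste0(stem, "_events.tsv"))
  }
  invisible(read_dataset_layout(dir))
}

#' Index a BIDS-style dataset directory
#'
#' @param dir Dataset root.
#' @return A `dataset_layout`: list with `root`, `subjects`, `paradigms`
#'   and a data.frame `files` with per-(subject, paradigm) recording and
#'   events paths. Every referenced file must exist.
#' @export
read_dataset_layout <- function(dir) {
  if (!dir.exists(dir)) stop("dataset directory not found: ", dir)
  recs <- list.files(dir, pattern = "_eeg\\.tsv$", recursive = TRUE,
                     full.names = TRUE)
  if (!length(recs)) stop("no recordings found under ", dir)
  files <- data.frame(
    subject = sub("^(sub-[0-9]+).*", "\\1", basename(recs)),
    paradigm = as.integer(sub(".*task-paradigm([0-9]+).*", "\\1",
                              basename(recs))),
    recording = recs,
    events = sub("_eeg\\.tsv$", "_events.tsv", recs),
    stringsAsFactors = FALSE)
  missing <- files$events[!file.exists(files$events)]
  if (length(missing)) {
    stop("missing events file(s): ", paste(missing, collapse = ", "))
  }
  structure(list(root = dir, subjects = sort(unique(files$subject)),
                 paradigms = sort(unique(files$paradigm)), files = files),
            class = "dataset_layout")
}
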