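# Domain types for one recording session -- stimulus epochs, sorted-unit
# spike trains, mean waveforms, multichannel LFP -- and the flat on-disk
# formats every other module consumes.
#
# Conventions: all times are in seconds, session-relative, and every window
# is half-open [start, end) so a boundary spike is never double-counted.

#' Closed label vocabularies
#'
#' Stimulus classes are bird's own song (`BOS`), its time-reversed version
#' (`BOS_REV`), conspecific song (`CON`) and white noise (`WN`). Contexts are
#' `solitary` (no audience), `social` (female audience, passive listening)
#' and `directed` (singing to a female). Unknown labels are hard errors:
#' silent label drift would corrupt every context comparison downstream.
#'
#' @name vocabularies
#' @export
ncm_stimuli <- function() c("BOS", "BOS_REV", "CON", "WN")

#' @rdname vocabularies
#' @export
ncm_contexts <- function() c("solitary", "social", "directed")

#' @rdname vocabularies
#' @export
ncm_sources <- function() c("playback", "vocalization")

#' Construct a validated stimulus-epoch table
#'
#' One row per playback or singing trial. `motif_bounds` carries the
#' per-motif sub-intervals used as firing-rate windows for songs; white
#' noise has a single bound spanning the whole stimulus, so whole-stimulus
#' rates fall out of the same code path.
#'
#' @param trial_id Integer trial identifiers.
#' @param stimulus Labels from [ncm_stimuli()].
#' @param context Labels from [ncm_contexts()].
#' @param onset_s,offset_s Stimulus interval in seconds.
#' @param motif_bounds List of two-column matrices `(start_s, end_s)`, one
#'   row per motif, nested in the epoch, sorted and non-overlapping.
#' @param source `"playback"` or `"vocalization"`.
#' @return A `data.frame` of class `epoch_table`, sorted by onset.
#' @export
epoch_table <- function(trial_id, stimulus, context, onset_s, offset_s,
                        motif_bounds, source) {
  df <- data.frame(
    trial_id = as.integer(trial_id),
    stimulus = as.character(stimulus),
    context = as.character(context),
    onset_s = as.numeric(onset_s),
    offset_s = as.numeric(offset_s),
    source = as.character(source),
    stringsAsFactors = FALSE
  )
  df$motif_bounds <- lapply(motif_bounds, function(m) {
    m <- matrix(as.numeric(m), ncol = 2,
                dimnames = list(NULL, c("start_s", "end_s")))
    m
  })
  df <- df[order(df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("epoch_table", "data.frame")
  validate_epochs(df)
  df
}

#' Validate an epoch table against its invariants
#'
#' Checks label vocabularies, onset < offset, motif nesting/ordering, the
#' single whole-stimulus bound for white noise, and pairwise non-overlap of
#' epochs.
#'
#' @param epochs An [epoch_table()].
#' @return The input, invisibly, or an error.
#' @export
validate_epochs <- function(epochs) {
  stopifnot(is.data.frame(epochs))
  bad_stim <- setdiff(unique(epochs$stimulus), ncm_stimuli())
  if (length(bad_stim) > 0)
    stop("unknown stimulus label(s): ", paste(bad_stim, collapse = ", "))
  bad_ctx <- setdiff(unique(epochs$context), ncm_contexts())
  if (length(bad_ctx) > 0)
    stop("unknown context label(s): ", paste(bad_ctx, collapse = ", "))
  bad_src <- setdiff(unique(epochs$source), ncm_sources())
  if (length(bad_src) > 0)
    stop("unknown source label(s): ", paste(bad_src, collapse = ", "))
  if (any(epochs$onset_s >= epochs$offset_s))
    stop("every epoch must satisfy onset_s < offset_s")
  for (i in seq_len(nrow(epochs))) {
    m <- epochs$motif_bounds[[i]]
    if (nrow(m) < 1) stop("epoch ", epochs$trial_id[i], " has no motif bounds")
    if (any(m[, 1] >= m[, 2]))
      stop("epoch ", epochs$trial_id[i], ": motif start >= end")
    if (any(m[, 1] < epochs$onset_s[i] - 1e-9) ||
        any(m[, 2] > epochs$offset_s[i] + 1e-9))
      stop("epoch ", epochs$trial_id[i], ": motif bounds outside stimulus")
    if (nrow(m) > 1) {
      if (is.unsorted(m[, 1]))
        stop("epoch ", epochs$trial_id[i], ": motif bounds unsorted")
      if (any(m[-nrow(m), 2] > m[-1, 1] + 1e-9))
        stop("epoch ", epochs$trial_id[i], ": overlapping motif bounds")
    }
    if (epochs$stimulus[i] == "WN") {
      ok <- nrow(m) == 1 &&
        abs(unname(m[1, 1]) - epochs$onset_s[i]) < 1e-9 &&
        abs(unname(m[1, 2]) - epochs$offset_s[i]) < 1e-9
      if (!ok)
        stop("epoch ", epochs$trial_id[i],
             ": WN must have one motif bound equal to the whole stimulus")
    }
  }
  if (nrow(epochs) > 1) {
    o <- order(epochs$onset_s)
    on <- epochs$onset_s[o]
    off <- epochs$offset_s[o]
    if (any(off[-length(off)] > on[-1] + 1e-12))
      stop("epochs overlap in time")
  }
  invisible(epochs)
}

#' Construct a spike train for one sorted unit
#'
#' @param unit_id Unit identifier.
#' @param spike_times_s Spike times in seconds; sorted on construction.
#' @param session_duration_s Total session duration; all times must fall in
#'   `[0, session_duration_s]`.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(unit_id, spike_times_s, session_duration_s) {
  spike_times_s <- sort(as.numeric(spike_times_s))
  if (length(spike_times_s) > 0 &&
      (spike_times_s[1] < 0 || spike_times_s[length(spike_times_s)] >
         session_duration_s))
    stop("spike times must lie within [0, session_duration_s]")
  structure(
    list(unit_id = as.character(unit_id),
         spike_times_s = spike_times_s,
         session_duration_s = as.numeric(session_duration_s)),
    class = "spike_train"
  )
}

#' Construct a mean spike waveform
#'
#' @param unit_id Unit identifier.
#' @param samples Amplitudes (arbitrary units), at least 8 samples.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return An object of class `waveform`.
#' @export
waveform <- function(unit_id, samples, sampling_rate_hz) {
  samples <- as.numeric(samples)
  if (length(samples) < 8) stop("waveform needs at least 8 samples")
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  structure(
    list(unit_id = as.character(unit_id), samples = samples,
         sampling_rate_hz = as.numeric(sampling_rate_hz)),
    class = "waveform"
  )
}

#' Construct a multichannel LFP recording
#'
#' @param signal Numeric matrix, samples in rows, channels in columns.
#' @param sampling_rate_hz Sampling rate in Hz; must exceed 100 Hz so the
#'   0--50 Hz analysis range is below Nyquist.
#' @param channels Channel names; defaults to the matrix column names.
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(signal, sampling_rate_hz, channels = NULL) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (is.null(channels)) channels <- colnames(signal)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(signal)))
  if (length(channels) != ncol(signal))
    stop("channel names must match signal columns")
  if (sampling_rate_hz <= 100)
    stop("sampling_rate_hz must exceed 100 Hz (2 x the 50 Hz analysis limit)")
  colnames(signal) <- channels
  structure(
    list(channels = as.character(channels), signal = signal,
         sampling_rate_hz = as.numeric(sampling_rate_hz)),
    class = "lfp_recording"
  )
}

#' Assemble a session
#'
#' @param session_id Session identifier.
#' @param epochs An [epoch_table()].
#' @param spike_trains List of [spike_train()] objects.
#' @param waveforms List of [waveform()] objects; every waveform must have a
#'   matching spike train.
#' @param lfp Optional [lfp_recording()].
#' @param metadata Free-form key/value list.
#' @return An object of class `ncm_session`.
#' @export
ncm_session <- function(session_id, epochs, spike_trains, waveforms = list(),
                        lfp = NULL, metadata = list()) {
  validate_epochs(epochs)
  train_ids <- vapply(spike_trains, function(x) x$unit_id, character(1))
  if (anyDuplicated(train_ids)) stop("duplicate unit_id among spike trains")
  names(spike_trains) <- train_ids
  wf_ids <- vapply(waveforms, function(x) x$unit_id, character(1))
  if (length(wf_ids) > 0 && !all(wf_ids %in% train_ids))
    stop("waveform unit_id without a matching spike train: ",
         paste(setdiff(wf_ids, train_ids), collapse = ", "))
  names(waveforms) <- wf_ids
  structure(
    list(session_id = as.character(session_id), epochs = epochs,
         spike_trains = spike_trains, waveforms = waveforms, lfp = lfp,
         metadata = metadata),
    class = "ncm_session"
  )
}

# ---------------------------------------------------------------------------
# motif-bound text encoding: "start:end" pairs joined by ";"

format_motif_bounds <- function(m) {
  paste(sprintf("%.9g:%.9g", m[, 1], m[, 2]), collapse = ";")
}

parse_motif_bounds <- function(s, path = "<string>", line = NA_integer_) {
  pairs <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- matrix(NA_real_, nrow = length(pairs), ncol = 2,
                dimnames = list(NULL, c("start_s", "end_s")))
  for (i in seq_along(pairs)) {
    se <- strsplit(pairs[i], ":", fixed = TRUE)[[1]]
    if (length(se) != 2 || anyNA(suppressWarnings(as.numeric(se))))
      stop_parse(path, line, paste0("malformed motif bound '", pairs[i], "'"))
    out[i, ] <- as.numeric(se)
  }
  out
}

# ---------------------------------------------------------------------------
# readers / writers

#' Read a stimulus-epoch table from CSV
#'
#' Expected header:
#' `trial_id,stimulus,context,onset_s,offset_s,motif_bounds,source`, with
#' motif bounds encoded as `start:end` pairs joined by `;`. Unknown labels
#' and malformed rows raise errors naming the offending file line.
#'
#' @param path CSV file path.
#' @return An [epoch_table()] sorted by onset.
#' @export
read_epoch_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("trial_id", "stimulus", "context", "onset_s", "offset_s",
            "motif_bounds", "source")
  if (!identical(names(df), need))
    stop("epoch table '", path, "' must have header ",
         paste(need, collapse = ","))
  if (nrow(df) == 0) {
    return(epoch_table(integer(0), character(0), character(0), numeric(0),
                       numeric(0), list(), character(0)))
  }
  for (i in seq_len(nrow(df))) {
    line <- i + 1L # header occupies line 1
    if (!df$stimulus[i] %in% ncm_stimuli())
      stop_parse(path, line, paste0("unknown stimulus '", df$stimulus[i], "'"))
    if (!df$context[i] %in% ncm_contexts())
      stop_parse(path, line, paste0("unknown context '", df$context[i], "'"))
    if (!df$source[i] %in% ncm_sources())
      stop_parse(path, line, paste0("unknown source '", df$source[i], "'"))
  }
  bounds <- lapply(seq_len(nrow(df)), function(i)
    parse_motif_bounds(df$motif_bounds[i], path, i + 1L))
  epoch_table(df$trial_id, df$stimulus, df$context,
              as.numeric(df$onset_s), as.numeric(df$offset_s),
              bounds, df$source)
}

#' Write a stimulus-epoch table to CSV
#'
#' @param epochs An [epoch_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_table <- function(epochs, path) {
  out <- data.frame(
    trial_id = epochs$trial_id,
    stimulus = epochs$stimulus,
    context = epochs$context,
    onset_s = sprintf("%.9f", epochs$onset_s),
    offset_s = sprintf("%.9f", epochs$offset_s),
    motif_bounds = vapply(epochs$motif_bounds, format_motif_bounds,
                          character(1)),
    source = epochs$source,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-unit spike times from CSV
#'
#' Expected header `unit_id,spike_time_s`. Returns one [spike_train()] per
#' distinct unit, times sorted. Negative times are a validation error.
#'
#' @param path CSV file path.
#' @param session_duration_s Session duration used for range validation;
#'   defaults to the latest spike time.
#' @return Named list of [spike_train()] objects.
#' @export
read_spike_table <- function(path, session_duration_s = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("unit_id", "spike_time_s")))
    stop("spike table '", path, "' must have header unit_id,spike_time_s")
  if (nrow(df) > 0 && any(df$spike_time_s < 0))
    stop("negative spike time in '", path, "'")
  if (is.null(session_duration_s))
    session_duration_s <- if (nrow(df) > 0) max(df$spike_time_s) else 0
  ids <- unique(df$unit_id)
  out <- lapply(ids, function(id)
    spike_train(id, df$spike_time_s[df$unit_id == id], session_duration_s))
  names(out) <- ids
  out
}

#' @rdname read_spike_table
#' @param trains Named list of [spike_train()] objects to serialize.
#' @export
write_spike_table <- function(trains, path) {
  rows <- lapply(trains, function(tr)
    if (length(tr$spike_times_s) > 0)
      data.frame(unit_id = tr$unit_id,
                 spike_time_s = sprintf("%.9f", tr$spike_times_s),
                 stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(unit_id = character(0), spike_time_s = character(0))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write mean-waveform tables
#'
#' CSV with header `unit_id,sampling_rate_hz,samples`, samples `;`-joined.
#'
#' @param path CSV file path.
#' @return `read_waveform_table`: named list of [waveform()] objects.
#' @export
read_waveform_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), c("unit_id", "sampling_rate_hz", "samples")))
    stop("waveform table '", path,
         "' must have header unit_id,sampling_rate_hz,samples")
  out <- lapply(seq_len(nrow(df)), function(i)
    waveform(df$unit_id[i],
             as.numeric(strsplit(df$samples[i], ";", fixed = TRUE)[[1]]),
             as.numeric(df$sampling_rate_hz[i])))
  names(out) <- df$unit_id
  out
}

#' @rdname read_waveform_table
#' @param waveforms Named list of [waveform()] objects.
#' @export
write_waveform_table <- function(waveforms, path) {
  out <- data.frame(
    unit_id = vapply(waveforms, function(w) w$unit_id, character(1)),
    sampling_rate_hz = vapply(waveforms, function(w)
      sprintf("%.9g", w$sampling_rate_hz), character(1)),
    samples = vapply(waveforms, function(w)
      paste(sprintf("%.9g", w$samples), collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  if (length(waveforms) == 0)
    out <- data.frame(unit_id = character(0), sampling_rate_hz = character(0),
                      samples = character(0))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write LFP recordings
#'
#' On disk an LFP is `<base>.bin` (little-endian 32-bit float, channel-major)
#' plus a `<base>.json` sidecar holding `sampling_rate_hz`, `channels` and
#' `n_samples`. Binary round trips are exact only to float32 precision
#' (about 1e-7 relative), a deliberate size/precision trade-off.
#'
#' @param base Path without extension.
#' @return `read_lfp`: an [lfp_recording()].
#' @export
read_lfp <- function(base) {
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  n <- as.integer(meta$n_samples)
  chans <- as.character(meta$channels)
  con <- file(paste0(base, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n * length(chans), size = 4,
               endian = "little")
  sig <- matrix(x, nrow = n, ncol = length(chans)) # channel-major on disk
  lfp_recording(sig, meta$sampling_rate_hz, chans)
}

#' @rdname read_lfp
#' @param lfp An [lfp_recording()].
#' @export
write_lfp <- function(lfp, base) {
  meta <- list(sampling_rate_hz = lfp$sampling_rate_hz,
               channels = lfp$channels,
               n_samples = nrow(lfp$signal))
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(base, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(lfp$signal), con, size = 4, endian = "little")
  invisible(base)
}

#' Write and read per-unit metrics tables
#'
#' One row per unit x stimulus x context with the derived response
#' quantities; numeric fields round-trip to 1e-9.
#'
#' @param metrics Data frame with columns `unit_id, unit_class, stimulus,
#'   context, n_trials, mean_fr_hz, mean_blfr_hz, z, rs, ssa_ratio,
#'   offset_ratio, offset_z, responsive`.
#' @param path CSV file path.
#' @export
write_metrics_table <- function(metrics, path) {
  cols <- metrics_columns()
  stopifnot(all(cols %in% names(metrics)))
  out <- metrics[, cols, drop = FALSE]
  num <- c("mean_fr_hz", "mean_blfr_hz", "z", "rs", "ssa_ratio",
           "offset_ratio", "offset_z")
  for (cn in num) out[[cn]] <- sprintf("%.12g", out[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), metrics_columns()))
    stop("metrics table '", path, "' has unexpected header")
  df$responsive <- as.logical(df$responsive)
  df
}

metrics_columns <- function() {
  c("unit_id", "unit_class", "stimulus", "context", "n_trials",
    "mean_fr_hz", "mean_blfr_hz", "z", "rs", "ssa_ratio", "offset_ratio",
    "offset_z", "responsive")
}

#' Write a session to a directory
#'
#' Emits `epochs.csv`, `spikes.csv`, `waveforms.csv`, optional
#' `lfp.bin`/`lfp.json`, and a `session.json` with the id, duration and
#' metadata.
#'
#' @param session An [ncm_session()].
#' @param dir Output directory (created if missing).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_epoch_table(session$epochs, file.path(dir, "epochs.csv"))
  write_spike_table(session$spike_trains, file.path(dir, "spikes.csv"))
  write_waveform_table(session$waveforms, file.path(dir, "waveforms.csv"))
  dur <- if (length(session$spike_trains) > 0)
    session$spike_trains[[1]]$session_duration_s else 0
  meta <- list(session_id = session$session_id,
               session_duration_s = dur,
               metadata = session$metadata)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(session$lfp)) write_lfp(session$lfp, file.path(dir, "lfp"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  epochs <- read_epoch_table(file.path(dir, "epochs.csv"))
  trains <- read_spike_table(file.path(dir, "spikes.csv"),
                             session_duration_s = meta$session_duration_s)
  waveforms <- read_waveform_table(file.path(dir, "waveforms.csv"))
  lfp <- if (file.exists(file.path(dir, "lfp.json")))
    read_lfp(file.path(dir, "lfp")) else NULL
  ncm_session(meta$session_id, epochs, trains, waveforms, lfp,
              as.list(meta$metadata))
}
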