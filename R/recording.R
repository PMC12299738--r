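#' Multichannel EEG recording container
#'
#' Bundles a samples-by-channels matrix of microvolt values with its sampling
#' rate, channel labels and free-form provenance metadata. All downstream
#' operations (filtering, blink detection, epoching) take and return this
#' class.
#'
#' @param data numeric matrix, samples x channels, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique channel names, one per
#'   column of `data`.
#' @param meta named list of provenance fields (system label, seed, filter
#'   history, ...). A `filter_history` character vector is appended to by the
#'   filtering functions.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != ncol(data)) {
    stop("length(channel_labels) must equal ncol(data)")
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique")
  }
  colnames(data) <- channel_labels
  if (is.null(meta$filter_history)) meta$filter_history <- character(0)
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels, meta = meta),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs
  ))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (length(x$meta$filter_history)) {
    cat("  filters :", paste(x$meta$filter_history, collapse = " | "), "\n")
  }
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `eeg_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' Extract one channel as a numeric vector
#' @param rec an `eeg_recording`.
#' @param channel channel label.
#' @return numeric vector of microvolt samples.
#' @export
get_channel <- function(rec, channel) {
  if (!channel %in% rec$channel_labels) {
    stop(sprintf(
      "channel '%s' not found; available: %s",
      channel, paste(rec$channel_labels, collapse = ", ")
    ))
  }
  rec$data[, channel]
}

#' Flag large-amplitude samples
#'
#' Automated stand-in for visual inspection of raw traces: reports (never
#' removes) any sample whose absolute amplitude exceeds a threshold.
#'
#' @param rec an `eeg_recording`.
#' @param threshold_uv absolute amplitude threshold in microvolts.
#' @return data.frame with columns `channel`, `sample`, `value_uv`
#'   (zero rows when the recording is clean).
#' @export
flag_large_amplitude <- function(rec, threshold_uv = 500) {
  idx <- which(abs(rec$data) > threshold_uv, arr.ind = TRUE)
  data.frame(
    channel = rec$channel_labels[idx[, 2L]],
    sample = as.integer(idx[, 1L]),
    value_uv = rec$data[idx],
    stringsAsFactors = FALSE
  )
}

#' Write a recording to CSV + JSON sidecar
#'
#' The CSV holds one column per channel (microvolts); the sidecar carries
#' sampling rate, labels, units and metadata, so the pair round-trips through
#' [read_recording()].
#'
#' @param rec an `eeg_recording`.
#' @param path path of the CSV file; the sidecar is written next to it with
#'   a `.json` extension.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  data.table::fwrite(data.table::as.data.table(rec$data), path)
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(
      fs = rec$fs, channel_labels = rec$channel_labels, units = "uV",
      meta = rec$meta
    ),
    sidecar,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path path to an `.edf` file or to a `.csv` with a `.json` sidecar
#'   beside it.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @return An `eeg_recording` in file channel order, in microvolts.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "edf") {
    return(read_recording_edf(path))
  }
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop(sprintf("CSV sidecar not found: %s (need fs and channel labels)", sidecar))
  }
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(side$fs)) stop("sidecar is missing required field 'fs'")
  dat <- as.matrix(data.table::fread(path))
  labels <- side$channel_labels
  if (is.null(labels)) labels <- colnames(dat)
  meta <- if (is.list(side$meta)) side$meta else list()
  eeg_recording(dat, fs = side$fs, channel_labels = labels, meta = meta)
}
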