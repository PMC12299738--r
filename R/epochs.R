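# Blink-locked epoching and the composite time-frequency denoiser.

#' Segment a recording into blink-locked epochs
#'
#' Cuts a 3-s window around each blink maximum (T0 at time zero). Events
#' whose window would extend past either end of the recording are dropped
#' with a message; they are never padded.
#'
#' @param rec an `eeg_recording`.
#' @param events a `blink_events` object (or anything with `peak_samples`).
#' @param span epoch extent in seconds relative to T0.
#' @return An `epoch_set`: array `trials` (K x channels x samples),
#'   `time_axis` in seconds (0 at T0), `fs`, `channel_labels`, and
#'   `n_dropped` for provenance.
#' @export
epoch_around_blinks <- function(rec, events, span = c(-1.5, 1.5)) {
  fs <- rec$fs
  pre <- round(-span[1] * fs)
  post <- round(span[2] * fs)
  n <- n_samples(rec)
  peaks <- events$peak_samples
  usable <- peaks - pre >= 1L & peaks + post <= n
  if (sum(!usable) > 0) {
    message(sprintf("dropping %d blink(s) whose epoch exceeds the recording", sum(!usable)))
  }
  peaks <- peaks[usable]
  if (length(peaks) == 0L) stop("no usable blink events for epoching")
  T_len <- pre + post + 1L
  C <- ncol(rec$data)
  trials <- array(0, dim = c(length(peaks), C, T_len))
  for (k in seq_along(peaks)) {
    trials[k, , ] <- t(rec$data[(peaks[k] - pre):(peaks[k] + post), , drop = FALSE])
  }
  structure(
    list(
      trials = trials,
      time_axis = ((-pre):post) / fs,
      fs = fs,
      channel_labels = rec$channel_labels,
      peak_samples = peaks,
      n_dropped = sum(!usable)
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples (%.2f..%.2f s)\n",
    dim(x$trials)[1], dim(x$trials)[2], dim(x$trials)[3],
    min(x$time_axis), max(x$time_axis)
  ))
  invisible(x)
}

#' Baseline-correct trials and average them
#'
#' Subtracts from every trial and channel its mean over the pre-blink
#' baseline interval, then averages across trials.
#'
#' @param trials K x channels x samples array.
#' @param time_axis epoch time axis, seconds.
#' @param baseline baseline interval `(from, to)` in seconds.
#' @return A `cleaned_average`: matrix `waveform` (channels x samples),
#'   `n_trials`, `time_axis`, `baseline_interval`, and the baseline-corrected
#'   `trials` array.
#' @export
baseline_correct_and_average <- function(trials, time_axis, baseline = c(-1.5, -0.5)) {
  if (length(dim(trials)) != 3L) stop("trials must be a K x channels x samples array")
  bidx <- which(time_axis >= baseline[1] & time_axis <= baseline[2])
  if (length(bidx) == 0L) stop("baseline window lies outside the epoch")
  K <- dim(trials)[1]
  corrected <- trials
  for (k in seq_len(K)) {
    mu <- apply(trials[k, , bidx, drop = FALSE], 2, mean)
    corrected[k, , ] <- trials[k, , ] - mu
  }
  avg <- apply(corrected, c(2, 3), mean)
  structure(
    list(
      waveform = avg, n_trials = K, time_axis = time_axis,
      baseline_interval = baseline, trials = corrected
    ),
    class = "cleaned_average"
  )
}

#' Time-frequency denoise blink-locked epochs
#'
#' For every trial and channel: forward STFT, delta-band binary mask,
#' least-squares inverse STFT; then baseline correction over the pre-blink
#' interval and trial averaging. One identical mask is used for every
#' channel and trial.
#'
#' @param epochs an `epoch_set`.
#' @param p an [stft_params()]; defaults to the 128 ms / 100 ms Hamming
#'   analysis at the epoch sampling rate.
#' @param f_keep,t_zero mask specification, see [build_mask()].
#' @param baseline baseline interval for [baseline_correct_and_average()].
#' @return `list(cleaned_trials = K x C x T array, average =
#'   cleaned_average, mask = binary_mask)`.
#' @export
denoise_epochs <- function(epochs, p = stft_params(epochs$fs),
                           f_keep = c(0.5, 4.0), t_zero = c(-0.5, 0.1),
                           baseline = c(-1.5, -0.5)) {
  dims <- dim(epochs$trials)
  K <- dims[1]; C <- dims[2]; T_len <- dims[3]
  t_start <- epochs$time_axis[1]
  t0_sample <- which.min(abs(epochs$time_axis)) # anchor the frame grid at T0
  probe <- stft_forward(epochs$trials[1, 1, ], p, t_start = t_start,
                        center_sample = t0_sample)
  mask <- build_mask(probe$frame_times, probe$freqs, f_keep, t_zero)
  cleaned <- array(0, dim = dims)
  for (k in seq_len(K)) {
    for (ch in seq_len(C)) {
      X <- stft_forward(epochs$trials[k, ch, ], p, t_start = t_start,
                        center_sample = t0_sample)
      Y <- apply_mask(X, mask)
      cleaned[k, ch, ] <- istft_inverse(Y, out_length = T_len)
    }
  }
  avg <- baseline_correct_and_average(cleaned, epochs$time_axis, baseline)
  list(cleaned_trials = avg$trials, average = avg, mask = mask)
}
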