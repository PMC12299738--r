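# Shared fixtures, built once per test run and memoized. Everything is
# generated in code from fixed seeds; no data files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# A default 3-minute recording (dry system) plus its ground truth.
default_session <- function() {
  memo("default_session", generate_recording(synth_config(seed = 42), "dry"))
}

# The same recording preprocessed (notch + 0.5-20 Hz band-pass).
default_preprocessed <- function() {
  memo("default_preprocessed", {
    s <- default_session()
    bandpass_filter(notch_filter(s$recording), 0.5, 20)
  })
}

# A noiseless session: blinks + BROs only, nothing stochastic in the signal.
noiseless_session <- function() {
  memo("noiseless_session", {
    cfg <- synth_config(
      seed = 7, background_std_uv = 0, alpha_amp_uv = 0,
      line_noise_amp_uv = 0
    )
    generate_recording(cfg, "dry")
  })
}

events_from_truth <- function(gt, fs = 256) {
  structure(
    list(
      peak_samples = gt$blink_peak_samples,
      scores = rep(NA_real_, length(gt$blink_peak_samples)),
      params = list(fs = fs, min_separation_s = 3)
    ),
    class = "blink_events"
  )
}

# Epoch set wrapping one waveform as K identical single-channel trials.
epochs_of <- function(x, reps = 2, fs = 256) {
  n <- length(x)
  tr <- array(0, c(reps, 1, n))
  for (r in seq_len(reps)) tr[r, 1, ] <- x
  structure(
    list(
      trials = tr, time_axis = seq(-(n - 1) / 2, (n - 1) / 2) / fs,
      fs = fs, channel_labels = "Fp1", peak_samples = integer(reps),
      n_dropped = 0L
    ),
    class = "epoch_set"
  )
}

# Matched-filter scoring of detected events against ground truth.
score_detection <- function(detected, truth, fs = 256, tol_s = 0.1) {
  tol <- tol_s * fs
  if (length(detected) == 0L) return(list(precision = NA_real_, recall = 0))
  hits <- vapply(detected, function(p) any(abs(truth - p) <= tol), logical(1))
  found <- vapply(truth, function(g) any(abs(detected - g) <= tol), logical(1))
  list(precision = mean(hits), recall = mean(found))
}
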