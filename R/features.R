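# Artifact-removal quantification and BRO response characteristics.

nearest_index <- function(time_axis, t) which.min(abs(time_axis - t))

#' Ocular contamination index
#'
#' Ratio of the trial-averaged signal amplitude at the blink maximum (0 ms)
#' to that at the -1000 ms pre-blink baseline. Absolute amplitudes are used
#' so the index stays well-defined and positive when the baseline sample
#' crosses zero; large OCI on raw data reflects the blink spike, and the
#' percent drop after cleaning quantifies artifact removal.
#'
#' @param waveform numeric trial-averaged waveform (one channel).
#' @param time_axis epoch time axis, seconds (must cover 0 and -1 s).
#' @param stage label stored with the result (`"raw"` or `"cleaned"`).
#' @return List of class `oci_result`: `oci`, `amp_t0`, `amp_baseline`,
#'   `stage`.
#' @export
compute_oci <- function(waveform, time_axis, stage = "raw") {
  if (min(time_axis) > -1 || max(time_axis) < 0) {
    stop("time axis must cover both 0 ms and -1000 ms")
  }
  amp0 <- waveform[nearest_index(time_axis, 0)]
  ampb <- waveform[nearest_index(time_axis, -1)]
  if (abs(ampb) < .Machine$double.eps) {
    stop("baseline amplitude is zero; OCI undefined")
  }
  structure(
    list(oci = abs(amp0) / abs(ampb), amp_t0 = amp0, amp_baseline = ampb,
         stage = stage),
    class = "oci_result"
  )
}

#' Measure the C1 and C2 BRO components
#'
#' C1 is the largest positive peak within 0-190 ms post-blink and C2 the
#' largest negative peak within 210-450 ms. Each amplitude is the mean over
#' a 20 ms window centred on its peak (truncated at the epoch edges);
#' latency is the peak time. The baseline amplitude is the mean over the
#' (-1300, -1100) ms pre-blink interval. Ties break to the earliest
#' latency.
#'
#' @param waveform numeric trial-averaged cleaned waveform (one channel).
#' @param time_axis epoch time axis, seconds.
#' @param c1_window,c2_window component search windows, ms post-blink.
#' @param peak_halfwidth_ms half-width of the amplitude-averaging window, ms.
#' @param baseline_window baseline interval, ms.
#' @return List of class `component_measures`: `c1_amp`, `c1_lat`, `c2_amp`,
#'   `c2_lat` (ms), `baseline_amp`.
#' @export
measure_components <- function(waveform, time_axis,
                               c1_window = c(0, 190), c2_window = c(210, 450),
                               peak_halfwidth_ms = 10,
                               baseline_window = c(-1300, -1100)) {
  tms <- time_axis * 1000
  need <- c(baseline_window[1], c2_window[2])
  if (min(tms) > need[1] || max(tms) < need[2]) {
    stop("component/baseline windows extend past the epoch")
  }
  peak_amp <- function(i) {
    idx <- which(tms >= tms[i] - peak_halfwidth_ms & tms <= tms[i] + peak_halfwidth_ms)
    mean(waveform[idx])
  }
  i1 <- which(tms >= c1_window[1] & tms <= c1_window[2])
  i2 <- which(tms >= c2_window[1] & tms <= c2_window[2])
  p1 <- i1[which.max(waveform[i1])] # which.max/min take the first (earliest) tie
  p2 <- i2[which.min(waveform[i2])]
  bidx <- which(tms >= baseline_window[1] & tms <= baseline_window[2])
  structure(
    list(
      c1_amp = peak_amp(p1), c1_lat = tms[p1],
      c2_amp = peak_amp(p2), c2_lat = tms[p2],
      baseline_amp = mean(waveform[bidx])
    ),
    class = "component_measures"
  )
}

# Complex Morlet wavelet bank (6 cycles), returned as a list of kernels.
morlet_bank <- function(freqs, fs, n_cycles = 6) {
  lapply(freqs, function(f) {
    sig_t <- n_cycles / (2 * pi * f)
    half <- ceiling(4 * sig_t * fs)
    t <- (-half:half) / fs
    env <- exp(-t^2 / (2 * sig_t^2))
    w <- env * exp(1i * 2 * pi * f * t)
    w / sum(env) # L1-normalized envelope: unit response to a matched sinusoid
  })
}

#' Morlet continuous wavelet transform log power
#'
#' Convolves the signal with 6-cycle complex Morlet wavelets at each
#' requested frequency and returns the logarithm of the squared coefficient
#' magnitudes. A floor of `1e-12` times the maximum squared magnitude keeps
#' the logarithm finite on silent segments.
#'
#' @param x numeric waveform.
#' @param fs sampling rate, Hz.
#' @param freqs frequency grid, Hz (within `(0, fs/2)`); default 0.5-20 Hz
#'   in 0.5 Hz steps, covering all delta sub-bands used downstream.
#' @param time_axis optional time axis of `x` (seconds) stored with the
#'   result.
#' @param n_cycles Morlet cycles.
#' @return A `tf_power`: matrix `log_power` (frequencies x times), `freqs`,
#'   `times`.
#' @export
cwt_log_power <- function(x, fs, freqs = seq(0.5, 20, by = 0.5),
                          time_axis = NULL, n_cycles = 6) {
  if (length(freqs) == 0L) stop("frequency grid is empty")
  if (any(freqs <= 0 | freqs >= fs / 2)) stop("frequencies must lie in (0, fs/2)")
  n <- length(x)
  bank <- morlet_bank(freqs, fs, n_cycles)
  maxlen <- max(vapply(bank, length, integer(1)))
  nfft <- stats::nextn(n + maxlen, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  power <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    w <- bank[[i]]
    half <- (length(w) - 1L) %/% 2L
    W <- stats::fft(c(w, rep(0, nfft - length(w))))
    conv <- stats::fft(X * W, inverse = TRUE) / nfft
    power[i, ] <- Mod(conv[(half + 1L):(half + n)])^2
  }
  floor_val <- 1e-12 * max(power)
  if (floor_val == 0) floor_val <- .Machine$double.xmin
  if (is.null(time_axis)) time_axis <- (seq_len(n) - 1L) / fs
  structure(
    list(log_power = log(power + floor_val), freqs = freqs, times = time_axis),
    class = "tf_power"
  )
}

#' Baseline-correct a time-frequency power map
#'
#' Subtracts from every frequency row its mean log power over the pre-blink
#' baseline interval. Applied per trial before trial averaging.
#'
#' @param P a `tf_power`.
#' @param baseline baseline interval in seconds.
#' @return The corrected `tf_power`.
#' @export
tf_baseline_correct <- function(P, baseline = c(-1.5, -0.5)) {
  bidx <- which(P$times >= baseline[1] & P$times <= baseline[2])
  if (length(bidx) == 0L) stop("baseline interval lies outside the map's time axis")
  mu <- rowMeans(P$log_power[, bidx, drop = FALSE])
  P$log_power <- P$log_power - mu
  P$baseline_interval <- baseline
  P
}

#' Sum spectral coefficients into delta sub-band time series
#'
#' Bins the frequency axis into low-delta (0.5-1.5 Hz), mid-delta
#' (1.5-3.5 Hz) and high-delta (3.5-4.5 Hz) by default -- membership is
#' closed on the left and open on the right, so shared edges are never
#' double-counted -- and sums coefficients across in-band frequencies at
#' each time point inside the post-blink window.
#'
#' @param P a `tf_power` (typically baseline-corrected, trial-averaged).
#' @param bands named list of `(lo, hi)` band edges, Hz.
#' @param window time window in seconds.
#' @return Named list of numeric series (one per band) with the window's
#'   time axis as attribute `times`.
#' @export
band_series <- function(P,
                        bands = list(
                          low_delta = c(0.5, 1.5),
                          mid_delta = c(1.5, 3.5),
                          high_delta = c(3.5, 4.5)
                        ),
                        window = c(0, 1.0)) {
  tidx <- which(P$times >= window[1] & P$times <= window[2])
  if (length(tidx) == 0L) stop("time window lies outside the map")
  out <- lapply(names(bands), function(b) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    fidx <- which(P$freqs >= lo & P$freqs < hi)
    if (length(fidx) == 0L) {
      stop(sprintf(
        "band '%s' [%g, %g) contains no grid frequencies (grid: %g..%g Hz)",
        b, lo, hi, min(P$freqs), max(P$freqs)
      ))
    }
    colSums(P$log_power[fidx, tidx, drop = FALSE])
  })
  names(out) <- names(bands)
  attr(out, "times") <- P$times[tidx]
  out
}
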