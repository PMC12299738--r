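# Short-time Fourier analysis/synthesis and the delta-band binary mask.
#
# Analysis uses a 128 ms Hamming window with a 100 ms hop. At 256 Hz the
# native bin spacing of a 33-sample window would be ~7.8 Hz -- far too
# coarse to represent a 0.5-4 Hz keep-band -- so frames are zero-padded to
# n_fft = fs samples (1 s), giving a 1 Hz frequency grid on which the mask
# is realizable. Synthesis is least-squares (window-weighted overlap-add
# normalized by the summed squared window), since a Hamming window at
# 26/33-sample hop does not satisfy constant-overlap-add exactly.

#' STFT parameters
#'
#' The canonical analysis uses a 128 ms Hamming window with 100 ms of
#' overlap between successive windows, i.e. a frame advance (hop) of 28 ms.
#' Reading the 100 ms figure as the *advance* instead would leave adjacent
#' 128 ms windows overlapping by just 7 samples; the least-squares
#' synthesis normalization then ripples by more than an order of magnitude
#' at the frame rate, and a masked reconstruction acquires spurious peaks
#' pinned to the normalization minima and strong frame-rate modulation
#' sidebands -- incompatible with the delta-band-concentrated cleaned
#' signals the mask is meant to produce. The dense-overlap reading is
#' therefore the default; `hop_ms` is available to build either variant
#' explicitly.
#'
#' @param fs sampling rate, Hz.
#' @param window_ms analysis window length, ms (Hamming).
#' @param overlap_ms overlap between successive windows, ms (ignored when
#'   `hop_ms` is given).
#' @param hop_ms optional explicit frame advance, ms.
#' @param n_fft transform length in samples (zero-padded); defaults to `fs`,
#'   i.e. a 1 Hz frequency grid on which a 0.5-4 Hz keep-band is
#'   representable. Sample counts are `round(ms * fs / 1000)`.
#' @return List of class `stft_params` with `win_len`, `hop`, `n_fft`,
#'   `window` (the Hamming taper) and `fs`.
#' @export
stft_params <- function(fs, window_ms = 128, overlap_ms = 100, hop_ms = NULL,
                        n_fft = round(fs)) {
  win_len <- round(window_ms * fs / 1000)
  hop <- if (is.null(hop_ms)) {
    win_len - round(overlap_ms * fs / 1000)
  } else {
    round(hop_ms * fs / 1000)
  }
  if (hop < 1L) stop("window/overlap combination yields a non-positive hop")
  if (hop > win_len) stop("hop must not exceed the window length")
  if (n_fft < win_len) stop("n_fft must be at least the window length")
  k <- seq_len(win_len) - 1L
  window <- 0.54 - 0.46 * cos(2 * pi * k / (win_len - 1))
  structure(
    list(fs = fs, win_len = win_len, hop = hop, n_fft = as.integer(n_fft),
         window = window),
    class = "stft_params"
  )
}

stft_frame_starts <- function(n, p, center_sample = NULL) {
  s0 <- 1L
  if (!is.null(center_sample)) {
    # shift the grid so one frame centre coincides with the anchor sample
    half <- (p$win_len - 1L) %/% 2L
    s0 <- ((center_sample - 1L - half) %% p$hop) + 1L
  }
  n_frames <- max(1L, ceiling((n - p$win_len + 1L - s0) / p$hop) + 1L)
  s0 + (seq_len(n_frames) - 1L) * p$hop
}

#' Forward STFT of one epoch channel
#'
#' @param x numeric waveform (length at least one window).
#' @param p an [stft_params()].
#' @param t_start time of `x[1]` in seconds (e.g. -1.5 for a blink-locked
#'   epoch), so frame times are reported relative to T0.
#' @param center_sample optional sample index to which the frame grid is
#'   anchored: one frame centre coincides with this sample. Blink-locked
#'   epochs anchor the grid at T0, so mask frame times are exact multiples
#'   of the hop around the blink maximum.
#' @return A `tf_map`: complex matrix `values` (frames x frequencies,
#'   one-sided), `frame_times` (window centres, s), `freqs` (Hz), plus the
#'   analysis parameters and original length needed for inversion.
#' @export
stft_forward <- function(x, p, t_start = 0, center_sample = NULL) {
  n <- length(x)
  if (n < p$win_len) stop("input shorter than the analysis window")
  starts <- stft_frame_starts(n, p, center_sample)
  xp <- c(x, rep(0, max(0, starts[length(starts)] + p$win_len - 1L - n)))
  frames <- vapply(starts, function(s) {
    c(xp[s:(s + p$win_len - 1L)] * p$window, rep(0, p$n_fft - p$win_len))
  }, numeric(p$n_fft))
  spec <- stats::mvfft(frames) # n_fft x n_frames
  nb <- p$n_fft %/% 2L + 1L
  structure(
    list(
      values = t(spec[seq_len(nb), , drop = FALSE]),
      frame_times = t_start + (starts - 1L + (p$win_len - 1) / 2) / p$fs,
      freqs = (seq_len(nb) - 1L) * p$fs / p$n_fft,
      params = p, n_samples = n, t_start = t_start, frame_starts = starts
    ),
    class = "tf_map"
  )
}

#' Build the delta-band binary mask
#'
#' Unity gain exactly where the frequency lies in the closed keep-band and
#' the frame time lies outside the open blink-interval; zero elsewhere:
#' gain 0 for `f < f_keep[1]` or `f > f_keep[2]`, gain 0 for
#' `t_zero[1] < t < t_zero[2]`, gain 1 otherwise. One mask is used for all
#' channels, trials, subjects and systems.
#'
#' @param frame_times frame centre times, s (relative to T0).
#' @param freqs frequency axis, Hz.
#' @param f_keep closed frequency keep-band, Hz.
#' @param t_zero open time interval to zero around the blink, s.
#' @return A `binary_mask`: 0/1 matrix `gains` (frames x frequencies) with
#'   the grid axes attached.
#' @export
build_mask <- function(frame_times, freqs, f_keep = c(0.5, 4.0),
                       t_zero = c(-0.5, 0.1)) {
  if (is.unsorted(frame_times) || is.unsorted(freqs)) stop("grid axes must be monotone")
  f_ok <- freqs >= f_keep[1] & freqs <= f_keep[2]
  t_bad <- frame_times > t_zero[1] & frame_times < t_zero[2]
  gains <- outer(!t_bad, f_ok) * 1
  structure(
    list(gains = gains, frame_times = frame_times, freqs = freqs,
         f_keep = f_keep, t_zero = t_zero),
    class = "binary_mask"
  )
}

#' Apply a binary mask to a time-frequency map
#'
#' @param X a `tf_map` from [stft_forward()].
#' @param M a `binary_mask` on the identical grid.
#' @return The masked `tf_map`; zero-gain cells are exactly zero.
#' @export
apply_mask <- function(X, M) {
  if (!isTRUE(all.equal(dim(X$values), dim(M$gains))) ||
    max(abs(X$frame_times - M$frame_times)) > 1e-9 ||
    max(abs(X$freqs - M$freqs)) > 1e-9) {
    stop("mask grid does not match the time-frequency map grid")
  }
  X$values <- X$values * M$gains
  X
}

#' Least-squares inverse STFT
#'
#' Each frame is inverse-transformed (conjugate symmetry restores the full
#' spectrum from the one-sided map), re-weighted by the analysis window and
#' overlap-added; the result is normalized by the summed squared window.
#' For an unmasked map this reconstructs the input to machine precision.
#'
#' @param Y a `tf_map` (possibly masked).
#' @param out_length output length in samples; defaults to the analyzed
#'   length.
#' @return Numeric waveform of length `out_length`.
#' @export
istft_inverse <- function(Y, out_length = Y$n_samples) {
  p <- Y$params
  nb <- ncol(Y$values)
  n_fft <- p$n_fft
  # restore two-sided spectra: bins 2..(nb-1) mirror as conjugates
  spec <- t(Y$values) # nb x n_frames
  if (n_fft %% 2L == 0L) {
    full <- rbind(spec, Conj(spec[(nb - 1L):2L, , drop = FALSE]))
  } else {
    full <- rbind(spec, Conj(spec[nb:2L, , drop = FALSE]))
  }
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / n_fft
  starts <- Y$frame_starts
  total <- max(starts[length(starts)] + p$win_len - 1L, out_length)
  num <- numeric(total)
  den <- numeric(total)
  for (m in seq_along(starts)) {
    idx <- starts[m]:(starts[m] + p$win_len - 1L)
    num[idx] <- num[idx] + p$window * frames[seq_len(p$win_len), m]
    den[idx] <- den[idx] + p$window^2
  }
  zero_cov <- den[seq_len(out_length)] <= 0
  if (any(zero_cov)) {
    # a shifted frame grid may leave a few edge samples uncovered; those
    # reconstruct as zero. A gap strictly inside the covered span means the
    # hop exceeds the window support and synthesis is ill-posed.
    covered <- which(!zero_cov)
    interior_gap <- any(zero_cov[seq(min(covered), max(covered))])
    if (interior_gap) {
      gap <- intersect(which(zero_cov), seq(min(covered), max(covered)))[1L]
      stop(sprintf("window normalization vanishes at sample %d (hop too large for the window)", gap))
    }
    den[zero_cov] <- 1
  }
  (num / den)[seq_len(out_length)]
}
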