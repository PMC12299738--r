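# Semi-automated template-matching blink detection on the vEOG channel.
#
# The vEOG is the Fp1 channel band-passed 0.5-16 Hz. A stereotypical blink
# (manually delimited or auto-selected) serves as template; "convolution"
# with the signal is realized as normalized cross-correlation, so the match
# score is scale-invariant similarity rather than raw local power. Events
# are anchored at the sample of maximum vEOG amplitude within the matched
# window (T0), then a temporal threshold removes blinks less than 3 s apart.

#' Extract the vertical EOG waveform
#'
#' @param rec an `eeg_recording`.
#' @param channel label of the vEOG channel (Fp1 by default, the electrode
#'   closest to the eyes).
#' @param band band-pass edges in Hz applied zero-phase (4th-order
#'   Butterworth) before detection.
#' @return Numeric waveform, same length as the recording.
#' @export
extract_veog <- function(rec, channel = "Fp1", band = c(0.5, 16)) {
  x <- get_channel(rec, channel) # errors with available labels if absent
  one <- eeg_recording(matrix(x, ncol = 1), rec$fs, channel)
  filtered <- bandpass_filter(one, band[1], band[2], order = 4)
  as.numeric(filtered$data[, 1])
}

#' Select a blink template from the vEOG
#'
#' @param veog numeric vEOG waveform.
#' @param fs sampling rate, Hz.
#' @param mode `"manual_span"` cuts `span` verbatim; `"auto"` finds the
#'   largest excursion above `k_mad` MADs over the median and cuts
#'   `half_width_s` around its maximum (so tests and batch runs need no
#'   operator).
#' @param span integer `(start_sample, end_sample)` for manual mode.
#' @param k_mad robust threshold (in MADs above the median) an excursion
#'   must exceed for auto-selection.
#' @param half_width_s half-length of the auto-cut template, seconds.
#' @return A `blink_template`: list with `waveform`, `source_span`, `fs`.
#' @export
select_template <- function(veog, fs, mode = c("auto", "manual_span"),
                            span = NULL, k_mad = 5, half_width_s = 0.35) {
  mode <- match.arg(mode)
  n <- length(veog)
  if (mode == "manual_span") {
    if (is.null(span) || length(span) != 2L) stop("manual_span mode needs span = c(start, end)")
    if (span[1] < 1 || span[2] > n || span[1] >= span[2]) stop("span outside signal")
    idx <- span[1]:span[2]
  } else {
    thr <- stats::median(veog) + k_mad * stats::mad(veog)
    if (!any(veog > thr) || !is.finite(thr) || stats::mad(veog) == 0) {
      stop("auto template selection found no suprathreshold excursion in the vEOG")
    }
    center <- which.max(veog)
    half <- round(half_width_s * fs)
    idx <- max(1L, center - half):min(n, center + half)
  }
  tpl <- list(waveform = veog[idx], source_span = c(idx[1], idx[length(idx)]), fs = fs)
  if (length(tpl$waveform) < 0.2 * fs) stop("template shorter than 0.2 s")
  class(tpl) <- "blink_template"
  tpl
}

# Sliding mean / sum of squares via cumulative sums (windows fully inside
# the signal; length(out) = n - L + 1, out[i] summarizes x[i:(i+L-1)]).
moving_sums <- function(x, L) {
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  i <- seq_len(length(x) - L + 1L)
  list(sum = cs[i + L] - cs[i], sumsq = cs2[i + L] - cs2[i])
}

#' Match blink candidates by normalized cross-correlation
#'
#' Slides the mean-removed, unit-energy template over the vEOG and scores
#' each lag by normalized cross-correlation, with one amendment: windows
#' whose (mean-removed) energy falls below the template's are further
#' penalized by their relative RMS, so a low-amplitude noise fluctuation
#' that merely resembles the blink shape cannot reach the threshold. At or
#' above template energy the score is scale-invariant similarity in
#' `[-1, 1]`. Local maxima of the score above `amp_threshold_frac` times
#' the best score become candidate blinks; each is anchored at the sample
#' of maximum vEOG amplitude within its matched window, defining T0.
#'
#' @param veog numeric vEOG waveform.
#' @param tpl a `blink_template`.
#' @param amp_threshold_frac fraction of the global best score a local
#'   maximum must reach (in `(0, 1]`).
#' @return data.frame with columns `peak_sample`, `score`, sorted by
#'   `peak_sample`; zero rows (with a warning) when nothing is
#'   suprathreshold.
#' @export
match_blinks <- function(veog, tpl, amp_threshold_frac = 0.6) {
  if (!(amp_threshold_frac > 0 && amp_threshold_frac <= 1)) {
    stop("amp_threshold_frac must be in (0, 1]")
  }
  tw <- tpl$waveform - mean(tpl$waveform)
  tnorm <- sqrt(sum(tw^2))
  if (tnorm == 0) stop("template is constant")
  L <- length(tw)
  n <- length(veog)
  if (n < L) stop("signal shorter than template")
  # numerator: correlation of signal with mean-removed template at each lag
  num <- as.numeric(stats::convolve(veog, tw, conj = TRUE, type = "filter"))
  ms <- moving_sums(veog, L)
  local_energy <- pmax(ms$sumsq - ms$sum^2 / L, 0)
  denom <- pmax(sqrt(local_energy), tnorm) * tnorm
  score <- ifelse(denom > 1e-12 * tnorm^2, num / denom, 0)
  peak_rel <- which.max(tpl$waveform) # anchor offset inside the template
  best <- max(score)
  if (best <= 0) {
    warning("no positive-similarity match found")
    return(data.frame(peak_sample = integer(0), score = numeric(0)))
  }
  thr <- amp_threshold_frac * best
  m <- length(score)
  is_localmax <- score >= thr &
    score >= c(-Inf, score[-m]) &
    score > c(score[-1], -Inf)
  cand <- which(is_localmax)
  if (length(cand) == 0L) {
    warning("no suprathreshold matches; returning empty event list")
    return(data.frame(peak_sample = integer(0), score = numeric(0)))
  }
  # suppress secondary maxima of the same blink: greedy by score, one event
  # per template-length neighborhood
  ord <- cand[order(score[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord) {
    if (all(abs(i - keep) >= L)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  anchor <- vapply(keep, function(i) {
    win <- i:(i + L - 1L)
    win[which.max(veog[win])]
  }, integer(1))
  out <- data.frame(peak_sample = anchor, score = score[keep])
  out <- out[!duplicated(out$peak_sample), , drop = FALSE]
  out[order(out$peak_sample), , drop = FALSE]
}

#' Apply the 3-s temporal separation rule
#'
#' Any event with a neighbor closer than `min_separation_s` is removed --
#' both members of a close pair are dropped, since either of them would
#' have its analysis window contaminated by the adjacent blink.
#'
#' @param events data.frame with a `peak_sample` column (and optionally
#'   `score`), sorted or not.
#' @param fs sampling rate, Hz.
#' @param min_separation_s minimum allowed gap between retained blink
#'   maxima, seconds.
#' @return A `blink_events` object: the surviving rows plus the parameters
#'   used, with `peak_sample` strictly increasing and all gaps at least
#'   `min_separation_s`.
#' @export
enforce_min_separation <- function(events, fs, min_separation_s = 3) {
  events <- events[order(events$peak_sample), , drop = FALSE]
  t <- events$peak_sample / fs
  k <- length(t)
  if (k > 1L) {
    gap_prev <- c(Inf, diff(t))
    gap_next <- c(diff(t), Inf)
    keep <- gap_prev >= min_separation_s & gap_next >= min_separation_s
    events <- events[keep, , drop = FALSE]
  }
  structure(
    list(
      peak_samples = as.integer(events$peak_sample),
      scores = if ("score" %in% names(events)) events$score else rep(NA_real_, nrow(events)),
      params = list(fs = fs, min_separation_s = min_separation_s)
    ),
    class = "blink_events"
  )
}

#' @export
print.blink_events <- function(x, ...) {
  cat(sprintf(
    "<blink_events> %d blinks (min separation %.1f s)\n",
    length(x$peak_samples), x$params$min_separation_s
  ))
  invisible(x)
}

#' Full blink-detection pass over a recording
#'
#' Convenience composition: vEOG extraction, auto (or manual) template
#' selection, normalized cross-correlation matching and the temporal
#' separation rule. A recording in which no blink can be identified yields
#' an empty `blink_events` (with a warning), never an error, mirroring how
#' a blink-free subject is excluded rather than crashing a batch run.
#'
#' @param rec an `eeg_recording` (already notch/band-pass preprocessed).
#' @param veog_channel vEOG channel label.
#' @param amp_threshold_frac see [match_blinks()].
#' @param min_separation_s see [enforce_min_separation()].
#' @param template optional pre-selected `blink_template`.
#' @return A `blink_events` object.
#' @export
detect_blinks <- function(rec, veog_channel = "Fp1", amp_threshold_frac = 0.6,
                          min_separation_s = 3, template = NULL) {
  veog <- extract_veog(rec, veog_channel)
  if (is.null(template)) {
    template <- tryCatch(select_template(veog, rec$fs, mode = "auto"),
      error = function(e) NULL
    )
  }
  if (is.null(template)) {
    warning("no blink template could be selected; returning empty event set")
    return(enforce_min_separation(
      data.frame(peak_sample = integer(0), score = numeric(0)),
      rec$fs, min_separation_s
    ))
  }
  cand <- match_blinks(veog, template, amp_threshold_frac)
  enforce_min_separation(cand, rec$fs, min_separation_s)
}
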