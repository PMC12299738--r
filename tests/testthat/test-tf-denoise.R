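# Epoching, STFT analysis/synthesis and the binary-mask denoiser.

test_that("epoching centres each trial on its blink maximum", {
  fs <- 256
  rec <- eeg_recording(matrix(seq_len(180 * fs), ncol = 1), fs, "Fp1")
  ev <- structure(
    list(peak_samples = c(10 * fs, 90 * fs), scores = c(1, 1),
         params = list(fs = fs, min_separation_s = 3)),
    class = "blink_events"
  )
  ep <- epoch_around_blinks(rec, ev)
  expect_equal(dim(ep$trials), c(2, 1, 3 * fs + 1))
  expect_equal(ep$trials[1, 1, ], as.numeric((10 * fs - 1.5 * fs):(10 * fs + 1.5 * fs)))
  expect_equal(ep$time_axis[which(ep$trials[1, 1, ] == 10 * fs)], 0)
  # events whose span exceeds the recording are dropped, not padded
  ev2 <- structure(
    list(peak_samples = c(round(0.5 * fs), 90 * fs), scores = c(1, 1),
         params = list(fs = fs, min_separation_s = 3)),
    class = "blink_events"
  )
  expect_message(ep2 <- epoch_around_blinks(rec, ev2), "dropping 1")
  expect_equal(dim(ep2$trials)[1], 1L)
  ev3 <- structure(
    list(peak_samples = 1L, scores = 1, params = list(fs = fs, min_separation_s = 3)),
    class = "blink_events"
  )
  expect_error(suppressMessages(epoch_around_blinks(rec, ev3)), "no usable")
})

test_that("STFT of elementary signals lands in the expected bins", {
  fs <- 256
  # frequency-mapping checks need a window long enough to resolve the
  # frequencies involved; one-second windows give an exactly 1 Hz grid
  p1 <- stft_params(fs, window_ms = 1000, overlap_ms = 500, n_fft = 256)
  # DC: interior frames concentrate energy at the bottom of the grid
  # (the Hamming taper itself spreads a deterministic ~15% into the
  # first side bins, so "the DC column" means f <= 1 Hz here)
  Xdc <- stft_forward(rep(1, 4 * fs), p1)
  interior <- which(Xdc$frame_times > 0.6 & Xdc$frame_times < 3.4)
  for (m in interior) {
    pw <- Mod(Xdc$values[m, ])^2
    expect_gte(sum(pw[Xdc$freqs <= 1]) / sum(pw), 0.99)
    expect_equal(which.max(pw), 1L)
  }
  # 2 Hz tone: maximum-magnitude bin at 2 Hz
  t <- (seq_len(4 * fs) - 1) / fs
  X2 <- stft_forward(sin(2 * pi * 2 * t), p1)
  for (m in interior) {
    expect_equal(X2$freqs[which.max(Mod(X2$values[m, ]))], 2)
  }
  # at the canonical 128 ms window the 1 Hz grid is interpolated: a 2 Hz
  # tone still dominates DC and the out-of-band bins above 10 Hz
  p <- stft_params(fs)
  Xs <- stft_forward(sin(2 * pi * 2 * (0:768) / fs), p)
  mid <- nrow(Xs$values) %/% 2
  pw <- Mod(Xs$values[mid, ])^2
  expect_gt(sum(pw[Xs$freqs >= 1 & Xs$freqs <= 4]), sum(pw[Xs$freqs > 10]))
  expect_error(stft_forward(rnorm(10), p), "shorter")
})

test_that("windowed-frame energy matches its spectrum (Parseval)", {
  fs <- 256
  p <- stft_params(fs)
  set.seed(21)
  x <- rnorm(769)
  X <- stft_forward(x, p)
  starts <- X$frame_starts
  m <- length(starts) %/% 2 # an interior frame
  seg <- x[starts[m]:(starts[m] + p$win_len - 1L)] * p$window
  time_energy <- sum(seg^2)
  v <- X$values[m, ]
  # one-sided spectrum: interior bins count twice
  spec_energy <- (Mod(v[1])^2 + 2 * sum(Mod(v[2:(length(v) - 1)])^2) +
    Mod(v[length(v)])^2) / p$n_fft
  expect_equal(spec_energy, time_energy, tolerance = 1e-6)
})

test_that("the binary mask matches its piece-wise definition", {
  ft <- seq(-1.5, 1.5, by = 0.05)
  fq <- seq(0, 20, by = 0.25)
  M <- build_mask(ft, fq)
  pick <- function(t, f) M$gains[which.min(abs(ft - t)), which.min(abs(fq - f))]
  expect_equal(pick(0.05, 2), 0) # inside the blink interval
  expect_equal(pick(0.5, 2), 1) # delta band, post-blink
  expect_equal(pick(0.5, 10), 0) # above the keep band
  # exhaustive case-by-case check over the dense grid
  expected <- outer(ft, fq, function(t, f) {
    as.numeric(!(f < 0.5 | f > 4.0) & !(t > -0.5 & t < 0.1))
  })
  expect_identical(M$gains, expected, ignore_attr = TRUE)
  # boundary convention: closed in frequency, open in time
  expect_equal(pick(-0.5, 4.0), 1)
  expect_equal(pick(0.1, 0.5), 1)
})

test_that("mask application is exact, idempotent and shape-checked", {
  p <- stft_params(256)
  X <- stft_forward(rnorm(769), p, t_start = -1.5)
  ones <- build_mask(X$frame_times, X$freqs, f_keep = c(0, 128), t_zero = c(0, 0))
  expect_equal(apply_mask(X, ones)$values, X$values)
  zeros <- build_mask(X$frame_times, X$freqs, f_keep = c(-2, -1), t_zero = c(0, 0))
  expect_true(all(apply_mask(X, zeros)$values == 0))
  M <- build_mask(X$frame_times, X$freqs)
  once <- apply_mask(X, M)
  expect_identical(apply_mask(once, M)$values, once$values)
  Xs <- stft_forward(rnorm(512), p, t_start = -1)
  expect_error(apply_mask(Xs, M), "grid")
})

test_that("least-squares synthesis inverts the analysis to machine precision", {
  fs <- 256
  p <- stft_params(fs)
  set.seed(31)
  x <- rnorm(769)
  for (anchor in list(NULL, 385L)) {
    X <- stft_forward(x, p, t_start = -1.5, center_sample = anchor)
    y <- istft_inverse(X)
    interior <- (p$win_len + 1):(769 - p$win_len)
    rel <- sqrt(mean((y - x)[interior]^2)) / sqrt(mean(x[interior]^2))
    expect_lt(rel, 1e-8)
  }
  # all-zero map gives a zero waveform
  X0 <- stft_forward(rep(0, 769), p)
  expect_equal(istft_inverse(X0), rep(0, 769))
  # linearity of the masked round trip
  y <- rnorm(769)
  clean <- function(v) {
    X <- stft_forward(v, p, t_start = -1.5, center_sample = 385L)
    istft_inverse(apply_mask(X, build_mask(X$frame_times, X$freqs)), 769)
  }
  expect_equal(clean(x + y), clean(x) + clean(y), tolerance = 1e-9)
  # the sparse-hop variant still round-trips (synthesis is exact LS either way)
  ps <- stft_params(fs, hop_ms = 100)
  Xs <- stft_forward(x, ps, t_start = -1.5)
  ys <- istft_inverse(Xs)
  interior <- (ps$win_len + 1):(769 - ps$win_len)
  expect_lt(sqrt(mean((ys - x)[interior]^2)) / sqrt(mean(x[interior]^2)), 1e-8)
})

test_that("baseline correction and trial averaging match the naive loop", {
  tax <- seq(-1.5, 1.5, length.out = 769)
  # constant trial averages to zero
  tr <- array(7, c(1, 2, 769))
  avg <- baseline_correct_and_average(tr, tax)
  expect_equal(max(abs(avg$waveform)), 0)
  # antisymmetric pair cancels
  v <- sin(seq(0, 6 * pi, length.out = 769))
  tr2 <- array(0, c(2, 1, 769)); tr2[1, 1, ] <- v; tr2[2, 1, ] <- -v
  expect_equal(max(abs(baseline_correct_and_average(tr2, tax)$waveform)), 0)
  # random set against an explicit double loop
  set.seed(4)
  tr3 <- array(rnorm(20 * 3 * 769), c(20, 3, 769))
  got <- baseline_correct_and_average(tr3, tax)
  bidx <- which(tax >= -1.5 & tax <= -0.5)
  expected <- matrix(0, 3, 769)
  for (ch in 1:3) {
    for (k in 1:20) {
      expected[ch, ] <- expected[ch, ] + (tr3[k, ch, ] - mean(tr3[k, ch, bidx])) / 20
    }
  }
  expect_equal(got$waveform, expected, tolerance = 1e-12)
  expect_equal(got$n_trials, 20L)
  # the baseline-interval mean of the average is zero by construction
  expect_lt(max(abs(rowMeans(got$waveform[, bidx]))), 1e-12)
  expect_error(baseline_correct_and_average(tr3, tax, baseline = c(-9, -8)), "outside")
})

test_that("the denoiser keeps delta content, rejects alpha, and contracts energy", {
  fs <- 256
  tax <- (-384:384) / fs
  d10 <- denoise_epochs(epochs_of(sin(2 * pi * 10 * tax)))
  d2 <- denoise_epochs(epochs_of(sin(2 * pi * 2 * tax)))
  r10 <- sqrt(mean(d10$average$waveform^2))
  reg <- tax > 0.3
  r2 <- sqrt(mean(d2$average$waveform[1, reg]^2)) / sqrt(mean(sin(2 * pi * 2 * tax[reg])^2))
  expect_lt(r10 / sqrt(0.5), 0.25) # 10 Hz reduced to a fraction of its input RMS
  expect_gte(r2, 0.5) # post-blink delta content survives
  expect_gt(r2, 3 * r10) # and much better than out-of-band content
  # energy non-increase of each cleaned trial (binary mask + LS synthesis)
  set.seed(17)
  for (i in 1:5) {
    x <- rnorm(769)
    ep <- epochs_of(x, reps = 1)
    den <- denoise_epochs(ep)
    expect_lte(sum(den$cleaned_trials[1, 1, ]^2), sum(x^2) + 1e-9)
  }
})

test_that("denoising a default session removes the blink spike at T0", {
  rec <- default_preprocessed()
  ev <- detect_blinks(rec)
  ep <- suppressMessages(epoch_around_blinks(rec, ev))
  den <- denoise_epochs(ep)
  t0 <- which.min(abs(ep$time_axis))
  cm <- measure_components(den$average$waveform[2, ], ep$time_axis)
  # no positive excursion at T0 exceeding 5x the measured post-blink C1
  expect_lt(abs(den$average$waveform[2, t0]), 5 * abs(cm$c1_amp))
  # raw spike was two orders of magnitude above the cleaned T0 value
  raw_avg <- apply(ep$trials, c(2, 3), mean)
  expect_gt(raw_avg[2, t0] / abs(den$average$waveform[2, t0]), 20)
})
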