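# OCI, C1/C2 component measurement, Morlet CWT power and band series.

test_that("OCI is the ratio of absolute amplitudes at 0 and -1000 ms", {
  tax <- seq(-1.5, 1.5, by = 1 / 256)
  w <- rep(0, length(tax))
  w[which.min(abs(tax + 1))] <- 1
  w[which.min(abs(tax))] <- 100
  r <- compute_oci(w, tax)
  expect_equal(r$oci, 100)
  w2 <- rep(3, length(tax))
  expect_equal(compute_oci(w2, tax)$oci, 1)
  wz <- rep(0, length(tax)); wz[which.min(abs(tax))] <- 5
  expect_error(compute_oci(wz, tax), "undefined")
  expect_error(compute_oci(w[1:100], tax[1:100]), "cover")
})

test_that("component measurement recovers constructed Gaussian peaks", {
  fs <- 256
  tax <- (-384:384) / fs
  w <- 4 * exp(-(tax - 0.1)^2 / (2 * 0.03^2)) - 4 * exp(-(tax - 0.25)^2 / (2 * 0.03^2))
  cm <- measure_components(w, tax)
  expect_lt(abs(cm$c1_lat - 100), 4)
  expect_lt(abs(cm$c2_lat - 250), 4)
  # 20 ms-window smoothing keeps the amplitude within 5% of the peak
  expect_lt(abs(cm$c1_amp - 4), 0.05 * 4)
  expect_lt(abs(cm$c2_amp + 4), 0.05 * 4)
  expect_lt(abs(cm$baseline_amp), 1e-6)
})

test_that("all-zero waveforms give zero amplitudes and earliest-sample latencies", {
  tax <- (-384:384) / 256
  cm <- measure_components(rep(0, 769), tax)
  expect_equal(cm$c1_amp, 0)
  expect_equal(cm$c2_amp, 0)
  expect_equal(cm$baseline_amp, 0)
  expect_equal(cm$c1_lat, min(tax[tax >= 0]) * 1000)
  expect_equal(cm$c2_lat, min(tax[tax >= 0.21]) * 1000)
})

test_that("component latencies equal a brute-force windowed scan", {
  tax <- (-384:384) / 256
  tms <- tax * 1000
  set.seed(33)
  for (i in 1:20) {
    w <- as.numeric(stats::filter(rnorm(769), rep(1 / 8, 8), sides = 2))
    w[is.na(w)] <- 0
    cm <- measure_components(w, tax)
    i1 <- which(tms >= 0 & tms <= 190)
    i2 <- which(tms >= 210 & tms <= 450)
    expect_equal(cm$c1_lat, tms[i1[which.max(w[i1])]])
    expect_equal(cm$c2_lat, tms[i2[which.min(w[i2])]])
  }
  expect_error(measure_components(rnorm(100), tax[1:100]), "past the epoch")
})

test_that("Morlet log power ridges at the stimulus frequency and scales as log", {
  fs <- 256
  t <- seq(0, 8, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  P <- cwt_log_power(x, fs, freqs = seq(0.5, 10, by = 0.5))
  interior <- which(t > 2.5 & t < 5.5)
  ridge <- P$freqs[apply(P$log_power[, interior], 2, which.max)]
  expect_true(all(ridge == 2))
  # zero signal floors to a finite constant
  Pz <- cwt_log_power(rep(0, 1000), fs)
  expect_true(all(is.finite(Pz$log_power)))
  expect_equal(stats::sd(Pz$log_power), 0)
  # doubling the signal raises log power by log(4) (above-floor interior)
  P2 <- cwt_log_power(2 * x, fs, freqs = seq(0.5, 10, by = 0.5))
  d <- P2$log_power[, interior] - P$log_power[, interior]
  big <- P$log_power[, interior] > max(P$log_power) - 12 # well above floor
  expect_equal(mean(d[big]), log(4), tolerance = 1e-6)
  expect_lt(stats::sd(d[big]), 1e-6)
  expect_error(cwt_log_power(x, fs, freqs = numeric(0)), "empty")
  expect_error(cwt_log_power(x, fs, freqs = c(1, 200)), "fs/2")
})

test_that("time-frequency baseline correction zeroes each row's baseline mean", {
  tax <- (-384:384) / 256
  set.seed(44)
  P <- structure(
    list(log_power = matrix(rnorm(40 * 769), 40), freqs = seq(0.5, 20, 0.5),
         times = tax),
    class = "tf_power"
  )
  Pc <- tf_baseline_correct(P)
  bidx <- which(tax >= -1.5 & tax <= -0.5)
  expect_lt(max(abs(rowMeans(Pc$log_power[, bidx]))), 1e-12)
  # adding a row-constant leaves the corrected map unchanged
  P2 <- P
  P2$log_power <- P$log_power + matrix(rnorm(40), 40, 769)
  expect_equal(tf_baseline_correct(P2)$log_power, Pc$log_power, tolerance = 1e-12)
  # naive per-row loop oracle
  expected <- P$log_power
  for (i in 1:40) expected[i, ] <- P$log_power[i, ] - mean(P$log_power[i, bidx])
  expect_equal(Pc$log_power, expected, tolerance = 1e-12)
  expect_error(tf_baseline_correct(P, baseline = c(5, 6)), "outside")
})

test_that("band series sum in-band rows with [lo, hi) membership", {
  tax <- seq(-1.5, 1.5, by = 1 / 256)
  fq <- seq(0.5, 4.5, by = 0.5)
  ones <- structure(
    list(log_power = matrix(1, length(fq), length(tax)), freqs = fq, times = tax),
    class = "tf_power"
  )
  bs <- band_series(ones)
  # low delta [0.5, 1.5) contains exactly the 0.5 and 1.0 Hz rows
  expect_true(all(bs$low_delta == 2))
  expect_equal(length(bs$low_delta), sum(tax >= 0 & tax <= 1))
  # power confined to 2 Hz shows up only in mid-delta
  only2 <- ones
  only2$log_power[, ] <- 0
  only2$log_power[fq == 2, ] <- 3
  bs2 <- band_series(only2)
  expect_true(all(bs2$mid_delta == 3))
  expect_true(all(bs2$low_delta == 0) && all(bs2$high_delta == 0))
  # brute-force double loop on random maps
  set.seed(5)
  P <- ones
  P$log_power <- matrix(rnorm(length(fq) * length(tax)), length(fq))
  got <- band_series(P)
  tidx <- which(tax >= 0 & tax <= 1)
  for (b in names(got)) {
    lo <- list(low_delta = 0.5, mid_delta = 1.5, high_delta = 3.5)[[b]]
    hi <- list(low_delta = 1.5, mid_delta = 3.5, high_delta = 4.5)[[b]]
    expected <- vapply(tidx, function(ti) {
      s <- 0
      for (fi in seq_along(fq)) if (fq[fi] >= lo && fq[fi] < hi) s <- s + P$log_power[fi, ti]
      s
    }, numeric(1))
    expect_equal(unname(got[[b]]), expected, tolerance = 1e-12)
  }
  expect_error(
    band_series(P, bands = list(gamma = c(30, 40))),
    "no grid frequencies"
  )
})
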