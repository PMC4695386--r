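test_that("bandpass keeps the passband and rejects the stopband", {
  fs <- 1000
  t <- (0:9999) / fs
  s8 <- lfp_channel(sin(2 * pi * 8 * t), fs = fs)
  inb <- bandpass(s8, c(4, 12))
  core <- 2000:8000
  expect_gt(stats::sd(inb$samples[core]) / stats::sd(s8$samples[core]), 0.95)
  outb <- bandpass(s8, c(100, 300))
  expect_lt(sqrt(mean(outb$samples[core]^2)) /
              sqrt(mean(s8$samples[core]^2)), 0.01)
  expect_error(bandpass(s8, c(100, 600)), "Nyquist")
})

test_that("ripple-band output of a mixture is dominated by 150 Hz (FFT oracle)", {
  fs <- 1000
  t <- (0:4095) / fs
  mix <- lfp_channel(sin(2 * pi * 8 * t) + 0.5 * sin(2 * pi * 150 * t),
                     fs = fs)
  y <- bandpass(mix, c(100, 300))$samples
  spec <- Mod(fft(y * signal::hanning(length(y))))[1:2048]
  freqs <- (0:2047) * fs / 4096
  expect_equal(freqs[which.max(spec)], 150, tolerance = 1)
})

test_that("compute_mua matches direct binning and Poisson expectations", {
  # 100 spikes uniform over 10 s, 1 tetrode -> mean 10 Hz
  st <- seq(0.05, 9.95, length.out = 100)
  m <- compute_mua(st, c(0, 10), sigma = 0)
  expect_equal(m$mean_rate, 10, tolerance = 0.01)
  # sigma = 0 equals direct histogram
  expect_equal(m$rate * m$bin_width,
               tabulate(findInterval(st, seq(0, 10, 0.01)), 1000))
  # Poisson 20 Hz, 50 s: mean within 3 s.e.
  st2 <- with_substream(4, "mua", sort(runif(rpois(1, 20 * 50), 0, 50)))
  m2 <- compute_mua(st2, c(0, 50))
  se <- sqrt(20 / 50)
  expect_lt(abs(m2$mean_rate - 20), 3 * se)
  expect_warning(compute_mua(numeric(0), c(0, 1)), "empty")
})

test_that("detect_spwr finds injected bursts and respects the speed gate", {
  bw <- 0.01
  base <- rep(5, 6000)   # 60 s at 10 ms bins, 5 Hz
  noise <- with_substream(5, "spwr", rnorm(6000, 0, 1))
  rate <- base + noise
  bump <- exp(-((1:6000 - 3000)^2) / (2 * 15^2)) * 6 * stats::sd(rate)
  rate_b <- rate + bump
  mk_mua <- function(r) structure(list(
    t = (seq_along(r) - 0.5) * bw, rate = r, counts = r * bw,
    mean_rate = mean(r), sd_rate = stats::sd(r), bin_width = bw,
    sigma = 0, span = c(0, length(r) * bw)), class = "mua_trace")
  ev <- detect_spwr(mk_mua(rate_b), function(t) rep(2, length(t)))
  expect_equal(nrow(ev), 1L)
  # boundary oracle: nearest mean crossings around the peak, direct scan
  r <- rate_b; mu <- mean(r)
  pk <- which.max(r)
  lo <- pk; while (r[lo] > mu) lo <- lo - 1
  hi <- pk; while (r[hi] > mu) hi <- hi + 1
  expect_equal(ev$start, (lo - 0.5) * bw, tolerance = bw)
  expect_equal(ev$end, (hi - 0.5) * bw, tolerance = bw)
  # same bump where speed = 20 cm/s is excluded
  ev2 <- detect_spwr(mk_mua(rate_b), function(t) rep(20, length(t)))
  expect_equal(nrow(ev2), 0L)
  # constant trace: no events, warning
  expect_warning(ev3 <- detect_spwr(mk_mua(rep(5, 6000)), NULL), "constant")
  expect_equal(nrow(ev3), 0L)
})

test_that("ripple power z-score matches known amplitude modulation", {
  fs <- 1000
  t <- (0:59999) / fs
  # amplitude-modulated 150 Hz carrier: baseline alternates 10/30 uV,
  # one event at 100 uV
  amp <- ifelse(floor(t) %% 2 == 0, 10, 30)
  ev_window <- t >= 30 & t < 30.2
  amp[ev_window] <- 100
  x <- lfp_channel(amp * sin(2 * pi * 150 * t), fs = fs, band = c(100, 300))
  events <- interval_set(30, 30.2, kind = "spwr")
  z <- ripple_power_z(x, events)
  env <- hilbert_analytic(x$samples)$envelope
  base <- !(t >= 30 & t < 30.2)
  z_expect <- (max(env[t >= 30 & t < 30.2]) - mean(env[base])) / sd(env[base])
  expect_equal(z, z_expect, tolerance = 1e-9)
  expect_gt(z, 2)
  # zero-variance baseline errors
  flat <- lfp_channel(rep(5, 5000), fs = fs)
  expect_error(ripple_power_z(flat, interval_set(1, 1.2)), "baseline")
})

test_that("detect_sws separates theta and delta blocks", {
  fs <- 500
  blk <- function(f, dur) sin(2 * pi * f * (0:(dur * fs - 1)) / fs)
  x <- lfp_channel(c(blk(8, 60), blk(2, 60), blk(8, 60), blk(2, 60)),
                   fs = fs)
  sws <- detect_sws(x)
  expect_equal(nrow(sws), 2L)
  expect_equal(sws$start, c(60, 180), tolerance = 5)
  expect_equal(sws$end, c(120, 240), tolerance = 10)
  expect_equal(nrow(detect_sws(lfp_channel(blk(8, 120), fs = fs))), 0L)
  all_delta <- detect_sws(lfp_channel(blk(2, 120), fs = fs))
  expect_gt(interval_duration(all_delta) / 120, 0.85)
})

test_that("detect_frames thresholds at the notch of a bimodal count histogram", {
  # exactly alternating 0 / 20 counts per bin in 1 s blocks
  sws <- interval_set(0, 60, kind = "sws")
  st <- with_substream(6, "frames", {
    unlist(lapply(seq(0, 58, by = 2), function(b)
      sort(runif(rpois(1, 2000), b + 1, b + 2))))
  })
  fr <- detect_frames(st, sws)
  expect_true(all((fr$end - fr$start) > 0.8))
  starts_true <- seq(1, 59, by = 2)
  matched <- vapply(fr$start, function(s) min(abs(s - starts_true)),
                    numeric(1))
  expect_lt(max(matched), 0.06)
  thr <- attr(fr, "threshold")
  expect_gt(thr, 0)       # between the zero mode and the 20 Hz mode
  expect_lt(thr, 15)
  # unimodal counts fall back with a warning
  st_u <- with_substream(6, "frames_u", sort(runif(600, 0, 60)))
  expect_warning(detect_frames(st_u, sws), "unimodal")
})

test_that("event-triggered LFP recovers a deflection latency of 84 ms", {
  fs <- 2000
  t <- (0:119999) / fs
  x <- with_substream(7, "etl", rnorm(length(t), 0, 2))
  onsets <- seq(5, 55, by = 1)
  for (o in onsets) x <- x - 50 * exp(-(t - (o + 0.084))^2 / (2 * 0.01^2))
  res <- event_triggered_lfp(lfp_channel(x, fs = fs), onsets)
  expect_equal(res$latency_ms, 84, tolerance = 2)
  # single event: average equals the snippet
  res1 <- event_triggered_lfp(lfp_channel(x, fs = fs), onsets[1])
  i0 <- round((onsets[1] - 0.2) * fs) + 1
  expect_equal(res1$mean, x[i0:(i0 + length(res1$lag) - 1)])
  # white-noise average shrinks as 1/sqrt(n) (CLT oracle)
  wn <- with_substream(7, "etl2", rnorm(length(t), 0, 5))
  on1 <- seq(1, 10, by = 1); on2 <- seq(1, 50, by = 0.55)
  a1 <- sd(event_triggered_lfp(lfp_channel(wn, fs = fs), on1)$mean)
  a2 <- sd(event_triggered_lfp(lfp_channel(wn, fs = fs), on2)$mean)
  expect_lt(a2, a1)
})
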