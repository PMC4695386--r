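# build a Poisson unit with a given rate profile around constructed events
poisson_unit <- function(span, rate_fn, rate_max, seed, name = "unit") {
  with_substream(seed, name,
                 replayvta:::poisson_times(span[1], span[2], rate_fn,
                                           rate_max))
}

gain_events <- function(n = 200, dur = 0.4, gap = 2.5) {
  s <- seq(5, by = gap, length.out = n)
  interval_set(s, s + dur, kind = "spwr")
}

gain_rate_fn <- function(events, base, gain) {
  function(t) base * ifelse(in_intervals(t, events), gain, 1)
}

test_that("reward-response classification separates RR from nonRR units", {
  span <- c(0, 600)
  trials <- data.frame(nosepoke = seq(10, 580, by = 20),
                       correct = rep(c(TRUE, TRUE, TRUE, FALSE),
                                     length.out = 29))
  # null unit: identical Poisson rate everywhere -> mostly nonRR
  null_cls <- vapply(1:60, function(s) {
    st <- poisson_unit(span, function(t) rep(8, length(t)), 8, s, "null")
    classify_reward_response(st, trials, "swm", span)$class
  }, character(1))
  expect_gte(mean(null_cls == "nonRR"), 0.85)
  # responsive unit: 10 Hz correct vs 3 Hz error acquisition
  rr_cls <- vapply(1:40, function(s) {
    rate <- function(t) {
      r <- rep(5, length(t))
      for (i in seq_len(nrow(trials))) {
        w <- t >= trials$nosepoke[i] & t < trials$nosepoke[i] + 3
        r[w] <- if (trials$correct[i]) 10 else 3
      }
      r
    }
    st <- poisson_unit(span, rate, 10, s, "rr")
    classify_reward_response(st, trials, "swm", span)$class
  }, character(1))
  expect_gte(mean(rr_cls == "RR"), 0.95)
  # low baseline rate is unclassified regardless of responses
  st_low <- seq(5, 595, by = 15)      # 0.067 Hz
  expect_equal(classify_reward_response(st_low, trials, "swm", span)$class,
               "unclassified")
  # linear rule: acquisition vs pre-approach baseline
  lin_trials <- data.frame(nosepoke = seq(10, 580, by = 20), correct = TRUE)
  rate_lin <- function(t) {
    r <- rep(4, length(t))
    for (np in lin_trials$nosepoke) r[t >= np & t < np + 3] <- 12
    r
  }
  st_lin <- poisson_unit(span, rate_lin, 12, 1, "lin")
  expect_equal(classify_reward_response(st_lin, lin_trials, "linear",
                                        span)$class, "RR")
})

test_that("waveform features equal landmark arithmetic on templates", {
  fs <- 31000
  # symmetric biphasic template with peaks at 0.2 and 1.4 ms
  t_ms <- (0:93) / fs * 1000
  w <- 100 * exp(-(t_ms - 0.2)^2 / (2 * 0.05^2)) -
    80 * exp(-(t_ms - 0.8)^2 / (2 * 0.15^2)) +
    50 * exp(-(t_ms - 1.4)^2 / (2 * 0.08^2))
  f <- waveform_features(w, fs)
  expect_equal(f$duration_ms, 1.2, tolerance = 0.05)
  expect_equal(f$trough_to_peak_ratio, 80 / 180, tolerance = 0.02)
  # |peak| = |trough| gives ratio 0.5
  w2 <- 100 * exp(-(t_ms - 0.3)^2 / (2 * 0.05^2)) -
    100 * exp(-(t_ms - 0.9)^2 / (2 * 0.1^2)) +
    30 * exp(-(t_ms - 1.5)^2 / (2 * 0.08^2))
  expect_equal(waveform_features(w2, fs)$trough_to_peak_ratio, 0.5,
               tolerance = 0.02)
  # monophasic waveform is flagged with zeros
  mono <- waveform_features(100 * exp(-(t_ms - 0.5)^2 / (2 * 0.1^2)), fs)
  expect_true(mono$monophasic)
  expect_equal(mono$duration_ms, 0)
  expect_equal(mono$trough_to_peak_ratio, 0)
  # the simulator's parametric templates hit their requested landmarks
  w3 <- replayvta:::vta_waveform(duration_ms = 1.3, ratio = 0.55)
  f3 <- waveform_features(w3, fs)
  expect_equal(f3$duration_ms, 1.3, tolerance = 0.1)
  expect_equal(f3$trough_to_peak_ratio, 0.55, tolerance = 0.06)
})

test_that("PETH modulation depth recovers injected event gains", {
  span <- c(0, 520)
  ev <- gain_events()
  for (g in c(0.5, 2, 3)) {
    st <- poisson_unit(span, gain_rate_fn(ev, 10, g), 10 * max(1, g),
                       round(10 * g), "gain")
    pe <- peth(st, ev)
    expect_equal(pe$depth, abs(g - 1), tolerance = 0.15)
    expect_equal(pe$sign, sign(g - 1))
  }
  # homogeneous unit: depth near zero
  st0 <- poisson_unit(span, function(t) rep(10, length(t)), 10, 3, "null")
  expect_lt(peth(st0, ev)$depth, 0.1)
})

test_that("bootstrap modulation significance is calibrated and powerful", {
  span <- c(0, 260)
  ev <- gain_events(n = 100)
  # null calibration: false-positive rate within the nominal band
  fp <- vapply(1:100, function(s) {
    st <- poisson_unit(span, function(t) rep(10, length(t)), 10, s, "bootnull")
    bootstrap_modulation(st, ev, n_boot = 500, seed = s)$significant
  }, logical(1))
  expect_gte(mean(fp), 0.0)
  expect_lte(mean(fp), 0.08)
  # 3x gain: detected in nearly all seeds
  hits <- vapply(1:40, function(s) {
    st <- poisson_unit(span, gain_rate_fn(ev, 10, 3), 30, s, "bootgain")
    bootstrap_modulation(st, ev, n_boot = 500, seed = s)$significant
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(bootstrap_modulation(1:5, gain_events(5)), "10 events")
})

test_that("theta locking recovers kappa and is null for uniform phases", {
  fs <- 1000
  dur <- 200
  tt <- (0:(dur * fs - 1)) / fs
  theta <- lfp_channel(cos(2 * pi * 8 * tt), fs = fs, band = c(4, 12))
  # spikes at known phases: inverse-sample von Mises, place at matching times
  mk_spikes <- function(ph) {
    cyc <- sample(5:(8 * dur - 10), length(ph), replace = TRUE)
    sort((cyc + (ph %% (2 * pi)) / (2 * pi)) / 8)
  }
  ph_vm <- with_substream(21, "vm", rvonmises(8000, pi / 4, 2))
  st <- with_substream(21, "place", mk_spikes(ph_vm))
  tl <- theta_locking(st, theta)
  expect_equal(tl$kappa, 2, tolerance = 0.25)
  expect_equal(tl$mu_deg, 45, tolerance = 6)
  expect_lt(tl$rayleigh_p, 1e-10)
  # uniform phases: small kappa, non-significant Rayleigh in most seeds
  res <- vapply(1:20, function(s) {
    ph_u <- with_substream(s, "u", runif(5000, -pi, pi))
    st_u <- with_substream(s, "up", mk_spikes(ph_u))
    tl_u <- theta_locking(st_u, theta)
    c(tl_u$kappa, tl_u$rayleigh_p)
  }, numeric(2))
  expect_gte(mean(res[1, ] < 0.05), 0.9)
  expect_gte(mean(res[2, ] > 0.05), 0.9)
})

test_that("simulated VTA units reproduce their configured structure", {
  ses <- small_session()
  cfg <- ses$cfg
  tru <- ses$vta$truth
  expect_equal(sum(tru$class == "RR"), round(cfg$rr_fraction * cfg$n_vta_units))
  # with the event gain set to 1, PETH modulation is near zero on average
  events <- interval_set(ses$hc$truth$events$start,
                         ses$hc$truth$events$end, kind = "spwr")
  cfg1 <- ses$cfg; cfg1$vta_spwr_gain <- 1
  vta1 <- simulate_vta(ses$behavior, ses$hc, cfg1)
  depths <- vapply(vta1$units, function(st) peth(st, events)$depth,
                   numeric(1))
  expect_lt(mean(depths), 0.25)
  # profile table runs end to end
  theta <- bandpass(ses$hc$lfp, c(4, 12))
  run_fn <- function(t) approx(ses$behavior$t, ses$behavior$speed, t,
                               rule = 2)$y > 10
  prof <- vta_unit_profile(ses$vta$units[[1]], ses$vta$waveforms[[1]],
                           ses$behavior$trials, cfg$task, ses$behavior$span,
                           events, theta, run_fn, seed = 5)
  expect_true(prof$class %in% c("RR", "nonRR", "unclassified"))
  expect_gt(prof$duration_ms, 0.9)    # RR units are wide-waveform
})
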