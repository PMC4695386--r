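# VTA unit characterization: reward responsiveness, waveform features,
# SPW-R peri-event modulation with bootstrap significance, theta locking.

spike_count_in <- function(st, t0, t1) {
  vapply(seq_along(t0), function(i) sum(st >= t0[i] & st < t1[i]), numeric(1))
}

#' Classify reward responsiveness of a VTA unit
#'
#' SWM task: reward responsive (RR) when firing rate differs on correct
#' versus error trials in either the approach window (2 s before nosepoke)
#' or the acquisition window (3 s after), two-sided t-tests at p < 0.05.
#' Linear track (and SWM sessions with no error trials, with a message):
#' RR when acquisition rate differs from a 3 s pre-approach baseline ending
#' 2 s before nosepoke (paired t-test). Units with session baseline rate
#' below `min_rate` are unclassified.
#'
#' @param spike_times unit spike times (s).
#' @param trials data frame with `nosepoke` (s) and `correct` (logical).
#' @param task `"swm"` or `"linear"`.
#' @param session_span length-2 recording span (s) for the baseline rate.
#' @param min_rate exclusion floor (Hz), default 0.3.
#' @param alpha significance level.
#' @return list with `class` (`"RR"`, `"nonRR"`, `"unclassified"`),
#'   `p_approach`, `p_acquisition`, `baseline_hz`.
#' @export
classify_reward_response <- function(spike_times, trials,
                                     task = c("swm", "linear"),
                                     session_span, min_rate = 0.3,
                                     alpha = 0.05) {
  task <- match.arg(task)
  base_hz <- length(spike_times) / diff(session_span)
  if (base_hz < min_rate)
    return(list(class = "unclassified", p_approach = NA, p_acquisition = NA,
                baseline_hz = base_hz))
  np <- trials$nosepoke
  appr <- spike_count_in(spike_times, np - 2, np) / 2
  acq <- spike_count_in(spike_times, np, np + 3) / 3
  if (task == "swm" && sum(!trials$correct) >= 5 && sum(trials$correct) >= 5) {
    cw <- trials$correct
    p1 <- stats::t.test(appr[cw], appr[!cw])$p.value
    p2 <- stats::t.test(acq[cw], acq[!cw])$p.value
  } else {
    if (task == "swm")
      message("classify_reward_response: too few error trials; ",
              "using the acquisition-vs-baseline rule")
    if (nrow(trials) < 5) stop("classify_reward_response: fewer than 5 trials")
    pre <- spike_count_in(spike_times, np - 5, np - 2) / 3
    p1 <- NA_real_
    p2 <- stats::t.test(acq, pre, paired = TRUE)$p.value
  }
  cls <- if (isTRUE(p1 < alpha) || isTRUE(p2 < alpha)) "RR" else "nonRR"
  list(class = cls, p_approach = p1, p_acquisition = p2, baseline_hz = base_hz)
}

#' Waveform duration and trough-to-peak ratio
#'
#' Duration is the time from the waveform's major (largest) positive peak to
#' its final positive peak; the ratio is `trough / (peak + trough)` on
#' absolute amplitudes, with the trough taken between the two peaks.
#' Monophasic waveforms return zeros with `monophasic = TRUE`.
#'
#' @param w mean waveform samples (uV).
#' @param fs waveform sampling rate (Hz), default 31000.
#' @return list with `duration_ms`, `trough_to_peak_ratio`, `monophasic`.
#' @export
waveform_features <- function(w, fs = 31000) {
  n <- length(w)
  if (n < 5L) stop("waveform_features: waveform too short")
  is_peak <- c(FALSE, w[2:(n - 1)] > w[1:(n - 2)] & w[2:(n - 1)] >= w[3:n],
               FALSE) & w > 0
  pk <- which(is_peak)
  if (length(pk) < 2L)
    return(list(duration_ms = 0, trough_to_peak_ratio = 0, monophasic = TRUE))
  major <- pk[which.max(w[pk])]
  final <- pk[length(pk)]
  if (final <= major) {
    later <- pk[pk > major]
    if (!length(later))
      return(list(duration_ms = 0, trough_to_peak_ratio = 0, monophasic = TRUE))
    final <- later[length(later)]
  }
  trough <- min(w[major:final])
  peak <- w[major]
  ratio <- if (trough < 0) abs(trough) / (abs(peak) + abs(trough)) else 0
  list(duration_ms = 1000 * (final - major) / fs,
       trough_to_peak_ratio = ratio, monophasic = FALSE)
}

#' Peri-event time histogram with modulation depth
#'
#' Spike rate aligned to SPW-R event onsets, Gaussian smoothed (sigma =
#' 50 ms). Modulation depth is the baseline-normalized difference between
#' the PETH at the event midpoint (median midpoint lag across the
#' variable-length events) and the mean rate over a 300 ms baseline ending
#' 100 ms before onset.
#'
#' @param spike_times unit spike times (s).
#' @param events `interval_set` of SPW-R events.
#' @param window length-2 lag window (s) around onset.
#' @param bin_width PETH bin (s).
#' @param sigma smoothing s.d. (s), default 50 ms.
#' @param baseline length-2 baseline lag window (s), default
#'   `c(-0.4, -0.1)`.
#' @return object of class `peth`: `lag`, `rate` (Hz), `baseline_hz`,
#'   `midpoint_lag`, `depth`, `sign`, `n_events`.
#' @export
peth <- function(spike_times, events, window = c(-0.5, 0.5),
                 bin_width = 0.010, sigma = 0.050, baseline = c(-0.4, -0.1)) {
  if (nrow(events) < 10L) stop("peth: need at least 10 events")
  onsets <- events$start
  edges <- seq(window[1], window[2], by = bin_width)
  centers <- (edges[-length(edges)] + edges[-1L]) / 2
  counts <- numeric(length(centers))
  for (t0 in onsets) {
    rel <- spike_times[spike_times >= t0 + window[1] &
                         spike_times < t0 + window[2]] - t0
    counts <- counts + tabulate(findInterval(rel, edges,
                                             rightmost.closed = FALSE),
                                nbins = length(centers))
  }
  rate <- counts / (length(onsets) * bin_width)
  rate <- as.numeric(smooth_gaussian(rate, sigma / bin_width))
  mid_lag <- stats::median((events$end - events$start) / 2)
  base_sel <- centers >= baseline[1] & centers < baseline[2]
  base_hz <- mean(rate[base_sel])
  if (!is.finite(base_hz) || base_hz <= 0)
    stop("peth: zero baseline rate; unit excluded")
  mid_rate <- rate[which.min(abs(centers - mid_lag))]
  structure(list(lag = centers, rate = rate, baseline_hz = base_hz,
                 midpoint_lag = mid_lag,
                 depth = abs(mid_rate - base_hz) / base_hz,
                 sign = sign(mid_rate - base_hz),
                 n_events = length(onsets)),
            class = "peth")
}

#' Bootstrap significance of SPW-R modulation
#'
#' Resamples the event-aligned raster (event rows, with replacement) and
#' compares, at the stated level, the rate in a 50 ms bin at the event
#' midpoint with the mean baseline rate: significant when the bootstrap
#' confidence interval of their paired difference excludes zero. (Both
#' intervals are also returned; requiring the two marginal intervals not to
#' overlap is markedly conservative because the resampled midpoint and
#' baseline rates share the event draw.)
#'
#' @param spike_times unit spike times (s).
#' @param events `interval_set` of events (>= 10).
#' @param n_boot bootstrap resamples, default 1000.
#' @param seed RNG seed.
#' @param level CI level (default 0.95).
#' @param baseline baseline lag window (s).
#' @return list with `significant`, `ci_mid`, `ci_base`.
#' @export
bootstrap_modulation <- function(spike_times, events, n_boot = 1000, seed = 1,
                                 level = 0.95, baseline = c(-0.4, -0.1)) {
  ne <- nrow(events)
  if (ne < 10L) stop("bootstrap_modulation: need at least 10 events")
  mids <- events$start + (events$end - events$start) / 2
  mid_rate <- spike_count_in(spike_times, mids - 0.025, mids + 0.025) / 0.05
  base_rate <- spike_count_in(spike_times, events$start + baseline[1],
                              events$start + baseline[2]) /
    diff(baseline)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  idx <- with_substream(seed, "bootstrap_modulation",
                        matrix(sample.int(ne, ne * n_boot, replace = TRUE),
                               n_boot, ne))
  bm <- rowMeans(matrix(mid_rate[idx], n_boot, ne))
  bb <- rowMeans(matrix(base_rate[idx], n_boot, ne))
  ci_mid <- stats::quantile(bm, qs, names = FALSE)
  ci_base <- stats::quantile(bb, qs, names = FALSE)
  ci_diff <- stats::quantile(bm - bb, qs, names = FALSE)
  list(significant = ci_diff[1] > 0 || ci_diff[2] < 0,
       ci_diff = ci_diff, ci_mid = ci_mid, ci_base = ci_base)
}

#' Theta phase locking of a unit
#'
#' Per-spike theta phase from the interpolated Hilbert angle of the
#' theta-band LFP (0 radians at the theta peak), restricted to run epochs;
#' Rayleigh test against uniformity and von Mises maximum-likelihood
#' (mu, kappa).
#'
#' @param spike_times unit spike times (s).
#' @param theta_lfp theta-band `lfp_channel`.
#' @param run_mask_fn function of time returning TRUE in run epochs, or
#'   NULL for all spikes.
#' @param min_spikes reliability floor (default 50).
#' @return list with `mu_deg` (in `[-180, 180)`), `kappa`, `rayleigh_p`,
#'   `n`, `reliable`.
#' @export
theta_locking <- function(spike_times, theta_lfp, run_mask_fn = NULL,
                          min_spikes = 50) {
  st <- spike_times
  if (!is.null(run_mask_fn)) st <- st[run_mask_fn(st)]
  tt <- lfp_times(theta_lfp)
  st <- st[st >= tt[1] & st <= tt[length(tt)]]
  an <- hilbert_analytic(theta_lfp$samples)
  ph <- unwrap_phase(an$phase)
  sp_phase <- stats::approx(tt, ph, st, rule = 2)$y %% (2 * pi)
  sp_phase <- atan2(sin(sp_phase), cos(sp_phase))
  n <- length(sp_phase)
  if (n < 2L)
    return(list(mu_deg = NA, kappa = NA, rayleigh_p = NA, n = n,
                reliable = FALSE))
  vm <- vonmises_mle(sp_phase)
  ray <- rayleigh_test(sp_phase)
  list(mu_deg = phase_deg(vm$mu), kappa = vm$kappa, rayleigh_p = ray$p,
       n = n, reliable = n >= min_spikes)
}

# phase unwrapping for interpolation across the -pi/pi seam
unwrap_phase <- function(p) {
  d <- diff(p)
  jump <- cumsum(c(0, round(-d / (2 * pi))))
  p + 2 * pi * jump
}

#' Full unit profile table row
#'
#' @param spike_times unit spikes (s); `waveform` mean waveform;
#'   `trials`, `task`, `session_span` per [classify_reward_response()];
#'   `events` SPW-R events; `theta_lfp`, `run_mask_fn` per
#'   [theta_locking()]; `seed` for the bootstrap.
#' @return one-row data frame with class, waveform, PETH and theta-locking
#'   summaries.
#' @export
vta_unit_profile <- function(spike_times, waveform, trials, task,
                             session_span, events, theta_lfp,
                             run_mask_fn = NULL, seed = 1) {
  cls <- classify_reward_response(spike_times, trials, task, session_span)
  wf <- waveform_features(waveform)
  pe <- tryCatch(peth(spike_times, events), error = function(e) NULL)
  bs <- if (!is.null(pe))
    tryCatch(bootstrap_modulation(spike_times, events, seed = seed),
             error = function(e) NULL) else NULL
  th <- theta_locking(spike_times, theta_lfp, run_mask_fn)
  data.frame(class = cls$class, baseline_hz = cls$baseline_hz,
             duration_ms = wf$duration_ms,
             trough_to_peak_ratio = wf$trough_to_peak_ratio,
             depth = if (!is.null(pe)) pe$depth else NA,
             mod_sign = if (!is.null(pe)) pe$sign else NA,
             significant = if (!is.null(bs)) bs$significant else NA,
             mu_deg = th$mu_deg, kappa = th$kappa,
             rayleigh_p = th$rayleigh_p)
}
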