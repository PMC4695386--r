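# Multiunit rate estimation and event detection: SPW-R bursts, slow wave
# sleep epochs, and SWS frames.

#' Multiunit activity trace
#'
#' Bins aggregated hippocampal spike times in `bin_width` bins, expresses the
#' count as a rate per tetrode, and smooths with a Gaussian window.
#'
#' @param spike_times numeric vector of spike times (s), all tetrodes pooled.
#' @param span length-2 recording span `[t0, t1)` (s).
#' @param bin_width bin width (s); default 10 ms.
#' @param sigma smoothing s.d. (s); `0` disables smoothing. Default 10 ms.
#' @param n_tetrodes number of tetrodes contributing (rate is per tetrode).
#' @return object of class `mua_trace`: `t` (bin centers), `rate` (Hz per
#'   tetrode), `counts` (raw per-bin spike counts), `mean_rate`, `sd_rate`,
#'   `bin_width`, `sigma`.
#' @export
compute_mua <- function(spike_times, span, bin_width = 0.010, sigma = 0.010,
                        n_tetrodes = 1L) {
  stopifnot(span[2] > span[1])
  if (length(spike_times) == 0L)
    warning("compute_mua: empty spike set; returning all-zero trace")
  else if (any(spike_times < span[1] | spike_times >= span[2]))
    stop("compute_mua: spike times outside recording span")
  edges <- seq(span[1], span[2], by = bin_width)
  if (edges[length(edges)] < span[2]) edges <- c(edges, span[2])
  counts <- if (length(spike_times)) {
    tabulate(findInterval(spike_times, edges, rightmost.closed = FALSE),
             nbins = length(edges) - 1L)
  } else numeric(length(edges) - 1L)
  rate <- counts / bin_width / n_tetrodes
  rate <- smooth_gaussian(rate, sigma / bin_width)
  structure(list(t = (edges[-length(edges)] + edges[-1L]) / 2,
                 rate = as.numeric(rate), counts = counts,
                 mean_rate = mean(rate), sd_rate = stats::sd(rate),
                 bin_width = bin_width, sigma = sigma, span = span),
            class = "mua_trace")
}

#' Running speed from tracked position
#'
#' Centered difference of the (linearized) position samples, Gaussian
#' smoothed with `sigma` = 0.25 s.
#'
#' @param t sample times (s), uniform.
#' @param pos linear position (cm).
#' @param sigma smoothing s.d. (s).
#' @return numeric speed (cm/s), same length as `pos`.
#' @export
speed_from_position <- function(t, pos, sigma = 0.25) {
  n <- length(pos)
  stopifnot(length(t) == n, n >= 3L)
  dt <- stats::median(diff(t))
  v <- numeric(n)
  v[2:(n - 1L)] <- abs(pos[3:n] - pos[1:(n - 2L)]) / (2 * dt)
  v[1L] <- v[2L]; v[n] <- v[n - 1L]
  as.numeric(smooth_gaussian(v, sigma / dt))
}

#' Detect SPW-R multiunit events
#'
#' Bursts whose peak smoothed multiunit rate exceeds `threshold_sd` standard
#' deviations above the mean, with the peak constrained to times where the
#' animal's speed is below `speed_max`. Event boundaries are the nearest
#' crossings of the mean rate on each side of the peak; events whose
#' intervals touch are merged, and events shorter than `min_duration` are
#' dropped.
#'
#' @param mua a `mua_trace`.
#' @param speed_fn function mapping time (s) to speed (cm/s), or `NULL` to
#'   skip the behavioral constraint.
#' @param threshold_sd peak threshold in s.d. units (default 4).
#' @param speed_max speed ceiling at the peak (cm/s; default 10).
#' @param min_duration minimum event length (s; default 0.05, two decoding
#'   bins).
#' @return an `interval_set` of kind `"spwr"` with per-event `peak_t` and
#'   `peak_rate` columns.
#' @export
detect_spwr <- function(mua, speed_fn = NULL, threshold_sd = 4,
                        speed_max = 10, min_duration = 0.05) {
  mu <- mua$mean_rate; sdr <- mua$sd_rate
  if (!is.finite(sdr) || sdr <= 0) {
    warning("detect_spwr: constant MUA trace; no events")
    return(interval_set(numeric(0), numeric(0), kind = "spwr",
                        peak_t = numeric(0), peak_rate = numeric(0)))
  }
  thr <- mu + threshold_sd * sdr
  above <- mua$rate > thr
  if (!any(above))
    return(interval_set(numeric(0), numeric(0), kind = "spwr",
                        peak_t = numeric(0), peak_rate = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  below <- mua$rate <= mu
  n <- length(mua$rate)
  ev_s <- numeric(0); ev_e <- numeric(0); pk_t <- numeric(0); pk_r <- numeric(0)
  for (ci in cand) {
    i0 <- starts[ci]; i1 <- ends[ci]
    pk <- i0 - 1L + which.max(mua$rate[i0:i1])
    if (!is.null(speed_fn) && speed_fn(mua$t[pk]) >= speed_max) next
    lo <- pk
    while (lo > 1L && !below[lo]) lo <- lo - 1L
    hi <- pk
    while (hi < n && !below[hi]) hi <- hi + 1L
    ev_s <- c(ev_s, mua$t[lo]); ev_e <- c(ev_e, mua$t[hi])
    pk_t <- c(pk_t, mua$t[pk]); pk_r <- c(pk_r, mua$rate[pk])
  }
  if (length(ev_s) == 0L)
    return(interval_set(numeric(0), numeric(0), kind = "spwr",
                        peak_t = numeric(0), peak_rate = numeric(0)))
  m <- merge_interval_edges(ev_s, ev_e, gap = 0)
  # re-attach the max peak inside each merged interval
  pk_idx <- findInterval(pk_t, m$start)
  keep <- (m$end - m$start) >= min_duration
  peak_t <- peak_rate <- numeric(sum(keep))
  j <- 0L
  for (i in which(keep)) {
    j <- j + 1L
    sel <- pk_idx == i
    peak_t[j] <- pk_t[sel][which.max(pk_r[sel])]
    peak_rate[j] <- max(pk_r[sel])
  }
  interval_set(m$start[keep], m$end[keep], kind = "spwr",
               peak_t = peak_t, peak_rate = peak_rate)
}

#' Per-event ripple power z-score
#'
#' Event statistic: maximum of the Hilbert envelope of the ripple-band trace
#' within the event, standardized against the envelope over baseline samples
#' (all non-event samples, optionally restricted by a speed mask).
#'
#' @param ripple_lfp ripple-band `lfp_channel`.
#' @param events an `interval_set`.
#' @param baseline_mask optional logical vector per LFP sample restricting
#'   the baseline (e.g. speed < 10 cm/s).
#' @return numeric z-score per event.
#' @export
ripple_power_z <- function(ripple_lfp, events, baseline_mask = NULL) {
  env <- hilbert_analytic(ripple_lfp$samples)$envelope
  tt <- lfp_times(ripple_lfp)
  in_ev <- in_intervals(tt, events)
  base <- !in_ev
  if (!is.null(baseline_mask)) base <- base & baseline_mask
  mu <- mean(env[base]); sdv <- stats::sd(env[base])
  if (!is.finite(sdv) || sdv <= 1e-9 * max(abs(mu), 1))
    stop("ripple_power_z: zero-variance baseline")
  vapply(seq_len(nrow(events)), function(i) {
    sel <- tt >= events$start[i] & tt < events$end[i]
    (max(env[sel]) - mu) / sdv
  }, numeric(1))
}

#' Detect slow wave sleep epochs
#'
#' Windows with hippocampal theta/delta power ratio below `ratio_threshold`
#' and (optionally) a sleep-posture flag are merged into SWS epochs.
#'
#' @param lfp hippocampal `lfp_channel` (wideband).
#' @param posture_ok optional function of time returning TRUE where posture
#'   is consistent with sleep; `NULL` accepts all times.
#' @param ratio_threshold theta/delta ratio ceiling (default 1).
#' @param win,hop analysis window and hop (s).
#' @param gap_tol merge epochs separated by gaps shorter than this (s).
#' @return an `interval_set` of kind `"sws"`.
#' @export
detect_sws <- function(lfp, posture_ok = NULL, ratio_threshold = 1,
                       win = 10, hop = 5, gap_tol = 5) {
  th <- band_power_windows(lfp, c(4, 12), win, hop)
  de <- band_power_windows(lfp, c(1, 4), win, hop)
  ratio <- th$power / pmax(de$power, .Machine$double.eps)
  ok <- ratio < ratio_threshold
  if (!is.null(posture_ok)) ok <- ok & posture_ok((th$t0 + th$t1) / 2)
  if (!any(ok)) return(interval_set(numeric(0), numeric(0), kind = "sws"))
  m <- merge_interval_edges(th$t0[ok], th$t1[ok], gap = gap_tol)
  interval_set(m$start, m$end, kind = "sws")
}

#' Detect SWS frames
#'
#' Within SWS epochs, frames are maximal runs of 10 ms bins whose smoothed
#' population spike count exceeds a threshold set at the first local minimum
#' of the per-bin spike-count histogram (the notch between the silent-period
#' and active-period modes). A unimodal histogram falls back to a quantile
#' threshold with a warning.
#'
#' @param spike_times pooled hippocampal spike times (s).
#' @param sws an `interval_set` of SWS epochs.
#' @param bin_width count bin (s; default 10 ms).
#' @param sigma Gaussian smoothing s.d. (s; default 30 ms).
#' @param fallback_quantile threshold quantile if no histogram minimum is
#'   found.
#' @param min_duration minimum frame length (s).
#' @return an `interval_set` of kind `"frame"` with a `threshold` attribute
#'   (spike count per bin).
#' @export
detect_frames <- function(spike_times, sws, bin_width = 0.010, sigma = 0.030,
                          fallback_quantile = 0.5, min_duration = 0.05) {
  if (nrow(sws) == 0L) return(interval_set(numeric(0), numeric(0), kind = "frame"))
  fs <- numeric(0); fe <- numeric(0)
  counts_all <- integer(0)
  per_epoch <- vector("list", nrow(sws))
  for (i in seq_len(nrow(sws))) {
    edges <- seq(sws$start[i], sws$end[i], by = bin_width)
    if (length(edges) < 3L) next
    st <- spike_times[spike_times >= sws$start[i] & spike_times < edges[length(edges)]]
    counts <- tabulate(findInterval(st, edges, rightmost.closed = FALSE),
                       nbins = length(edges) - 1L)
    per_epoch[[i]] <- list(edges = edges, counts = counts)
    counts_all <- c(counts_all, counts)
  }
  if (!length(counts_all)) return(interval_set(numeric(0), numeric(0), kind = "frame"))
  h <- tabulate(counts_all + 1L)         # histogram over counts 0,1,2,...
  thr <- first_histogram_minimum(h)
  if (is.na(thr)) {
    warning("detect_frames: unimodal spike-count histogram; using quantile threshold")
    thr <- as.numeric(stats::quantile(counts_all, fallback_quantile))
  }
  for (i in seq_len(nrow(sws))) {
    pe <- per_epoch[[i]]
    if (is.null(pe)) next
    sm <- smooth_gaussian(pe$counts, sigma / bin_width)
    above <- sm > thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      fs <- c(fs, pe$edges[starts[k]]); fe <- c(fe, pe$edges[ends[k] + 1L])
    }
  }
  keep <- (fe - fs) >= min_duration
  out <- interval_set(fs[keep], fe[keep], kind = "frame")
  attr(out, "threshold") <- thr
  out
}

# First local minimum of an integer histogram (index scale = count value).
# Returns the count value at the minimum, or NA if the histogram decays
# monotonically (unimodal at zero) with no later mode.
first_histogram_minimum <- function(h) {
  if (length(h) < 3L) return(NA_real_)
  for (i in 2:(length(h) - 1L)) {
    if (h[i] <= h[i - 1L] && h[i] < max(h[(i + 1L):length(h)]))
      return(i - 1L)  # h[i] is the frequency of count value i-1
  }
  NA_real_
}

#' Event-triggered LFP average
#'
#' Averages event-onset-aligned LFP snippets and reports the latency of the
#' most negative deflection after onset.
#'
#' @param lfp an `lfp_channel`.
#' @param onsets event onset times (s).
#' @param window length-2 window around onset (s), e.g. `c(-0.2, 0.4)`.
#' @return list with `lag` (s, relative to onset), `mean` (average trace),
#'   `latency_ms` (argmin of the average within `[0, window[2]]`),
#'   `n_used`, `n_dropped`.
#' @export
event_triggered_lfp <- function(lfp, onsets, window = c(-0.2, 0.4)) {
  if (length(onsets) < 1L) stop("event_triggered_lfp: need at least one event")
  fs <- lfp$fs
  i_rel <- seq(round(window[1] * fs), round(window[2] * fs))
  n <- length(lfp$samples)
  acc <- numeric(length(i_rel)); used <- 0L
  for (t in onsets) {
    i0 <- round((t - lfp$t0) * fs) + 1L
    idx <- i0 + i_rel
    if (idx[1] < 1L || idx[length(idx)] > n) next
    acc <- acc + lfp$samples[idx]
    used <- used + 1L
  }
  if (used == 0L) stop("event_triggered_lfp: all events truncated by edges")
  avg <- acc / used
  lag <- i_rel / fs
  post <- which(lag >= 0)
  latency_ms <- 1000 * lag[post[which.min(avg[post])]]
  list(lag = lag, mean = avg, latency_ms = latency_ms,
       n_used = used, n_dropped = length(onsets) - used)
}
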