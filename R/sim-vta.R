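# VTA simulation: reward-responsive and non-responsive units with
# correct/error trial modulation, SPW-R-locked rate gain at a fixed lag
# (optionally restricted to reward-region trajectory content), von Mises
# theta locking during run, and an event-locked negative LFP deflection.

#' Simulate VTA unit spikes, waveforms and LFP
#'
#' @param beh a `behavior_session`.
#' @param hc output of [simulate_hippocampus()] (for event times and
#'   trajectory content).
#' @param cfg the shared [sim_config()].
#' @return list with `units` (list of spike-time vectors), `waveforms`
#'   (list of mean-waveform vectors, 31 kHz), `lfp` (`lfp_channel`),
#'   `truth` (per-unit table: class, baseline, gain, lag, kappa, mu).
#' @export
simulate_vta <- function(beh, hc, cfg) {
  with_substream(cfg$seed, "vta", {
    n <- cfg$n_vta_units
    n_rr <- round(cfg$rr_fraction * n)
    cls <- c(rep("RR", n_rr), rep("nonRR", n - n_rr))
    base <- cfg$vta_baseline_hz * exp(stats::rnorm(n, 0, 0.3))
    kap <- ifelse(cls == "RR", cfg$kappa_true, cfg$kappa_true / 2)
    mu <- (cfg$theta_mu_deg * pi / 180) + stats::runif(n, -0.5, 0.5)
    lag <- cfg$vta_lag_ms / 1000
    gwin <- cfg$vta_gain_window_ms / 1000
    # trial windows (test-phase rows on SWM; all rows on linear)
    trials <- beh$trials
    if (cfg$task == "swm") trials <- trials[trials$phase %in% "test", ]
    # gain windows for the event coupling
    gain_windows <- if (cfg$vta_coupling == "all") {
      ev <- hc$truth$events
      if (nrow(ev)) data.frame(s = ev$start + lag, e = ev$start + lag + gwin)
      else data.frame(s = numeric(0), e = numeric(0))
    } else {
      eb <- hc$truth$event_bins
      ev <- hc$truth$events
      if (!is.null(eb)) {
        eb <- eb[eb$in_reward & eb$event %in% ev$event[ev$replay], ]
        if (nrow(eb)) {
          m <- merge_interval_edges(eb$bin_start + lag, eb$bin_end + lag)
          data.frame(s = m$start, e = m$end)
        } else data.frame(s = numeric(0), e = numeric(0))
      } else data.frame(s = numeric(0), e = numeric(0))
    }
    dt <- 0.002
    ng <- ceiling(diff(beh$span) / dt)
    tg <- beh$span[1] + (seq_len(ng) - 0.5) * dt
    run_g <- stats::approx(beh$t, as.numeric(beh$speed > 10), tg,
                           method = "constant", rule = 2)$y > 0.5
    in_gain <- if (nrow(gain_windows))
      in_intervals(tg, interval_set(gain_windows$s, gain_windows$e)) else
        rep(FALSE, ng)
    appr_i <- acq_i <- rep(0L, ng)   # 0 none, 1 correct, 2 error
    for (r in seq_len(nrow(trials))) {
      np <- trials$nosepoke[r]; lab <- if (trials$correct[r]) 1L else 2L
      appr_i[tg >= np - 2 & tg < np] <- lab
      acq_i[tg >= np & tg < np + 3] <- lab
    }
    theta_ph <- 2 * pi * cfg$theta_freq_hz * tg
    units <- vector("list", n); waveforms <- vector("list", n)
    for (u in seq_len(n)) {
      r <- rep(base[u], ng)
      if (cls[u] == "RR") {
        r[appr_i == 1L] <- base[u] * cfg$vta_appr_gain_correct
        r[appr_i == 2L] <- base[u] * cfg$vta_appr_gain_error
        r[acq_i == 1L] <- base[u] * cfg$vta_acq_gain_correct
        r[acq_i == 2L] <- base[u] * cfg$vta_acq_gain_error
        r[in_gain] <- r[in_gain] * cfg$vta_spwr_gain
      }
      if (kap[u] > 0) {
        i0 <- besselI(kap[u], 0)
        r[run_g] <- r[run_g] * exp(kap[u] * cos(theta_ph[run_g] - mu[u])) / i0
      }
      cnt <- stats::rpois(ng, r * dt)
      hit <- which(cnt > 0)
      st <- rep(tg[hit] - dt / 2, cnt[hit]) +
        stats::runif(sum(cnt[hit]), 0, dt)
      units[[u]] <- sort(st)
      waveforms[[u]] <- vta_waveform(
        duration_ms = if (cls[u] == "RR") stats::runif(1, 1.1, 1.6)
        else stats::runif(1, 0.4, 0.8),
        ratio = if (cls[u] == "RR") stats::runif(1, 0.45, 0.6)
        else stats::runif(1, 0.2, 0.4))
    }
    ev <- hc$truth$events
    lfp <- {
      fs <- cfg$lfp_fs
      nn <- ceiling(diff(beh$span) * fs)
      tt <- beh$span[1] + (seq_len(nn) - 1L) / fs
      x <- stats::rnorm(nn, 0, 10)
      if (nrow(ev))
        for (t0 in ev$start) {
          ctr <- t0 + lag
          i0 <- max(1L, floor((ctr - 0.1 - beh$span[1]) * fs))
          i1 <- min(nn, ceiling((ctr + 0.1 - beh$span[1]) * fs))
          x[i0:i1] <- x[i0:i1] -
            40 * exp(-(tt[i0:i1] - ctr)^2 / (2 * 0.02^2))
        }
      lfp_channel(x, fs = fs, t0 = beh$span[1])
    }
    list(units = units, waveforms = waveforms, lfp = lfp,
         truth = data.frame(unit = seq_len(n), class = cls,
                            baseline_hz = base,
                            gain = ifelse(cls == "RR", cfg$vta_spwr_gain, 1),
                            lag_ms = cfg$vta_lag_ms, kappa = kap,
                            mu_deg = phase_deg(mu)))
  })
}

# parametric biphasic mean waveform with known landmarks (31 kHz)
vta_waveform <- function(duration_ms = 1.2, ratio = 0.5, fs = 31000,
                         peak_uv = 120) {
  t_ms <- (0:round(3e-3 * fs)) / fs * 1000
  tp <- 0.4; tf <- tp + duration_ms; ttr <- tp + 0.45 * duration_ms
  trough_uv <- peak_uv * ratio / (1 - ratio)
  w <- peak_uv * exp(-(t_ms - tp)^2 / (2 * 0.08^2)) -
    trough_uv * exp(-(t_ms - ttr)^2 / (2 * (0.12 * duration_ms)^2)) +
    0.45 * peak_uv * exp(-(t_ms - tf)^2 / (2 * (0.1 * duration_ms)^2))
  w
}
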