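# Slow-wave-sleep simulation: alternating frames (elevated population
# activity) and silent periods, SPW-Rs confined to frames, scaled VTA
# rates with an optional anti-coupling to SPW-R-rich frames, and a
# delta-dominated LFP.

#' Simulate a slow wave sleep epoch
#'
#' @param cfg a [sim_config()].
#' @param cells optional cell set from [simulate_hippocampus()] (reused so
#'   SWS replay content matches the wake tuning curves); generated fresh
#'   when NULL.
#' @param vta_truth optional unit truth table from [simulate_vta()]; when
#'   NULL a fresh set of units is drawn.
#' @return list with `spikes` (marked data frame as in
#'   [simulate_hippocampus()]), `vta_units` (list of spike vectors), `lfp`,
#'   `truth` (list: `frames` interval set with per-frame `spwr_rate_true`,
#'   `events` table, `event_bins`, `units` table).
#' @export
simulate_sws <- function(cfg, cells = NULL, vta_truth = NULL) {
  track <- sim_track(cfg)
  if (is.null(cells))
    cells <- with_substream(cfg$seed, "sws_cells", make_cells(cfg, track))
  with_substream(cfg$seed, "sws", {
    span <- c(0, cfg$sws_duration_s)
    # frame / silent alternation
    fs_ <- numeric(0); fe_ <- numeric(0)
    tcur <- stats::rlnorm(1, log(cfg$silent_median_s), 0.5)
    while (tcur < span[2]) {
      d <- stats::rlnorm(1, log(cfg$frame_median_s), 0.6)
      d <- max(d, 0.3)
      if (tcur + d > span[2]) break
      fs_ <- c(fs_, tcur); fe_ <- c(fe_, tcur + d)
      tcur <- tcur + d + max(0.2, stats::rlnorm(1, log(cfg$silent_median_s), 0.5))
    }
    frames <- interval_set(fs_, fe_, kind = "frame")
    nf <- nrow(frames)
    lam_f <- cfg$sws_spwr_rate_hz * exp(stats::rnorm(nf, 0, 0.5))
    # SPW-R events inside frames
    ev_rows <- list(); bin_rows <- list(); sp_t <- numeric(0); sp_c <- integer(0)
    eid <- 0L
    for (i in seq_len(nf)) {
      d <- fe_[i] - fs_[i]
      n_ev <- stats::rpois(1, lam_f[i] * d)
      if (!n_ev || d < 0.4) next
      onsets <- sort(stats::runif(n_ev, fs_[i], fe_[i] - 0.3))
      onsets <- onsets[c(TRUE, diff(onsets) > 0.4)]
      for (t0 in onsets) {
        eid <- eid + 1L
        t0 <- round(t0 / 0.025) * 0.025
        dur <- floor(stats::runif(1, 0.12, 0.25) / 0.025) * 0.025
        is_replay <- stats::runif(1) < cfg$sws_replay_fraction
        pid <- sample.int(length(track$paths), 1)
        plen <- track$paths[[pid]]$length
        v <- sample(c(-1, 1), 1) * cfg$replay_speed_cms
        s0 <- stats::runif(1, 0, plen)
        nb <- round(dur / 0.025)
        bs <- t0 + (seq_len(nb) - 1L) * 0.025
        if (is_replay) {
          s_bin <- pmin(pmax(s0 + v * (bs + 0.0125 - t0), 0), plen - 1e-9)
          g_bin <- path_to_global(track, pid, s_bin)
          tg <- seq(0, dur - 1e-3, by = 1e-3)
          s_t <- pmin(pmax(s0 + v * (tg + 5e-4), 0), plen - 1e-9)
          lam <- cell_tuning(cells, track, path_to_global(track, pid, s_t)) *
            cfg$event_gain + cfg$event_baseline_hz
        } else {
          g_bin <- stats::runif(nb, 0, track$total_cm)
          tg <- seq(0, dur - 1e-3, by = 1e-3)
          ch <- pmin(floor(tg / 0.025) + 1L, nb)
          lam <- cell_tuning(cells, track, g_bin[ch]) * cfg$event_gain +
            cfg$event_baseline_hz
        }
        nmat <- matrix(stats::rpois(length(lam), lam * 1e-3), nrow(lam))
        hit <- which(nmat > 0, arr.ind = TRUE)
        if (nrow(hit)) {
          reps <- nmat[hit]
          st <- rep(t0 + (hit[, 1] - 1) * 1e-3, reps) +
            stats::runif(sum(reps), 0, 1e-3)
          sp_t <- c(sp_t, st); sp_c <- c(sp_c, rep(hit[, 2], reps))
        }
        ev_rows[[eid]] <- data.frame(event = eid, start = t0, end = t0 + dur,
                                     replay = is_replay, frame = i)
        bin_rows[[eid]] <- data.frame(event = eid, bin_start = bs,
                                      bin_end = bs + 0.025, true_pos = g_bin)
      }
    }
    # background population spikes: frame vs silent rates
    nc <- cfg$n_place_cells
    frame_mask_rate <- function(t) {
      r <- rep(cfg$silent_cell_hz, length(t))
      r[in_intervals(t, frames)] <- cfg$frame_cell_hz
      r
    }
    for (ci in seq_len(nc)) {
      st <- poisson_times(span[1], span[2], frame_mask_rate, cfg$frame_cell_hz)
      sp_t <- c(sp_t, st); sp_c <- c(sp_c, rep(ci, length(st)))
    }
    o <- order(sp_t); sp_t <- sp_t[o]; sp_c <- sp_c[o]
    mk <- cells$centroids[sp_c, , drop = FALSE] +
      matrix(stats::rnorm(length(sp_t) * 4, 0, cfg$mark_sd_uv), ncol = 4)
    spikes <- data.frame(time = sp_t, tetrode = cells$tetrode[sp_c],
                         m1 = mk[, 1], m2 = mk[, 2], m3 = mk[, 3],
                         m4 = mk[, 4],
                         width = cells$width[sp_c] +
                           stats::rnorm(length(sp_t), 0, 2e-5),
                         cell = sp_c)
    # VTA units: scaled-down rates, optional anti-coupling in high-rate frames
    n <- cfg$n_vta_units
    if (is.null(vta_truth)) {
      n_rr <- round(cfg$rr_fraction * n)
      cls <- c(rep("RR", n_rr), rep("nonRR", n - n_rr))
      base <- cfg$vta_baseline_hz * exp(stats::rnorm(n, 0, 0.3))
    } else {
      cls <- vta_truth$class; base <- vta_truth$baseline_hz
      n <- length(cls)
    }
    high <- lam_f > mean(lam_f)
    vta_units <- lapply(seq_len(n), function(u) {
      b <- base[u] * cfg$sws_vta_scale
      rate_fn <- function(t) {
        r <- rep(b, length(t))
        if (cls[u] == "RR" && cfg$sws_high_frame_vta_gain != 1) {
          fi <- interval_index(t, frames)
          inhigh <- !is.na(fi) & high[pmax(fi, 1L)]
          r[inhigh] <- b * cfg$sws_high_frame_vta_gain
        }
        r
      }
      poisson_times(span[1], span[2], rate_fn,
                    b * max(1, cfg$sws_high_frame_vta_gain))
    })
    events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
      data.frame(event = integer(0), start = numeric(0), end = numeric(0),
                 replay = logical(0), frame = integer(0))
    # delta-dominated LFP with ripple bursts at events
    lfp <- {
      fs2 <- cfg$lfp_fs
      nn <- ceiling(diff(span) * fs2)
      tt <- span[1] + (seq_len(nn) - 1L) / fs2
      x <- stats::rnorm(nn, 0, 15) + 80 * sin(2 * pi * 2 * tt)
      for (i in seq_len(nrow(events))) {
        i0 <- max(1L, floor(events$start[i] * fs2) + 1L)
        i1 <- min(nn, ceiling(events$end[i] * fs2))
        if (i1 <= i0) next
        seg <- i0:i1
        w <- sin(pi * (seg - i0) / (i1 - i0))^2
        x[seg] <- x[seg] + 30 * w * sin(2 * pi * 180 * tt[seg])
      }
      lfp_channel(x, fs = fs2, t0 = span[1])
    }
    frames_out <- interval_set(fs_, fe_, kind = "frame",
                               spwr_rate_true = lam_f, high = high)
    list(spikes = spikes, vta_units = vta_units, lfp = lfp, span = span,
         truth = list(frames = frames_out, events = events,
                      event_bins = if (length(bin_rows))
                        do.call(rbind, bin_rows) else NULL,
                      units = data.frame(unit = seq_len(n), class = cls,
                                         baseline_hz = base)))
  })
}

#' Simulate a complete session
#'
#' Behavior, hippocampus and VTA under one configuration (plus an optional
#' SWS epoch with the same cells and units).
#'
#' @param cfg a [sim_config()].
#' @param sws also simulate the post-task SWS epoch.
#' @return session list: `cfg`, `track`, `behavior`, `hc`, `vta`, and
#'   optionally `sws`.
#' @export
simulate_session <- function(cfg, sws = FALSE) {
  beh <- simulate_behavior(cfg)
  hc <- simulate_hippocampus(beh, cfg)
  vta <- simulate_vta(beh, hc, cfg)
  out <- list(cfg = cfg, track = beh$track, behavior = beh, hc = hc,
              vta = vta)
  if (sws) {
    cells <- with_substream(cfg$seed, "hc_cells", make_cells(cfg, beh$track))
    out$sws <- simulate_sws(cfg, cells = cells, vta_truth = vta$truth)
  }
  out
}
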