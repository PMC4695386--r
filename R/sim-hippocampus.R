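# Hippocampal simulation: theta-modulated, direction-selective place cells
# with 4-D amplitude marks; SPW-R bursts during pauses whose spikes encode
# constant-speed trajectories (replay) or i.i.d. positions (nonreplay);
# ripple- and theta-carrying LFP.

#' Simulate hippocampal marked spikes, LFP and ground truth
#'
#' @param beh a `behavior_session`.
#' @param cfg the [sim_config()] used to build it.
#' @return list with `spikes` (data frame `time`, `tetrode`, `m1`..`m4`,
#'   `width`, `cell`), `unit_spikes` (per-cell spike times, the sorted-unit
#'   input), `lfp` (`lfp_channel`), `cells` (truth table), `truth` (list:
#'   `events` table, `event_bins` table with per-25 ms true trajectory
#'   positions and reward occupancy).
#' @export
simulate_hippocampus <- function(beh, cfg) {
  track <- beh$track
  cells <- with_substream(cfg$seed, "hc_cells", make_cells(cfg, track))
  run_sp <- with_substream(cfg$seed, "hc_run",
                           place_cell_run_spikes(beh, cfg, cells, track))
  ev <- with_substream(cfg$seed, "hc_events",
                       make_spwr_events(beh, cfg, cells, track))
  all_t <- c(run_sp$time, ev$spikes$time)
  all_c <- c(run_sp$cell, ev$spikes$cell)
  o <- order(all_t)
  all_t <- all_t[o]; all_c <- all_c[o]
  spikes <- with_substream(cfg$seed, "hc_marks", {
    mk <- cells$centroids[all_c, , drop = FALSE] +
      matrix(stats::rnorm(length(all_t) * 4, 0, cfg$mark_sd_uv),
             ncol = 4)
    noise_n <- stats::rpois(1, cfg$noise_rate_hz * cfg$n_tetrodes *
                              diff(beh$span))
    nt <- sort(stats::runif(noise_n, beh$span[1], beh$span[2]))
    data.frame(
      time = c(all_t, nt),
      tetrode = c(cells$tetrode[all_c],
                  sample.int(cfg$n_tetrodes, noise_n, replace = TRUE)),
      m1 = c(mk[, 1], stats::runif(noise_n, 50, 130)),
      m2 = c(mk[, 2], stats::runif(noise_n, 50, 130)),
      m3 = c(mk[, 3], stats::runif(noise_n, 50, 130)),
      m4 = c(mk[, 4], stats::runif(noise_n, 50, 130)),
      width = c(cells$width[all_c] + stats::rnorm(length(all_t), 0, 2e-5),
                stats::runif(noise_n, 1.5e-4, 4.5e-4)),
      cell = c(all_c, rep(NA_integer_, noise_n)))
  })
  spikes <- spikes[order(spikes$time), , drop = FALSE]
  rownames(spikes) <- NULL
  lfp <- with_substream(cfg$seed, "hc_lfp",
                        make_hc_lfp(beh, cfg, ev$events))
  unit_spikes <- lapply(seq_len(cfg$n_place_cells), function(ci)
    sort(all_t[all_c == ci]))
  list(spikes = spikes, unit_spikes = unit_spikes, lfp = lfp,
       cells = cells$table, truth = list(events = ev$events,
                                         event_bins = ev$event_bins))
}

make_cells <- function(cfg, track) {
  n <- cfg$n_place_cells
  spacing <- track$total_cm / n
  if (spacing > 3 * cfg$place_field_width_cm)
    warning("simulate_hippocampus: too few place cells to tile the track")
  centers <- (seq_len(n) - 0.5) * spacing + stats::runif(n, -2, 2)
  centers <- pmin(pmax(centers, 0), track$total_cm)
  # rejection-sample mark centroids at least mark_min_sep_uv apart
  centroids <- matrix(NA_real_, n, 4)
  got <- 0L
  while (got < n) {
    cand <- stats::runif(4, 120, 350)
    ok <- got == 0L ||
      all(sqrt(colSums((t(centroids[seq_len(got), , drop = FALSE]) - cand)^2))
          >= cfg$mark_min_sep_uv)
    if (ok) { got <- got + 1L; centroids[got, ] <- cand }
  }
  list(table = data.frame(cell = seq_len(n), center = centers,
                          peak_hz = cfg$peak_rate_hz,
                          sd_cm = cfg$place_field_width_cm,
                          dir_pref = rep(c(1, -1), length.out = n),
                          theta_phi = stats::runif(n, -pi, pi),
                          tetrode = rep(seq_len(cfg$n_tetrodes),
                                        length.out = n)),
       centroids = centroids,
       tetrode = rep(seq_len(cfg$n_tetrodes), length.out = n),
       width = stats::rnorm(n, 5e-4, 5e-5))
}

# tuning of all cells at positions g (vector): returns length(g) x n matrix
cell_tuning <- function(cells, track, g, dirn = NULL) {
  tb <- cells$table
  out <- vapply(seq_len(nrow(tb)), function(ci) {
    d <- track_distance(track, g, tb$center[ci])
    r <- tb$peak_hz[ci] * exp(-d^2 / (2 * tb$sd_cm[ci]^2))
    if (!is.null(dirn))
      r <- r * ifelse(dirn == tb$dir_pref[ci], 1, 0.2)
    r
  }, numeric(length(g)))
  matrix(out, nrow = length(g))
}

place_cell_run_spikes <- function(beh, cfg, cells, track) {
  dt <- 1 / cfg$pos_fs
  run <- beh$speed > 10
  dirn <- c(0, sign(diff(beh$pos))); dirn <- zoo_fill(ifelse(dirn == 0, NA, dirn))
  idx <- which(run)
  lam <- cell_tuning(cells, track, beh$pos[idx], dirn[idx]) +
    cfg$baseline_cell_rate_hz
  m <- cfg$theta_mod_depth
  tt <- numeric(0); cc <- integer(0)
  # counts at the (1+m)-inflated rate, then theta thinning at spike times
  nmat <- matrix(stats::rpois(length(lam), lam * dt * (1 + m)), nrow(lam))
  hit <- which(nmat > 0, arr.ind = TRUE)
  if (nrow(hit)) {
    reps <- nmat[hit]
    samp_t <- beh$t[idx[hit[, 1]]]
    st <- rep(samp_t, reps) + stats::runif(sum(reps), 0, dt)
    sc <- rep(hit[, 2], reps)
    phi <- cells$table$theta_phi[sc]
    acc <- stats::runif(length(st)) <
      (1 + m * cos(2 * pi * cfg$theta_freq_hz * st - phi)) / (1 + m)
    tt <- st[acc]; cc <- sc[acc]
  }
  # baseline spikes during pauses keep MUA nonzero between events
  for (ci in seq_len(cfg$n_place_cells)) {
    for (j in seq_len(nrow(beh$pauses))) {
      p <- beh$pauses[j, ]
      n <- stats::rpois(1, cfg$baseline_cell_rate_hz * 2 * (p$end - p$start))
      if (n) { tt <- c(tt, stats::runif(n, p$start, p$end)); cc <- c(cc, rep(ci, n)) }
    }
  }
  list(time = tt, cell = cc)
}

make_spwr_events <- function(beh, cfg, cells, track) {
  ev_rows <- list(); bin_rows <- list(); sp_t <- numeric(0); sp_c <- integer(0)
  eid <- 0L
  for (j in seq_len(nrow(beh$pauses))) {
    p <- beh$pauses[j, ]
    n_ev <- stats::rpois(1, cfg$spwr_rate_hz * (p$end - p$start))
    if (!n_ev) next
    onsets <- sort(stats::runif(n_ev, p$start + 0.3,
                                max(p$start + 0.31, p$end - 0.6)))
    onsets <- onsets[c(TRUE, diff(onsets) > 0.7)]
    for (t0 in onsets) {
      eid <- eid + 1L
      t0 <- round(t0 / 0.025) * 0.025   # content on the absolute 25 ms grid
      dur <- stats::runif(1, 0.12, 0.28)
      dur <- floor(dur / 0.025) * 0.025           # whole 25 ms bins
      is_replay <- stats::runif(1) < cfg$replay_fraction
      pid <- sample.int(length(track$paths), 1)
      plen <- track$paths[[pid]]$length
      v <- sample(c(-1, 1), 1) * cfg$replay_speed_cms * stats::runif(1, 0.8, 1.2)
      anchored <- stats::runif(1) < cfg$reward_bias
      if (anchored) {
        at_start <- stats::runif(1) < 0.5
        a <- stats::runif(1, 0, track$reward_halfwidth)
        if (at_start) { s0 <- if (v > 0) a else plen - a }
        else { s_end <- if (v > 0) plen - a else a; s0 <- s_end - v * dur }
      } else s0 <- stats::runif(1, 0, plen)
      c_dir <- if (stats::runif(1) < cfg$forward_fraction) sign(v) else -sign(v)
      nb <- round(dur / 0.025)
      bs <- t0 + (seq_len(nb) - 1L) * 0.025
      tctr <- bs + 0.0125 - t0
      s_bin <- pmin(pmax(s0 + v * tctr, 0), plen - 1e-9)
      g_bin <- path_to_global(track, pid, s_bin)
      if (is_replay) {
        # spikes from tuning along the trajectory, 1 ms resolution
        tg <- seq(0, dur - 1e-3, by = 1e-3)
        s_t <- pmin(pmax(s0 + v * (tg + 5e-4), 0), plen - 1e-9)
        g_t <- path_to_global(track, pid, s_t)
        lam <- cell_tuning(cells, track, g_t,
                           rep(c_dir, length(g_t))) * cfg$event_gain +
          cfg$event_baseline_hz
      } else {
        # i.i.d. position per 25 ms chunk
        g_chunk <- stats::runif(nb, 0, track$total_cm)
        d_chunk <- sample(c(1, -1), nb, replace = TRUE)
        g_bin <- g_chunk
        tg <- seq(0, dur - 1e-3, by = 1e-3)
        ch <- pmin(floor(tg / 0.025) + 1L, nb)
        lam <- cell_tuning(cells, track, g_chunk[ch],
                           d_chunk[ch]) * cfg$event_gain +
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
      ev_rows[[eid]] <- data.frame(
        event = eid, start = t0, end = t0 + dur, replay = is_replay,
        path_id = pid, speed = if (is_replay) v else NA_real_,
        s0 = if (is_replay) s0 else NA_real_, anchored = anchored,
        content_dir = if (is_replay) c_dir else NA_real_,
        well_pos = p$well_pos)
      bin_rows[[eid]] <- data.frame(
        event = eid, bin_start = bs, bin_end = bs + 0.025,
        true_pos = g_bin,
        in_reward = reward_region_mask(track, g_bin))
    }
  }
  list(events = if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(event = integer(0), start = numeric(0), end = numeric(0),
               replay = logical(0), path_id = integer(0), speed = numeric(0),
               s0 = numeric(0), anchored = logical(0),
               content_dir = numeric(0), well_pos = numeric(0)),
    event_bins = if (length(bin_rows)) do.call(rbind, bin_rows) else NULL,
    spikes = list(time = sp_t, cell = sp_c))
}

make_hc_lfp <- function(beh, cfg, events) {
  fs <- cfg$lfp_fs
  n <- ceiling(diff(beh$span) * fs)
  tt <- beh$span[1] + (seq_len(n) - 1L) / fs
  x <- stats::rnorm(n, 0, 15)
  run_env <- stats::approx(beh$t, as.numeric(beh$speed > 10), tt,
                           rule = 2)$y
  run_env <- smooth_gaussian(run_env, 0.25 * fs)
  x <- x + 60 * run_env * cos(2 * pi * cfg$theta_freq_hz * tt)
  for (i in seq_len(nrow(events))) {
    i0 <- max(1L, floor((events$start[i] - beh$span[1]) * fs) + 1L)
    i1 <- min(n, ceiling((events$end[i] - beh$span[1]) * fs))
    if (i1 <= i0) next
    seg <- i0:i1
    w <- sin(pi * (seg - i0) / (i1 - i0))^2
    x[seg] <- x[seg] + 30 * w * sin(2 * pi * 180 * tt[seg])
  }
  lfp_channel(x, fs = fs, t0 = beh$span[1])
}
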