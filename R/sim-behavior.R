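# Behavioral simulation: self-paced traversals between reward wells with
# log-normal dwells, a nosepoke at each arrival, and (SWM) the sample/test
# contingency in which the correct test choice is opposite the forced turn.

#' Simulate task behavior
#'
#' Linear task: alternating end-to-end traversals, one reward well per end.
#' SWM task: trials alternate a sample phase (forced run to a pseudorandom
#' force well) and a test phase (free choice at the choice point); the
#' correct choice is the side opposite the forced turn, and errors are
#' injected uniformly at random at `cfg$error_rate`.
#'
#' Traversals use a raised-cosine speed profile (peak about twice the mean
#' speed, below 10 cm/s only near the wells); dwells are stationary up to
#' sub-centimeter jitter, so speed is under 10 cm/s throughout each pause.
#'
#' @param cfg a [sim_config()].
#' @return list of class `behavior_session`: `t`, `pos` (global linear cm),
#'   `speed` (cm/s), `trials` (one row per nosepoke: `trial`, `phase`,
#'   `arm`, `nosepoke`, `correct`, `well_pos`), `pauses` (`interval_set`
#'   with per-pause `well_pos`), `track`, `span`.
#' @export
simulate_behavior <- function(cfg) {
  validate_sim_config(cfg)
  track <- sim_track(cfg)
  with_substream(cfg$seed, "behavior", {
    dt <- 1 / cfg$pos_fs
    dwells <- stats::rlnorm(2 * cfg$n_trials + 2, log(cfg$dwell_median_s),
                            cfg$dwell_sdlog)
    if (cfg$task == "linear") {
      legs <- build_linear_legs(cfg, track, dwells)
    } else {
      legs <- build_swm_legs(cfg, track, dwells)
    }
    tt <- numeric(0); pp <- numeric(0)
    trial_rows <- list(); pause_s <- pause_e <- pause_w <- numeric(0)
    tcur <- 0
    for (lg in legs) {
      if (lg$kind == "dwell") {
        n <- max(2L, round(lg$dur / dt))
        tt <- c(tt, tcur + (seq_len(n) - 1L) * dt)
        pp <- c(pp, lg$pos + stats::rnorm(n, 0, 0.2))
        pause_s <- c(pause_s, tcur); pause_e <- c(pause_e, tcur + n * dt)
        pause_w <- c(pause_w, lg$pos)
        if (!is.null(lg$trial)) {
          lg$trial$nosepoke <- tcur
          trial_rows[[length(trial_rows) + 1L]] <- lg$trial
        }
        tcur <- tcur + n * dt
      } else {
        # per-leg speed variability: real traversal durations vary, which
        # keeps alternating train/test blocks from aliasing with position
        dur <- lg$dist / (cfg$run_speed_cms * stats::runif(1, 0.75, 1.3))
        n <- max(2L, round(dur / dt))
        u <- (seq_len(n) - 0.5) / n
        s <- u - sin(2 * pi * u) / (2 * pi)   # raised-cosine speed profile
        tt <- c(tt, tcur + (seq_len(n) - 1L) * dt)
        pp <- c(pp, path_to_global(track, lg$path_id,
                                   lg$s0 + (lg$s1 - lg$s0) * s))
        tcur <- tcur + n * dt
      }
    }
    trials <- do.call(rbind, trial_rows)
    speed <- speed_from_position(tt, pp)
    structure(list(t = tt, pos = pp, speed = speed, trials = trials,
                   pauses = interval_set(pause_s, pause_e, kind = "pause",
                                         well_pos = pause_w),
                   track = track, span = c(0, tcur)),
              class = "behavior_session")
  })
}

build_linear_legs <- function(cfg, track, dwells) {
  L <- track$total_cm
  legs <- list()
  cur <- 0  # start at well A
  for (i in seq_len(cfg$n_trials)) {
    nxt <- if (cur == 0) L else 0
    legs[[length(legs) + 1L]] <- list(
      kind = "dwell", dur = dwells[i], pos = cur,
      trial = data.frame(trial = i, phase = NA_character_,
                         arm = if (cur == 0) 1L else 2L,
                         correct = TRUE, well_pos = cur))
    legs[[length(legs) + 1L]] <- list(kind = "run", path_id = 1L,
                                      s0 = cur, s1 = nxt, dist = L)
    cur <- nxt
  }
  legs[[length(legs) + 1L]] <- list(
    kind = "dwell", dur = dwells[cfg$n_trials + 1L], pos = cur,
    trial = data.frame(trial = cfg$n_trials + 1L, phase = NA_character_,
                       arm = if (cur == 0) 1L else 2L, correct = TRUE,
                       well_pos = cur))
  legs
}

build_swm_legs <- function(cfg, track, dwells) {
  # wells: force R3 (arm 1), R4 (arm 2); choice R1 (arm 1), R2 (arm 2)
  n <- cfg$n_trials
  force_arm <- sample(1:2, n, replace = TRUE)
  err <- runif(n) < cfg$error_rate
  choice_arm <- ifelse(err, force_arm, 3L - force_arm)  # correct = opposite
  legs <- list()
  prev_choice <- 1L
  k <- 0L
  for (i in seq_len(n)) {
    pid <- (force_arm[i] - 1L) * 2L + prev_choice  # path for the sample run
    plen <- track$paths[[pid]]$length
    legs[[length(legs) + 1L]] <- list(kind = "run", path_id = pid,
                                      s0 = plen, s1 = 0, dist = plen)
    k <- k + 1L
    legs[[length(legs) + 1L]] <- list(
      kind = "dwell", dur = dwells[k],
      pos = path_to_global(track, pid, 0),
      trial = data.frame(trial = i, phase = "sample", arm = force_arm[i],
                         correct = TRUE,
                         well_pos = path_to_global(track, pid, 0)))
    pid2 <- (force_arm[i] - 1L) * 2L + choice_arm[i]   # test run
    plen2 <- track$paths[[pid2]]$length
    legs[[length(legs) + 1L]] <- list(kind = "run", path_id = pid2,
                                      s0 = 0, s1 = plen2, dist = plen2)
    k <- k + 1L
    legs[[length(legs) + 1L]] <- list(
      kind = "dwell", dur = dwells[k],
      pos = path_to_global(track, pid2, plen2),
      trial = data.frame(trial = i, phase = "test", arm = choice_arm[i],
                         correct = !err[i],
                         well_pos = path_to_global(track, pid2, plen2)))
    prev_choice <- choice_arm[i]
  }
  legs
}
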