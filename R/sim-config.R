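# Simulation configuration. Defaults are the study conditions every
# downstream stage is validated against; see the methods vignette for the
# rationale behind each value.

#' Simulation configuration
#'
#' @param seed master seed; every generator stage draws from a named
#'   substream of it, so the seed fully determines the session.
#' @param task `"linear"` (200 cm track) or `"swm"` (end-to-end T-maze).
#' @param track_length_cm linear track length (cm).
#' @param arm_cm SWM segment length (cm).
#' @param n_trials number of trials (nosepokes at reward wells).
#' @param error_rate proportion of SWM test-phase trials with the wrong
#'   choice (injected uniformly at random).
#' @param dwell_median_s,dwell_sdlog log-normal reward-site dwell (self
#'   paced; median ~9 s).
#' @param run_speed_cms mean traversal speed (cm/s).
#' @param pos_fs position tracking rate (Hz).
#' @param lfp_fs LFP sampling rate (Hz).
#' @param n_place_cells number of hippocampal place cells.
#' @param place_field_width_cm Gaussian tuning s.d. (cm).
#' @param peak_rate_hz in-field peak rate (Hz).
#' @param baseline_cell_rate_hz out-of-field rate (Hz).
#' @param theta_freq_hz theta frequency (Hz).
#' @param theta_mod_depth multiplicative theta modulation of place-cell
#'   rate in `[0, 1]`.
#' @param n_tetrodes tetrodes the cells are distributed over.
#' @param mark_sd_uv per-channel amplitude mark s.d. (uV).
#' @param mark_min_sep_uv minimum centroid separation (uV, 4-D euclidean).
#' @param noise_rate_hz per-tetrode rate of sub-threshold noise spikes.
#' @param spwr_rate_hz SPW-R event rate during pauses (Hz).
#' @param replay_fraction proportion of events carrying true trajectories.
#' @param replay_speed_cms trajectory speed of injected replay (cm/s).
#' @param event_gain multiplicative place-cell rate gain inside events.
#' @param event_baseline_hz additive per-cell rate inside events (the
#'   non-spatial component of the population burst).
#' @param reward_bias probability that an injected trajectory is anchored
#'   (starts or ends) in a reward region.
#' @param forward_fraction probability that replayed direction content
#'   matches the propagation direction (forward replay).
#' @param n_vta_units number of VTA units.
#' @param rr_fraction proportion of VTA units that are reward responsive.
#' @param vta_baseline_hz VTA baseline rate (Hz).
#' @param vta_acq_gain_correct,vta_acq_gain_error multiplicative reward
#'   acquisition gains (0-3 s after nosepoke) on correct/error trials
#'   (RR units).
#' @param vta_appr_gain_correct,vta_appr_gain_error approach gains
#'   (2 s before nosepoke).
#' @param vta_spwr_gain rate gain of RR units during SPW-R events.
#' @param vta_lag_ms latency of the VTA gain window after SPW-R onset (ms).
#' @param vta_gain_window_ms duration of the gain window when coupling to
#'   whole events (ms).
#' @param vta_coupling `"all"` (gain throughout every event) or `"reward"`
#'   (gain only while the concurrent true trajectory occupies a reward
#'   region).
#' @param kappa_true von Mises concentration of RR-unit theta locking
#'   (nonRR units get half).
#' @param theta_mu_deg preferred theta phase (deg, 0 = peak).
#' @param sws_duration_s length of the SWS epoch (s).
#' @param frame_median_s,silent_median_s log-normal medians of frame and
#'   inter-frame (silent) durations (s).
#' @param frame_cell_hz,silent_cell_hz per-cell rates inside/outside frames.
#' @param sws_spwr_rate_hz mean within-frame SPW-R rate (Hz).
#' @param sws_replay_fraction replay fraction of SWS events.
#' @param sws_vta_scale VTA rate scale in SWS relative to baseline.
#' @param sws_high_frame_vta_gain extra RR gain in frames whose SPW-R rate
#'   is above the mean (1 = none).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, task = c("linear", "swm"),
                       track_length_cm = 200, arm_cm = 100,
                       n_trials = 40, error_rate = 0.25,
                       dwell_median_s = 9, dwell_sdlog = 0.6,
                       run_speed_cms = 40, pos_fs = 30, lfp_fs = 1000,
                       n_place_cells = 30, place_field_width_cm = 10,
                       peak_rate_hz = 15, baseline_cell_rate_hz = 0.2,
                       theta_freq_hz = 8, theta_mod_depth = 0.5,
                       n_tetrodes = 4, mark_sd_uv = 15, mark_min_sep_uv = 40,
                       noise_rate_hz = 1,
                       spwr_rate_hz = 0.3, replay_fraction = 0.25,
                       replay_speed_cms = 500, event_gain = 6,
                       event_baseline_hz = 3,
                       reward_bias = 0.7, forward_fraction = 0.7,
                       n_vta_units = 6, rr_fraction = 0.6,
                       vta_baseline_hz = 6,
                       vta_acq_gain_correct = 2.5, vta_acq_gain_error = 0.8,
                       vta_appr_gain_correct = 1.5, vta_appr_gain_error = 1,
                       vta_spwr_gain = 2, vta_lag_ms = 84,
                       vta_gain_window_ms = 100,
                       vta_coupling = c("all", "reward"),
                       kappa_true = 0.5, theta_mu_deg = 0,
                       sws_duration_s = 300,
                       frame_median_s = 2, silent_median_s = 1,
                       frame_cell_hz = 12, silent_cell_hz = 0.05,
                       sws_spwr_rate_hz = 0.4, sws_replay_fraction = 0.16,
                       sws_vta_scale = 0.5, sws_high_frame_vta_gain = 1) {
  cfg <- as.list(environment())
  cfg$task <- match.arg(task)
  cfg$vta_coupling <- match.arg(vta_coupling)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pos_rate <- c("track_length_cm", "arm_cm", "dwell_median_s",
                "run_speed_cms", "pos_fs", "lfp_fs", "place_field_width_cm",
                "peak_rate_hz", "theta_freq_hz", "spwr_rate_hz",
                "replay_speed_cms", "event_gain", "vta_baseline_hz",
                "vta_spwr_gain", "sws_duration_s", "frame_median_s",
                "silent_median_s")
  for (f in pos_rate)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("sim_config: ", f, " must be positive")
  props <- c("error_rate", "replay_fraction", "reward_bias", "rr_fraction",
             "forward_fraction", "sws_replay_fraction")
  for (f in props)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("sim_config: ", f, " must be in [0, 1]")
  if (cfg$n_place_cells < 1 || cfg$n_vta_units < 1 || cfg$n_trials < 1)
    stop("sim_config: counts must be at least 1")
  if (cfg$kappa_true < 0) stop("sim_config: kappa_true must be >= 0")
  if (cfg$vta_lag_ms < 0) stop("sim_config: vta_lag_ms must be >= 0")
  invisible(cfg)
}

#' Track object implied by a simulation configuration
#' @param cfg a `sim_config`.
#' @export
sim_track <- function(cfg) {
  if (cfg$task == "linear") make_track("linear", length_cm = cfg$track_length_cm)
  else make_track("swm", arm_cm = cfg$arm_cm)
}
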