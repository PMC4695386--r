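# Session file I/O and the end-to-end pipeline driver. Tables are columnar
# UTF-8 text with a provenance header (# key: value lines); LFP traces use a
# flat binary container with a text sidecar describing rate and units.

#' Analysis configuration: every fixed constant of the pipeline
#'
#' @param ... overrides of the defaults.
#' @return list of class `analysis_config` with a `hash` attribute.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    speed_max_cms = 10, mua_bin_s = 0.010, mua_sigma_s = 0.010,
    spwr_threshold_sd = 4, spwr_min_duration_s = 0.05,
    ripple_band_hz = c(100, 300), theta_band_hz = c(4, 12),
    delta_band_hz = c(1, 4),
    spatial_bin_cm = 10, run_bin_s = 0.5, event_bin_s = 0.025,
    replay_band_cm = 15, n_shuffles = 1500,
    p_replay = 0.05, p_nonreplay = 0.2, di_threshold = 0.5,
    vta_lag_s = 0.084, peth_sigma_s = 0.050,
    peth_baseline_s = c(-0.4, -0.1), min_rate_hz = 0.3,
    frame_bin_s = 0.010, frame_sigma_s = 0.030,
    n_permutations = 1000, n_bootstrap = 1000,
    mark_min_peak_uv = 100, mark_min_width_s = 300e-6,
    sorted_min_peak_hz = 3)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("analysis_config: unknown field ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

#' Deterministic hash of a configuration
#' @param cfg any list of atomic values.
#' @export
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 12), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 131 + cp) %% 2147483647
  sprintf("%08x", h)
}

write_table_prov <- function(df, path, prov = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(prov)) writeLines(sprintf("# %s: %s", nm, prov[[nm]]), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

read_table_prov <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

write_lfp <- function(lfp, stem) {
  meta <- data.frame(field = c("fs", "t0", "n"),
                     value = c(lfp$fs, lfp$t0, length(lfp$samples)))
  utils::write.table(meta, paste0(stem, ".meta"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(lfp$samples, con, size = 8)
}

read_lfp <- function(stem) {
  meta <- utils::read.table(paste0(stem, ".meta"), header = TRUE, sep = "\t")
  v <- stats::setNames(meta$value, meta$field)
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = v[["n"]], size = 8)
  if (length(x) != v[["n"]])
    stop("read_lfp: sample count does not match header in ", stem)
  lfp_channel(x, fs = v[["fs"]], t0 = v[["t0"]])
}

#' Write a simulated session to a directory
#'
#' @param session a session from [simulate_session()].
#' @param dir output directory (created).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(seed = session$cfg$seed, task = session$cfg$task)
  write_table_prov(data.frame(t = session$behavior$t,
                              pos = session$behavior$pos,
                              speed = session$behavior$speed),
                   file.path(dir, "position.tsv"), prov)
  write_table_prov(session$behavior$trials, file.path(dir, "trials.tsv"), prov)
  write_table_prov(session$hc$spikes, file.path(dir, "hc_spikes.tsv"), prov)
  vta_df <- do.call(rbind, lapply(seq_along(session$vta$units), function(u)
    if (length(session$vta$units[[u]]))
      data.frame(time = session$vta$units[[u]], unit = u) else NULL))
  write_table_prov(vta_df, file.path(dir, "vta_spikes.tsv"), prov)
  write_lfp(session$hc$lfp, file.path(dir, "hc_lfp"))
  write_lfp(session$vta$lfp, file.path(dir, "vta_lfp"))
  write_table_prov(data.frame(field = c("task", "track_length_cm", "arm_cm",
                                        "t0", "t1"),
                              value = c(session$cfg$task,
                                        session$cfg$track_length_cm,
                                        session$cfg$arm_cm,
                                        session$behavior$span[1],
                                        session$behavior$span[2])),
                   file.path(dir, "track.tsv"), prov)
  write_table_prov(session$hc$truth$events, file.path(dir, "truth_events.tsv"),
                   prov)
  write_table_prov(session$vta$truth, file.path(dir, "truth_units.tsv"), prov)
  invisible(dir)
}

#' Load a session directory
#'
#' Validates monotone time bases and consistent sampling headers; errors
#' name the offending file and row.
#'
#' @param dir session directory from [write_session()].
#' @return session-like list with `behavior`, `hc`, `vta`, `track`, `truth`.
#' @export
read_session <- function(dir) {
  tk <- read_table_prov(file.path(dir, "track.tsv"))
  v <- stats::setNames(tk$value, tk$field)
  span <- c(as.numeric(v[["t0"]]), as.numeric(v[["t1"]]))
  track <- if (v[["task"]] == "linear")
    make_track("linear", length_cm = as.numeric(v[["track_length_cm"]]))
  else make_track("swm", arm_cm = as.numeric(v[["arm_cm"]]))
  pos <- read_table_prov(file.path(dir, "position.tsv"))
  if (any(diff(pos$t) <= 0))
    stop("read_session: position.tsv: non-monotone time at row ",
         which(diff(pos$t) <= 0)[1] + 1L)
  hc <- read_table_prov(file.path(dir, "hc_spikes.tsv"))
  bad <- which(hc$time < span[1] | hc$time > span[2])
  if (length(bad))
    stop("read_session: hc_spikes.tsv: spike time out of range at row ",
         bad[1])
  vta <- read_table_prov(file.path(dir, "vta_spikes.tsv"))
  units <- lapply(sort(unique(vta$unit)), function(u)
    sort(vta$time[vta$unit == u]))
  trials <- read_table_prov(file.path(dir, "trials.tsv"))
  list(track = track,
       behavior = list(t = pos$t, pos = pos$pos, speed = pos$speed,
                       trials = trials, track = track, span = span),
       hc = list(spikes = hc, lfp = read_lfp(file.path(dir, "hc_lfp"))),
       vta = list(units = units, lfp = read_lfp(file.path(dir, "vta_lfp"))),
       truth = list(
         events = tryCatch(read_table_prov(file.path(dir, "truth_events.tsv")),
                           error = function(e) NULL),
         units = tryCatch(read_table_prov(file.path(dir, "truth_units.tsv")),
                          error = function(e) NULL)))
}

#' Run the pipeline end to end
#'
#' Chains the stages over one session: simulate, detect (SPW-R), decode
#' (cross-validation), replay (score + classify), vta (unit profiles),
#' couple (reward-site bias), report. Outputs are deterministic given
#' `(cfg, config, seed)`; every table carries the configuration hash.
#'
#' @param out_dir results directory.
#' @param cfg a [sim_config()] (stage `simulate`).
#' @param config an [analysis_config()].
#' @param stages character vector of stages to run (order enforced).
#' @param n_shuffles shuffle count override for the replay stage.
#' @return invisible list of stage results.
#' @export
run_pipeline <- function(out_dir, cfg = sim_config(),
                         config = analysis_config(),
                         stages = c("simulate", "detect", "decode", "replay",
                                    "vta", "couple", "report"),
                         n_shuffles = 250) {
  all_stages <- c("simulate", "detect", "decode", "replay", "vta", "couple",
                  "report")
  stages <- all_stages[all_stages %in% stages]
  deps <- list(detect = "simulate", decode = "simulate",
               replay = c("detect", "decode"), vta = "detect",
               couple = c("replay", "vta"))
  for (s in stages)
    if (!all(deps[[s]] %in% stages))
      stop("run_pipeline: stage '", s, "' requires ",
           paste(setdiff(deps[[s]], stages), collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config_hash = attr(config, "hash"), seed = cfg$seed)
  res <- list()
  log_line <- function(...) message(sprintf(...))
  if ("simulate" %in% stages) {
    res$session <- simulate_session(cfg)
    log_line("simulate: %d HC spikes, %d events, %d VTA units",
             nrow(res$session$hc$spikes), nrow(res$session$hc$truth$events),
             length(res$session$vta$units))
  }
  ses <- res$session
  if ("detect" %in% stages) {
    mua <- compute_mua(ses$hc$spikes$time, ses$behavior$span,
                       config$mua_bin_s, config$mua_sigma_s,
                       n_tetrodes = length(unique(ses$hc$spikes$tetrode)))
    speed_fn <- stats::approxfun(ses$behavior$t, ses$behavior$speed,
                                 rule = 2)
    res$spwr <- detect_spwr(mua, speed_fn, config$spwr_threshold_sd,
                            config$speed_max_cms,
                            config$spwr_min_duration_s)
    write_table_prov(as.data.frame(res$spwr), file.path(out_dir, "spwr.tsv"),
                     prov)
    log_line("detect: %d SPW-R events", nrow(res$spwr))
  }
  if ("decode" %in% stages) {
    res$cv <- cross_validate(ses, "clusterless")
    write_table_prov(data.frame(median_error_cm = res$cv$median_error_cm,
                                direction_error = res$cv$direction_error,
                                n_bins = res$cv$n_bins),
                     file.path(out_dir, "decoding.tsv"), prov)
    log_line("decode: median error %.1f cm", res$cv$median_error_cm)
  }
  if ("replay" %in% stages) {
    sp <- mark_filter(ses$hc$spikes, config$mark_min_peak_uv,
                      config$mark_min_width_s)
    model <- fit_encoding(sp, ses$behavior$t, ses$behavior$pos,
                          ses$behavior$speed, ses$track)
    scored <- score_session_events(ses, model, res$spwr, config,
                                   n_shuffles = n_shuffles)
    res$replay <- scored
    write_table_prov(scored$table, file.path(out_dir, "replay.tsv"), prov)
    log_line("replay: %d/%d classified replay",
             sum(scored$table$label == "replay"), nrow(scored$table))
  }
  if ("vta" %in% stages) {
    run_fn <- local({
      bt <- ses$behavior$t; sp <- ses$behavior$speed
      function(t) stats::approx(bt, sp, t, rule = 2)$y > config$speed_max_cms
    })
    theta <- bandpass(ses$hc$lfp, config$theta_band_hz)
    res$vta <- do.call(rbind, lapply(seq_along(ses$vta$units), function(u)
      vta_unit_profile(ses$vta$units[[u]], ses$vta$waveforms[[u]],
                       ses$behavior$trials, cfg$task, ses$behavior$span,
                       res$spwr, theta, run_fn,
                       seed = substream_seed(cfg$seed, paste0("boot_", u)))))
    write_table_prov(res$vta, file.path(out_dir, "vta_units.tsv"), prov)
    log_line("vta: %d units (%d RR)", nrow(res$vta),
             sum(res$vta$class == "RR"))
  }
  if ("couple" %in% stages) {
    res$couple <- couple_stats(ses, res$replay, config)
    write_table_prov(res$couple, file.path(out_dir, "coupling.tsv"), prov)
    log_line("couple: %d rows", nrow(res$couple))
  }
  if ("report" %in% stages) {
    rep <- data.frame(
      stage = c("simulate", "detect", "decode", "replay", "vta", "couple"),
      summary = c(
        if (!is.null(ses)) sprintf("%d events truth", nrow(ses$hc$truth$events)) else "skipped",
        if (!is.null(res$spwr)) sprintf("%d SPW-R", nrow(res$spwr)) else "skipped",
        if (!is.null(res$cv)) sprintf("median error %.2f cm",
                                      res$cv$median_error_cm) else "skipped",
        if (!is.null(res$replay)) sprintf("%d replay",
                                          sum(res$replay$table$label == "replay")) else "skipped",
        if (!is.null(res$vta)) sprintf("%d RR units",
                                       sum(res$vta$class == "RR")) else "skipped",
        if (!is.null(res$couple)) sprintf("%d rows", nrow(res$couple)) else "skipped"))
    write_table_prov(rep, file.path(out_dir, "report.tsv"), prov)
  }
  invisible(res)
}

#' Decode and classify all candidate events of a session
#'
#' @param ses session; `model` fitted encoding model; `events` SPW-R
#'   `interval_set`; `config` an [analysis_config()].
#' @param n_shuffles Monte Carlo shuffles per event.
#' @return list with `table` (per-event label, best-path fit, p-values),
#'   `posteriors` (list), `pool` (pooled rows).
#' @export
score_session_events <- function(ses, model, events, config,
                                 n_shuffles = 250) {
  sp <- mark_filter(ses$hc$spikes, config$mark_min_peak_uv,
                    config$mark_min_width_s)
  posts <- decode_events(model, sp, events, config$event_bin_s)
  keep <- !vapply(posts, is.null, logical(1))
  pool <- do.call(rbind, lapply(posts[keep], function(p) p$P))
  rows <- lapply(seq_len(nrow(events)), function(i) {
    if (!keep[i])
      return(data.frame(event = i, label = "ambiguous", path_id = NA,
                        R = NA, speed = NA, intercept = NA,
                        p_column = NA, p_pseudo = NA))
    cl <- classify_replay(posts[[i]], pool, ses$track,
                          n_shuffles = n_shuffles,
                          seed = substream_seed(ses$cfg$seed,
                                                paste0("event_", i)),
                          p_replay = config$p_replay,
                          p_nonreplay = config$p_nonreplay,
                          band = config$replay_band_cm)
    data.frame(event = i, label = cl$label,
               path_id = cl$best$path_id, R = cl$best$fit$R,
               speed = cl$best$fit$speed, intercept = cl$best$fit$intercept,
               p_column = cl$best$p_column, p_pseudo = cl$best$p_pseudo)
  })
  list(table = do.call(rbind, rows), posteriors = posts, pool = pool)
}

#' Decode per-event posteriors in 25 ms bins
#'
#' Bins lie on the absolute 25 ms grid of the session clock (the same
#' frame convention used throughout), covering the event interval.
#'
#' @param model encoding model; `spikes` mark-filtered spikes; `events`
#'   interval set; `bin_s` bin width.
#' @return list of `posterior` objects (NULL for events shorter than 2
#'   bins).
#' @export
decode_events <- function(model, spikes, events, bin_s = 0.025) {
  lapply(seq_len(nrow(events)), function(i) {
    e0 <- floor(events$start[i] / bin_s) * bin_s
    e1 <- ceiling(events$end[i] / bin_s) * bin_s
    nb <- round((e1 - e0) / bin_s)
    if (nb < 2L) return(NULL)
    decode(model, spikes, e0 + (0:nb) * bin_s)
  })
}

# reward-site bias summary per unit class for the couple stage
couple_stats <- function(ses, replay, config) {
  tab <- replay$table
  rep_idx <- which(tab$label == "replay")
  if (!length(rep_idx))
    return(data.frame(unit = integer(0), class = character(0),
                      n_bins = integer(0), excess = numeric(0),
                      chi2 = numeric(0), p = numeric(0)))
  rw <- track_bins(ses$track)$reward
  ind_all <- integer(0); starts <- numeric(0); ends <- numeric(0)
  for (i in rep_idx) {
    p <- replay$posteriors[[i]]
    ind_all <- c(ind_all, reward_site_bias(p$P, rw)$indicators)
    starts <- c(starts, p$time_edges[-length(p$time_edges)])
    ends <- c(ends, p$time_edges[-1L])
  }
  bias_ref <- mean(ind_all)
  do.call(rbind, lapply(seq_along(ses$vta$units), function(u) {
    sel <- spike_associated_bins(starts, ends, ses$vta$units[[u]],
                                 lag = config$vta_lag_s)$selected
    if (!any(sel))
      return(data.frame(unit = u, class = ses$vta$truth$class[u],
                        n_bins = 0L, excess = NA, chi2 = NA, p = NA))
    ec <- excess_bias_chi2(sum(ind_all[sel]), sum(sel), bias_ref)
    data.frame(unit = u, class = ses$vta$truth$class[u], n_bins = sum(sel),
               excess = ec$excess, chi2 = ec$chi2, p = ec$p)
  }))
}
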