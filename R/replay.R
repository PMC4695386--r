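# Replay detection: constant-speed trajectory fitting over candidate paths,
# column-cycle and pseudo-event Monte Carlo shuffles, classification, and
# per-bin direction/geometry labels.

#' Default trajectory search grid
#'
#' Signed speeds of 0.5-15 m/s in 0.25 m/s steps (both directions);
#' intercepts at the spatial bin centers of the path.
#' @param path_length_cm length of the candidate path (cm).
#' @param bin_width spatial bin width (cm).
#' @export
trajectory_grid <- function(path_length_cm, bin_width = 10) {
  sp <- seq(50, 1500, by = 25)
  list(speeds = c(-rev(sp), sp),
       intercepts = seq(bin_width / 2, path_length_cm, by = bin_width))
}

# Precompute, for one event x one path, everything repeated scoring needs:
#  - fine path grid (1 cm, extended by the band half-width beyond both ends)
#  - Ind: S x F band membership (along-track distance <= band for on-path
#    points; 1-D path distance for the linear extensions)
#  - col: T x n_traj fine-grid column index of each trajectory at each bin
# Scores are then gathers into B = P %*% Ind (T x F).
.traj_cache <- new.env(parent = emptyenv())

traj_machine <- function(track, path_id, time_edges, band = 15,
                         grid = NULL) {
  p <- track$paths[[path_id]]
  if (p$length <= band) stop("traj_machine: degenerate path shorter than band")
  if (is.null(grid)) grid <- trajectory_grid(p$length, track$bin_width)
  key <- paste(track$type, track$total_cm, track$bin_width, path_id, band,
               length(time_edges), signif(diff(range(time_edges)), 8),
               sep = "|")
  hit <- get0(key, envir = .traj_cache)
  if (!is.null(hit)) return(hit)
  bins <- track_bins(track)
  fine <- seq(-band, p$length + band, by = 1)
  F <- length(fine)
  on_path <- fine >= 0 & fine <= p$length
  Ind <- matrix(FALSE, nrow(bins), F)
  g_fine <- path_to_global(track, path_id, pmin(pmax(fine, 0), p$length))
  for (j in which(on_path))
    Ind[, j] <- track_distance(track, bins$center, g_fine[j]) <= band
  # linear extension beyond the ends: band in path coordinates only
  path_coord_of_bin <- rep(NA_real_, nrow(bins))
  samp <- seq(0, p$length, by = 1)
  gb <- path_to_global(track, path_id, samp)
  for (s in seq_len(nrow(bins))) {
    d <- abs(gb - bins$center[s])
    if (min(d) < track$bin_width / 2) path_coord_of_bin[s] <- samp[which.min(d)]
  }
  for (j in which(!on_path)) {
    Ind[, j] <- !is.na(path_coord_of_bin) &
      abs(path_coord_of_bin - fine[j]) <= band
  }
  Tn <- length(time_edges) - 1L
  tc <- (time_edges[-length(time_edges)] + time_edges[-1L]) / 2
  tc <- tc - tc[1L]
  ns <- length(grid$speeds); ni <- length(grid$intercepts)
  pos <- outer(tc, grid$speeds)                        # T x ns
  pos <- pos[, rep(seq_len(ns), times = ni), drop = FALSE] +
    rep(grid$intercepts, each = ns)[col(matrix(0, Tn, ns * ni))]
  col_idx <- matrix(pmin(pmax(round(pos + band) + 1L, 1L), F), Tn)
  out <- list(path_id = path_id, grid = grid, Ind = Ind, col = col_idx,
              Tn = Tn, F = F, S = nrow(bins),
              speeds = rep(grid$speeds, times = ni),
              intercepts = rep(grid$intercepts, each = ns))
  assign(key, out, envir = .traj_cache)
  out
}

# Best replay score over the grid for posterior P (T x S), given a machine.
# Returns list(R, speed, intercept, scores) with scores optional.
traj_best <- function(P, mach) {
  B <- P %*% mach$Ind                     # T x F band mass
  flat <- as.vector(seq_len(mach$Tn)) + mach$Tn * (mach$col - 1L)
  sc <- colMeans(matrix(B[flat], mach$Tn))
  k <- which.max(sc)
  list(R = sc[k], speed = mach$speeds[k], intercept = mach$intercepts[k])
}

#' Replay score of one explicit trajectory
#'
#' Mean posterior mass within `band` cm (along-track distance) of the
#' constant-speed trajectory `intercept + speed * t`, with `t` measured
#' from the first bin center. Trajectory positions are evaluated on a 1 cm
#' grid.
#'
#' @param post event `posterior`.
#' @param track a `track`; `path_id` candidate path index.
#' @param speed signed speed (cm/s); `intercept` path coordinate (cm) at
#'   the first bin center.
#' @param band scoring band half-width (cm).
#' @return the replay score in `[0, 1]`.
#' @export
replay_score <- function(post, track, path_id, speed, intercept, band = 15) {
  mach <- traj_machine(track, path_id, post$time_edges, band)
  tc <- (post$time_edges[-length(post$time_edges)] + post$time_edges[-1L]) / 2
  tc <- tc - tc[1L]
  p <- intercept + speed * tc
  cols <- pmin(pmax(round(p + band) + 1L, 1L), mach$F)
  B <- post$P %*% mach$Ind
  mean(B[cbind(seq_len(mach$Tn), cols)])
}

#' Fit constant-speed trajectories to a candidate event
#'
#' Grid search over signed speed and intercept maximizing the replay score
#' (mean posterior mass within `band` cm of the trajectory, with along-track
#' distances) on each candidate path.
#'
#' @param post a `posterior` with 25 ms bins for the event.
#' @param track a `track`.
#' @param path_ids candidate path indices; default all paths of the track.
#' @param band half-width of the scoring band (cm), default 15.
#' @return list of per-path fits: `path_id`, `R`, `speed` (cm/s, signed),
#'   `intercept` (cm along path).
#' @export
fit_trajectory <- function(post, track, path_ids = NULL, band = 15) {
  if (is.null(path_ids)) path_ids <- seq_along(track$paths)
  if (nrow(post$P) < 2L) stop("fit_trajectory: event needs >= 2 time bins")
  lapply(path_ids, function(pid) {
    mach <- traj_machine(track, pid, post$time_edges, band)
    c(list(path_id = pid), traj_best(post$P, mach))
  })
}

#' Column-cycle shuffle null for the replay score
#'
#' Circularly shifts the position PDF of every event time bin by an
#' independent random distance, refits the whole trajectory grid, and
#' records the best score. `p = (1 + #[R_shuf >= R_obs]) / (n + 1)`.
#'
#' @param post event `posterior`.
#' @param track,path_id,band as in [fit_trajectory()].
#' @param n number of shuffles (default 1500).
#' @param seed integer seed for the event's shuffle substream.
#' @return list with `R_obs`, `scores` (length `n`), `p`.
#' @export
column_cycle_shuffle <- function(post, track, path_id, n = 1500, seed = 1,
                                 band = 15) {
  if (n < 100) warning("column_cycle_shuffle: n < 100 gives unstable p")
  mach <- traj_machine(track, path_id, post$time_edges, band)
  obs <- traj_best(post$P, mach)
  S <- mach$S; Tn <- mach$Tn; F <- mach$F
  # G[t, f, k]: band mass at fine point f for row t shifted by k-1 bins
  G <- array(0, c(Tn, F, S))
  idx <- seq_len(S)
  for (k in seq_len(S)) {
    shifted <- ((idx - (k - 1L) - 1L) %% S) + 1L
    G[, , k] <- post$P[, shifted, drop = FALSE] %*% mach$Ind
  }
  base <- as.vector(seq_len(Tn)) + Tn * (mach$col - 1L)
  scores <- with_substream(seed, paste0("colcycle_", path_id), {
    vapply(seq_len(n), function(i) {
      kshift <- sample.int(S, Tn, replace = TRUE) - 1L
      flat <- base + (Tn * F) * kshift            # recycled down columns
      max(colMeans(matrix(G[flat], Tn)))
    }, numeric(1))
  })
  p <- (1 + sum(scores >= obs$R - 1e-12)) / (n + 1)
  list(R_obs = obs$R, fit = obs, scores = scores, p = p)
}

#' Pseudo-event shuffle null for the replay score
#'
#' Replaces each event time bin's PDF with one drawn at random (with
#' replacement) from the pool of all candidate-event bins in the session,
#' refits, and records the best score. Controls for static location bias.
#'
#' @param post event `posterior`.
#' @param pool_P matrix of pooled candidate-event rows (n_pool x S).
#' @param track,path_id,band,n,seed as in [column_cycle_shuffle()].
#' @return list with `R_obs`, `scores`, `p`.
#' @export
pseudo_event_shuffle <- function(post, pool_P, track, path_id, n = 1500,
                                 seed = 1, band = 15) {
  if (nrow(pool_P) < 100) stop("pseudo_event_shuffle: pool has < 100 rows")
  if (n < 100) warning("pseudo_event_shuffle: n < 100 gives unstable p")
  mach <- traj_machine(track, path_id, post$time_edges, band)
  obs <- traj_best(post$P, mach)
  Bpool <- pool_P %*% mach$Ind              # n_pool x F
  np <- nrow(pool_P); Tn <- mach$Tn
  colsT <- np * (mach$col - 1L)             # T x n_traj offsets
  scores <- with_substream(seed, paste0("pseudo_", path_id), {
    vapply(seq_len(n), function(i) {
      rows <- sample.int(np, Tn, replace = TRUE)
      max(colMeans(matrix(Bpool[rows + colsT], Tn)))
    }, numeric(1))
  })
  p <- (1 + sum(scores >= obs$R - 1e-12)) / (n + 1)
  list(R_obs = obs$R, fit = obs, scores = scores, p = p)
}

#' Score and classify one candidate event
#'
#' Runs the trajectory fit and both shuffles on each candidate path
#' (standard mode) or on the best-scoring path only (stringent mode), and
#' applies the classification rule: replay if both shuffle p-values are
#' below `p_replay` on at least one path; nonreplay-enriched if both exceed
#' `p_nonreplay` on every path; otherwise ambiguous. Events with fewer than
#' `min_bins` time bins are ambiguous by construction.
#'
#' @param post event `posterior` (25 ms bins).
#' @param pool_P pooled candidate rows for the pseudo-event shuffle.
#' @param track a `track`.
#' @param n_shuffles Monte Carlo samples per shuffle (default 1500).
#' @param seed event-specific seed (use [substream_seed()] on the event id).
#' @param mode `"standard"` or `"stringent"`.
#' @param p_replay,p_nonreplay classification thresholds.
#' @param min_bins minimum bins for fitting (default 3).
#' @param band scoring band (cm).
#' @return list with `label`, `best` (best path fit), `paths` (per-path
#'   p-values and fits).
#' @export
classify_replay <- function(post, pool_P, track, n_shuffles = 1500, seed = 1,
                            mode = c("standard", "stringent"),
                            p_replay = 0.05, p_nonreplay = 0.2,
                            min_bins = 3L, band = 15) {
  mode <- match.arg(mode)
  if (nrow(post$P) < min_bins)
    return(list(label = "ambiguous", best = NULL, paths = NULL))
  fits <- fit_trajectory(post, track, band = band)
  Rs <- vapply(fits, `[[`, numeric(1), "R")
  pids <- if (mode == "stringent") which.max(Rs) else seq_along(fits)
  res <- lapply(pids, function(pid) {
    cc <- column_cycle_shuffle(post, track, pid, n = n_shuffles, seed = seed,
                               band = band)
    pe <- pseudo_event_shuffle(post, pool_P, track, pid, n = n_shuffles,
                               seed = seed, band = band)
    list(path_id = pid, fit = fits[[pid]], p_column = cc$p, p_pseudo = pe$p)
  })
  pc <- vapply(res, `[[`, numeric(1), "p_column")
  pp <- vapply(res, `[[`, numeric(1), "p_pseudo")
  label <- if (any(pc < p_replay & pp < p_replay)) "replay"
  else if (mode == "standard" && all(pc > p_nonreplay & pp > p_nonreplay))
    "nonreplay_enriched"
  else if (mode == "stringent" && all(pc > p_nonreplay & pp > p_nonreplay))
    "nonreplay_enriched"
  else "ambiguous"
  best_sig <- which(pc < p_replay & pp < p_replay)
  best <- if (length(best_sig)) {
    bb <- best_sig[which.max(vapply(res[best_sig],
                                    function(r) r$fit$R, numeric(1)))]
    res[[bb]]
  } else res[[which.max(vapply(res, function(r) r$fit$R, numeric(1)))]]
  list(label = label, best = best, paths = res)
}

#' Per-bin direction index and replay geometry labels
#'
#' The direction index is `DI = (O - I) / (O + I)` from the direction
#' posterior; bins with `|DI|` at or below the threshold stay unlabeled.
#' A bin is centrifugal when the along-track distance between the fitted
#' trajectory position and the animal increases through it, centripetal
#' when it decreases; forward when the decoded run direction matches the
#' spatial propagation direction of the fit, reverse when opposite.
#'
#' @param post event `posterior` with a `direction_P` component.
#' @param fit a trajectory fit (`path_id`, `speed`, `intercept`).
#' @param animal_pos the animal's global linear position (cm) at event time.
#' @param track a `track`.
#' @param di_threshold `|DI|` threshold (default 0.5).
#' @return data frame per bin: `di`, `traj_pos` (global cm), `direction`
#'   (`"outbound"`/`"inbound"`/NA), `order` (`"forward"`/`"reverse"`/NA),
#'   `geometry` (`"centrifugal"`/`"centripetal"`/NA).
#' @export
label_bin_geometry <- function(post, fit, animal_pos, track,
                               di_threshold = 0.5) {
  if (is.null(post$direction_P)) stop("label_bin_geometry: no direction posterior")
  O <- post$direction_P[, 1L]; I <- post$direction_P[, 2L]
  denom <- O + I
  di <- ifelse(denom > 0, (O - I) / denom, NA_real_)
  tc <- (post$time_edges[-length(post$time_edges)] + post$time_edges[-1L]) / 2
  s_path <- fit$intercept + fit$speed * (tc - tc[1L])
  gpos <- path_to_global(track, fit$path_id, s_path)
  dist_animal <- track_distance(track, gpos, animal_pos)
  dd <- c(diff(dist_animal), NA)
  dd[length(dd)] <- dd[length(dd) - 1L]
  strong <- !is.na(di) & abs(di) > di_threshold
  direction <- ifelse(strong, ifelse(di > 0, "outbound", "inbound"), NA)
  # propagation in global coordinates: outbound = increasing linear coord
  dglob <- c(diff(gpos), NA); dglob[length(dglob)] <- dglob[length(dglob) - 1L]
  prop <- ifelse(dglob > 0, "outbound", "inbound")
  order_lab <- ifelse(strong, ifelse(direction == prop, "forward", "reverse"),
                      NA)
  geometry <- ifelse(strong, ifelse(dd > 0, "centrifugal", "centripetal"), NA)
  data.frame(di = di, traj_pos = gpos, direction = direction,
             order = order_lab, geometry = geometry)
}

#' Covariate-matched event subsets
#'
#' Greedy nearest-neighbor matching without replacement inside a caliper,
#' tightened until the matched covariates show no rank-sum difference
#' (p > 0.2).
#'
#' @param a,b numeric covariate vectors (durations or spike counts) of the
#'   two groups.
#' @param caliper initial caliper (same units); default the pooled s.d.
#' @param seed tie-breaking seed.
#' @return list with `idx_a`, `idx_b` (matched indices) and `p` (rank-sum).
#' @export
match_events <- function(a, b, caliper = NULL, seed = 1) {
  if (!length(a) || !length(b)) stop("match_events: empty group")
  if (is.null(caliper)) caliper <- stats::sd(c(a, b))
  repeat {
    ord <- with_substream(seed, "match", sample(seq_along(a)))
    used <- rep(FALSE, length(b))
    ia <- integer(0); ib <- integer(0)
    for (i in ord) {
      d <- abs(b - a[i]); d[used] <- Inf
      j <- which.min(d)
      if (d[j] <= caliper) { used[j] <- TRUE; ia <- c(ia, i); ib <- c(ib, j) }
    }
    if (length(ia) < 10L) stop("match_events: fewer than 10 matchable pairs")
    p <- suppressWarnings(stats::wilcox.test(a[ia], b[ib])$p.value)
    if (is.na(p)) p <- 1
    if (p > 0.2) return(list(idx_a = ia, idx_b = ib, p = p))
    caliper <- caliper / 2
  }
}
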