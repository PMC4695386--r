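# Bayesian reconstruction of position and run direction from hippocampal
# spikes: clusterless (marked point process over 4-channel amplitude marks)
# and sorted (Poisson population decoding over tuning curves).

#' Filter marked spikes on putative-pyramidal criteria
#'
#' @param spikes data frame with columns `time`, `tetrode`, `m1`..`m4`
#'   (peak amplitudes, uV) and `width` (s).
#' @param min_peak minimum peak amplitude over the four channels (uV).
#' @param min_width minimum spike width (s).
#' @export
mark_filter <- function(spikes, min_peak = 100, min_width = 300e-6) {
  pk <- pmax(spikes$m1, spikes$m2, spikes$m3, spikes$m4)
  spikes[pk > min_peak & spikes$width > min_width, , drop = FALSE]
}

#' Posterior container
#'
#' @param P numeric T x S matrix; rows are normalized in the constructor
#'   (all-zero rows become uniform).
#' @param time_edges numeric vector of T+1 bin edges (s).
#' @param space data frame from [track_bins()].
#' @param direction_P optional T x 2 matrix (outbound, inbound).
#' @export
posterior <- function(P, time_edges, space, direction_P = NULL) {
  P <- as.matrix(P)
  stopifnot(nrow(P) == length(time_edges) - 1L, ncol(P) == nrow(space))
  rs <- rowSums(P)
  zero <- rs <= 0 | !is.finite(rs)
  if (any(zero)) P[zero, ] <- 1 / ncol(P)
  P[!zero, ] <- P[!zero, , drop = FALSE] / rs[!zero]
  if (!is.null(direction_P)) {
    rs <- rowSums(direction_P)
    zero <- rs <= 0 | !is.finite(rs)
    if (any(zero)) direction_P[zero, ] <- 0.5
    direction_P[!zero, ] <- direction_P[!zero, , drop = FALSE] / rs[!zero]
  }
  stopifnot(all(abs(rowSums(P) - 1) < 1e-9))
  structure(list(P = P, time_edges = time_edges, space = space,
                 direction_P = direction_P),
            class = "posterior")
}

#' Fit the clusterless encoding model
#'
#' Per-tetrode Gaussian kernel density over (linear position, 4-D amplitude
#' mark), an analogous 2-class density over run direction, occupancy over
#' position, and the per-position total spike intensity. Position kernels use
#' the along-track distance of the track graph.
#'
#' @param spikes mark-filtered data frame (`time`, `tetrode`, `m1`..`m4`).
#' @param pos_t,pos_lin position sample times (s) and global linear
#'   coordinates (cm).
#' @param speed running speed at position samples (cm/s).
#' @param track a `track`.
#' @param time_mask optional `interval_set` restricting encoding to within
#'   the given intervals (for cross-validation).
#' @param speed_min encoding restricted to run samples with speed above this
#'   (cm/s).
#' @param bw_pos,bw_mark Gaussian bandwidths: position (cm), per-channel
#'   amplitude (uV).
#' @param min_spikes tetrodes with fewer encoding spikes are excluded.
#' @param occupancy_floor floor on occupancy, as a fraction of uniform.
#' @return an `encoding_model`.
#' @export
fit_encoding <- function(spikes, pos_t, pos_lin, speed, track,
                         time_mask = NULL, speed_min = 10,
                         bw_pos = 6, bw_mark = 15, min_spikes = 50,
                         occupancy_floor = 1e-3) {
  run <- speed > speed_min
  if (!is.null(time_mask)) run <- run & in_intervals(pos_t, time_mask)
  if (!any(run)) stop("fit_encoding: no run-epoch position samples")
  dt_pos <- stats::median(diff(pos_t))
  bins <- track_bins(track)
  S <- nrow(bins)
  # direction of travel at position samples (+1 outbound/increasing)
  dirn <- c(0, sign(diff(pos_lin))); dirn[dirn == 0] <- NA
  dirn <- zoo_fill(dirn)
  occ_idx <- pmin(pmax(floor(pos_lin[run] / track$bin_width) + 1L, 1L), S)
  occupancy <- tabulate(occ_idx, nbins = S) * dt_pos
  occupancy <- pmax(occupancy, occupancy_floor * sum(occupancy) / S)
  t_dir <- c(sum(run & dirn > 0), sum(run & dirn < 0)) * dt_pos
  t_dir <- pmax(t_dir, dt_pos)
  # spike-time covariates
  sp_speed <- stats::approx(pos_t, speed, spikes$time, rule = 2)$y
  sp_pos <- stats::approx(pos_t, pos_lin, spikes$time, rule = 2)$y
  sp_dir <- stats::approx(pos_t, dirn, spikes$time, method = "constant",
                          rule = 2)$y
  enc <- sp_speed > speed_min
  if (!is.null(time_mask)) enc <- enc & in_intervals(spikes$time, time_mask)
  tets <- sort(unique(spikes$tetrode))
  mods <- list(); dropped <- integer(0)
  for (tt in tets) {
    sel <- enc & spikes$tetrode == tt
    if (sum(sel) < min_spikes) { dropped <- c(dropped, tt); next }
    marks <- as.matrix(spikes[sel, c("m1", "m2", "m3", "m4")])
    pos <- sp_pos[sel]
    # position kernel evaluated at bin centers, n_enc x S
    Kpos <- vapply(bins$center, function(cc)
      dnorm(track_distance(track, pos, cc), sd = bw_pos), numeric(sum(sel)))
    lambda_x <- colSums(Kpos) / occupancy          # total intensity (Hz/cm-ish)
    dir_cls <- ifelse(sp_dir[sel] > 0, 1L, 2L)
    mods[[as.character(tt)]] <- list(
      tetrode = tt, marks = marks, Kpos = Kpos, lambda_x = lambda_x,
      dir_cls = dir_cls, n_enc = sum(sel))
  }
  if (!length(mods)) stop("fit_encoding: no tetrode has enough encoding spikes")
  structure(list(tetrodes = mods, occupancy = occupancy, t_dir = t_dir,
                 bins = bins, track = track, bw_pos = bw_pos,
                 bw_mark = bw_mark, dropped = dropped,
                 dt_pos = dt_pos),
            class = "encoding_model")
}

# forward-fill NAs (run-direction at turnarounds)
zoo_fill <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(rep(1, length(x)))
  idx <- cumsum(ok)
  x[ok][pmax(idx, 1L)]
}

# Gaussian mark cross-kernel exp(-||a-b||^2 / (2 bw^2)), chunk-friendly.
mark_kernel <- function(A, B, bw) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  exp(-pmax(d2, 0) / (2 * bw^2))
}

#' Clusterless decoding
#'
#' Per time bin, the log likelihood over position bins sums, across
#' tetrodes, the log generalized firing rate at each in-bin spike's mark
#' plus the Poisson no-spike factor `-dt * Lambda(x)`; rows are normalized
#' in log space. Bins with no spikes on any tetrode return a uniform row. A
#' direction posterior over (outbound, inbound) is computed analogously
#' from the per-direction mark densities.
#'
#' @param model an `encoding_model`.
#' @param spikes mark-filtered spikes to decode.
#' @param time_edges bin edges (s), non-overlapping.
#' @param likelihood `"intensity"` (full marked point-process intensity with
#'   the no-spike factor; default) or `"conditional"` (per-spike conditional
#'   position density only).
#' @param chunk decode-spike block size for the mark-kernel product.
#' @return a `posterior`.
#' @export
decode <- function(model, spikes, time_edges,
                   likelihood = c("intensity", "conditional"), chunk = 512L) {
  likelihood <- match.arg(likelihood)
  Tn <- length(time_edges) - 1L
  S <- nrow(model$bins)
  dt <- diff(time_edges)
  logL <- matrix(0, Tn, S)
  logD <- matrix(0, Tn, 2L)
  any_spike <- rep(FALSE, Tn)
  for (m in model$tetrodes) {
    bin_of <- findInterval(spikes$time[spikes$tetrode == m$tetrode], time_edges,
                           rightmost.closed = FALSE)
    sel <- which(spikes$tetrode == m$tetrode)[bin_of >= 1L & bin_of <= Tn]
    bin_of <- bin_of[bin_of >= 1L & bin_of <= Tn]
    if (length(sel)) {
      marks <- as.matrix(spikes[sel, c("m1", "m2", "m3", "m4")])
      n <- nrow(marks)
      for (i0 in seq(1L, n, by = chunk)) {
        ii <- i0:min(i0 + chunk - 1L, n)
        W <- mark_kernel(marks[ii, , drop = FALSE], m$marks, model$bw_mark)
        G <- W %*% m$Kpos                       # n_ii x S
        G <- sweep(G, 2L, model$occupancy, "/") # generalized rate at marks
        lg <- log(pmax(G, 1e-300))
        for (k in seq_along(ii)) {
          b <- bin_of[ii[k]]
          logL[b, ] <- logL[b, ] + lg[k, ]
          any_spike[b] <- TRUE
        }
        # direction: class intensity = sum of mark kernel over same-class
        # encoding spikes / time in class
        for (d in 1:2) {
          gd <- rowSums(W[, m$dir_cls == d, drop = FALSE]) / model$t_dir[d]
          lgd <- log(pmax(gd, 1e-300))
          for (k in seq_along(ii)) logD[bin_of[ii[k]], d] <-
              logD[bin_of[ii[k]], d] + lgd[k]
        }
      }
    }
    if (likelihood == "intensity") {
      logL <- logL - outer(dt, m$lambda_x)
      n_d <- c(sum(m$dir_cls == 1L), sum(m$dir_cls == 2L)) / model$t_dir
      logD <- logD - outer(dt, n_d)
    }
  }
  P <- exp(logL - apply(logL, 1L, max))
  Dp <- exp(logD - apply(logD, 1L, max))
  P[!any_spike, ] <- 1          # stated fallback: uniform when no spikes
  Dp[!any_spike, ] <- 1
  posterior(P, time_edges, model$bins, direction_P = Dp)
}

#' Spatial tuning curves of sorted units
#'
#' Occupancy-normalized, Gaussian-smoothed firing rate maps over the track
#' bins, from run-epoch spikes; cells whose peak rate is below `min_peak_hz`
#' are dropped (place-cell criterion).
#'
#' @param unit_spikes list of numeric spike-time vectors (s), one per unit.
#' @param pos_t,pos_lin,speed as in [fit_encoding()].
#' @param track a `track`.
#' @param time_mask optional `interval_set` restriction.
#' @param speed_min run threshold (cm/s).
#' @param smooth_sd spatial smoothing s.d. (cm).
#' @param min_peak_hz peak-rate inclusion criterion (Hz).
#' @return list with `rates` (S x C matrix, Hz) and `kept` (unit indices).
#' @export
tuning_curves <- function(unit_spikes, pos_t, pos_lin, speed, track,
                          time_mask = NULL, speed_min = 10, smooth_sd = 5,
                          min_peak_hz = 3) {
  run <- speed > speed_min
  if (!is.null(time_mask)) run <- run & in_intervals(pos_t, time_mask)
  dt_pos <- stats::median(diff(pos_t))
  bins <- track_bins(track); S <- nrow(bins)
  occ_idx <- pmin(pmax(floor(pos_lin[run] / track$bin_width) + 1L, 1L), S)
  occ <- tabulate(occ_idx, nbins = S) * dt_pos
  occ <- pmax(occ, 1e-3 * sum(occ) / S)
  rates <- sapply(unit_spikes, function(st) {
    sp_speed <- stats::approx(pos_t, speed, st, rule = 2)$y
    keep <- sp_speed > speed_min
    if (!is.null(time_mask)) keep <- keep & in_intervals(st, time_mask)
    sp_pos <- stats::approx(pos_t, pos_lin, st[keep], rule = 2)$y
    idx <- pmin(pmax(floor(sp_pos / track$bin_width) + 1L, 1L), S)
    r <- tabulate(idx, nbins = S) / occ
    as.numeric(smooth_gaussian(r, smooth_sd / track$bin_width))
  })
  rates <- matrix(rates, nrow = S)
  kept <- which(apply(rates, 2L, max) > min_peak_hz)
  list(rates = rates[, kept, drop = FALSE], kept = kept, bins = bins)
}

#' Cluster-sort marked spikes by their amplitude marks
#'
#' Emulates amplitude-space spike sorting: k-means on the 4-D marks of each
#' tetrode. Spikes from cells with overlapping amplitude clusters are
#' misassigned, which is exactly the regime where clusterless decoding
#' retains information a cluster-based decoder loses.
#'
#' @param spikes mark-filtered spike data frame.
#' @param k_per_tetrode integer vector (or single value) of cluster counts
#'   per tetrode.
#' @param seed RNG seed for the k-means starts.
#' @return list of spike-time vectors, one per cluster (all tetrodes
#'   pooled).
#' @export
sort_spikes_kmeans <- function(spikes, k_per_tetrode, seed = 1) {
  tets <- sort(unique(spikes$tetrode))
  k_per_tetrode <- rep_len(k_per_tetrode, length(tets))
  out <- list()
  for (i in seq_along(tets)) {
    sel <- spikes$tetrode == tets[i]
    M <- as.matrix(spikes[sel, c("m1", "m2", "m3", "m4")])
    k <- min(k_per_tetrode[i], nrow(M))
    cl <- with_substream(seed, paste0("kmeans_", tets[i]),
                         stats::kmeans(M, centers = k, nstart = 5,
                                       iter.max = 50)$cluster)
    for (j in seq_len(k))
      out[[length(out) + 1L]] <- sort(spikes$time[sel][cl == j])
  }
  out
}

#' Sorted-unit Poisson population decoding
#'
#' @param curves S x C matrix of tuning rates (Hz); all-zero cells dropped.
#' @param counts T x C matrix of per-bin spike counts.
#' @param time_edges bin edges (s).
#' @param space track bins data frame.
#' @return a `posterior` (no direction component).
#' @export
decode_sorted <- function(curves, counts, time_edges, space) {
  keep <- colSums(curves) > 0
  curves <- curves[, keep, drop = FALSE]
  counts <- as.matrix(counts)[, keep, drop = FALSE]
  dt <- diff(time_edges)
  logf <- log(pmax(t(curves), 1e-12))          # C x S
  logL <- counts %*% logf - outer(dt, rowSums(curves))
  P <- exp(logL - apply(logL, 1L, max))
  P[rowSums(counts) == 0, ] <- 1
  posterior(P, time_edges, space)
}

#' Cross-validated decoding report
#'
#' Splits run epochs into alternating 1 s blocks (odd blocks train, even
#' blocks test), decodes the test blocks in 500 ms bins, and reports the
#' median along-track error between the MAP estimate and the true position,
#' a confusion matrix over spatial bins, and the direction 0/1 error
#' (clusterless mode).
#'
#' @param session a session list (see [simulate_session()]): needs
#'   `behavior` and `hc$spikes` (clusterless) or `hc$unit_spikes` (sorted).
#' @param mode `"clusterless"` or `"sorted"`.
#' @param block block length (s), decode_bin decoding bin (s).
#' @param ... passed to [fit_encoding()] / [tuning_curves()].
#' @return list with `median_error_cm`, `confusion`, `direction_error`,
#'   `n_bins`.
#' @export
cross_validate <- function(session, mode = c("clusterless", "sorted"),
                           block = 1, decode_bin = 0.5, ...) {
  mode <- match.arg(mode)
  beh <- session$behavior; track <- session$track
  run <- beh$speed > 10
  rr <- rle(run)
  ends <- cumsum(rr$lengths); starts <- ends - rr$lengths + 1L
  seg_i <- which(rr$values)
  tr_s <- numeric(0); tr_e <- numeric(0); te_s <- numeric(0); te_e <- numeric(0)
  parity <- 0L
  for (k in seg_i) {
    t0 <- beh$t[starts[k]]; t1 <- beh$t[ends[k]]
    bs <- seq(t0, t1, by = block)
    for (b in bs) {
      b1 <- min(b + block, t1)
      if (b1 - b < 0.25) next
      if (parity %% 2L == 0L) { tr_s <- c(tr_s, b); tr_e <- c(tr_e, b1) }
      else { te_s <- c(te_s, b); te_e <- c(te_e, b1) }
      parity <- parity + 1L
    }
  }
  if (sum(tr_e - tr_s) < 2 || sum(te_e - te_s) < 1)
    stop("cross_validate: run epochs too short")
  train <- interval_set(tr_s, tr_e, kind = "train")
  test <- interval_set(te_s, te_e, kind = "test")
  bins <- track_bins(track); S <- nrow(bins)
  # test-time decoding bins
  edges <- unlist(lapply(seq_len(nrow(test)), function(i)
    seq(test$start[i], test$end[i], by = decode_bin)))
  edges <- sort(unique(edges))
  keep_bin <- in_intervals((edges[-length(edges)] + edges[-1L]) / 2, test) &
    diff(edges) > decode_bin * 0.99
  if (mode == "clusterless") {
    sp <- mark_filter(session$hc$spikes)
    model <- fit_encoding(sp, beh$t, beh$pos, beh$speed, track,
                          time_mask = train, ...)
    post <- decode(model, sp, edges)
  } else {
    tc <- tuning_curves(session$hc$unit_spikes, beh$t, beh$pos, beh$speed,
                        track, time_mask = train, ...)
    counts <- sapply(session$hc$unit_spikes[tc$kept], function(st)
      tabulate(findInterval(st, edges, rightmost.closed = FALSE),
               nbins = length(edges) - 1L))
    post <- decode_sorted(tc$rates, counts, edges, bins)
  }
  centers_t <- (edges[-length(edges)] + edges[-1L]) / 2
  true_pos <- stats::approx(beh$t, beh$pos, centers_t, rule = 2)$y
  true_spd <- stats::approx(beh$t, beh$speed, centers_t, rule = 2)$y
  use <- keep_bin & true_spd > 10
  # only bins with spikes carry information; uniform rows are excluded
  has_spk <- apply(post$P, 1L, function(r) stats::sd(r) > 1e-12)
  use <- use & has_spk
  if (!any(use)) stop("cross_validate: no informative test bins")
  map_bin <- apply(post$P[use, , drop = FALSE], 1L, which.max)  # ties: lowest
  err <- track_distance(track, bins$center[map_bin], true_pos[use])
  true_bin <- pmin(pmax(floor(true_pos[use] / track$bin_width) + 1L, 1L), S)
  confusion <- matrix(0L, S, S)
  for (i in seq_along(map_bin))
    confusion[true_bin[i], map_bin[i]] <- confusion[true_bin[i], map_bin[i]] + 1L
  dir_err <- NA_real_
  if (!is.null(post$direction_P)) {
    dirn <- c(0, sign(diff(beh$pos))); dirn <- zoo_fill(ifelse(dirn == 0, NA, dirn))
    true_dir <- stats::approx(beh$t, dirn, centers_t, method = "constant",
                              rule = 2)$y[use]
    dec_dir <- ifelse(post$direction_P[use, 1L] >= 0.5, 1, -1)
    dir_err <- mean(dec_dir != true_dir)
  }
  list(median_error_cm = stats::median(err), confusion = confusion,
       direction_error = dir_err, n_bins = sum(use))
}
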