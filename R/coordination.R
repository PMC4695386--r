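# Coordination of VTA spikes with replayed spatial content: lagged
# spike-associated bins, reward-site bias, excess bias with chi-square and
# permutation logistic-regression interaction tests, lag sweep, and SWS
# frame statistics.

#' Replay time bins associated with lagged VTA spikes
#'
#' Bin `b` is selected when at least one unit spike falls in
#' `[b.start + lag, b.end + lag)` (half-open); `multiplicity` optionally
#' counts spikes instead of the binary indicator.
#'
#' @param bin_start,bin_end numeric vectors of replay time-bin edges (s).
#' @param vta_spikes unit spike times (s).
#' @param lag fixed delay (s), default 0.084.
#' @param weighted count spikes per bin instead of binary selection.
#' @return list with `selected` (logical per bin) and `count` (spikes per
#'   shifted bin).
#' @export
spike_associated_bins <- function(bin_start, bin_end, vta_spikes,
                                  lag = 0.084, weighted = FALSE) {
  stopifnot(length(bin_start) == length(bin_end), lag >= 0)
  count <- vapply(seq_along(bin_start), function(i)
    sum(vta_spikes >= bin_start[i] + lag & vta_spikes < bin_end[i] + lag),
    numeric(1))
  list(selected = count >= 1L, count = if (weighted) count else pmin(count, 1))
}

#' Reward-site indicator and bias of posterior time bins
#'
#' A bin scores 1 when its mean posterior probability per spatial bin inside
#' the reward regions strictly exceeds the mean outside them (ties score 0);
#' the bias is the mean indicator.
#'
#' @param P T x S posterior matrix (rows normalized).
#' @param reward_mask logical length-S reward-region membership of the
#'   spatial bins.
#' @return list with `indicators` (0/1 per bin) and `bias`.
#' @export
reward_site_bias <- function(P, reward_mask) {
  if (all(reward_mask) || !any(reward_mask))
    stop("reward_site_bias: reward regions must be a strict subset of bins")
  P <- as.matrix(P)
  mr <- rowMeans(P[, reward_mask, drop = FALSE])
  mn <- rowMeans(P[, !reward_mask, drop = FALSE])
  ind <- as.integer(mr > mn)
  list(indicators = ind, bias = mean(ind))
}

#' Excess reward-site bias with chi-square test
#'
#' One-sample proportion test of the spike-associated bins' indicator
#' proportion against the all-replay-bins proportion as a fixed reference
#' (`chi2 = n (p_hat - p0)^2 / (p0 (1 - p0))`, df = 1); a two-sample 2x2
#' variant is available.
#'
#' @param k_unit indicator-1 count among the unit's spike-associated bins.
#' @param n_unit number of spike-associated bins.
#' @param p_ref reference proportion (all replay bins), or for
#'   `type = "two_sample"` a length-2 vector `c(k_ref, n_ref)`.
#' @param type `"one_sample"` (default) or `"two_sample"`.
#' @return list with `excess`, `chi2`, `p`.
#' @export
excess_bias_chi2 <- function(k_unit, n_unit, p_ref,
                             type = c("one_sample", "two_sample")) {
  type <- match.arg(type)
  stopifnot(n_unit > 0)
  p_hat <- k_unit / n_unit
  if (type == "one_sample") {
    p0 <- p_ref[1]
    if (n_unit * min(p0, 1 - p0) < 5)
      warning("excess_bias_chi2: expected count below 5")
    chi2 <- n_unit * (p_hat - p0)^2 / (p0 * (1 - p0))
    list(excess = p_hat - p0, chi2 = chi2,
         p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  } else {
    k2 <- p_ref[1]; n2 <- p_ref[2]
    tab <- rbind(c(k_unit, n_unit - k_unit), c(k2, n2 - k2))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(excess = p_hat - k2 / n2, chi2 = unname(ct$statistic),
         p = ct$p.value)
  }
}

# Saturated logistic-regression interaction coefficient and SE for the
# 2 (group) x 2 (comparison) design in which the reference data A occupies
# the group=0 cell of both comparison strata. MLE = difference of empirical
# log-odds; SE from the inverse Fisher information (sum of 1/(n p q) over
# the four cells). Haldane 0.5 correction guards empty cells. Verified
# against stats::glm in the test suite.
interaction_coef <- function(kB, nB, kC, nC, kA1, nA1, kA0, nA0) {
  lo <- function(k, n) log((k + 0.5) / (n - k + 0.5))
  vterm <- function(k, n) {
    p <- (k + 0.5) / (n + 1)
    1 / (n * p * (1 - p))
  }
  beta <- (lo(kB, nB) - lo(kA1, nA1)) - (lo(kC, nC) - lo(kA0, nA0))
  se <- sqrt(vterm(kB, nB) + vterm(kA1, nA1) + vterm(kC, nC) + vterm(kA0, nA0))
  c(beta = beta, se = se)
}

#' Permutation test of the excess-bias interaction
#'
#' Logistic regression of the reward-site indicator on group (B or C = 1 vs
#' reference A = 0), comparison (B-vs-A = 1, C-vs-A = 0) and their
#' interaction; the interaction coefficient is compared, one-tailed, to a
#' null distribution built by refitting on data whose cell proportions are
#' the overall mean plus independent Gaussian perturbations. The
#' perturbation s.d. is calibrated (bisection, at most 20 rounds) so the
#' simulated interaction coefficients' s.d. matches the observed
#' coefficient's standard error within 10%.
#'
#' @param kA,nA indicator-1 count and total for the reference bins (A).
#' @param kB,nB counts for group B; `kC`,`nC` for group C.
#' @param n_iter permutation iterations (default 1000).
#' @param seed RNG seed.
#' @return list with `p` (one-tailed), `beta_obs`, `se_obs`, `sd_pert`,
#'   `beta_null` (simulated coefficients).
#' @export
permutation_interaction_test <- function(kA, nA, kB, nB, kC, nC,
                                         n_iter = 1000, seed = 1) {
  if (n_iter < 1) stop("permutation_interaction_test: n_iter must be >= 1")
  stopifnot(nA > 0, nB > 0, nC > 0)
  obs <- interaction_coef(kB, nB, kC, nC, kA, nA, kA, nA)
  pbar <- (kA + kB + kC) / (nA + nB + nC)
  ns <- c(nB, nA, nC, nA)
  sim_betas <- function(sd_pert, m, rng_name) {
    with_substream(seed, rng_name, {
      ps <- matrix(pmin(pmax(pbar + stats::rnorm(4 * m, 0, sd_pert),
                             1e-6), 1 - 1e-6), m, 4, byrow = FALSE)
      ks <- matrix(stats::rbinom(4 * m, rep(ns, each = m), as.vector(ps)),
                   m, 4)
      vapply(seq_len(m), function(i)
        interaction_coef(ks[i, 1], nB, ks[i, 3], nC,
                         ks[i, 2], nA, ks[i, 4], nA)[1], numeric(1))
    })
  }
  # calibrate perturbation s.d. so sd(beta_sim) ~ se_obs
  lo <- 0; hi <- max(0.5, 4 * obs["se"])
  sd_pert <- obs["se"] / 2
  for (it in seq_len(20)) {
    s <- stats::sd(sim_betas(sd_pert, 200L, paste0("calib_", it)))
    if (abs(s - obs["se"]) <= 0.1 * obs["se"]) break
    if (s < obs["se"]) lo <- sd_pert else hi <- sd_pert
    sd_pert <- (lo + hi) / 2
  }
  beta_null <- sim_betas(sd_pert, n_iter, "final")
  p <- (1 + sum(beta_null >= obs["beta"])) / (n_iter + 1)
  list(p = p, beta_obs = unname(obs["beta"]), se_obs = unname(obs["se"]),
       sd_pert = unname(sd_pert), beta_null = beta_null)
}

#' Excess reward-site bias as a function of VTA lag
#'
#' Sweeps the spike-association delay over `lags` and reports the excess
#' bias (spike-associated-bin bias minus all-bin bias) at each, with the
#' argmax.
#'
#' @param bin_start,bin_end replay time-bin edges (s).
#' @param indicators 0/1 reward indicators per bin (from
#'   [reward_site_bias()]).
#' @param vta_spikes unit spike times (s).
#' @param lags delays to test (s); default 0 to 200 ms in 25 ms steps.
#' @return data frame with `lag_ms`, `excess`, `n_bins`; attribute
#'   `argmax_ms`.
#' @export
lag_sweep <- function(bin_start, bin_end, indicators, vta_spikes,
                      lags = seq(0, 0.2, by = 0.025)) {
  bias_all <- mean(indicators)
  res <- lapply(lags, function(lg) {
    sel <- spike_associated_bins(bin_start, bin_end, vta_spikes, lag = lg)$selected
    data.frame(lag_ms = 1000 * lg,
               excess = if (any(sel)) mean(indicators[sel]) - bias_all else NA,
               n_bins = sum(sel))
  })
  out <- do.call(rbind, res)
  attr(out, "argmax_ms") <- out$lag_ms[which.max(out$excess)]
  out
}

#' Per-frame statistics and group splits
#'
#' Per frame: duration, SPW-R rate (event midpoints per second), spatial
#' content (mean over 25 ms bins of the maximum decoded probability), and
#' per-unit firing rate. Splits compare each unit's rate across frames
#' above/below the mean SPW-R rate and above/below the mean spatial
#' content, and (inverse split) frame spatial content across frames
#' above/below that unit's mean rate.
#'
#' @param frames `interval_set` of frames.
#' @param frame_posteriors list of `posterior` objects, one per frame
#'   (25 ms bins), or NULL to skip content statistics.
#' @param spwr_events `interval_set` of SPW-R events.
#' @param vta_units list of unit spike-time vectors.
#' @param min_frames minimum frames per split side (default 5).
#' @return list with `frames` (per-frame table), `unit_rates` (frames x
#'   units), and `splits` (per-unit paired differences per split).
#' @export
frame_stats <- function(frames, frame_posteriors, spwr_events, vta_units,
                        min_frames = 5L) {
  nf <- nrow(frames)
  dur <- frames$end - frames$start
  mids <- if (nrow(spwr_events)) spwr_events$start +
    (spwr_events$end - spwr_events$start) / 2 else numeric(0)
  spwr_rate <- vapply(seq_len(nf), function(i)
    sum(mids >= frames$start[i] & mids < frames$end[i]) / dur[i], numeric(1))
  content <- if (!is.null(frame_posteriors))
    vapply(frame_posteriors, function(p) mean(apply(p$P, 1L, max)),
           numeric(1)) else rep(NA_real_, nf)
  unit_rates <- sapply(vta_units, function(st)
    spike_count_in(st, frames$start, frames$end) / dur)
  unit_rates <- matrix(unit_rates, nrow = nf)
  split_diff <- function(split_high) {
    if (sum(split_high) < min_frames || sum(!split_high) < min_frames)
      return(rep(NA_real_, ncol(unit_rates)))
    colMeans(unit_rates[split_high, , drop = FALSE]) -
      colMeans(unit_rates[!split_high, , drop = FALSE])
  }
  splits <- list(
    spwr_rate = split_diff(spwr_rate > mean(spwr_rate)),
    content = if (all(is.na(content))) NULL
    else split_diff(content > mean(content)),
    inverse_by_unit = if (all(is.na(content))) NULL
    else apply(unit_rates, 2L, function(r) {
      hi <- r > mean(r)
      if (sum(hi) < min_frames || sum(!hi) < min_frames) return(NA_real_)
      mean(content[hi]) - mean(content[!hi])
    }))
  list(frames = data.frame(start = frames$start, end = frames$end,
                           duration = dur, spwr_rate = spwr_rate,
                           content = content),
       unit_rates = unit_rates, splits = splits)
}
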