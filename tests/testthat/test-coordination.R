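test_that("spike-associated bins follow the half-open lag convention", {
  bs <- seq(0, 0.975, by = 0.025); be <- bs + 0.025
  # lag 0: a spike inside a bin selects that bin
  sel <- spike_associated_bins(bs, be, vta_spikes = 0.26, lag = 0)
  expect_equal(which(sel$selected), 11L)
  # spike at exactly bin start + 84 ms: half-open boundary rule
  sel2 <- spike_associated_bins(bs, be, vta_spikes = bs[5] + 0.084,
                                lag = 0.084)
  expect_equal(which(sel2$selected), 5L)
  sel3 <- spike_associated_bins(bs, be, vta_spikes = be[5] + 0.084,
                                lag = 0.084)
  expect_equal(which(sel3$selected), 6L)
  # weighted mode counts spikes
  sel4 <- spike_associated_bins(bs, be, c(0.255, 0.26, 0.51), lag = 0,
                                weighted = TRUE)
  expect_equal(sel4$count[11], 2)
})

test_that("independent Poisson spikes leave the selected-bin bias unbiased", {
  set.seed(31)
  n <- 4000
  bs <- (0:(n - 1)) * 0.025; be <- bs + 0.025
  ind <- rbinom(n, 1, 0.45)
  spikes <- sort(runif(2000, 0, n * 0.025))
  sel <- spike_associated_bins(bs, be, spikes, lag = 0.084)$selected
  se <- sqrt(0.45 * 0.55 / sum(sel))
  expect_lt(abs(mean(ind[sel]) - mean(ind)), 2.5 * se)
})

test_that("reward-site indicators follow the strict mean-comparison rule", {
  rw <- c(TRUE, FALSE, FALSE)
  r <- reward_site_bias(rbind(c(0.5, 0.3, 0.2)), rw)
  expect_equal(r$indicators, 1L)         # 0.5 > 0.25
  # uniform row: tie broken to 0 ("exceeded" is strict)
  expect_equal(reward_site_bias(rbind(rep(1 / 3, 3)), rw)$indicators, 0L)
  # bias is the mean indicator
  P <- matrix(1 / 3, 10, 3)
  P[1:6, 1] <- 0.6; P[1:6, 2:3] <- 0.2
  expect_equal(reward_site_bias(P, rw)$bias, 0.6)
  expect_error(reward_site_bias(P, c(TRUE, TRUE, TRUE)), "strict subset")
})

test_that("one-sample chi-square matches hand arithmetic and is calibrated", {
  r <- suppressWarnings(excess_bias_chi2(4, 5, 6 / 10))
  expect_equal(r$excess, 0.2)
  expect_equal(r$chi2, 5 * 0.2^2 / 0.24, tolerance = 1e-12)
  expect_equal(suppressWarnings(excess_bias_chi2(6, 10, 0.6))$chi2, 0)
  # null calibration: unit bins subsampled from all bins -> uniform p
  ps <- with_substream(32, "chi2", {
    vapply(1:500, function(i) {
      ind <- rbinom(2000, 1, 0.45)
      sel <- sample(2000, 400)
      excess_bias_chi2(sum(ind[sel]), 400, mean(ind))$p
    }, numeric(1))
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_warning(excess_bias_chi2(1, 4, 0.5), "below 5")
})

test_that("closed-form interaction coefficient matches the glm fit", {
  kA <- 450; nA <- 1000; kB <- 300; nB <- 600; kC <- 200; nC <- 500
  cf <- replayvta:::interaction_coef(kB, nB, kC, nC, kA, nA, kA, nA)
  mk <- function(k, n, g, cmp) data.frame(
    y = rep(c(1, 0), c(k, n - k)), g = g, cmp = cmp)
  dat <- rbind(mk(kA, nA, 0, 1), mk(kB, nB, 1, 1),
               mk(kA, nA, 0, 0), mk(kC, nC, 1, 0))
  fit <- glm(y ~ g * cmp, binomial, dat)
  expect_equal(unname(cf["beta"]), unname(coef(fit)["g:cmp"]),
               tolerance = 0.01)
  expect_equal(unname(cf["se"]),
               unname(sqrt(diag(vcov(fit)))["g:cmp"]), tolerance = 0.01)
})

test_that("permutation interaction test is calibrated under the null", {
  rej <- with_substream(33, "permnull", {
    vapply(1:200, function(i) {
      nA <- 2000; nB <- 800; nC <- 800
      p0 <- 0.45
      res <- permutation_interaction_test(rbinom(1, nA, p0), nA,
                                          rbinom(1, nB, p0), nB,
                                          rbinom(1, nC, p0), nC,
                                          n_iter = 400, seed = i)
      res$p < 0.05
    }, logical(1))
  })
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.1)
  expect_error(permutation_interaction_test(1, 10, 1, 10, 1, 10, n_iter = 0),
               "n_iter")
})

test_that("permutation interaction test detects an injected excess", {
  hits <- vapply(1:20, function(i) {
    set.seed(1000 + i)
    nA <- 4000; nB <- 2000; nC <- 2000
    kA <- rbinom(1, nA, 0.45)
    kB <- rbinom(1, nB, 0.53)     # +0.08 excess in B only
    kC <- rbinom(1, nC, 0.45)
    permutation_interaction_test(kA, nA, kB, nB, kC, nC,
                                 n_iter = 400, seed = i)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("lag sweep recovers the injected coupling delay", {
  set.seed(34)
  n <- 6000
  bs <- (0:(n - 1)) * 0.1; be <- bs + 0.025   # sparse bins, no overlap
  ind <- rbinom(n, 1, 0.4)
  # spikes preferentially 84 ms after reward-indicating bins
  src <- which(ind == 1)
  spikes <- sort(c(bs[sample(src, 2500, TRUE)] + 0.084 + runif(2500, 0, 0.02),
                   runif(1500, 0, max(be))))
  sw <- lag_sweep(bs, be, ind, spikes)
  expect_equal(attr(sw, "argmax_ms"), 75)
  # coupling at zero lag peaks at zero
  spikes0 <- sort(c(bs[sample(src, 2500, TRUE)] + runif(2500, 0, 0.02),
                    runif(1500, 0, max(be))))
  expect_equal(attr(lag_sweep(bs, be, ind, spikes0), "argmax_ms"), 0)
  # no coupling: flat curve within noise
  sp_u <- sort(runif(3000, 0, max(be)))
  sw_u <- lag_sweep(bs, be, ind, sp_u)
  se <- sqrt(0.4 * 0.6 / min(sw_u$n_bins))
  expect_lt(max(abs(sw_u$excess)), 3 * se)
})

test_that("frame statistics compute content, rates and splits", {
  fr <- interval_set(seq(0, 90, by = 10), seq(4, 94, by = 10), kind = "frame")
  tr <- make_track("linear", 200)
  # uniform posteriors: spatial content exactly 1/S
  posts <- lapply(1:10, function(i)
    toy_posterior(matrix(1 / 20, 8, 20), tr, t0 = fr$start[i]))
  ev <- interval_set(c(1, 11, 12, 21, 31, 41),
                     c(1, 11, 12, 21, 31, 41) + 0.1, "spwr")
  units <- list(sort(runif(500, 0, 94)), sort(runif(300, 0, 94)))
  fs <- frame_stats(fr, posts, ev, units)
  expect_true(all(abs(fs$frames$content - 1 / 20) < 1e-12))
  expect_equal(fs$frames$spwr_rate[1:3], c(0.25, 0.5, 0.25))
  expect_equal(dim(fs$unit_rates), c(10L, 2L))
  # rate independent of frames: split difference small
  expect_lt(abs(fs$splits$spwr_rate[1]), 3)
  # fewer than 5 frames per side: comparison skipped
  fr2 <- fr[1:6, ]; class(fr2) <- class(fr)
  fs2 <- frame_stats(fr2, posts[1:6], ev, units)
  expect_true(all(is.na(fs2$splits$spwr_rate)))
})
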