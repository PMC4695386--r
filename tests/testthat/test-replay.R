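lin100 <- function() fixture("lin100", function() make_track("linear", 100))

test_that("a perfect-line posterior scores R = 1 at the injected speed", {
  tr <- lin100()
  v <- 500; s0 <- 15
  tc <- (0:7) * 0.025 + 0.0125
  P <- matrix(0, 8, 10)
  for (t in 1:8) {
    pos <- s0 + v * (tc[t] - tc[1])
    P[t, pmin(pmax(floor(pos / 10) + 1, 1), 10)] <- 1
  }
  post <- toy_posterior(P, tr)
  fit <- fit_trajectory(post, tr)[[1]]
  expect_equal(fit$R, 1)
  expect_lte(abs(fit$speed - v), 25)   # one grid step
})

test_that("uniform rows give the band-counting score for a flat mid-track line", {
  tr <- lin100()
  post <- toy_posterior(matrix(0.1, 10, 10), tr)
  # flat trajectory at a mid-track bin center: the 15 cm band holds 3 bins
  expect_equal(replay_score(post, tr, 1, speed = 0, intercept = 45), 0.3)
})

test_that("grid scores match exhaustive enumeration on a 2-bin toy", {
  tr <- fixture("lin40", function() make_track("linear", 40))
  P <- rbind(c(0.4, 0.3, 0.2, 0.1), c(0.1, 0.3, 0.2, 0.4))
  post <- toy_posterior(P, tr)
  centers <- track_bins(tr)$center
  grid <- trajectory_grid(40, 10)
  best_R <- -1
  for (v in grid$speeds) for (ic in grid$intercepts) {
    pos <- round(ic + v * c(0, 0.025))        # 1 cm trajectory grid
    R <- mean(vapply(1:2, function(t)
      sum(P[t, abs(centers - pos[t]) <= 15]), numeric(1)))
    expect_equal(replay_score(post, tr, 1, v, ic), R, tolerance = 1e-12)
    best_R <- max(best_R, R)
  }
  expect_equal(fit_trajectory(post, tr)[[1]]$R, best_R, tolerance = 1e-12)
})

test_that("replay score is invariant under time reversal with flipped speed", {
  dec <- small_decoded()
  idx <- which(dec$keep)[1:5]
  for (i in idx) {
    p <- dec$posts[[i]]
    fit <- fit_trajectory(p, dec$ses$track)[[1]]
    Tn <- nrow(p$P)
    endpos <- fit$intercept + fit$speed * (Tn - 1) * 0.025
    rev_post <- posterior(p$P[Tn:1, ], p$time_edges, p$space)
    expect_equal(replay_score(rev_post, dec$ses$track, 1, -fit$speed, endpos),
                 fit$R, tolerance = 1e-12)
  }
})

test_that("column-cycle shuffle is exact for uniform rows and matches enumeration", {
  tr <- lin100()
  post_u <- toy_posterior(matrix(0.1, 6, 10), tr)
  cc <- column_cycle_shuffle(post_u, tr, 1, n = 200, seed = 1)
  expect_true(all(abs(cc$scores - cc$R_obs) < 1e-12))
  expect_equal(cc$p, 1)
  # T = 2, S = 3: Monte Carlo p converges to the full 9-shift enumeration
  tr3 <- fixture("lin30", function() make_track("linear", 30))
  P <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.2, 0.7))
  post <- toy_posterior(P, tr3)
  obs <- fit_trajectory(post, tr3)[[1]]$R
  scores_enum <- c()
  for (k1 in 0:2) for (k2 in 0:2) {
    Ps <- rbind(P[1, ((0:2 - k1) %% 3) + 1], P[2, ((0:2 - k2) %% 3) + 1])
    scores_enum <- c(scores_enum,
                     fit_trajectory(toy_posterior(Ps, tr3), tr3)[[1]]$R)
  }
  p_enum <- mean(scores_enum >= obs - 1e-12)
  cc2 <- column_cycle_shuffle(post, tr3, 1, n = 5000, seed = 2)
  expect_equal(cc2$p, p_enum, tolerance = 0.02)
})

test_that("pseudo-event shuffle handles degenerate pools and location bias", {
  tr <- lin100()
  # all pool rows identical: every shuffle score identical
  row <- c(0.5, 0.2, 0.1, 0.05, 0.05, 0.02, 0.02, 0.02, 0.02, 0.02)
  pool <- matrix(rep(row, 120), 120, byrow = TRUE)
  post <- toy_posterior(matrix(rep(row, 4), 4, byrow = TRUE), tr)
  ps <- pseudo_event_shuffle(post, pool, tr, 1, n = 300, seed = 3)
  expect_equal(length(unique(round(ps$scores, 12))), 1L)
  expect_true(ps$p %in% c(1 / 301, 1))
  # a temporally constant, reward-site-concentrated event is NOT
  # significant under this shuffle when the pool shares the bias
  expect_gt(ps$p, 0.2)
  expect_error(pseudo_event_shuffle(post, pool[1:20, ], tr, 1), "pool")
})

test_that("classification applies the two-shuffle rule", {
  dec <- small_decoded()
  tr <- dec$ses$track
  # a decoded true-replay event classifies as replay
  idx_r <- which(dec$keep &
                   vapply(seq_len(nrow(dec$events)), function(i)
                     isTRUE(truth_label(dec$events, dec$ses$hc$truth$events, i)),
                     logical(1)))
  cl <- classify_replay(dec$posts[[idx_r[1]]], dec$pool, tr,
                        n_shuffles = 250, seed = 9)
  expect_equal(cl$label, "replay")
  expect_lt(cl$best$p_column, 0.05)
  expect_lt(cl$best$p_pseudo, 0.05)
  # uniform rows: both p-values 1 on every path -> nonreplay enriched
  post_u <- toy_posterior(matrix(0.1, 6, 10), lin100())
  pool_u <- matrix(0.1, 200, 10)
  cl_u <- classify_replay(post_u, pool_u, lin100(), n_shuffles = 250,
                          seed = 10)
  expect_equal(cl_u$label, "nonreplay_enriched")
  # too few bins is ambiguous by construction
  post2 <- toy_posterior(matrix(0.1, 2, 10), lin100())
  expect_equal(classify_replay(post2, pool_u, lin100())$label, "ambiguous")
  # stringent mode shuffles only the best path and still flags replay
  cl_s <- classify_replay(dec$posts[[idx_r[1]]], dec$pool, tr,
                          n_shuffles = 250, seed = 9, mode = "stringent")
  expect_equal(cl_s$label, "replay")
  expect_length(cl_s$paths, 1L)
})

test_that("direction/geometry labels follow the fitted motion and animal position", {
  tr <- fixture("lin200", function() make_track("linear", 200))
  mk_dir <- function(d, n) {
    dp <- matrix(0.05, n, 2); dp[, if (d > 0) 1 else 2] <- 0.95
    dp
  }
  # animal at 190 cm, fit moving 180 -> 140, decoded direction inbound:
  # away from the animal (centrifugal) and forward (inbound propagation)
  P <- matrix(1 / 20, 5, 20)
  post <- toy_posterior(P, tr, direction_P = mk_dir(-1, 5))
  fit <- list(path_id = 1, speed = (140 - 180) / 0.1, intercept = 180)
  lab <- label_bin_geometry(post, fit, animal_pos = 190, track = tr)
  expect_true(all(lab$di < -0.5))
  expect_true(all(lab$geometry == "centrifugal"))
  expect_true(all(lab$order == "forward"))
  # animal at 0 cm, fit moving 100 -> 40, decoded outbound:
  # approaching the animal (centripetal) and reverse
  post2 <- toy_posterior(P, tr, direction_P = mk_dir(+1, 5))
  fit2 <- list(path_id = 1, speed = (40 - 100) / 0.1, intercept = 100)
  lab2 <- label_bin_geometry(post2, fit2, animal_pos = 0, track = tr)
  expect_true(all(lab2$geometry == "centripetal"))
  expect_true(all(lab2$order == "reverse"))
  # DI formula and the threshold rule
  dp <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  post3 <- toy_posterior(matrix(1 / 20, 2, 20), tr, direction_P = dp)
  lab3 <- label_bin_geometry(post3, fit, 190, tr)
  expect_equal(lab3$di, c(0.8, 0.2))
  expect_true(is.na(lab3$order[2]))     # |DI| <= 0.5 unlabeled
})

test_that("event matching equalizes covariates within a caliper", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  m <- match_events(c(a, rnorm(20, 2.5, 0.1)), c(b, rnorm(20, 2.5, 0.1)),
                    caliper = 0.5, seed = 1)
  expect_gte(length(m$idx_a), 10)
  expect_gt(m$p, 0.2)
  # log-normal vs shifted log-normal durations match after tightening
  x <- with_substream(11, "match", exp(rnorm(150, log(0.16), 0.3)))
  y <- with_substream(12, "match", exp(rnorm(150, log(0.21), 0.3)))
  m2 <- match_events(x, y, seed = 2)
  expect_gt(suppressWarnings(wilcox.test(x[m2$idx_a], y[m2$idx_b]))$p.value,
            0.2)
  expect_error(match_events(1:20, 1:20 + 100, caliper = 1), "pairs")
})
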