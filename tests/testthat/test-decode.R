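# Construct a tiny controlled encoding scenario: a few "cells" with fixed
# positions and marks, position samples visiting the whole track.
tiny_encoding <- function(n_rep = 60, track = make_track("linear", 60),
                          cells = data.frame(
                            pos = c(10, 30, 50),
                            tet = c(1L, 1L, 2L),
                            m = c(150, 280, 200))) {
  pos_t <- seq(0, 59.9, by = 0.1)
  pos_lin <- rep(seq(1, 59, length.out = 120), length.out = length(pos_t))
  speed <- rep(20, length(pos_t))
  sp <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
    tt <- pos_t[abs(pos_lin - cells$pos[ci]) < 4][seq_len(n_rep)] + 0.01
    data.frame(time = tt, tetrode = cells$tet[ci],
               m1 = cells$m[ci], m2 = cells$m[ci], m3 = cells$m[ci],
               m4 = cells$m[ci], width = 5e-4)
  }))
  list(spikes = sp, pos_t = pos_t, pos_lin = pos_lin, speed = speed,
       track = track, cells = cells)
}

test_that("clusterless posterior equals a hand-computed Bayes rule", {
  te <- tiny_encoding()
  model <- fit_encoding(te$spikes, te$pos_t, te$pos_lin, te$speed, te$track,
                        min_spikes = 10)
  # decode two bins: one spike with cell-2 mark, one with cell-3 mark
  qs <- data.frame(time = c(100.01, 100.6), tetrode = c(1L, 2L),
                   m1 = c(280, 200), m2 = c(280, 200), m3 = c(280, 200),
                   m4 = c(280, 200), width = 5e-4)
  edges <- c(100, 100.5, 101)
  post <- decode(model, qs, edges)
  # independent Bayes computation from the same kernel definitions
  bins <- track_bins(te$track)
  manual_row <- function(spk_row, dt) {
    logL <- rep(0, nrow(bins))
    for (m in model$tetrodes) {
      lam_tot <- m$lambda_x
      if (spk_row$tetrode == m$tetrode) {
        km <- exp(-colSums((t(m$marks) -
                              as.numeric(spk_row[c("m1", "m2", "m3", "m4")]))^2) /
                    (2 * model$bw_mark^2))
        lam <- as.numeric(km %*% m$Kpos) / model$occupancy
        logL <- logL + log(pmax(lam, 1e-300))
      }
      logL <- logL - dt * lam_tot
    }
    p <- exp(logL - max(logL)); p / sum(p)
  }
  expect_equal(post$P[1, ], manual_row(qs[1, ], 0.5), tolerance = 1e-12)
  expect_equal(post$P[2, ], manual_row(qs[2, ], 0.5), tolerance = 1e-12)
  # MAP at the encoding field of the matching cell
  expect_equal(bins$center[which.max(post$P[1, ])], 30, tolerance = 5)
  expect_equal(bins$center[which.max(post$P[2, ])], 50, tolerance = 5)
})

test_that("bins without spikes decode to exactly uniform rows", {
  te <- tiny_encoding()
  model <- fit_encoding(te$spikes, te$pos_t, te$pos_lin, te$speed, te$track,
                        min_spikes = 10)
  post <- decode(model, te$spikes[0, ], c(0, 0.025, 0.05))
  S <- nrow(track_bins(te$track))
  expect_true(all(post$P == 1 / S))
  # hence no reward-site preference in the absence of activity
  rw <- track_bins(te$track)$reward
  expect_equal(rowMeans(post$P[, rw, drop = FALSE]),
               rowMeans(post$P[, !rw, drop = FALSE]))
  expect_true(all(post$direction_P == 0.5))
})

test_that("decoding is invariant to spike order within a bin", {
  te <- tiny_encoding()
  model <- fit_encoding(te$spikes, te$pos_t, te$pos_lin, te$speed, te$track,
                        min_spikes = 10)
  qs <- data.frame(time = c(100.1, 100.2, 100.3), tetrode = 1L,
                   m1 = c(150, 280, 150), m2 = c(150, 280, 150),
                   m3 = c(150, 280, 150), m4 = c(150, 280, 150),
                   width = 5e-4)
  p1 <- decode(model, qs, c(100, 100.5))
  p2 <- decode(model, qs[c(3, 1, 2), ], c(100, 100.5))
  expect_equal(p1$P, p2$P, tolerance = 1e-12)
})

test_that("doubling the encoding data leaves the normalized model unchanged", {
  te <- tiny_encoding()
  m1 <- fit_encoding(te$spikes, te$pos_t, te$pos_lin, te$speed, te$track,
                     min_spikes = 10)
  shift <- 1000
  sp2 <- rbind(te$spikes, transform(te$spikes, time = time + shift))
  m2 <- fit_encoding(sp2, c(te$pos_t, te$pos_t + shift),
                     rep(te$pos_lin, 2), rep(te$speed, 2), te$track,
                     min_spikes = 10)
  qs <- data.frame(time = 100.1, tetrode = 1L, m1 = 280, m2 = 280,
                   m3 = 280, m4 = 280, width = 5e-4)
  expect_equal(decode(m1, qs, c(100, 100.5))$P,
               decode(m2, qs, c(100, 100.5))$P, tolerance = 1e-9)
})

test_that("sorted decoding matches exhaustive enumeration on a 5-cell toy", {
  track <- make_track("linear", 40)   # 4 bins
  curves <- matrix(c(8, 1, 1, 1,
                     1, 8, 1, 1,
                     1, 1, 8, 1,
                     1, 1, 1, 8,
                     2, 2, 2, 2), nrow = 4)
  counts <- rbind(c(2, 0, 0, 1, 1), c(0, 0, 3, 0, 0), c(0, 0, 0, 0, 0))
  edges <- c(0, 0.5, 1, 1.5)
  post <- decode_sorted(curves, counts, edges, track_bins(track))
  for (t in 1:2) {
    lik <- vapply(1:4, function(s)
      prod(curves[s, ]^counts[t, ]) * exp(-0.5 * sum(curves[s, ])),
      numeric(1))
    expect_equal(post$P[t, ], lik / sum(lik), tolerance = 1e-12)
  }
  expect_equal(post$P[3, ], rep(0.25, 4))   # empty bin
  # uniform tuning curves give a uniform posterior regardless of counts
  pu <- decode_sorted(matrix(3, 4, 5), counts, edges, track_bins(track))
  expect_true(all(abs(pu$P - 0.25) < 1e-12))
  # delta-like tuning: single spike of the matching cell -> MAP at its bin
  delta <- matrix(1e-6, 4, 1); delta[3, 1] <- 10
  pd <- decode_sorted(delta, matrix(c(1), 1, 1), c(0, 0.025),
                      track_bins(track))
  expect_equal(which.max(pd$P[1, ]), 3L)
})

test_that("cross-validated clusterless decoding recovers position and direction", {
  ses <- small_session()
  cv <- cross_validate(ses, "clusterless")
  expect_lte(cv$median_error_cm, 10)
  expect_lte(cv$direction_error, 0.3)
  expect_equal(sum(cv$confusion), cv$n_bins)
  # confusion mass concentrates near the diagonal
  S <- nrow(cv$confusion)
  diag_mass <- sum(cv$confusion[abs(row(cv$confusion) - col(cv$confusion)) <= 1])
  expect_gt(diag_mass / cv$n_bins, 0.7)
})

test_that("clusterless beats amplitude-cluster sorting when marks overlap", {
  ses <- fixture("overlap_session", function() {
    simulate_session(sim_config(seed = 31, n_trials = 12, n_tetrodes = 2,
                                mark_min_sep_uv = 5, mark_sd_uv = 25))
  })
  cv_cl <- cross_validate(ses, "clusterless")
  # sorted units from k-means on the overlapping marks (what a
  # cluster-based pipeline would have to work with)
  sp <- mark_filter(ses$hc$spikes)
  k <- table(ses$hc$cells$tetrode)
  ses2 <- ses
  ses2$hc$unit_spikes <- sort_spikes_kmeans(sp, as.integer(k), seed = 1)
  cv_so <- cross_validate(ses2, "sorted")
  expect_lte(cv_cl$median_error_cm, cv_so$median_error_cm)
})
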