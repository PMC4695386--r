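# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small default linear session (fast; used by several module tests)
small_session <- function() {
  fixture("small_session", function() {
    simulate_session(sim_config(seed = 42, n_trials = 10))
  })
}

# encoding model + detected events + per-event posteriors for the small
# session
small_decoded <- function() {
  fixture("small_decoded", function() {
    ses <- small_session()
    beh <- ses$behavior
    sp <- mark_filter(ses$hc$spikes)
    model <- fit_encoding(sp, beh$t, beh$pos, beh$speed, ses$track)
    mua <- compute_mua(ses$hc$spikes$time, beh$span,
                       n_tetrodes = length(unique(ses$hc$spikes$tetrode)))
    events <- detect_spwr(mua, approxfun(beh$t, beh$speed, rule = 2))
    posts <- decode_events(model, sp, events)
    keep <- !vapply(posts, is.null, logical(1))
    pool <- do.call(rbind, lapply(posts[keep], function(p) p$P))
    list(ses = ses, model = model, mua = mua, events = events,
         posts = posts, keep = keep, pool = pool)
  })
}

# toy posterior helper: rows given as a matrix over a linear track
toy_posterior <- function(P, track, bin_s = 0.025, t0 = 0,
                          direction_P = NULL) {
  posterior(P, time_edges = t0 + (0:nrow(P)) * bin_s,
            space = track_bins(track), direction_P = direction_P)
}

# truth label of a detected event by midpoint containment
truth_label <- function(events, truth, i) {
  mid <- events$start[i] + (events$end[i] - events$start[i]) / 2
  j <- which(truth$start <= mid & truth$end > mid)
  if (length(j)) truth$replay[j[1]] else NA
}
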