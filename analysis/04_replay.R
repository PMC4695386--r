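#!/usr/bin/env Rscript
# Replay detection on the detected SPW-R events: decode each event in
# 25 ms bins, fit constant-speed trajectories, run the column-cycle and
# pseudo-event shuffles (250 Monte Carlo samples here; 1500 in the full
# configuration) and classify replay / nonreplay-enriched / ambiguous.

library(replayvta)

ses <- read_session("scratch/session")
beh <- ses$behavior
ses$cfg <- list(seed = 20260919)

sp <- mark_filter(ses$hc$spikes)
model <- fit_encoding(sp, beh$t, beh$pos, beh$speed, ses$track)
ev_tab <- read.table("results/spwr_events.tsv", header = TRUE, sep = "\t")
events <- interval_set(ev_tab$start, ev_tab$end, kind = "spwr")

scored <- score_session_events(ses, model, events, analysis_config(),
                               n_shuffles = 250)
tab <- scored$table

truth <- ses$truth$events
mid <- events$start + (events$end - events$start) / 2
truth_replay <- vapply(mid, function(m) {
  j <- which(truth$start <= m & truth$end > m)
  if (length(j)) truth$replay[j[1]] else NA
}, logical(1))

cat(sprintf("%d/%d events classified replay (%.1f%%)\n",
            sum(tab$label == "replay"), nrow(tab),
            100 * mean(tab$label == "replay")))
ok <- !is.na(truth_replay)
cat(sprintf("sensitivity on true replay: %.1f%%; false replay rate: %.1f%%\n",
            100 * mean(tab$label[ok & truth_replay] == "replay"),
            100 * mean(tab$label[ok & !truth_replay] == "replay")))
cat(sprintf("fitted |speed| of replay events: median %.0f cm/s\n",
            median(abs(tab$speed[tab$label == "replay"]), na.rm = TRUE)))

tab$truth_replay <- truth_replay
write.table(tab, "results/replay_events.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("wrote results/replay_events.tsv\n")
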