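#!/usr/bin/env Rscript
# Generate the study's synthetic session: linear-track behavior with
# self-paced reward dwells, theta-modulated place cells with amplitude
# marks, SPW-R bursts carrying replay trajectories, and VTA units with
# reward responses, event-locked gain and theta locking. Writes the
# session files and the ground-truth sidecars under scratch/session/.

library(replayvta)

cfg <- sim_config(seed = 20260919)
ses <- simulate_session(cfg)
write_session(ses, "scratch/session")

tr <- ses$hc$truth$events
cat(sprintf("session span: %.0f s, %d trials\n",
            diff(ses$behavior$span), nrow(ses$behavior$trials)))
cat(sprintf("hippocampal spikes: %d on %d tetrodes; %d place cells\n",
            nrow(ses$hc$spikes), length(unique(ses$hc$spikes$tetrode)),
            nrow(ses$hc$cells)))
cat(sprintf("SPW-R events: %d (%d carrying replay, %.0f%%)\n",
            nrow(tr), sum(tr$replay), 100 * mean(tr$replay)))
cat(sprintf("VTA units: %d (%d reward responsive)\n",
            length(ses$vta$units),
            sum(ses$vta$truth$class == "RR")))
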