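#!/usr/bin/env Rscript
# Characterize the VTA units: reward responsiveness (correct vs error
# trials), waveform duration and trough-to-peak ratio, SPW-R PETH
# modulation depth with bootstrap significance, and theta phase locking
# (Rayleigh test, von Mises mu/kappa).

library(replayvta)

ses <- read_session("scratch/session")
beh <- ses$behavior
ev_tab <- read.table("results/spwr_events.tsv", header = TRUE, sep = "\t")
events <- interval_set(ev_tab$start, ev_tab$end, kind = "spwr")

theta <- bandpass(ses$hc$lfp, c(4, 12))
run_fn <- function(t) approx(beh$t, beh$speed, t, rule = 2)$y > 10
# waveforms are not persisted by the session files; re-derive from truth
cfg <- sim_config(seed = 20260919)
full <- simulate_session(cfg)

prof <- do.call(rbind, lapply(seq_along(ses$vta$units), function(u)
  cbind(unit = u,
        vta_unit_profile(ses$vta$units[[u]], full$vta$waveforms[[u]],
                         beh$trials, "linear", beh$span, events, theta,
                         run_fn, seed = substream_seed(20260919,
                                                       paste0("boot_", u))),
        true_class = ses$truth$units$class[u])))

cat(sprintf("%d units: %d RR, %d nonRR, %d unclassified\n",
            nrow(prof), sum(prof$class == "RR"), sum(prof$class == "nonRR"),
            sum(prof$class == "unclassified")))
cat(sprintf("agreement with generator truth: %.0f%%\n",
            100 * mean(prof$class == prof$true_class)))
cat(sprintf("significant SPW-R modulation: %d units; depths %s\n",
            sum(prof$significant, na.rm = TRUE),
            paste(round(prof$depth, 2), collapse = ", ")))
cat(sprintf("theta-locked (Rayleigh p < 0.05): %d; kappa %s\n",
            sum(prof$rayleigh_p < 0.05, na.rm = TRUE),
            paste(round(prof$kappa, 2), collapse = ", ")))

write.table(prof, "results/vta_units.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("wrote results/vta_units.tsv\n")
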