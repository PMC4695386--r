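---
title: "Methods: hippocampal replay decoding and VTA coordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hippocampal replay decoding and VTA coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(replayvta)
```

# Scope

`replayvta` implements an analysis chain for simultaneous hippocampal and
ventral tegmental area (VTA) tetrode recordings on appetitive spatial
tasks: detection of sharp wave-ripple (SPW-R) multiunit events, clusterless
Bayesian reconstruction of position and run direction, shuffle-based replay
classification, VTA unit characterization, reward-site-bias statistics
relating VTA spikes to replayed content, and slow-wave-sleep (SWS) frame
analysis. A synthetic session generator with exported ground truth defines
the conditions under which every stage is validated; no real recordings
ship with the package.

# The models and procedures

## SPW-R event detection

Pooled hippocampal spikes are binned at 10 ms, expressed as a rate per
tetrode, and smoothed with a 10 ms Gaussian. Events are bursts whose peak
exceeds the trace mean by 4 standard deviations, with the peak restricted
to times when running speed is below 10 cm/s. Boundaries are the nearest
crossings of the mean on each side of the peak; touching intervals merge,
and events shorter than 50 ms (two decoding bins) are dropped. Whether the
rate is smoothed before thresholding is configurable; the 10 ms default
matches the smoothing used for hippocampal peri-event histograms. "Ripple
power" per event is summarized as the maximum of the Hilbert envelope of
the 100-300 Hz band inside the event, standardized against the envelope
over non-event, low-speed samples; the maximum (rather than the mean) is a
package choice, isolated in `ripple_power_z()`.

## Clusterless reconstruction

Decoding uses unsorted spikes jointly with their four-channel peak
amplitudes ("marks"; putative pyramidal spikes only: peak above 100 uV,
width above 300 us). Per tetrode, encoding run epochs (speed over 10 cm/s)
define a Gaussian kernel density over (linear position, 4-D mark) with
bandwidths of 6 cm and 15 uV per channel — roughly the spatial bin scale
and the within-cell mark scatter — plus an occupancy estimate floored at
1e-3 of uniform. Position kernels use the along-track graph distance, so
arms of the maze that adjoin in the linearization but not in space do not
leak into each other.

For a time bin, the log likelihood over position sums, per in-bin spike,
the log generalized firing rate at that spike's mark, and subtracts the
Poisson no-spike factor `dt * Lambda(x)`; tetrodes multiply. A uniform
spatial prior is used throughout. Bins without spikes return exactly
uniform rows — this is the stated fallback and doubles as a decoder-bias
control: with no activity the reconstruction cannot prefer reward sites. A
`likelihood = "conditional"` switch drops the no-spike factor and decodes
from per-spike conditional densities alone; the full-intensity form is the
default. Run direction is reconstructed independently from per-direction
mark densities, giving a two-class posterior per bin.

Cross-validation alternates 1 s training and testing blocks over run
epochs, decodes test blocks in 500 ms bins, and reports the median
along-track distance between the MAP bin center and the true position,
plus a confusion matrix and the direction 0/1 error. Sorted decoding
(Poisson population decoding over occupancy-normalized tuning curves,
place cells with peak rate over 3 Hz) is provided for comparison;
`sort_spikes_kmeans()` emulates amplitude-space cluster sorting so the
comparison reflects what a cluster-based pipeline could actually recover,
not ground-truth unit identities.

## Replay detection

Candidate events are decoded in non-overlapping 25 ms bins laid on the
absolute 25 ms grid of the session clock. A constant-speed trajectory is
fitted per candidate path by grid search — signed speeds 0.5 to 15 m/s in
0.25 m/s steps, intercepts at the spatial bin centers, trajectory
positions evaluated on a 1 cm grid — maximizing the replay score: the mean
posterior mass within 15 cm (along-track) of the trajectory. Two Monte
Carlo nulls are built per path: the column-cycle shuffle circularly shifts
each bin's position PDF by an independent random distance (destroying
linear alignment while keeping per-bin content), and the pseudo-event
shuffle rebuilds the event from PDFs drawn at random from the session's
pooled candidate bins (destroying event identity while keeping the
session's location bias). P-values use the `(1 + k) / (n + 1)` rule, so
they are valid and never zero. An event is replay when both p-values fall
below 0.05 on at least one path, nonreplay-enriched when both exceed 0.2
on every path, otherwise ambiguous; events shorter than three bins are
ambiguous by construction. The stringent variant runs the shuffles only on
the best-scoring path. In standard mode all paths are shuffled and
significance is required on the same path — whether the path is selected
before or after shuffling is not prescribed anywhere we could find, and
this choice is the more conservative.

Per-bin direction indices `DI = (O - I) / (O + I)` come from the direction
posterior; bins with `|DI|` above 0.5 are labeled. A bin is centrifugal
when the along-track distance between the fitted trajectory position and
the animal increases through it, centripetal when it decreases; forward
when the decoded running direction matches the propagation direction of
the fit, reverse when opposite. This generalizes the force-site shorthand
(outbound content of an away-moving event is forward replay) and
reproduces it in the test suite's worked cases.

## VTA unit characterization

Reward responsiveness on the choice task compares firing on correct versus
error trials in the approach (2 s before nosepoke) and acquisition (3 s
after) windows with two-sided t-tests at 0.05; on the linear track (or
when a session lacks error trials) acquisition is compared against a 3 s
baseline ending 2 s before the nosepoke. Units below 0.3 Hz are
unclassified. Waveform duration is the time from the major to the final
positive peak; the trough-to-peak ratio is `trough / (peak + trough)` on
absolute amplitudes.

Event-aligned PETHs use 10 ms bins smoothed with a 50 ms Gaussian.
Modulation depth is the baseline-normalized difference between the PETH at
the event midpoint and the mean over a 300 ms baseline ending 100 ms
before onset (a 5 s baseline ending 1 s before is available as an option).
Because event lengths vary, "the midpoint" is the median midpoint lag
across events, and the depth is read from the smoothed PETH. Significance
bootstraps the event-aligned raster: event rows are resampled with
replacement and the 50 ms midpoint-bin rate is compared with the baseline
rate at the 0.05 level via the bootstrap confidence interval of their
paired difference. The paired-difference form is a deliberate calibration
choice: requiring the two marginal 95% intervals not to overlap tests far
below the nominal level (empirically under 1% false positives), whereas
the paired interval sits in the expected 2-8% band; both marginal
intervals are still returned for inspection.

Theta phases are interpolated Hilbert angles of the 4-12 Hz band, with 0
degrees at the theta peak and preferred phase reported in [-180, 180).
Rayleigh's test (large-sample approximation) tests uniformity; (mu, kappa)
are von Mises maximum-likelihood estimates, with kappa by Best-Fisher
inversion refined by Newton steps on the exact Bessel ratio and capped at
50 for degenerate samples. These circular primitives are implemented in
the package because no installed library provides them.

## VTA-replay coordination

Each 25 ms replay bin gets a reward-site indicator: 1 when the mean
posterior probability per spatial bin inside the reward regions (10 cm
around each well, configurable, with an option to mask the animal's
current location) strictly exceeds the mean outside. Averaging per spatial
bin normalizes for the unequal sizes of the reward and non-reward sets.
Spike-associated bins are those followed, after a fixed 84 ms lag, by at
least one spike of the unit (half-open windows; counted once per bin per
unit). Excess bias is the spike-associated-bin proportion minus the
all-replay-bin proportion; the default chi-square is the one-sample
proportion test against the replay-bin proportion as a fixed reference
(`n (p - p0)^2 / (p0 (1 - p0))`, df 1), with a two-sample 2x2 switch. The
published statistics for this contrast could not be reproduced exactly by
either construction, so the simpler one-sample form is the default and the
choice is isolated in `excess_bias_chi2()`.

The RR-versus-nonRR contrast uses a logistic regression of the indicator
on group, comparison and their interaction, with the reference bins
occupying the group-0 cell of both comparisons. For this saturated binary
design the interaction MLE and its standard error have closed forms
(differences of empirical log-odds; inverse Fisher information), which the
package uses directly — the permutation calibration refits thousands of
times — and which a unit test verifies against `stats::glm`. The one-tail
permutation null perturbs each cell's proportion around the overall mean
with a Gaussian whose s.d. is calibrated by bisection (at most 20 rounds,
200 simulations per round) until the simulated interaction coefficients'
spread matches the observed standard error within 10%; 1000 final
iterations give `p = (1 + k) / (n + 1)`. The lag sweep recomputes the
excess at delays 0-200 ms in 25 ms steps; coupling injected at 84 ms peaks
at the 75 ms grid point because the 75 ms selection window [75, 100) ms
overlaps the true delay most.

## SWS frames

SWS epochs have a theta/delta (4-12 / 1-4 Hz) power ratio below 1 in 10 s
windows hopped by 5 s. Within SWS, population counts in 10 ms bins
smoothed with a 30 ms Gaussian are thresholded at the first local minimum
of the spike-count histogram (the notch between the silent and active
modes); a unimodal histogram falls back to a quantile with a warning.
Frame statistics are the per-frame duration, SPW-R rate (event midpoints
per second), spatial content (mean over 25 ms bins of the maximum decoded
probability), and per-unit rate, with splits of unit rate by
above/below-mean SPW-R rate and spatial content, and the inverse split of
content by unit rate.

# The synthetic generator

`sim_config()` fixes the study conditions; one master seed drives named
substreams per stage, so a seed fully determines a session and stages can
be regenerated independently.

Behavior: linear 200 cm track (or the five-segment end-to-end T-maze with
100 cm segments and 300 cm reward-to-reward trajectories), log-normal
self-paced dwells (median 9 s), traversals with a raised-cosine speed
profile around a 40 cm/s mean, jittered 25% per leg — real traversal
durations vary, and without that variability alternating 1 s
train/test blocks would alias with position and direction. On the choice
task the correct test-phase turn is opposite the forced sample turn, with
errors injected uniformly at 0.25.

Hippocampus: 30 place cells tile the track with 10 cm Gaussian tuning,
15 Hz peaks, direction preference (opposite-direction rate scaled by 0.2),
and theta modulation at 8 Hz with depth 0.5. Marks are 4-D Gaussians
(s.d. 15 uV) around centroids rejection-sampled at least 40 uV apart, so
clusterless decoding is possible without perfect separability. During
pauses, SPW-R events arrive at 0.3 Hz; a quarter carry constant-speed
trajectories (5 m/s, anchored to a reward region with probability 0.7),
sampled at 1 ms and emitted as an inhomogeneous Poisson with a 6x tuning
gain plus a 3 Hz per-cell burst baseline — the non-spatial component of
the population burst, which keeps event peaks detectable at the 4 s.d.
criterion wherever the trajectory runs. Nonreplay events draw content
i.i.d. per 25 ms step. Event content, like event decoding, lives on the
absolute 25 ms grid. The LFP carries theta during run, 180 Hz ripple
bursts during events, and white noise.

VTA: units are RR or nonRR; RR units multiply their rate by configurable
gains in the approach/acquisition windows (correct versus error), by
`vta_spwr_gain` in a window delayed 84 ms after event onset — either for
every event or, with `vta_coupling = "reward"`, only while the concurrent
true trajectory occupies a reward region — and are von Mises theta-locked
(`kappa_true`, nonRR units at half). The VTA LFP carries a negative
deflection 84 ms after each event onset. Waveforms are parametric biphasic
templates with known landmark positions, wide for RR units.

SWS: frames (log-normal, median 2 s) alternate with silent periods
(median 1 s); cells fire at 12 Hz inside frames and 0.05 Hz outside —
chosen so the 10 ms spike-count histogram is clearly bimodal, as it is in
real up/down alternation — with SPW-Rs only inside frames at per-frame
rates drawn log-normally around the mean, and VTA rates scaled by 0.5,
optionally with an extra RR gain in frames whose SPW-R rate is above the
mean.

What the generator does not emulate: biophysical LFP shape, spike
waveform dynamics beyond the four amplitudes and two summary metrics,
theta sequences within run epochs, behavioral vacillation, and
non-stationarity across a session. Passing tests therefore demonstrate
that the estimators recover what they are defined to recover under
realistic rates and geometry — not that they are robust to every artifact
of real tetrode data.

# Validation conditions and problem sizes

The package validates itself on these conditions (chosen once for adequate
statistical power at comfortable runtimes, and reported by
`scripts/acceptance.R`):

- Decoder recovery: one default session (30 cells, about 10 minutes,
  40 trials); clusterless cross-validated median error is required within
  one 10 cm bin. Typical runs give 5-9 cm with direction error below 10%.
- Replay calibration: 500 null events assembled by the pseudo-event
  generative process must yield at most 7% replay classifications at 250
  shuffles; 200 injected constant-speed events (a replay-rich session:
  SPW-R rate 0.6 Hz, replay fraction 0.85) must exceed 80% sensitivity.
- Column-cycle null: p-values on row-shifted events are checked for
  uniformity (KS) — the shuffle's own null must be honest.
- Modulation depth: gains 0.5/2/3 injected into 400 ms events recover
  depths 0.5/1/2 within 0.15; 400 ms events are used because 50 ms
  smoothing of shorter events pulls the midpoint rate toward baseline,
  which is a property of the estimator worth knowing, not a bug.
- Coupling: sessions with reward-restricted VTA gain (gain 8, baseline
  4 Hz, replay speed 3.5 m/s, 40 trials) — a lower baseline keeps
  spike-associated bins from being dominated by chance associations, and
  the slower replay speed leaves more than one 25 ms bin inside a 10 cm
  reward region per event. RR excess bias must be positive with the
  permutation interaction test below 0.05 in most seeds, nonRR excess
  within noise, and the pooled lag sweep peaking at 75 ms.
- Frames: 600 s SWS epochs with a 0.7x RR gain in SPW-R-rich frames must
  give negative high-minus-low rate differences in at least 90% of seeds.

Numerical conventions used throughout: intervals are half-open `[start,
end)` in seconds; spatial bins are 0-based with centers at
`(i + 0.5) * 10` cm; MAP ties break toward the lowest bin index;
likelihoods are accumulated in log space and renormalized per row (no NaN
rows); Monte Carlo p-values use the plus-one rule; per-event shuffle RNG
streams are indexed by event id, so results do not depend on processing
order; logit cells get a Haldane 0.5 correction.

# Known limitations

The trajectory grid quantizes positions at 1 cm and speeds at 0.25 m/s;
scores of trajectories near band edges can differ from the continuous
ideal by a bin's mass. The one-sample chi-square treats the replay-bin
proportion as fixed, which is anticonservative when the reference sample
is small — the two-sample switch is the remedy. Frame detection assumes a
bimodal spike-count histogram; sparse recordings (population rates near or
below one spike per 10 ms bin inside frames) defeat the first-minimum rule
and trigger the quantile fallback. The linear-track geometry uses a single
candidate path with signed speeds; on the T-maze the four reward-to-reward
paths overlap on the central arm, so a trajectory confined there fits all
four and path identity is not meaningful for such events.
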