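#' Reference per-session replay counts
#'
#' Per-session counts of replay-classified and total SPW-R events from the
#' original five-animal tetrode dataset this pipeline re-implements (14
#' behavioral sessions with reconstruction-grade hippocampal data; the two
#' sessions of the fifth animal lacked sufficient hippocampal activity for
#' position reconstruction and carry no replay count). Used for the
#' worked-example arithmetic in the acceptance checks: the proportion of
#' SPW-R events classified replay and its across-session mean.
#'
#' @return data frame with `rat`, `session`, `replay`, `total`.
#' @export
reference_session_counts <- function() {
  data.frame(
    rat = c(1, 1, 1, 1, 1, 2, 2, 2, 3, 3, 4, 4, 4, 4),
    session = c(1:5, 1:3, 1:2, 1:4),
    replay = c(173, 141, 92, 71, 55, 120, 48, 68, 78, 30, 65, 53, 49, 64),
    total = c(798, 434, 425, 344, 203, 377, 210, 219, 241, 93, 328, 275,
              234, 464))
}

#' Reference counts of replay events by reward-site location
#'
#' Counts of replay events at forced versus choice reward locations in the
#' same reference dataset (replay events at reward sites on the SWM task).
#'
#' @return list with `forced` and `choice` event counts.
#' @export
reference_replay_locations <- function() {
  list(forced = 703, choice = 173, total = 876)
}
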