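#' Block-design run schedule
#'
#' Timing of one scanner run of the two-exemplar block design.  A run is
#' divided into `subruns_per_run` equal subruns; each subrun contains
#' `blocks_per_subrun` stimulus blocks (half per exemplar, exemplars
#' alternating across blocks, and the leading exemplar alternating across
#' subruns: A,B,A,B,... in subrun 1, B,A,B,A,... in subrun 2, and so on).
#' During a block, individual phase-randomized presentations occur at
#' `1 / (stim_duration + isi)` Hz.  Blocks are separated by
#' `interblock_gap`-s and subruns by `intersubrun_gap`-s fixation periods.
#' The defaults give 14-s blocks of 28 presentations at 2 Hz, and a 504-s
#' (252-volume) run.
#'
#' @param subruns_per_run,blocks_per_subrun Design counts;
#'   `blocks_per_subrun` must be even.
#' @param block_duration,interblock_gap,intersubrun_gap Seconds.
#' @param stim_duration,isi Presentation timing in seconds.
#' @param TR Repetition time in seconds; must divide the run length.
#' @param lead_in,lead_out Fixation at run start/end, seconds (the lead-in
#'   also covers the initial volumes discarded before modeling).
#' @return An object of class `run_schedule` with elements `blocks`
#'   (data.frame: subrun, block, exemplar, onset, duration), `events`
#'   (data.frame of individual presentations: onset, duration, exemplar,
#'   subrun, block), `n_volumes`, `TR`, `run_duration`, and the parameters.
#' @examples
#' sch <- schedule_runs()
#' table(sch$blocks$exemplar, sch$blocks$subrun)
#' @export
schedule_runs <- function(subruns_per_run = 4, blocks_per_subrun = 6,
                          block_duration = 14, interblock_gap = 2,
                          intersubrun_gap = 24, stim_duration = 0.25,
                          isi = 0.25, TR = 2, lead_in = 28, lead_out = 28) {
  if (block_duration <= 0 || TR <= 0 || stim_duration <= 0 || isi < 0 ||
      blocks_per_subrun %% 2 != 0) {
    stop("invalid design")
  }
  period <- stim_duration + isi
  n_pres <- floor(block_duration / period)
  if (n_pres < 1) stop("invalid design: block shorter than one presentation")

  blocks <- NULL
  t <- lead_in
  for (s in seq_len(subruns_per_run)) {
    lead <- if (s %% 2 == 1) c("A", "B") else c("B", "A")
    ex <- rep_len(lead, blocks_per_subrun)
    for (b in seq_len(blocks_per_subrun)) {
      blocks <- rbind(blocks, data.frame(
        subrun = s, block = b, exemplar = ex[b],
        onset = t, duration = block_duration))
      t <- t + block_duration + if (b < blocks_per_subrun) interblock_gap else 0
    }
    t <- t + if (s < subruns_per_run) intersubrun_gap else 0
  }
  run_duration <- t + lead_out
  if (abs(run_duration %% TR) > 1e-9 &&
      abs(run_duration %% TR - TR) > 1e-9) {
    stop("invalid design: TR does not divide the run length")
  }
  events <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    data.frame(
      onset = blocks$onset[i] + (seq_len(n_pres) - 1L) * period,
      duration = stim_duration,
      exemplar = blocks$exemplar[i],
      subrun = blocks$subrun[i], block = blocks$block[i])
  }))
  structure(list(
    blocks = blocks, events = events,
    n_volumes = as.integer(round(run_duration / TR)), TR = TR,
    run_duration = run_duration,
    subruns_per_run = subruns_per_run,
    blocks_per_subrun = blocks_per_subrun,
    block_duration = block_duration, interblock_gap = interblock_gap,
    intersubrun_gap = intersubrun_gap, stim_duration = stim_duration,
    isi = isi, lead_in = lead_in, lead_out = lead_out
  ), class = "run_schedule")
}

#' @export
print.run_schedule <- function(x, ...) {
  cat(sprintf(
    "run schedule: %d subruns x %d blocks of %gs, %d volumes at TR = %gs\n",
    x$subruns_per_run, x$blocks_per_subrun, x$block_duration,
    x$n_volumes, x$TR))
  invisible(x)
}
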