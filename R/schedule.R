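#' Generate delay eyeblink conditioning trial schedules
#'
#' Builds one schedule per training session. Each session holds 22 blocks of
#' 10 trials; within a block, 9 trials pair the light CS with the corneal
#' airpuff US and 1 trial presents the CS alone, at a seeded pseudorandom
#' position. The CS lasts 280 ms and the 30 ms US co-terminates with it, so
#' the US starts 250 ms after CS onset on paired trials. Inter-trial
#' intervals are at least 12 s (12 s plus an exponential tail, mean 3 s).
#'
#' @param n_sessions number of training sessions (>= 1).
#' @param seed integer seed; schedules are reproducible given the seed.
#' @param n_blocks,trials_per_block,n_paired block structure; defaults follow
#'   the standard protocol (22 blocks of 10 trials, 9 paired + 1 CS-only).
#' @param cs_duration_ms,us_duration_ms stimulus durations in ms.
#' @param iti_min_s,iti_mean_extra_s inter-trial interval: minimum plus the
#'   mean of the exponential excess.
#' @return list of `trial_schedule` data frames, one per session, with columns
#'   `session`, `block`, `trial_in_block`, `trial_index`, `trial_type`
#'   (`"paired"` or `"cs_only"`), `cs_onset_ms` (0 by convention),
#'   `us_onset_ms` (`NA` on CS-only trials), and `iti_s`.
#' @examples
#' sched <- generate_schedule(1, seed = 7)[[1]]
#' table(sched$trial_type)
#' @export
generate_schedule <- function(n_sessions, seed,
                              n_blocks = 22L, trials_per_block = 10L,
                              n_paired = 9L,
                              cs_duration_ms = 280, us_duration_ms = 30,
                              iti_min_s = 12, iti_mean_extra_s = 3) {
  if (!is.numeric(n_sessions) || length(n_sessions) != 1L || n_sessions < 1 ||
      n_sessions != round(n_sessions)) {
    stop_invalid("`n_sessions` must be a positive integer")
  }
  stopifnot(n_paired < trials_per_block, us_duration_ms < cs_duration_ms)
  us_onset <- cs_duration_ms - us_duration_ms  # co-termination
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_sessions), function(s) {
      n_trials <- n_blocks * trials_per_block
      type <- character(n_trials)
      for (b in seq_len(n_blocks)) {
        blk <- rep("paired", trials_per_block)
        blk[sample.int(trials_per_block, trials_per_block - n_paired)] <- "cs_only"
        type[(b - 1L) * trials_per_block + seq_len(trials_per_block)] <- blk
      }
      sched <- data.frame(
        session = s,
        block = rep(seq_len(n_blocks), each = trials_per_block),
        trial_in_block = rep(seq_len(trials_per_block), n_blocks),
        trial_index = seq_len(n_trials),
        trial_type = type,
        cs_onset_ms = 0,
        us_onset_ms = ifelse(type == "paired", us_onset, NA_real_),
        iti_s = iti_min_s + rexp(n_trials, rate = 1 / iti_mean_extra_s)
      )
      attr(sched, "cs_duration_ms") <- cs_duration_ms
      attr(sched, "us_duration_ms") <- us_duration_ms
      class(sched) <- c("trial_schedule", "data.frame")
      sched
    })
  })
}
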